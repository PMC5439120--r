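test_that("minimum bound is the elementwise maximum over conditions", {
  A <- matrix(0, 2, 2)
  B <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(minimum_bound(list(B)), B)
  expect_equal(minimum_bound(list(A, B)), B)
  g1 <- matrix(c(1, 5, 2, 0), 2); g2 <- matrix(c(3, 1, 2, 2), 2)
  g3 <- matrix(c(0, 0, 9, 1), 2)
  # brute-force elementwise check
  expected <- matrix(mapply(max, g1, g2, g3), 2)
  expect_equal(minimum_bound(list(g1, g2, g3)), expected)
  expect_error(minimum_bound(list(g1, matrix(0, 3, 3))), "shape")
})

test_that("qLE is a squared CDF: bounded, monotone, matches squared ECDF", {
  set.seed(28)
  B <- matrix(rexp(10000), 100)
  G <- matrix(runif(10000, 0, max(B)), 100)
  q <- qle_map(G, B)
  expect_true(all(q >= 0 & q <= 1))
  # monotone in G for fixed B
  ord <- order(G)
  expect_true(all(diff(q[ord]) > -1e-9))
  # squared-ECDF oracle
  E <- stats::ecdf(as.vector(B))
  expect_lt(max(abs(q - matrix(E(G)^2, 100))), 0.02)
  # degenerate bound
  expect_warning(qd <- qle_map(G, matrix(1, 100, 100)), "degenerate")
  expect_true(all(qd == 0.25))
})

test_that("feature extraction labels 8-connected supra-threshold regions", {
  f <- seq(2, 48, length.out = 20)
  tm <- seq(0, 190, by = 10)
  qle <- matrix(0, 20, 20)
  qle[3:5, 4:6] <- 0.9       # low-frequency blob
  qle[15:17, 12:14] <- 0.95  # high-frequency blob
  fs <- extract_features(qle, f, tm, threshold = 0.8)
  expect_length(fs$masks, 2)
  expect_setequal(fs$bands, c("theta", "beta_gamma"))
  expect_equal(sum(fs$masks[[1]] & fs$masks[[2]]), 0)

  # threshold 0: the whole plane is supra-threshold; the single region is
  # split once at the theta / beta-gamma boundary
  all_on <- extract_features(qle, f, tm, threshold = 0)
  expect_true(all(all_on$H))
  expect_length(all_on$masks, 2)
  expect_true(all(Reduce(`|`, all_on$masks)))

  expect_warning(empty <- extract_features(qle, f, tm, threshold = 0.99),
                 "no time-frequency point")
  expect_length(empty$masks, 0)

  # diagonal touching counts as connected (8-connectivity)
  qle2 <- matrix(0, 20, 20)
  qle2[4, 4] <- 1; qle2[5, 5] <- 1
  fs2 <- extract_features(qle2, f, tm, threshold = 0.5)
  expect_length(fs2$masks, 1)
})

test_that("regions spanning the 12 Hz boundary are split into bands", {
  f <- exp(seq(log(2), log(48), length.out = 30))
  tm <- seq(0, 145, by = 5)
  qle <- matrix(0, 30, 30)
  rows <- which(f > 6 & f < 25)
  qle[rows, 10:14] <- 0.9
  fs <- extract_features(qle, f, tm, threshold = 0.8)
  expect_length(fs$masks, 2)
  expect_setequal(fs$bands, c("theta", "beta_gamma"))
  low <- fs$masks[[which(fs$bands == "theta")]]
  expect_true(all(f[rowSums(low) > 0] < 12))
})

test_that("masked marginal distributions follow their defining arithmetic", {
  g <- matrix(0, 4, 6)
  h <- matrix(FALSE, 4, 6)
  g[2, 3] <- 5; h[2, 3] <- TRUE
  d <- feature_distributions(h, g)
  expect_equal(d$y_T, c(0, 0, 5 / 4, 0, 0, 0))
  expect_equal(d$y_F, c(0, 5 / 6, 0, 0))

  # separable blob: marginals proportional to the factors
  u <- c(0, 1, 2, 1); v <- c(0, 1, 3, 2, 1, 0)
  g2 <- u %o% v
  h2 <- g2 > 0
  d2 <- feature_distributions(h2, g2)
  expect_gt(cor(d2$y_T, v), 0.999)
  expect_gt(cor(d2$y_F, u), 0.999)
  expect_true(all(d2$y_T >= 0) && all(d2$y_F >= 0))

  expect_warning(dz <- feature_distributions(matrix(FALSE, 4, 6), g),
                 "empty")
  expect_equal(sum(dz$y_T) + sum(dz$y_F), 0)
})

test_that("centroids land on a constructed Gaussian blob", {
  f <- exp(seq(log(2), log(48), length.out = 64))
  tm <- seq(0, 315, by = 5)
  fi <- which.min(abs(f - 17)); ti <- which.min(abs(tm - 60))
  g <- exp(-outer((seq_len(64) - fi)^2 / 18, (seq_len(64) - ti)^2 / 40, "+"))
  h <- g > 0.3
  cc <- feature_centroids(h, g, f, tm)
  expect_equal(nrow(cc), 1)
  expect_lt(abs(log(cc$freq_hz / 17)), log(f[2] / f[1]) * 1.5)
  expect_lt(abs(cc$latency_ms - 60), 5 + 1e-9)
  expect_lte(cc$rp, max(g[h]))
})

test_that("two separated spectral peaks yield two centroids, high first", {
  f <- exp(seq(log(2), log(48), length.out = 64))
  tm <- seq(0, 315, by = 5)
  mk <- function(fc, tc, sf = 10, st = 30) {
    fi <- which.min(abs(f - fc)); ti <- which.min(abs(tm - tc))
    exp(-outer((seq_len(64) - fi)^2 / sf, (seq_len(64) - ti)^2 / st, "+"))
  }
  g <- mk(34, 30) + mk(17, 60)
  h <- g > 0.25
  cc <- feature_centroids(h, g, f, tm)
  expect_gte(nrow(cc), 2)
  expect_true(all(diff(cc$freq_hz) < 0))  # frequency descending
  expect_lt(abs(log(cc$freq_hz[1] / 34)), 3 * log(f[2] / f[1]))
  expect_lt(abs(log(cc$freq_hz[nrow(cc)] / 17)), 3 * log(f[2] / f[1]))
})

test_that("flat distributions fall back with a warning", {
  g <- matrix(1, 5, 5)
  h <- matrix(TRUE, 5, 5)
  expect_warning(cc <- feature_centroids(h, g, 1:5, 1:5), "flat")
  expect_equal(nrow(cc), 1)
})

test_that("surprise follows its defining log-ratio", {
  expect_equal(surprise(0.3, 0.3, 1), 0)
  expect_equal(surprise(0.2, 0.4, 0.5), 0)
  s1 <- surprise(0.4, 0.5); s2 <- surprise(0.2, 0.5)
  expect_equal(s2 - s1, log(2))
  expect_equal(surprise(0.2, 0.5, 1), -log(0.4), tolerance = 1e-12)
  expect_equal(surprise(0.2, 0.5, 1), 0.9163, tolerance = 1e-4)
  expect_error(surprise(0, 0.5), "dF")
  expect_error(surprise(0.5, -1), "dT")
  expect_error(surprise(0.5, 0.5, 0), "C_cfc")
})

test_that("identical temporal envelopes give near-identical y_T curves", {
  f <- exp(seq(log(2), log(48), length.out = 64))
  tm <- seq(0, 315, by = 5)
  envelope <- exp(-(seq_len(64) - 20)^2 / 50)
  fi_th <- which.min(abs(f - 5)); fi_bg <- which.min(abs(f - 30))
  spec_th <- exp(-(seq_len(64) - fi_th)^2 / 8)
  spec_bg <- exp(-(seq_len(64) - fi_bg)^2 / 8)
  g <- spec_th %o% envelope + spec_bg %o% envelope
  h_th <- (spec_th %o% envelope) > 0.1
  h_bg <- (spec_bg %o% envelope) > 0.1
  y1 <- feature_distributions(h_th, g)$y_T
  y2 <- feature_distributions(h_bg, g)$y_T
  expect_gt(cor(y1, y2), 0.9)
})

test_that("shrinking the theta separation moves surprise as the model predicts", {
  # overlap-based estimator on constructed marginals: closer theta-1/theta-2
  # distributions raise dF and dT, lowering the evidence for a difference
  grid <- seq_len(100)
  mk_d <- function(mu_f, mu_t) list(
    y_F = exp(-(grid - mu_f)^2 / 40),
    y_T = exp(-(grid - mu_t)^2 / 160))
  fake_fs <- function(sep) {
    structure(list(distributions = list(
      theta1 = list(c1 = mk_d(30, 30)),
      theta2 = list(c1 = mk_d(30 + sep, 30 + 3 * sep))),
      centroids = data.frame()), class = "mmr_features")
  }
  s_wide <- mmr_surprise(fake_fs(30), "c1")
  s_narrow <- mmr_surprise(fake_fs(10), "c1")
  expect_gt(s_narrow$dF, s_wide$dF)
  expect_gt(s_narrow$dT, s_wide$dT)
  expect_equal(s_wide$S, -log(s_wide$dF / s_wide$dT), tolerance = 1e-12)
})
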