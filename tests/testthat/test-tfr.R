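test_that("whitening yields unit variance on the retained trial subspace", {
  set.seed(10)
  X <- matrix(rnorm(30 * 400), 30) * seq(0.5, 3, length.out = 30)
  ep <- make_epochs(X, rep(c("standard", "deviant"), 15))
  w <- whiten_trials(ep)
  Xc <- w$trials - rowMeans(w$trials)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  keep <- ev > 1e-6
  expect_true(all(abs(ev[keep] - 1) < 0.05))
})

test_that("already-white data keep their total variance through whitening", {
  set.seed(11)
  X <- matrix(rnorm(40 * 2000), 40)
  ep <- make_epochs(X, rep("standard", 40))
  w <- whiten_trials(ep)
  v_in <- sum((X - rowMeans(X))^2)
  v_out <- sum((w$trials - rowMeans(w$trials))^2)
  expect_equal(v_out / v_in, 1, tolerance = 0.05)
})

test_that("whitening retains exactly the components above threshold", {
  set.seed(12)
  # construct a trial covariance with one dominant direction and the rest
  # far below the retention threshold
  n <- 12
  u <- rnorm(n); u <- u / sqrt(sum(u^2))
  base <- matrix(rnorm(n * 500, sd = 1e-5), n)
  X <- u %o% rnorm(500) * 100 + base
  ep <- make_epochs(X, rep("standard", n))
  w <- whiten_trials(ep, min_pvaf = 1e-4)
  expect_equal(attr(w, "whitening")$retained, 1L)
  expect_equal(sum(attr(w, "whitening")$pvaf >= 1e-4), 1L)
  expect_error(whiten_trials(make_epochs(matrix(1:5, 1), "standard")),
               "2 trials")
})

test_that("Morlet center frequencies span 1.94-48.40 Hz with constant ratio", {
  f <- morlet_center_freqs()
  expect_length(f, 128)
  expect_equal(f[1], 1.94, tolerance = 0.005 * 1.94)
  expect_equal(f[128], 48.40, tolerance = 0.005 * 48.40)
  ratios <- f[-1] / f[-128]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_true(all(diff(f) > 0))
})

test_that("CWT of a pure sinusoid peaks at the nearest scale", {
  fs <- 250
  tgrid <- seq(-500, 1500 - 1000 / fs, by = 1000 / fs)
  x <- sin(2 * pi * 10 * tgrid / 1000)
  ep <- make_epochs(matrix(x, 1, byrow = TRUE)[rep(1, 2), ],
                    c("standard", "deviant"), fs = fs)
  tens <- cwt_morlet(ep)
  mid <- which(tens$time_ms > -100 & tens$time_ms < 700)
  prof <- colMeans(Mod(tens$coeffs[1, mid, ]))
  # oracle: the analytic response of the unit-energy Morlet bank to a
  # sinusoid at f0 is sqrt(s) * exp(-(s w0' - w0)^2 / 2); its argmax over
  # the discrete scale set is the expected peak
  scales <- 6 / (2 * pi * tens$scale_freqs_hz)
  resp <- sqrt(scales) * exp(-(scales * 2 * pi * 10 - 6)^2 / 2)
  expect_equal(which.max(prof), which.max(resp))
  # ... which sits within one scale step of the carrier
  expect_lte(abs(which.max(prof) -
                   which.min(abs(tens$scale_freqs_hz - 10))), 1)
})

test_that("CWT of a unit impulse gives a time-symmetric ridge at zero", {
  fs <- 250
  n <- 500
  x <- numeric(n); x[n / 2] <- 1
  ep <- make_epochs(matrix(x, 1)[rep(1, 2), ], c("standard", "deviant"),
                    fs = fs, t0_ms = -n / 2 / fs * 1000)
  tens <- cwt_morlet(ep, fmin = 4, fmax = 40)
  mag <- Mod(tens$coeffs[1, , ])
  peak_t <- apply(mag, 2, which.max)
  expect_true(all(abs(tens$time_ms[peak_t]) < 1000 / fs + 1e-9))
  # symmetry around the impulse
  k <- 30
  i0 <- n / 2
  expect_equal(mag[i0 + 1:k, 64], mag[i0 - (1:k) + 0, 64], tolerance = 1e-6)
})

test_that("CWT energy obeys the filter-bank Parseval identity per trial", {
  # oracle: for each trial, the total CWT energy must equal the FFT energy
  # weighted by the bank's analytic aggregate transfer function
  # sum_k |Psi_hat(s_k w)|^2; trial length a power of two so the transform
  # is unpadded and the identity exact
  set.seed(13)
  fs <- 200
  n <- 512
  X <- matrix(rnorm(12 * n), 12)
  ep <- make_epochs(X, rep(c("standard", "deviant"), 6), fs = fs)
  tens <- cwt_morlet(ep, n_scales = 64)
  scales <- 6 / (2 * pi * tens$scale_freqs_hz)
  omega <- 2 * pi * fs * c(0:(n / 2), (n / 2 + 1):(n - 1) - n) / n
  pos <- omega > 0
  w_agg <- numeric(n)
  for (s in scales) {
    psi2 <- numeric(n)
    psi2[pos] <- (pi^(-0.25) * sqrt(2 * pi * s * fs) *
                    exp(-(s * omega[pos] - 6)^2 / 2))^2
    w_agg <- w_agg + psi2
  }
  e_tf <- apply(tens$coeffs, 1, function(m) sum(Mod(m)^2))
  e_ref <- apply(X, 1, function(x) sum(Mod(fft(x))^2 * w_agg) / n)
  expect_equal(e_tf, e_ref, tolerance = 1e-8)
  expect_gt(cor(e_tf, e_ref), 0.99)
})

test_that("truncation crops to -100..700 ms and zeroes the baseline mean", {
  fs <- 1000
  tgrid <- seq(-500, 1500, by = 1000 / fs)
  x <- sin(2 * pi * 8 * tgrid / 1000)
  ep <- make_epochs(matrix(x, 1)[rep(1, 10), ], rep(c("standard", "deviant"), 5),
                    fs = fs)
  tens <- truncate_and_baseline(cwt_morlet(ep, n_scales = 32))
  expect_equal(range(tens$time_ms), c(-100, 700))
  expect_length(tens$time_ms, 801)
  b <- tens$time_ms >= -100 & tens$time_ms < 0
  mu <- apply(tens$coeffs[, b, ], c(1, 3), mean)
  expect_lt(max(Mod(mu)), 1e-10)
})

test_that("a post-stimulus burst survives truncation nearly untouched", {
  fs <- 250
  tgrid <- seq(-500, 1500 - 1000 / fs, by = 1000 / fs)
  x <- ifelse(tgrid >= 200 & tgrid <= 400,
              sin(2 * pi * 20 * tgrid / 1000), 0)
  ep <- make_epochs(matrix(x, 1)[rep(1, 2), ], c("standard", "deviant"),
                    fs = fs)
  full <- cwt_morlet(ep)
  tb <- truncate_and_baseline(full)
  k20 <- which.min(abs(tb$scale_freqs_hz - 20))
  sel_full <- full$time_ms >= 250 & full$time_ms <= 350
  sel_tb <- tb$time_ms >= 250 & tb$time_ms <= 350
  a <- Mod(full$coeffs[1, sel_full, k20])
  b <- Mod(tb$coeffs[1, sel_tb, k20])
  expect_equal(a, b, tolerance = 0.01)
  # pre-stimulus region is near zero relative to the burst
  pre <- Mod(tb$coeffs[1, tb$time_ms < 0, k20])
  expect_lt(max(pre), 0.05 * max(b))
})

test_that("magnitude rejection drops exactly the inflated trial", {
  set.seed(14)
  n_tr <- 100
  coeffs <- array(complex(real = rnorm(n_tr * 50 * 8),
                          imaginary = rnorm(n_tr * 50 * 8)),
                  c(n_tr, 50, 8))
  coeffs[42, , ] <- coeffs[42, , ] * 10
  tens <- structure(list(coeffs = coeffs,
                         scale_freqs_hz = morlet_center_freqs(8, 2, 40),
                         time_ms = seq_len(50), labels = rep("standard", n_tr),
                         fs = 250, coi = rep(0, 8)),
                    class = "tf_tensor")
  out <- reject_magnitude(tens, z = 2.5)
  expect_equal(attr(out, "n_rejected"), 1L)
  expect_equal(dim(out$coeffs)[1], n_tr - 1)

  # identical trials: nothing rejected; z = Inf: nothing rejected
  same <- tens; same$coeffs[] <- 1 + 1i
  expect_equal(attr(reject_magnitude(same), "n_rejected"), 0L)
  expect_equal(attr(reject_magnitude(tens, z = Inf), "n_rejected"), 0L)
})

test_that("epochs too short for the widest wavelet are refused", {
  ep <- make_epochs(matrix(rnorm(2 * 100), 2), c("standard", "deviant"),
                    fs = 250)
  expect_error(cwt_morlet(ep), "cone-of-influence")
})
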