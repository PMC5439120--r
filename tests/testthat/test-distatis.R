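# Independent dense-algebra helpers used as oracles: written naively with
# explicit matrix products, no reuse of package internals.
naive_center_normalize <- function(cp) {
  n <- nrow(cp)
  m <- rep(1 / n, n)
  Xi <- diag(n) - rep(1, n) %*% t(m)
  S <- -0.5 * Xi %*% cp %*% t(Xi)
  ev <- eigen(S, symmetric = TRUE)$values
  l1 <- ev[which.max(abs(ev))]
  S / l1
}

test_that("cross-product matrices obey Gram-matrix duality", {
  set.seed(20)
  p <- matrix(rnorm(6 * 9), 6)
  cp <- cross_products(p)
  ev_f <- eigen(cp$CP_F, symmetric = TRUE, only.values = TRUE)$values
  ev_t <- eigen(cp$CP_T, symmetric = TRUE, only.values = TRUE)$values
  nz <- ev_f[ev_f > 1e-8]
  expect_equal(sort(nz), sort(ev_t[ev_t > 1e-8]), tolerance = 1e-8)

  # rank-1 surface
  u <- rnorm(6); v <- rnorm(9)
  cp1 <- cross_products(u %o% v)
  expect_equal(cp1$CP_F, (u %o% u) * sum(v^2), tolerance = 1e-10)

  # small-integer toy against hand arithmetic
  toy <- matrix(c(1, 2, 0, 3, 1, 1, 2, 0, 1, 1, 0, 2), 3, 4)
  cpt <- cross_products(toy)
  expect_equal(cpt$CP_F, toy %*% t(toy))
  expect_equal(cpt$CP_F[1, 1], sum(toy[1, ]^2))
  expect_equal(cpt$CP_T[2, 3], sum(toy[, 2] * toy[, 3]))
})

test_that("double centering gives zero means and unit first eigenvalue", {
  set.seed(21)
  p <- matrix(runif(5 * 7), 5)
  cp <- cross_products(p)
  S <- center_and_normalize(cp$CP_F)
  expect_lt(max(abs(rowMeans(S))), 1e-10)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), 1, tolerance = 1e-10)
  # matches the naive textbook computation
  expect_equal(unclass(S), naive_center_normalize(cp$CP_F),
               tolerance = 1e-10, ignore_attr = TRUE)

  # 4x4 toy
  cp4 <- crossprod(matrix(c(2, 0, 1, 3, 1, 1, 0, 2, 0, 2, 2, 1, 1, 0, 1, 1),
                          4, 4))
  expect_equal(unclass(center_and_normalize(cp4)),
               naive_center_normalize(cp4),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(center_and_normalize(matrix(0, 3, 3)), "degenerate")
})

test_that("compromises weight conditions equally regardless of size", {
  A <- diag(3); B <- 2 * diag(3); C <- 4 * diag(3)
  S_list <- c(replicate(2, A, simplify = FALSE),
              replicate(2, B, simplify = FALSE),
              replicate(200, C, simplify = FALSE))
  cond <- c(rep("a", 2), rep("b", 2), rep("c", 200))
  comp <- build_compromise(S_list, cond)
  expect_equal(comp$compromise, (A + B + C) / 3)

  # identical inputs pass through
  same <- build_compromise(replicate(4, B, simplify = FALSE), rep("x", 4))
  expect_equal(same$compromise, B)

  # PSD preserved under the convex combination
  set.seed(22)
  mk_psd <- function() { m <- matrix(rnorm(16), 4); crossprod(m) }
  ps <- replicate(6, mk_psd(), simplify = FALSE)
  cc <- build_compromise(ps, rep(c("a", "b"), 3))
  expect_true(all(eigen(cc$compromise, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("eigenvector weights follow the sqrt-eigenvalue pvaf rule", {
  fake <- function(vals, vecs) list(values = vals, vectors = vecs,
                                    compromise = NULL,
                                    condition_compromises = NULL)
  cF <- fake(c(4, 1), diag(2))
  cT <- fake(c(4, 1), diag(2))
  cs <- select_weights(cF, cT, pvaf_min = 0.01)
  expect_equal(cs$pvaf_F, c(2 / 3, 1 / 3))
  expect_equal(cs$rc_F, 0.5)
  expect_equal(cs$rc_T, 0.5)

  set.seed(23)
  m1 <- crossprod(matrix(rnorm(25), 5)); m2 <- crossprod(matrix(rnorm(36), 6))
  e1 <- eigen(m1, symmetric = TRUE); e2 <- eigen(m2, symmetric = TRUE)
  cs2 <- select_weights(fake(e1$values, e1$vectors),
                        fake(e2$values, e2$vectors))
  expect_equal(cs2$rc_F + cs2$rc_T, 1, tolerance = 1e-12)
  norms <- apply(cs2$W_F, 2, function(v) sum(v^2))
  expect_equal(norms, rep(1, ncol(cs2$W_F)), tolerance = 1e-12)
})

test_that("projection is the identity for a complete basis and idempotent", {
  set.seed(24)
  p <- matrix(runif(5 * 6), 5)
  grp <- mmr_group(list(p, p + matrix(rnorm(30, sd = 0.1), 5)),
                   c("a", "a"), pvaf_min = 0)   # retain everything
  cs <- grp$weights
  P <- project_surface(p, cs)
  expect_equal(P, p, tolerance = 1e-8)

  # idempotence on a truncated basis
  cs$W_F <- cs$W_F[, 1:2, drop = FALSE]
  cs$W_T <- cs$W_T[, 1:2, drop = FALSE]
  P1 <- project_surface(p, cs)
  # re-project the spectral part: the operator applied twice equals once
  cmF <- colMeans(p)
  projF <- function(x) cs$W_F %*% crossprod(cs$W_F, sweep(x, 2, colMeans(x))) +
    rep(1, nrow(x)) %o% colMeans(x)
  expect_equal(projF(projF(p)), projF(p), tolerance = 1e-10)

  # surfaces built from discarded eigenvectors project to zero (use
  # eigenvectors with nonzero eigenvalue: the last one spans the centering
  # null space and is not part of either subspace)
  disc_F <- grp$weights$W_F[, 3, drop = FALSE]
  disc_T <- grp$weights$W_T[, 3, drop = FALSE]
  cs2 <- grp$weights
  cs2$W_F <- grp$weights$W_F[, 1:2, drop = FALSE]
  cs2$W_T <- grp$weights$W_T[, 1:2, drop = FALSE]
  orth <- disc_F %*% t(disc_T)
  expect_lt(max(abs(project_surface(orth, cs2))), 1e-10)

  # truncation never increases the Frobenius norm
  expect_lte(sqrt(sum(P1^2)), sqrt(sum(p^2)) + 1e-12)
})

test_that("aggregation means by condition then rescales into [0, 1]", {
  set.seed(25)
  Ps <- replicate(4, matrix(rnorm(12), 3), simplify = FALSE)
  agg <- aggregate_projections(Ps, c("a", "b", "b", "c"))
  expect_equal(agg$g$a * (agg$rescale_range[2] - agg$rescale_range[1]) +
                 agg$rescale_range[1], Ps[[1]], tolerance = 1e-12)
  expect_equal(max(c(unlist(agg$g), agg$G)), 1)
  expect_gte(min(c(unlist(agg$g), agg$G)), 0)

  all_same <- aggregate_projections(replicate(3, Ps[[1]], simplify = FALSE),
                                    c("a", "b", "c"), rescale = FALSE)
  expect_equal(all_same$G, Ps[[1]])
})

test_that("duplicating every member of one condition leaves G unchanged", {
  set.seed(26)
  surfs <- replicate(6, matrix(runif(25), 5), simplify = FALSE)
  cond <- rep(c("a", "b", "c"), each = 2)
  g1 <- mmr_group(surfs, cond)
  g2 <- mmr_group(c(surfs, surfs[cond == "b"]), c(cond, "b", "b"))
  expect_equal(g1$G, g2$G, tolerance = 1e-10)
})

test_that("the full chain matches an independent dense-algebra oracle", {
  set.seed(27)
  surfs <- replicate(6, matrix(runif(25), 5), simplify = FALSE)
  cond <- rep(c("a", "b", "c"), each = 2)
  grp <- mmr_group(surfs, cond, pvaf_min = 0.01)

  # --- oracle: plain loops and dense eigen calls ---
  SF <- list(); ST <- list()
  for (i in seq_along(surfs)) {
    p <- surfs[[i]]
    SF[[i]] <- naive_center_normalize(p %*% t(p))
    ST[[i]] <- naive_center_normalize(t(p) %*% p)
  }
  mean_mats <- function(lst) Reduce(`+`, lst) / length(lst)
  comp <- function(S_list) {
    by_cond <- lapply(unique(cond), function(d) mean_mats(S_list[cond == d]))
    mean_mats(by_cond)
  }
  CF <- comp(SF); CT <- comp(ST)
  eF <- eigen(CF, symmetric = TRUE); eT <- eigen(CT, symmetric = TRUE)
  pick <- function(e) {
    pv <- sqrt(pmax(e$values, 0)) / sum(sqrt(pmax(e$values, 0)))
    W <- e$vectors[, pv >= 0.01, drop = FALSE]
    for (j in seq_len(ncol(W))) {
      W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
      W[, j] <- W[, j] * sign(W[which.max(abs(W[, j])), j])
    }
    W
  }
  WF <- pick(eF); WT <- pick(eT)
  rcF <- max(eF$values) / (max(eF$values) + max(eT$values))
  rcT <- 1 - rcF
  proj <- function(p) {
    K <- nrow(p); J <- ncol(p)
    cm <- rep(1, K) %*% t(colMeans(p))
    pF <- WF %*% t(WF) %*% (p - cm) + cm
    rm_ <- rowMeans(p) %*% t(rep(1, J))
    pT <- WT %*% t(WT) %*% t(p - rm_) + t(rm_)
    pF * rcF + t(pT * rcT)
  }
  P <- lapply(surfs, proj)
  gs <- lapply(unique(cond), function(d) mean_mats(P[cond == d]))
  G <- mean_mats(gs)
  rng <- range(c(unlist(gs), G))
  G <- (G - rng[1]) / (rng[2] - rng[1])

  expect_lt(max(abs(grp$weights$rc_F - rcF)), 1e-10)
  expect_lt(max(abs(grp$G - G)), 1e-8)
})
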