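# Modified joint DISTATIS over spectral and temporal cross-product
# matrices: double centering, first-eigenvalue normalization, condition and
# grand compromises, eigenvector weight selection, and the weighted joint
# projection of each surface.

#' Spectral and temporal cross-product matrices of a surface
#'
#' @param p scales x time surface (matrix or `mmr_tf`).
#' @return list with `CP_F` (scales x scales) and `CP_T` (time x time).
#' @export
cross_products <- function(p) {
  if (inherits(p, "mmr_tf")) p <- p$p
  p <- as.matrix(p)
  if (any(!is.finite(p))) stop("surface contains non-finite values")
  list(CP_F = tcrossprod(p), CP_T = crossprod(p))
}

#' Double-center and first-eigenvalue-normalize a cross-product matrix
#'
#' Applies the MDS centering operator S = -1/2 Xi CP Xi' with
#' Xi = I - 1 m' (uniform masses m = 1/n), then divides by the first
#' (largest-magnitude) eigenvalue so every input matrix enters the
#' compromise on the same scale. For a positive semidefinite cross-product
#' input that eigenvalue is negative, so the division also restores
#' positive semidefiniteness: the result has zero row and column means and
#' unit first eigenvalue.
#'
#' @param cp square symmetric matrix.
#' @param masses per-point mass vector summing to 1 (default uniform).
#' @return the normalized matrix S with attribute `lambda1` (the
#'   pre-normalization first eigenvalue).
#' @export
center_and_normalize <- function(cp, masses = NULL) {
  cp <- as.matrix(cp)
  n <- nrow(cp)
  stopifnot(n == ncol(cp))
  m <- masses %||% rep(1 / n, n)
  stopifnot(length(m) == n, abs(sum(m) - 1) < 1e-8)
  # Xi %*% cp %*% t(Xi) expanded: cp - 1 m'cp - cp m 1' + (m'cp m) 1 1'
  mc <- as.vector(crossprod(m, cp))     # m' cp (row vector)
  cm <- as.vector(cp %*% m)             # cp m
  mm <- sum(mc * m)
  S <- -0.5 * (cp - rep(1, n) %o% mc - cm %o% rep(1, n) + mm)
  # for a PSD cross-product matrix, -1/2 Xi CP Xi' is negative semidefinite:
  # its first (largest-magnitude) eigenvalue is negative, and dividing by it
  # yields a PSD matrix with unit top eigenvalue
  l1 <- top_eigenvalue(S)
  if (!is.finite(l1) || l1 == 0) {
    stop("degenerate surface: first eigenvalue of the centered ",
         "cross-product is zero")
  }
  S <- S / l1
  attr(S, "lambda1") <- l1
  S
}

# largest eigenvalue of a symmetric PSD matrix via power iteration
top_eigenvalue <- function(A, tol = 1e-12, max_iter = 1000L) {
  n <- nrow(A)
  # deterministic non-constant start: the constant vector is annihilated by
  # double-centered matrices, so seed with an oscillating profile instead
  v <- sin(seq_len(n)) + seq_len(n) / n
  v <- v / sqrt(sum(v^2))
  l_old <- 0
  for (i in seq_len(max_iter)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.vector(w) / nw
    l <- as.vector(crossprod(v, A %*% v))
    if (abs(l - l_old) < tol * max(abs(l), 1)) break
    l_old <- l
  }
  l
}

#' Build condition and grand compromises
#'
#' The condition compromise is the unweighted mean of that condition's
#' normalized matrices; the grand compromise is the mean of the condition
#' compromises, so conditions are equi-weighted regardless of how many
#' members each contains.
#'
#' @param S_list list of normalized matrices (same shape).
#' @param condition factor/character vector, one entry per matrix.
#' @return list with `condition_compromises` (named list), `compromise`
#'   (the grand mean), `values`/`vectors` (its eigendecomposition).
#' @export
build_compromise <- function(S_list, condition) {
  stopifnot(length(S_list) == length(condition), length(S_list) > 0)
  condition <- as.character(condition)
  conds <- unique(condition)
  cc <- lapply(conds, function(d) {
    members <- S_list[condition == d]
    if (length(members) == 0) stop("condition '", d, "' is empty")
    Reduce(`+`, members) / length(members)
  })
  names(cc) <- conds
  C <- Reduce(`+`, cc) / length(cc)
  e <- eigen(C, symmetric = TRUE)
  list(condition_compromises = cc, compromise = C,
       values = e$values, vectors = e$vectors)
}

#' Select eigenvector weights and relative contributions
#'
#' pvaf per eigenvector is sqrt(lambda) / sum(sqrt(lambda)) over the
#' non-negative eigenvalues; eigenvectors with pvaf >= `pvaf_min` are
#' retained and renormalized to unit L2 norm, with the sign convention that
#' each vector's largest-magnitude element is positive. The relative
#' contribution of a dimension is its first eigenvalue over the sum of the
#' two dimensions' first eigenvalues.
#'
#' @param comp_F,comp_T results of [build_compromise()] for the spectral
#'   and temporal dimensions.
#' @param pvaf_min retention threshold (default 0.01).
#' @return object of class `compromise_set`: `W_F`, `W_T` (columns =
#'   retained unit eigenvectors), `pvaf_F`, `pvaf_T`, `rc_F`, `rc_T`, and
#'   the two compromise results.
#' @export
select_weights <- function(comp_F, comp_T, pvaf_min = 0.01) {
  pick <- function(comp) {
    ev <- pmax(comp$values, 0)
    pvaf <- sqrt(ev) / sum(sqrt(ev))
    keep <- which(pvaf >= pvaf_min)
    if (length(keep) == 0) {
      warning("no eigenvector reaches pvaf >= ", pvaf_min,
              "; retaining the first")
      keep <- 1L
    }
    W <- comp$vectors[, keep, drop = FALSE]
    for (j in seq_len(ncol(W))) {
      W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
      W[, j] <- W[, j] * sign(W[which.max(abs(W[, j])), j])
    }
    list(W = W, pvaf = pvaf)
  }
  f <- pick(comp_F)
  t_ <- pick(comp_T)
  l1F <- max(comp_F$values)
  l1T <- max(comp_T$values)
  structure(list(W_F = f$W, W_T = t_$W,
                 pvaf_F = f$pvaf, pvaf_T = t_$pvaf,
                 rc_F = l1F / (l1F + l1T), rc_T = l1T / (l1F + l1T),
                 comp_F = comp_F, comp_T = comp_T),
            class = "compromise_set")
}

#' Joint compromise projection of one surface
#'
#' Projects the surface onto the retained spectral and temporal eigenvector
#' bases and combines the two, weighted by the relative contributions:
#' P = p_F rc_F + (p_T rc_T)'. The retained eigenvectors come from
#' mass-centered compromise matrices and therefore span a subspace of
#' zero-mean profiles; the projection is applied to the correspondingly
#' centered surface, and the mean profile removed by the centering operator
#' is restored afterwards. With a complete basis the projection is then
#' exactly the identity, it is idempotent per dimension, and any surface
#' built purely from discarded eigenvectors projects to zero.
#'
#' @param p scales x time surface (matrix or `mmr_tf`).
#' @param cs a `compromise_set` from [select_weights()].
#' @return scales x time projection matrix.
#' @export
project_surface <- function(p, cs) {
  stopifnot(inherits(cs, "compromise_set"))
  if (inherits(p, "mmr_tf")) p <- p$p
  p <- as.matrix(p)
  if (nrow(p) != nrow(cs$W_F) || ncol(p) != nrow(cs$W_T)) {
    stop("surface shape (", nrow(p), " x ", ncol(p),
         ") does not match the weight bases (", nrow(cs$W_F), " scales, ",
         nrow(cs$W_T), " time points)")
  }
  # spectral: center each time point's profile across scales (the uniform
  # mass vector of the centering operator), project, restore the mean
  cmF <- colMeans(p)
  pF <- cs$W_F %*% crossprod(cs$W_F, sweep(p, 2, cmF)) +
    rep(1, nrow(p)) %o% cmF
  cmT <- rowMeans(p)
  pT <- cs$W_T %*% crossprod(cs$W_T, t(p - cmT)) +
    rep(1, ncol(p)) %o% cmT
  pF * cs$rc_F + t(pT * cs$rc_T)
}

#' Aggregate projections into condition and grand means
#'
#' Condition mean = mean of member projections; grand mean = mean of the
#' condition means. Both are then jointly min-max rescaled to [0, 1] using
#' the global minimum and maximum over the grand mean and all condition
#' means, preserving their relative ordering so condition surfaces stay
#' comparable.
#'
#' @param P_list list of projection matrices.
#' @param condition one condition label per projection.
#' @param rescale apply the joint [0, 1] rescaling (default TRUE).
#' @return list with `g` (named list of condition means), `G` (grand mean),
#'   and `rescale_range` (the min/max used).
#' @export
aggregate_projections <- function(P_list, condition, rescale = TRUE) {
  stopifnot(length(P_list) == length(condition), length(P_list) > 0)
  condition <- as.character(condition)
  conds <- unique(condition)
  g <- lapply(conds, function(d) {
    members <- P_list[condition == d]
    Reduce(`+`, members) / length(members)
  })
  names(g) <- conds
  G <- Reduce(`+`, g) / length(g)
  rng <- range(c(unlist(g), G))
  if (rescale) {
    if (rng[1] == rng[2]) {
      warning("all projection values identical; rescaling skipped")
    } else {
      g <- lapply(g, function(m) (m - rng[1]) / (rng[2] - rng[1]))
      G <- (G - rng[1]) / (rng[2] - rng[1])
    }
  }
  list(g = g, G = G, rescale_range = rng)
}

#' Group-level joint DISTATIS of MMR-TF surfaces
#'
#' Full chain: per-surface spectral/temporal cross-products, double
#' centering with uniform masses and first-eigenvalue normalization,
#' condition-equal compromises, eigenvector weight selection, joint
#' projection of every surface, and condition/grand aggregation with the
#' joint [0, 1] rescaling.
#'
#' @param surfaces list of scales x time matrices or `mmr_tf` objects.
#' @param condition condition label per surface.
#' @param pvaf_min eigenvector retention threshold (default 0.01).
#' @param scale_freqs_hz,time_ms axes for plotting; taken from the first
#'   `mmr_tf` input when available.
#' @return object of class `mmr_group`: `G`, `g`, `projections`, `weights`
#'   (the `compromise_set`), `condition`, axes.
#' @export
mmr_group <- function(surfaces, condition, pvaf_min = 0.01,
                      scale_freqs_hz = NULL, time_ms = NULL) {
  stopifnot(length(surfaces) == length(condition))
  if (inherits(surfaces[[1]], "mmr_tf")) {
    scale_freqs_hz <- scale_freqs_hz %||% surfaces[[1]]$scale_freqs_hz
    time_ms <- time_ms %||% surfaces[[1]]$time_ms
  }
  mats <- lapply(surfaces, function(s) if (inherits(s, "mmr_tf")) s$p else as.matrix(s))
  SF <- vector("list", length(mats))
  ST <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    cp <- cross_products(mats[[i]])
    SF[[i]] <- center_and_normalize(cp$CP_F)
    ST[[i]] <- center_and_normalize(cp$CP_T)
  }
  comp_F <- build_compromise(SF, condition)
  comp_T <- build_compromise(ST, condition)
  cs <- select_weights(comp_F, comp_T, pvaf_min = pvaf_min)
  P <- lapply(mats, project_surface, cs = cs)
  agg <- aggregate_projections(P, condition)
  structure(list(G = agg$G, g = agg$g, projections = P,
                 weights = cs, condition = as.character(condition),
                 rescale_range = agg$rescale_range,
                 scale_freqs_hz = scale_freqs_hz, time_ms = time_ms),
            class = "mmr_group")
}

#' @export
print.mmr_group <- function(x, ...) {
  cat("Joint DISTATIS group analysis:", length(x$projections),
      "surfaces,", length(x$g), "condition(s)\n")
  cat("  members:", paste(sprintf("%s=%d", names(table(x$condition)),
                                  table(x$condition)), collapse = ", "), "\n")
  cat("  retained eigenvectors: spectral", ncol(x$weights$W_F),
      "| temporal", ncol(x$weights$W_T), "\n")
  cat("  relative contribution: rc_F =", round(x$weights$rc_F, 3),
      "rc_T =", round(x$weights$rc_T, 3), "\n")
  invisible(x)
}

#' @export
summary.mmr_group <- function(object, ...) {
  print(object)
  cat("  grand compromise range:",
      paste(round(range(object$G), 3), collapse = " .. "), "\n")
  for (d in names(object$g)) {
    cat("  condition", d, "max RP:", round(max(object$g[[d]]), 3), "\n")
  }
  invisible(object)
}

#' @export
plot.mmr_group <- function(x, which = "G", ...) {
  p <- if (identical(which, "G")) x$G else x$g[[which]]
  if (is.null(p)) stop("unknown surface '", which, "'")
  if (is.null(x$scale_freqs_hz)) {
    graphics::image(t(p), main = paste("compromise projection:", which), ...)
  } else {
    plot_tf_surface(p, x$scale_freqs_hz, x$time_ms,
                    main = paste("compromise projection:", which), ...)
  }
  invisible(x)
}
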