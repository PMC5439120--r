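# The probabilistic time-frequency mismatch response: bootstrap difference
# and error surfaces, joint per-scale normalization, and the kernel-CDF
# probability map. Surfaces are stored scales x time.

#' Bootstrap difference and error estimates
#'
#' `M` is the squared complex modulus of the mean, over `n_boot` draws with
#' replacement, of (random deviant trial - random standard trial), per
#' time-frequency point; the complex mean is taken first and the modulus
#' squared after, so only phase-consistent differences survive. `E` is the
#' label-blind analogue built from pairs drawn from all retained trials
#' regardless of type.
#'
#' @param t a `tf_tensor` (truncated and baselined).
#' @param n_boot number of bootstrap draws (default 1001).
#' @param seed RNG seed.
#' @return list of class `bootstrap_estimates`: `M`, `E` (scales x time),
#'   `n_boot`, `seed`; `MM`/`EE` are filled by [scale_normalize()].
#' @export
bootstrap_difference <- function(t, n_boot = 1001, seed = NULL) {
  stopifnot(inherits(t, "tf_tensor"))
  n_tr <- dim(t$coeffs)[1]
  dev <- which(t$labels == "deviant")
  std <- which(t$labels == "standard")
  if (length(dev) == 0 || length(std) == 0) {
    stop("both deviant and standard trials must be present")
  }
  flat <- matrix(t$coeffs, nrow = n_tr)      # trials x (time*scales)
  wts <- with_seed(seed, {
    rd <- sample(dev, n_boot, replace = TRUE)
    rs <- sample(std, n_boot, replace = TRUE)
    ra <- sample.int(n_tr, n_boot, replace = TRUE)
    rb <- sample.int(n_tr, n_boot, replace = TRUE)
    list(m = (tabulate(rd, n_tr) - tabulate(rs, n_tr)) / n_boot,
         e = (tabulate(ra, n_tr) - tabulate(rb, n_tr)) / n_boot)
  })
  # the bootstrap mean is a weighted sum over trials (counts / n_boot)
  nt <- dim(t$coeffs)[2]
  ns <- dim(t$coeffs)[3]
  msum <- as.vector(wts$m %*% flat)
  esum <- as.vector(wts$e %*% flat)
  M <- t(matrix(Mod(msum)^2, nt, ns))        # scales x time
  E <- t(matrix(Mod(esum)^2, nt, ns))
  structure(list(M = M, E = E, MM = NULL, EE = NULL,
                 n_boot = n_boot, seed = seed,
                 scale_freqs_hz = t$scale_freqs_hz, time_ms = t$time_ms),
            class = "bootstrap_estimates")
}

#' Jointly normalize M and E across scales
#'
#' Per scale k, both M[k, ] and E[k, ] are divided by
#' sqrt(sum_j M[k, j]^2 + sum_j E[k, j]^2), so the squared values of MM and
#' EE sum to one per scale. This equates the natural energy differences
#' between scales (low frequencies carry more power). All-zero scales are
#' left at zero and flagged.
#'
#' @param est a `bootstrap_estimates`.
#' @return the same object with `MM`, `EE` filled and a `zero_scales`
#'   attribute listing degenerate scales.
#' @export
scale_normalize <- function(est) {
  stopifnot(inherits(est, "bootstrap_estimates"),
            !is.null(est$M), !is.null(est$E),
            all(dim(est$M) == dim(est$E)))
  denom <- sqrt(rowSums(est$M^2) + rowSums(est$E^2))
  zero <- denom == 0
  denom[zero] <- 1
  est$MM <- est$M / denom
  est$EE <- est$E / denom
  attr(est, "zero_scales") <- which(zero)
  est
}

#' Map normalized differences to probabilities via the pooled kernel CDF
#'
#' Pools the values of MM and EE, fits a Gaussian-kernel CDF with automatic
#' bandwidth (see [kde_cdf()]), and replaces each MM value by its CDF value.
#' The result is the probabilistic time-frequency mismatch response: a
#' scales x time map in [0, 1].
#'
#' @param est a `bootstrap_estimates` with MM/EE filled (run
#'   [scale_normalize()] first).
#' @param cdf_method "kde" (default) or "ecdf".
#' @return object of class `mmr_tf` (see [mmr_tf()]).
#' @export
probability_map <- function(est, cdf_method = c("kde", "ecdf")) {
  stopifnot(inherits(est, "bootstrap_estimates"))
  if (is.null(est$MM)) est <- scale_normalize(est)
  cdf_method <- match.arg(cdf_method)
  pooled <- c(est$MM, est$EE)
  if (max(pooled) == min(pooled)) {
    warning("degenerate pooled MM/EE distribution; returning 0.5 everywhere")
    p <- matrix(0.5, nrow(est$MM), ncol(est$MM))
  } else {
    C <- kde_cdf(pooled, method = cdf_method)
    p <- matrix(C(est$MM), nrow(est$MM), ncol(est$MM))
  }
  structure(list(p = p,
                 MM = est$MM, EE = est$EE, M = est$M, E = est$E,
                 scale_freqs_hz = est$scale_freqs_hz,
                 time_ms = est$time_ms,
                 n_boot = est$n_boot, seed = est$seed,
                 cdf_method = cdf_method),
            class = "mmr_tf")
}

#' Compute the probabilistic time-frequency mismatch response
#'
#' One-call estimator running [bootstrap_difference()], [scale_normalize()]
#' and [probability_map()] on a truncated, baselined TF tensor. The result
#' is a scales x time probability surface: at each time-frequency point,
#' the probability that the phase-consistent deviant-minus-standard
#' difference exceeds the label-blind error estimate, relative to the
#' pooled distribution of both.
#'
#' @param t a `tf_tensor`.
#' @param n_boot bootstrap draws (default 1001).
#' @param seed RNG seed.
#' @param cdf_method "kde" or "ecdf".
#' @return object of class `mmr_tf` with elements `p` (the surface), `MM`,
#'   `EE`, `M`, `E`, `scale_freqs_hz`, `time_ms`, `n_boot`, `seed`.
#' @export
mmr_tf <- function(t, n_boot = 1001, seed = NULL,
                   cdf_method = c("kde", "ecdf")) {
  est <- bootstrap_difference(t, n_boot = n_boot, seed = seed)
  est <- scale_normalize(est)
  probability_map(est, cdf_method = cdf_method)
}

#' @export
print.mmr_tf <- function(x, ...) {
  cat("MMR-TF surface:", nrow(x$p), "scales x", ncol(x$p), "time points\n")
  cat("  frequencies:", round(min(x$scale_freqs_hz), 2), "..",
      round(max(x$scale_freqs_hz), 2), "Hz; time:",
      min(x$time_ms), "..", max(x$time_ms), "ms\n")
  cat("  n_boot:", x$n_boot, " CDF:", x$cdf_method, "\n")
  imax <- arrayInd(which.max(x$p), dim(x$p))
  cat("  max p =", round(max(x$p), 4), "at",
      round(x$scale_freqs_hz[imax[1]], 2), "Hz,",
      round(x$time_ms[imax[2]], 1), "ms\n")
  invisible(x)
}

#' @export
summary.mmr_tf <- function(object, ...) {
  qs <- stats::quantile(object$p, c(0.5, 0.9, 0.99, 1))
  cat("MMR-TF surface quantiles (p):\n")
  print(round(qs, 4))
  invisible(qs)
}

#' Heat-map plot of a time-frequency surface
#'
#' @param x an `mmr_tf` (or `mmr_group` / matrix with axes supplied).
#' @param ... passed to [graphics::image()].
#' @export
plot.mmr_tf <- function(x, ...) {
  plot_tf_surface(x$p, x$scale_freqs_hz, x$time_ms,
                  main = "MMR-TF probability surface", ...)
  invisible(x)
}

# shared image plot: time on x, log-frequency on y
plot_tf_surface <- function(p, freqs, time_ms, main = "", ...) {
  graphics::image(time_ms, log2(freqs), t(p),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (ms)", ylab = "frequency (Hz, log2)",
                  yaxt = "n", main = main, ...)
  at <- pretty(log2(freqs))
  graphics::axis(2, at = at, labels = round(2^at, 1))
  invisible(NULL)
}
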