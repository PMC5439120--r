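# Shared internal helpers: seeded RNG scoping, seed derivation, kernel CDFs.

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed and a string id.
#'
#' Used so that every (subject, condition) block in a group run draws from an
#' independent, reproducible stream. The hash is a plain polynomial over the
#' UTF-8 bytes of the id, reduced modulo a Mersenne prime so the result stays
#' a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param id character scalar identifying the stream (e.g. "s03_vowel").
#' @return integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, id) {
  stopifnot(length(id) == 1L, is.character(id))
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% m
  as.integer(h)
}

#' Smoothed cumulative distribution function of a sample.
#'
#' Builds the Gaussian-kernel CDF of `x` with automatically selected
#' bandwidth (Sheather-Jones plug-in, computed on a subsample for large n,
#' with the normal-reference rule as fallback). For speed the kernel CDF is
#' evaluated on a fine binned grid and interpolated; the approximation error
#' is far below the bandwidth-induced smoothing. `method = "ecdf"` returns
#' the empirical step CDF instead and is used as an independent check.
#'
#' @param x numeric sample (finite values).
#' @param method "kde" (default) or "ecdf".
#' @param n_grid grid resolution for the kernel method.
#' @return a function mapping numeric values to [0, 1].
#' @export
kde_cdf <- function(x, method = c("kde", "ecdf"), n_grid = 2048L) {
  method <- match.arg(method)
  x <- as.vector(x)
  if (any(!is.finite(x))) stop("kde_cdf: input contains non-finite values")
  if (method == "ecdf") return(stats::ecdf(x))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # degenerate sample: everything sits at one point
    x0 <- rng[1]
    return(function(q) ifelse(q < x0, 0, ifelse(q > x0, 1, 0.5)))
  }
  h <- auto_bandwidth(x)
  lo <- rng[1] - 4 * h
  hi <- rng[2] + 4 * h
  # bin the sample on a grid much finer than h, then sum Gaussian CDFs per bin
  n_bins <- max(n_grid * 2L, 4096L)
  centers <- seq(lo, hi, length.out = n_bins)
  bw <- centers[2] - centers[1]
  idx <- pmin(pmax(floor((x - lo) / bw) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  keep <- which(counts > 0L)
  grid <- seq(lo, hi, length.out = n_grid)
  cdf_vals <- numeric(n_grid)
  n <- length(x)
  # outer() over occupied bins only; occupied bins << n for big samples
  z <- outer(grid, centers[keep], function(a, b) (a - b) / h)
  cdf_vals <- as.vector(stats::pnorm(z) %*% counts[keep]) / n
  cdf_vals <- cummax(pmin(pmax(cdf_vals, 0), 1))
  f <- stats::approxfun(grid, cdf_vals, rule = 2)
  function(q) pmin(pmax(f(q), 0), 1)
}

# Sheather-Jones bandwidth with a subsample cap; falls back to bw.nrd0 when
# SJ fails (e.g. heavily tied data).
auto_bandwidth <- function(x, cap = 5000L) {
  xs <- if (length(x) > cap) {
    x[round(seq(1L, length(x), length.out = cap))]
  } else x
  h <- tryCatch(stats::bw.SJ(xs), error = function(e) NA_real_)
  if (!is.finite(h) || h <= 0) h <- stats::bw.nrd0(xs)
  if (!is.finite(h) || h <= 0) h <- 1e-8 * max(abs(x), 1)
  h
}

# Select indices of time axis t (ms) in [a, b); closed-left, open-right.
interval_idx <- function(t, a, b) which(t >= a & t < b)

`%||%` <- function(a, b) if (is.null(a)) b else a
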