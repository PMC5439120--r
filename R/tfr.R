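# Trial-dimension PCA whitening and the complex Morlet continuous wavelet
# transform (FFT implementation), plus post-transform truncation, complex
# baseline subtraction, and magnitude-based trial rejection.

#' PCA-whiten epochs along the trial dimension
#'
#' Treats trials as variables and time points as observations: trials are
#' centered (zero temporal mean), the trial-by-trial covariance is
#' eigendecomposed, components explaining at least `min_pvaf` of the total
#' variance are retained, and the data are reconstructed in whitened
#' coordinates (unit variance per retained component) mapped back to trial
#' space (ZCA-style: E L^-1/2 E' X).
#'
#' @param block single-channel `eeg_epochs`.
#' @param min_pvaf minimum eigenvalue fraction retained (default 1e-4,
#'   i.e. 0.01% of total variance).
#' @return whitened `eeg_epochs` (labels and mask preserved).
#' @export
whiten_trials <- function(block, min_pvaf = 1e-4) {
  stopifnot(inherits(block, "eeg_epochs"), is.matrix(block$trials))
  X <- block$trials
  if (nrow(X) < 2) stop("whitening needs at least 2 trials")
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- which(ev / sum(ev) >= min_pvaf)
  E <- e$vectors[, keep, drop = FALSE]
  W <- E %*% (t(E) / sqrt(ev[keep]))
  block$trials <- W %*% Xc
  attr(block, "whitening") <- list(retained = length(keep),
                                   pvaf = ev / sum(ev))
  block
}

#' Log-spaced Morlet center frequencies
#'
#' @param n_scales number of scales (default 128).
#' @param fmin,fmax lowest / highest center frequency in Hz (defaults 1.94
#'   and 48.40).
#' @return ascending numeric vector of center frequencies.
#' @export
morlet_center_freqs <- function(n_scales = 128L, fmin = 1.94, fmax = 48.40) {
  exp(seq(log(fmin), log(fmax), length.out = n_scales))
}

#' Complex Morlet continuous wavelet transform of epoched trials
#'
#' 6-cycle (omega0 = 6) complex Morlet CWT computed per trial by the FFT
#' method with unit-energy scale normalization. Scales are log-spaced so the
#' center frequencies (omega0 / (2 pi s)) run `fmin` to `fmax`. The
#' transform is computed on the full epoch; truncate afterwards with
#' [truncate_and_baseline()] so the analysis window sits away from the
#' epoch edges.
#'
#' @param block single-channel `eeg_epochs` (typically whitened).
#' @param n_scales number of scales (default 128).
#' @param cycles Morlet carrier parameter omega0 (default 6).
#' @param fmin,fmax center-frequency range in Hz.
#' @return object of class `tf_tensor`: `coeffs` (complex trials x time x
#'   scales), `scale_freqs_hz`, `time_ms`, `labels`, `fs`, and a `coi`
#'   element giving each scale's cone-of-influence radius (ms).
#' @export
cwt_morlet <- function(block, n_scales = 128L, cycles = 6,
                       fmin = 1.94, fmax = 48.40) {
  stopifnot(inherits(block, "eeg_epochs"), is.matrix(block$trials))
  X <- t(block$trials)                    # time x trials
  n <- nrow(X)
  fs <- block$fs
  dt <- 1 / fs
  freqs <- morlet_center_freqs(n_scales, fmin, fmax)
  scales <- cycles / (2 * pi * freqs)     # seconds
  # effective support of the widest wavelet must fit inside the epoch
  if (n * dt < 2 * sqrt(2) * max(scales)) {
    stop("epoch (", round(n * dt, 3), " s) shorter than the lowest ",
         "scale's cone-of-influence support (",
         round(2 * sqrt(2) * max(scales), 3), " s)")
  }
  nfft <- stats::nextn(n, 2)
  Xp <- rbind(X, matrix(0, nfft - n, ncol(X)))
  Xf <- stats::mvfft(Xp)
  omega <- 2 * pi * fs * c(seq(0, floor(nfft / 2)),
                           seq(floor(nfft / 2) + 1, nfft - 1) - nfft) / nfft
  pos <- omega > 0
  coeffs <- array(complex(real = 0), c(ncol(X), n, n_scales))
  for (k in seq_len(n_scales)) {
    s <- scales[k]
    psi <- numeric(nfft)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - cycles)^2 / 2)
    Wk <- stats::mvfft(Xf * psi, inverse = TRUE) / nfft
    coeffs[, , k] <- t(Wk[seq_len(n), , drop = FALSE])
  }
  structure(list(coeffs = coeffs,
                 scale_freqs_hz = freqs,
                 time_ms = block$time_ms,
                 labels = block$labels,
                 fs = fs,
                 coi = sqrt(2) * scales * 1000),
            class = "tf_tensor")
}

#' @export
print.tf_tensor <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("TF tensor:", d[1], "trials x", d[2], "time points x", d[3],
      "scales\n")
  cat("  frequencies:", round(min(x$scale_freqs_hz), 2), "..",
      round(max(x$scale_freqs_hz), 2), "Hz (log-spaced)\n")
  cat("  time:", min(x$time_ms), "..", max(x$time_ms), "ms @", x$fs, "Hz\n")
  invisible(x)
}

#' Truncate the TF tensor and subtract the complex pre-stimulus mean
#'
#' Restricts the time axis to `window` (inclusive endpoints) and subtracts,
#' per trial and scale, the complex mean over the `baseline` interval
#' (closed-left, open-right) from every time point.
#'
#' @param t a `tf_tensor` computed on the full epoch.
#' @param window c(start, end) in ms (default -100..700).
#' @param baseline c(start, end) in ms (default -100..0).
#' @return truncated, baselined `tf_tensor`.
#' @export
truncate_and_baseline <- function(t, window = c(-100, 700),
                                  baseline = c(-100, 0)) {
  stopifnot(inherits(t, "tf_tensor"))
  keep <- which(t$time_ms >= window[1] - 1e-9 & t$time_ms <= window[2] + 1e-9)
  if (length(keep) == 0) stop("window outside the tensor's time axis")
  t$coeffs <- t$coeffs[, keep, , drop = FALSE]
  t$time_ms <- t$time_ms[keep]
  bidx <- interval_idx(t$time_ms, baseline[1], baseline[2])
  if (length(bidx) == 0) stop("baseline interval outside the window")
  # complex mean over baseline, per trial x scale
  mu <- apply(t$coeffs[, bidx, , drop = FALSE], c(1, 3), mean)
  nt <- length(t$time_ms)
  t$coeffs <- t$coeffs - aperm(array(mu, c(dim(mu), nt)), c(1, 3, 2))
  t
}

#' Reject trials by total squared CWT magnitude
#'
#' Per-trial statistic: the sum over time and scale of the squared
#' coefficient modulus. Trials above mean + z standard deviations are
#' dropped from the tensor.
#'
#' @param t a `tf_tensor`.
#' @param z threshold in standard deviations (default 2.5; `Inf` keeps all).
#' @return `tf_tensor` with outlier trials removed; the number removed is
#'   recorded in `attr(, "n_rejected")`.
#' @export
reject_magnitude <- function(t, z = 2.5) {
  stopifnot(inherits(t, "tf_tensor"))
  n_tr <- dim(t$coeffs)[1]
  if (n_tr < 10) stop("magnitude rejection needs at least 10 trials")
  stat <- apply(t$coeffs, 1, function(m) sum(Mod(m)^2))
  sdv <- stats::sd(stat)
  drop <- if (!is.finite(sdv) || sdv == 0 || !is.finite(z)) {
    rep(FALSE, n_tr)
  } else {
    stat > mean(stat) + z * sdv
  }
  if (all(drop)) stop("all trials rejected; review the z threshold")
  t$coeffs <- t$coeffs[!drop, , , drop = FALSE]
  t$labels <- t$labels[!drop]
  attr(t, "n_rejected") <- sum(drop)
  t
}
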