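# Continuous-EEG container, zero-phase FIR bandpass, re-referencing,
# epoching with baseline correction, and joint-probability artifact
# rejection.

#' Continuous multichannel EEG container
#'
#' @param data channels x samples voltage matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names unique channel labels (10-20 names for real
#'   recordings).
#' @param reference label of the current reference.
#' @return object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, fs, channel_names = NULL,
                           reference = "unknown") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  stopifnot(length(channel_names) == nrow(data))
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 reference = reference),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat("Continuous EEG:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  reference:", x$reference, "\n")
  invisible(x)
}

# FIR bandpass kernel: Hamming windowed-sinc, order set from the low band
# edge so the measured rolloff there is ~24 dB/octave.
design_bandpass <- function(fs, lo, hi) {
  stopifnot(hi < fs / 2, lo > 0, lo < hi)
  # transition width of one octave below the low edge (lo/2 .. lo) gives
  # ~24 dB/octave at that edge with a Hamming window (-53 dB stopband)
  trans <- lo / 2
  n_taps <- round(3.3 * fs / trans)
  n_taps <- n_taps + (n_taps %% 2L == 0L)  # odd => integer group delay
  signal::fir1(n_taps - 1L, c(lo, hi) * 2 / fs, type = "pass")
}

#' Zero-phase FIR bandpass filter
#'
#' Hamming windowed-sinc FIR applied by FFT convolution with the linear-phase
#' group delay compensated exactly (the kernel is symmetric, so the
#' compensated response is zero-phase). Default band 2-50 Hz.
#'
#' @param cont an [eeg_continuous()].
#' @param lo,hi band edges in Hz.
#' @return filtered [eeg_continuous()].
#' @export
eeg_bandpass <- function(cont, lo = 2, hi = 50) {
  stopifnot(inherits(cont, "eeg_continuous"))
  h <- design_bandpass(cont$fs, lo, hi)
  n <- ncol(cont$data)
  if (n < 3 * length(h)) {
    stop("recording (", n, " samples) shorter than 3x the filter length (",
         length(h), " taps); edge contamination would dominate")
  }
  delay <- (length(h) - 1L) / 2L
  nfft <- stats::nextn(n + length(h) - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  out <- cont$data
  for (ch in seq_len(nrow(out))) {
    X <- stats::fft(c(cont$data[ch, ], numeric(nfft - n)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    out[ch, ] <- y[delay + seq_len(n)]  # compensate the linear-phase delay
  }
  res <- eeg_continuous(out, cont$fs, cont$channel_names, cont$reference)
  attr(res, "filter") <- list(lo = lo, hi = hi, n_taps = length(h))
  res
}

#' Re-reference continuous EEG
#'
#' `common_average` subtracts the per-sample mean of the scalp channels
#' (all channels not listed in `exclude`); `linked_mastoids` subtracts the
#' per-sample mean of the reference channels (default M1, M2); `nasion`
#' leaves the data unchanged (recordings here are nasion-referenced at
#' acquisition) and only relabels the reference.
#'
#' @param cont an [eeg_continuous()].
#' @param scheme "common_average", "linked_mastoids", or "nasion".
#' @param ref_channels channels forming the reference for
#'   `linked_mastoids` (default c("M1", "M2")).
#' @param exclude channels excluded from a common-average reference (and
#'   from nothing else), e.g. an eye channel.
#' @return re-referenced [eeg_continuous()].
#' @export
eeg_rereference <- function(cont,
                            scheme = c("common_average", "linked_mastoids",
                                       "nasion"),
                            ref_channels = NULL, exclude = character()) {
  stopifnot(inherits(cont, "eeg_continuous"))
  scheme <- match.arg(scheme)
  out <- cont$data
  if (scheme == "common_average") {
    use <- setdiff(cont$channel_names, exclude)
    ref <- colMeans(cont$data[use, , drop = FALSE])
    out[use, ] <- sweep(cont$data[use, , drop = FALSE], 2, ref)
    refname <- "common_average"
  } else if (scheme == "linked_mastoids") {
    ref_channels <- ref_channels %||% c("M1", "M2")
    if (!all(ref_channels %in% cont$channel_names)) {
      stop("reference channels missing: ",
           paste(setdiff(ref_channels, cont$channel_names), collapse = ", "))
    }
    ref <- colMeans(cont$data[ref_channels, , drop = FALSE])
    out <- sweep(cont$data, 2, ref)
    refname <- paste(ref_channels, collapse = "+")
  } else {
    refname <- "nasion"
  }
  eeg_continuous(out, cont$fs, cont$channel_names, reference = refname)
}

#' Epoch continuous EEG around stimulus onsets
#'
#' Cuts `window` (inclusive endpoints, so -500..1500 ms at 1000 Hz gives
#' 2001 samples) around each event onset and subtracts the per-trial,
#' per-channel mean over the `baseline` interval (closed-left, open-right).
#' Events without full window support are dropped with a warning.
#'
#' @param cont an [eeg_continuous()].
#' @param events data.frame with columns onset_sample (1-based) and label.
#' @param channel single channel to keep, or NULL for all channels.
#' @param window c(start, end) in ms relative to onset.
#' @param baseline c(start, end) in ms; NULL skips baseline correction.
#' @return object of class `eeg_epochs`: `trials` (trials x time matrix for
#'   a single channel, or trials x channels x time array), `labels`,
#'   `time_ms`, `fs`, `channel_names`, `retained` (logical mask).
#' @export
eeg_epoch <- function(cont, events, channel = NULL,
                      window = c(-500, 1500), baseline = c(-500, 0)) {
  stopifnot(inherits(cont, "eeg_continuous"))
  stopifnot(all(c("onset_sample", "label") %in% names(events)))
  fs <- cont$fs
  rel <- seq(round(window[1] / 1000 * fs), round(window[2] / 1000 * fs))
  time_ms <- rel / fs * 1000
  n_samp <- ncol(cont$data)
  ok <- events$onset_sample + rel[1] >= 1 &
    events$onset_sample + rel[length(rel)] <= n_samp
  if (!all(ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  ev <- events[ok, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with full window support")
  chans <- if (is.null(channel)) cont$channel_names else channel
  stopifnot(all(chans %in% cont$channel_names))
  n_tr <- nrow(ev)
  single <- length(chans) == 1L
  if (single) {
    trials <- matrix(NA_real_, n_tr, length(rel))
    x <- cont$data[chans, ]
    for (i in seq_len(n_tr)) trials[i, ] <- x[ev$onset_sample[i] + rel]
  } else {
    trials <- array(NA_real_, c(n_tr, length(chans), length(rel)))
    for (i in seq_len(n_tr)) {
      trials[i, , ] <- cont$data[chans, ev$onset_sample[i] + rel]
    }
  }
  out <- structure(list(trials = trials, labels = ev$label,
                        time_ms = time_ms, fs = fs, channel_names = chans,
                        retained = rep(TRUE, n_tr)),
                   class = "eeg_epochs")
  if (!is.null(baseline)) out <- baseline_correct(out, baseline) else out
}

#' Baseline-correct epochs
#'
#' Subtracts the per-trial (and per-channel) mean over the baseline interval
#' (closed-left, open-right). Idempotent.
#'
#' @param block an [eeg_epoch()] result.
#' @param baseline c(start, end) in ms.
#' @return corrected `eeg_epochs`.
#' @export
baseline_correct <- function(block, baseline = c(-500, 0)) {
  stopifnot(inherits(block, "eeg_epochs"))
  idx <- interval_idx(block$time_ms, baseline[1], baseline[2])
  if (length(idx) == 0) stop("baseline interval outside the epoch window")
  if (is.matrix(block$trials)) {
    mu <- rowMeans(block$trials[, idx, drop = FALSE])
    block$trials <- block$trials - mu
  } else {
    mu <- apply(block$trials[, , idx, drop = FALSE], c(1, 2), mean)
    block$trials <- block$trials - as.vector(mu)  # recycles over time dim
  }
  block
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- if (is.matrix(x$trials)) dim(x$trials) else dim(x$trials)
  cat("Epoched EEG:", d[1], "trials,",
      if (is.matrix(x$trials)) 1 else d[2], "channel(s),",
      d[length(d)], "time points (",
      min(x$time_ms), "..", max(x$time_ms), "ms @", x$fs, "Hz)\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  cat("  retained:", sum(x$retained), "/", length(x$retained), "\n")
  invisible(x)
}

# Per-trial improbability score: summed negative log empirical probability
# of the trial's sample amplitudes under the all-trials amplitude
# distribution (histogram with automatic bin count, or Gaussian KDE).
jointprob_scores <- function(trials, estimator = c("histogram", "kde")) {
  estimator <- match.arg(estimator)
  pooled <- as.vector(trials)
  if (estimator == "histogram") {
    brks <- pretty(range(pooled), n = grDevices::nclass.FD(pooled))
    hh <- graphics::hist(pooled, breaks = brks, plot = FALSE)
    p <- hh$counts / sum(hh$counts)
    p[p == 0] <- min(p[p > 0]) / 10  # guard for empty interior bins
    bin <- findInterval(trials, hh$breaks, all.inside = TRUE)
    logp <- matrix(log(p[bin]), nrow = nrow(trials))
  } else {
    d <- stats::density(pooled, n = 1024)
    f <- stats::approxfun(d$x, pmax(d$y, min(d$y[d$y > 0]) / 10), rule = 2)
    logp <- matrix(log(f(trials)), nrow = nrow(trials))
  }
  -rowSums(logp)
}

#' Joint-probability artifact rejection
#'
#' Scores each trial by the summed negative log empirical probability of its
#' sample amplitudes (per channel) and flags trials whose score exceeds
#' mean + z standard deviations of the score distribution. The data are not
#' modified; only the `retained` mask is updated. For multichannel epochs a
#' trial is rejected if it is flagged on any channel.
#'
#' @param block an `eeg_epochs`.
#' @param z rejection threshold in standard deviations (default 2.5;
#'   `Inf` retains everything).
#' @param estimator "histogram" (automatic bin count) or "kde".
#' @return `eeg_epochs` with updated `retained` mask.
#' @export
reject_joint_probability <- function(block, z = 2.5,
                                     estimator = c("histogram", "kde")) {
  stopifnot(inherits(block, "eeg_epochs"))
  n_tr <- length(block$labels)
  if (n_tr < 10) stop("joint-probability rejection needs at least 10 trials")
  flag <- rep(FALSE, n_tr)
  score_one <- function(m) {
    s <- jointprob_scores(m, estimator)
    sdv <- stats::sd(s)
    if (!is.finite(sdv) || sdv == 0) return(rep(FALSE, length(s)))
    s > mean(s) + z * sdv
  }
  if (is.matrix(block$trials)) {
    flag <- score_one(block$trials)
  } else {
    for (ch in seq_len(dim(block$trials)[2])) {
      flag <- flag | score_one(block$trials[, ch, ])
    }
  }
  retained <- block$retained & !flag
  if (!any(retained)) {
    stop("all trials rejected; review the z threshold (z = ", z, ")")
  }
  block$retained <- retained
  block
}

#' Drop non-retained trials
#'
#' @param block an `eeg_epochs`.
#' @return `eeg_epochs` containing only retained trials.
#' @export
drop_rejected <- function(block) {
  stopifnot(inherits(block, "eeg_epochs"))
  keep <- block$retained
  block$trials <- if (is.matrix(block$trials)) {
    block$trials[keep, , drop = FALSE]
  } else {
    block$trials[keep, , , drop = FALSE]
  }
  block$labels <- block$labels[keep]
  block$retained <- rep(TRUE, sum(keep))
  block
}
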