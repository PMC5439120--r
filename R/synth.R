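# Synthetic sleep-EEG oddball simulator: trial sequences, oscillatory burst
# cascade, 1/f background noise, and continuous multichannel blocks with a
# ground-truth event table.

#' Oddball paradigm specification
#'
#' Describes one experimental block of an auditory oddball paradigm:
#' how many trials, which fraction are deviants, the inter-stimulus
#' interval, and whether two deviants may follow each other.
#'
#' @param n_trials number of trials in the block.
#' @param deviant_fraction fraction of trials that are deviants, in [0, 1].
#' @param isi_ms inter-stimulus (onset-to-onset) interval in milliseconds.
#' @param no_successive_deviants if TRUE (default), no two deviants may be
#'   adjacent in the sequence.
#' @param seed RNG seed for the sequence draw.
#' @return an object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials = 600L, deviant_fraction = 0.15,
                          isi_ms = 1200, no_successive_deviants = TRUE,
                          seed = NULL) {
  stopifnot(n_trials > 0, deviant_fraction >= 0, deviant_fraction <= 1,
            isi_ms > 0)
  if (no_successive_deviants && deviant_fraction > 0.5) {
    stop("deviant_fraction must be <= 0.5 when successive deviants are ",
         "forbidden (adjacency constraint infeasible)")
  }
  structure(list(n_trials = as.integer(n_trials),
                 deviant_fraction = deviant_fraction,
                 isi_ms = isi_ms,
                 no_successive_deviants = isTRUE(no_successive_deviants),
                 seed = seed),
            class = "paradigm_spec")
}

#' Oscillatory burst specification
#'
#' One element of the deviant-response cascade: a Hann-tapered sinusoid (or
#' linear chirp) added to every deviant trial at a fixed post-onset latency.
#'
#' @param band_label one of "gamma", "beta", "theta1", "theta2", "theta2b"
#'   (free-form labels are accepted).
#' @param center_freq_hz carrier frequency in Hz (2-48).
#' @param peak_latency_ms latency of the envelope peak, ms after onset.
#' @param duration_ms envelope duration (full Hann width) in ms.
#' @param amplitude peak amplitude in microvolts.
#' @param chirp_end_freq_hz optional end frequency for a linear
#'   instantaneous-frequency sweep (downward theta sweeps).
#' @param phase_rad carrier phase at the envelope onset (radians).
#' @return an object of class `burst_spec`.
#' @export
burst_spec <- function(band_label, center_freq_hz, peak_latency_ms,
                       duration_ms, amplitude,
                       chirp_end_freq_hz = NULL, phase_rad = 0) {
  stopifnot(center_freq_hz >= 2, center_freq_hz <= 48,
            duration_ms > 0, amplitude >= 0)
  structure(list(band_label = band_label,
                 center_freq_hz = center_freq_hz,
                 peak_latency_ms = peak_latency_ms,
                 duration_ms = duration_ms,
                 amplitude = amplitude,
                 chirp_end_freq_hz = chirp_end_freq_hz,
                 phase_rad = phase_rad),
            class = "burst_spec")
}

#' Background-noise specification
#'
#' Spectrally shaped Gaussian noise emulating infant sleep EEG: a 1/f^alpha
#' base spectrum with additional delta (2-4 Hz) and theta (4-8 Hz) band
#' emphasis.
#'
#' @param spectral_exponent alpha of the 1/f^alpha amplitude law.
#' @param band_power_weights named list of multiplicative band emphases,
#'   each `list(lo, hi, gain)` in Hz / linear amplitude gain.
#' @param channel_count number of channels.
#' @param amplitude_sd target per-channel standard deviation in microvolts.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(spectral_exponent = 1.5,
                       band_power_weights = list(
                         delta = list(lo = 2, hi = 4, gain = 2.0),
                         theta = list(lo = 4, hi = 8, gain = 1.5)),
                       channel_count = 11L,
                       amplitude_sd = 20) {
  stopifnot(amplitude_sd > 0, channel_count >= 1)
  structure(list(spectral_exponent = spectral_exponent,
                 band_power_weights = band_power_weights,
                 channel_count = as.integer(channel_count),
                 amplitude_sd = amplitude_sd),
            class = "noise_spec")
}

#' The default deviant-response cascade
#'
#' Gamma onset burst, beta synchronization, an early theta oscillation
#' temporally coupled with the gamma-beta packet, a later theta modulation,
#' and its low-frequency offset. Amplitudes are calibrated so that the full
#' pipeline recovers all bursts from ~600-trial blocks at the default noise
#' level (see the methods vignette).
#'
#' @param amplitude_scale multiplies every burst amplitude (0 gives a null
#'   block with no deviant response).
#' @param latency_shift_ms added to every peak latency (condition-difficulty
#'   manipulation).
#' @return list of `burst_spec` objects.
#' @export
default_burst_set <- function(amplitude_scale = 1, latency_shift_ms = 0) {
  # durations give each carrier enough cycles under the Hann envelope that
  # its wavelet ridge peaks at the carrier frequency; peak latency is the
  # envelope centre
  b <- list(
    burst_spec("gamma",   34, 25, 100, 2.5),
    burst_spec("beta",    17, 60, 200, 2.2),
    burst_spec("theta1",   5, 70, 400, 4.0),
    burst_spec("theta2",   6, 220, 450, 4.0),
    burst_spec("theta2b",  3, 500, 500, 3.0)
  )
  lapply(b, function(s) {
    s$amplitude <- s$amplitude * amplitude_scale
    s$peak_latency_ms <- s$peak_latency_ms + latency_shift_ms
    s
  })
}

#' Generate an oddball label sequence
#'
#' Draws a standard/deviant sequence with an exact deviant count of
#' `round(n_trials * deviant_fraction)`, uniformly at random over all
#' sequences satisfying the no-successive-deviants constraint (when set).
#' Uniformity uses the standard bijection between k non-adjacent positions
#' among n and k unrestricted positions among n - k + 1.
#'
#' @param paradigm a [paradigm_spec()].
#' @return character vector of "standard" / "deviant" labels.
#' @export
generate_sequence <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  n <- paradigm$n_trials
  k <- round(n * paradigm$deviant_fraction)
  if (paradigm$no_successive_deviants && k > ceiling(n / 2)) {
    stop("infeasible: ", k, " non-adjacent deviants cannot be placed in ",
         n, " trials (adjacency constraint allows at most ceiling(n/2))")
  }
  labels <- rep("standard", n)
  if (k > 0) {
    pos <- with_seed(paradigm$seed, {
      if (paradigm$no_successive_deviants) {
        sort(sample.int(n - k + 1L, k)) + seq_len(k) - 1L
      } else {
        sort(sample.int(n, k))
      }
    })
    labels[pos] <- "deviant"
  }
  labels
}

#' Sampled waveform of one burst
#'
#' The Hann-tapered (co)sinusoid or linear chirp a [burst_spec()] injects,
#' sampled at `fs`, returned with its onset offset relative to the stimulus.
#'
#' @param burst a [burst_spec()].
#' @param fs sampling rate in Hz.
#' @param phase_jitter_rad extra phase added to the carrier (for phase-jitter
#'   simulations; 0 keeps the response phase-locked).
#' @return list with `wave` (numeric vector, microvolts) and
#'   `onset_ms` (envelope start relative to stimulus onset).
#' @export
burst_waveform <- function(burst, fs, phase_jitter_rad = 0) {
  stopifnot(inherits(burst, "burst_spec"))
  if (burst$center_freq_hz >= fs / 2 ||
      (!is.null(burst$chirp_end_freq_hz) &&
       burst$chirp_end_freq_hz >= fs / 2)) {
    stop("burst frequency ", burst$center_freq_hz,
         " Hz at or above Nyquist (fs = ", fs, " Hz)")
  }
  n <- max(2L, round(burst$duration_ms / 1000 * fs))
  t <- seq_len(n) / fs  # seconds from envelope onset
  env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  f0 <- burst$center_freq_hz
  f1 <- burst$chirp_end_freq_hz %||% f0
  # linear instantaneous-frequency sweep f0 -> f1 over the envelope
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * max(t)) * t^2) +
    burst$phase_rad + phase_jitter_rad
  list(wave = burst$amplitude * env * sin(phase),
       onset_ms = burst$peak_latency_ms - burst$duration_ms / 2)
}

# 1/f^alpha shaped Gaussian noise with band emphasis, one channel.
shaped_noise <- function(n, fs, noise) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- c(0, seq_len(n - 1)) / n * fs
  freqs <- pmin(freqs, fs - freqs)           # two-sided axis
  gain <- ifelse(freqs < 0.5, 0, 1 / pmax(freqs, 0.5)^(noise$spectral_exponent / 2))
  # band emphasis as smooth log-frequency Gaussian bumps (real sleep spectra
  # have no hard band edges)
  for (bw in noise$band_power_weights) {
    fc <- sqrt(bw$lo * bw$hi)
    sigma <- log(bw$hi / bw$lo) / 2.355      # FWHM spans the band
    bump <- exp(-(log(pmax(freqs, 0.1)) - log(fc))^2 / (2 * sigma^2))
    gain <- gain * (1 + (bw$gain - 1) * bump)
  }
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  x <- x / stats::sd(x) * noise$amplitude_sd
  x
}

# Default dipolar scalp topography over the 10-20 montage used here:
# central maximum, inverted mastoids (auditory dipole geometry).
default_topography <- function(channel_names) {
  base <- c(F5 = 0.6, Fz = 0.8, F6 = 0.6,
            C5 = 0.7, Cz = 1.0, C6 = 0.7,
            P5 = 0.4, Pz = 0.5, P6 = 0.4,
            M1 = -0.5, M2 = -0.5)
  g <- base[channel_names]
  g[is.na(g)] <- 1.0
  unname(g)
}

#' Synthesize a continuous oddball EEG block
#'
#' Generates spectrally shaped background noise on every channel, adds a
#' common low-amplitude onset response to every trial, and injects the
#' deviant-response burst cascade into deviant trials, all projected through
#' a dipolar scalp topography. Returns the continuous recording plus the
#' ground-truth event table.
#'
#' @param paradigm a [paradigm_spec()].
#' @param bursts list of [burst_spec()] objects (deviant-only responses).
#' @param noise a [noise_spec()].
#' @param fs sampling rate in Hz (default 1000).
#' @param channel_names channel labels; default the 11-channel 10-20 montage
#'   of the target paradigm.
#' @param topography per-channel gain applied to evoked responses; default
#'   a central-positive / mastoid-negative dipolar pattern.
#' @param standard_response_uv amplitude of the common onset response added
#'   to all trials (a slow 4 Hz damped wave), microvolts.
#' @param phase_jitter_sd SD (radians) of trial-to-trial carrier phase
#'   jitter for the bursts; 0 (default) keeps responses phase-locked.
#' @param random_block_phase if TRUE (default), each burst's carrier phase
#'   is offset by a single uniform random draw held fixed for the whole
#'   block: responses stay phase-locked within the block (which is what the
#'   complex bootstrap mean detects) while relative burst phases vary
#'   between blocks/subjects, as they do between real recordings. Set FALSE
#'   for fully deterministic waveforms.
#' @param pad_s padding (seconds) of plain background before the first and
#'   after the last event, so filtering and epoching stay off the edges.
#' @param seed RNG seed (overrides `paradigm$seed` when given).
#' @param block_id identifier written into the event table.
#' @return list of class `oddball_block` with elements `eeg`
#'   (an [eeg_continuous()]) and `events` (data.frame: onset_sample,
#'   label, block_id).
#' @export
synthesize_block <- function(paradigm, bursts = default_burst_set(),
                             noise = noise_spec(), fs = 1000,
                             channel_names = NULL, topography = NULL,
                             standard_response_uv = 2,
                             phase_jitter_sd = 0,
                             random_block_phase = TRUE,
                             pad_s = 3, seed = NULL,
                             block_id = "block1") {
  stopifnot(inherits(paradigm, "paradigm_spec"))
  for (b in bursts) {
    fmax <- max(b$center_freq_hz, b$chirp_end_freq_hz %||% 0)
    if (fs < 2 * fmax) {
      stop("fs = ", fs, " Hz cannot represent a ", fmax, " Hz burst")
    }
  }
  if (is.null(channel_names)) {
    channel_names <- c("F5", "Fz", "F6", "C5", "Cz", "C6",
                       "P5", "Pz", "P6", "M1", "M2")[seq_len(noise$channel_count)]
  }
  n_ch <- length(channel_names)
  if (is.null(topography)) topography <- default_topography(channel_names)
  stopifnot(length(topography) == n_ch)
  seed <- seed %||% paradigm$seed
  with_seed(seed, {
    labels <- generate_sequence(paradigm_spec(
      paradigm$n_trials, paradigm$deviant_fraction, paradigm$isi_ms,
      paradigm$no_successive_deviants, seed = NULL))
    isi_smp <- round(paradigm$isi_ms / 1000 * fs)
    onsets <- round(pad_s * fs) + (seq_len(paradigm$n_trials) - 1L) * isi_smp
    n_samples <- max(onsets) + isi_smp + round(pad_s * fs)
    data <- matrix(0, n_ch, n_samples)
    for (ch in seq_len(n_ch)) data[ch, ] <- shaped_noise(n_samples, fs, noise)

    # common onset response on every trial: damped 4 Hz half wave
    n_std <- round(0.25 * fs)
    t_std <- seq_len(n_std) / fs
    std_wave <- standard_response_uv * sin(2 * pi * 4 * t_std) *
      exp(-t_std / 0.08)
    evoked <- numeric(n_samples)
    for (o in onsets) {
      idx <- o + seq_len(n_std)
      evoked[idx] <- evoked[idx] + std_wave
    }

    # deviant-only burst cascade; block-level phase offsets decouple the
    # bursts' relative phases between blocks while keeping each block
    # phase-locked
    block_phase <- if (isTRUE(random_block_phase)) {
      stats::runif(length(bursts), 0, 2 * pi)
    } else rep(0, length(bursts))
    dev_onsets <- onsets[labels == "deviant"]
    for (o in dev_onsets) {
      for (bi in seq_along(bursts)) {
        b <- bursts[[bi]]
        jit <- block_phase[bi] +
          if (phase_jitter_sd > 0) stats::rnorm(1, 0, phase_jitter_sd) else 0
        bw <- burst_waveform(b, fs, phase_jitter_rad = jit)
        start <- o + round(bw$onset_ms / 1000 * fs)
        idx <- start + seq_along(bw$wave)
        ok <- idx >= 1 & idx <= n_samples
        evoked[idx[ok]] <- evoked[idx[ok]] + bw$wave[ok]
      }
    }
    data <- data + outer(topography, evoked)
    events <- data.frame(onset_sample = onsets + 1L,  # 1-based sample index
                         label = labels,
                         block_id = block_id,
                         stringsAsFactors = FALSE)
    structure(list(eeg = eeg_continuous(data, fs, channel_names,
                                        reference = "nasion"),
                   events = events),
              class = "oddball_block")
  })
}

#' Write / read an event table as TSV
#'
#' Columns: onset_sample (1-based), label ("standard"/"deviant"), block_id.
#' @param events data.frame as produced by [synthesize_block()].
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "label")
  if (!all(need %in% names(ev))) {
    stop("event table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  ev
}
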