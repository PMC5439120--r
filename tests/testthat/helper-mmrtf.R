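# Shared fixtures: all built in code at test time.

# Single-channel epochs object from a trials x time matrix.
make_epochs <- function(trials, labels, fs = 250,
                        t0_ms = -500) {
  n_t <- ncol(trials)
  structure(list(trials = trials,
                 labels = labels,
                 time_ms = seq(0, n_t - 1) / fs * 1000 + t0_ms,
                 fs = fs,
                 channel_names = "Cz",
                 retained = rep(TRUE, nrow(trials))),
            class = "eeg_epochs")
}

# TF tensor with constant complex coefficients per label class.
make_constant_tensor <- function(n_dev, n_std, n_time = 8, n_scales = 5,
                                 a = 1 + 1i, b = 0 + 0i, fs = 250) {
  n_tr <- n_dev + n_std
  coeffs <- array(complex(real = 0), c(n_tr, n_time, n_scales))
  labels <- c(rep("deviant", n_dev), rep("standard", n_std))
  coeffs[labels == "deviant", , ] <- a
  coeffs[labels == "standard", , ] <- b
  structure(list(coeffs = coeffs,
                 scale_freqs_hz = mmrtf::morlet_center_freqs(n_scales, 2, 40),
                 time_ms = seq(0, n_time - 1) / fs * 1000,
                 labels = labels, fs = fs,
                 coi = rep(0, n_scales)),
            class = "tf_tensor")
}

# Full-size validation cohort (12 subjects x 3 conditions x 600 trials,
# identical four-burst cascades), memoized so the recovery and latency
# checks share one run.
recovery_cohort <- function() {
  if (!is.null(.cohort_cache[["recovery"]])) {
    return(.cohort_cache[["recovery"]])
  }
  cfg <- mmrtf::run_config(
    conditions = c("c1", "c2", "c3"),
    n_subjects = 12,
    synth = list(n_trials = 600, fs = 250,
                 noise = mmrtf::noise_spec(channel_count = 3),
                 channel_names = c("Cz", "M1", "M2"),
                 bursts = mmrtf::default_burst_set()[1:4],
                 pad_s = 2),
    n_boot = 1001, seed = 20260926, verbose = FALSE)
  res <- mmrtf::run_pipeline(cfg)
  .cohort_cache[["recovery"]] <- res
  res
}

# Small synthetic oddball cohort processed end to end; memoized so several
# tests can share one run.
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(n_subjects = 3, n_trials = 100, fs = 200,
                         n_boot = 301, seed = 417,
                         amplitude_scale = 1, key = "default") {
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- mmrtf::run_config(
    conditions = c("c1", "c2", "c3"),
    n_subjects = n_subjects,
    synth = list(n_trials = n_trials, fs = fs,
                 noise = mmrtf::noise_spec(channel_count = 3),
                 channel_names = c("Cz", "M1", "M2"),
                 amplitude_scale = amplitude_scale,
                 pad_s = 2),
    n_boot = n_boot, seed = seed, verbose = FALSE)
  res <- mmrtf::run_pipeline(cfg)
  .cohort_cache[[key]] <- res
  res
}
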