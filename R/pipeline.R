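# End-to-end orchestration: synthesize or load blocks, preprocess,
# time-frequency transform, per-block MMR-TF, group DISTATIS, feature
# extraction; with logging, provenance, and file outputs.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with validated defaults. Either
#' provide `inputs` (recorded data) or leave it NULL to synthesize a cohort
#' from the `synth` settings.
#'
#' @param conditions condition labels (one block per subject per
#'   condition).
#' @param n_subjects number of synthetic subjects (ignored when `inputs`
#'   given).
#' @param synth list: n_trials, deviant_fraction, isi_ms, fs, noise
#'   (a [noise_spec()]), amplitude_scale, standard_response_uv,
#'   phase_jitter_sd, channel_names, and optionally bursts (a list of
#'   [burst_spec()] replacing the default cascade).
#' @param condition_params named list (per condition) of lists with
#'   amplitude_scale and latency_shift_ms, multiplying/shifting the default
#'   burst cascade to emulate contrast difficulty.
#' @param montage list: channel (analysis channel, default "Cz") and
#'   reference ("linked_mastoids", "common_average" or "nasion").
#' @param filter_band c(lo, hi) Hz.
#' @param epoch_window,baseline epoching windows in ms.
#' @param reject_z joint-probability rejection threshold (SD units).
#' @param cwt list: n_scales, cycles, fmin, fmax.
#' @param tf_window,tf_baseline post-CWT truncation and baseline windows.
#' @param tf_reject_z post-CWT magnitude rejection threshold.
#' @param n_boot bootstrap draws per block.
#' @param pvaf_min DISTATIS eigenvector retention threshold.
#' @param qle_threshold feature-extraction threshold.
#' @param cdf_method "kde" or "ecdf" for all CDF mappings.
#' @param seed master seed (mandatory; per-block seeds are derived from it).
#' @param channel_qc run the spatial-PCA montage QC (needs multichannel
#'   synthesis; default FALSE).
#' @param output_dir directory for artifacts, or NULL for in-memory only.
#' @param inputs optional list of recorded blocks; each element a list with
#'   subject, condition, eeg (an [eeg_continuous()] or RDS path), events
#'   (data.frame or TSV path).
#' @param verbose print stage-boundary log lines (default TRUE).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(conditions = c("nonspeech", "vowel", "consonant"),
                       n_subjects = 12L,
                       synth = list(),
                       condition_params = NULL,
                       montage = list(channel = "Cz",
                                      reference = "linked_mastoids"),
                       filter_band = c(2, 50),
                       epoch_window = c(-500, 1500),
                       baseline = c(-500, 0),
                       reject_z = 2.5,
                       cwt = list(),
                       tf_window = c(-100, 700),
                       tf_baseline = c(-100, 0),
                       tf_reject_z = 2.5,
                       n_boot = 1001L,
                       pvaf_min = 0.01,
                       qle_threshold = 0.8,
                       cdf_method = "kde",
                       seed = NULL,
                       channel_qc = FALSE,
                       output_dir = NULL,
                       inputs = NULL,
                       verbose = TRUE) {
  if (is.null(seed)) stop("a master seed is mandatory for a pipeline run")
  synth_def <- list(n_trials = 600L, deviant_fraction = 0.15,
                    isi_ms = 1200, fs = 1000, noise = noise_spec(),
                    amplitude_scale = 1, standard_response_uv = 2,
                    phase_jitter_sd = 0, channel_names = NULL, pad_s = 3,
                    bursts = NULL)
  synth <- utils::modifyList(synth_def, synth)
  cwt_def <- list(n_scales = 128L, cycles = 6, fmin = 1.94, fmax = 48.40)
  cwt <- utils::modifyList(cwt_def, cwt)
  stopifnot(filter_band[1] > 0, filter_band[1] < filter_band[2],
            filter_band[2] < synth$fs / 2,
            reject_z > 0, tf_reject_z > 0,
            n_boot >= 1, pvaf_min >= 0, pvaf_min < 1,
            qle_threshold >= 0, qle_threshold <= 1,
            synth$deviant_fraction >= 0, synth$deviant_fraction <= 0.5)
  if (is.null(condition_params)) {
    condition_params <- stats::setNames(
      lapply(seq_along(conditions), function(i) {
        list(amplitude_scale = 1, latency_shift_ms = 0)
      }), conditions)
  }
  stopifnot(all(conditions %in% names(condition_params)))
  structure(list(conditions = conditions, n_subjects = as.integer(n_subjects),
                 synth = synth, condition_params = condition_params,
                 montage = montage, filter_band = filter_band,
                 epoch_window = epoch_window, baseline = baseline,
                 reject_z = reject_z, cwt = cwt, tf_window = tf_window,
                 tf_baseline = tf_baseline, tf_reject_z = tf_reject_z,
                 n_boot = as.integer(n_boot), pvaf_min = pvaf_min,
                 qle_threshold = qle_threshold, cdf_method = cdf_method,
                 seed = as.integer(seed), channel_qc = isTRUE(channel_qc),
                 output_dir = output_dir, inputs = inputs,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; nested lists map to the
#' corresponding argument lists.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$synth$noise)) {
    vals$synth$noise <- do.call(noise_spec, vals$synth$noise)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

log_msg <- function(config, ...) {
  if (config$verbose) message("[mmrtf] ", ...)
}

# Preprocess + transform one block into an MMR-TF surface.
process_block <- function(config, eeg, events, block_seed, id) {
  stage <- "bandpass"
  res <- tryCatch({
    cont <- eeg_bandpass(eeg, config$filter_band[1], config$filter_band[2])
    stage <- "rereference"
    cont <- eeg_rereference(cont, config$montage$reference)
    stage <- "epoch"
    epochs <- eeg_epoch(cont, events, channel = config$montage$channel,
                        window = config$epoch_window,
                        baseline = config$baseline)
    stage <- "artifact rejection"
    epochs <- reject_joint_probability(epochs, z = config$reject_z)
    n_rej_jp <- sum(!epochs$retained)
    epochs <- drop_rejected(epochs)
    stage <- "whitening"
    epochs <- whiten_trials(epochs)
    stage <- "cwt"
    tens <- cwt_morlet(epochs, n_scales = config$cwt$n_scales,
                       cycles = config$cwt$cycles,
                       fmin = config$cwt$fmin, fmax = config$cwt$fmax)
    tens <- truncate_and_baseline(tens, config$tf_window, config$tf_baseline)
    tens <- reject_magnitude(tens, z = config$tf_reject_z)
    n_rej_tf <- attr(tens, "n_rejected")
    stage <- "mmr"
    surf <- mmr_tf(tens, n_boot = config$n_boot, seed = block_seed,
                   cdf_method = config$cdf_method)
    list(surface = surf,
         n_trials = length(epochs$labels),
         n_rejected_jointprob = n_rej_jp,
         n_rejected_magnitude = n_rej_tf)
  }, error = function(e) {
    stop("block ", id, ": stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

#' Run the full MMR-TF pipeline
#'
#' Synthesizes (or loads) one block per subject and condition, preprocesses
#' and transforms each, computes per-block MMR-TF surfaces with seeds
#' derived from the master seed, runs the joint DISTATIS group analysis,
#' and extracts features. With `output_dir` set, writes the centroid table
#' (CSV), the resolved configuration (YAML), a plain-text summary report,
#' and the group/feature objects (RDS).
#'
#' @param config a [run_config()].
#' @return object of class `mmr_pipeline`: `group` ([mmr_group()]),
#'   `features` ([mmr_features()]), `surfaces`, `block_info` (per-block
#'   trial/rejection counts), `channel_qc` (a `channel_loadings` or NULL),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  blocks <- list()
  if (is.null(config$inputs)) {
    log_msg(config, "synthesizing ", config$n_subjects, " subject(s) x ",
            length(config$conditions), " condition(s)")
    for (s in seq_len(config$n_subjects)) {
      for (d in config$conditions) {
        id <- sprintf("s%02d_%s", s, d)
        cp <- config$condition_params[[d]]
        base <- config$synth$bursts %||% default_burst_set()
        bursts <- lapply(base, function(b) {
          b$amplitude <- b$amplitude * cp$amplitude_scale *
            config$synth$amplitude_scale
          b$peak_latency_ms <- b$peak_latency_ms + cp$latency_shift_ms
          b
        })
        par <- paradigm_spec(config$synth$n_trials,
                             config$synth$deviant_fraction,
                             config$synth$isi_ms)
        blk <- synthesize_block(
          par, bursts = bursts, noise = config$synth$noise,
          fs = config$synth$fs,
          channel_names = config$synth$channel_names,
          standard_response_uv = config$synth$standard_response_uv,
          phase_jitter_sd = config$synth$phase_jitter_sd,
          pad_s = config$synth$pad_s,
          seed = derive_seed(config$seed, paste0("synth_", id)),
          block_id = id)
        blocks[[id]] <- list(subject = s, condition = d,
                             eeg = blk$eeg, events = blk$events)
      }
    }
  } else {
    for (inp in config$inputs) {
      id <- sprintf("%s_%s", inp$subject, inp$condition)
      eeg <- inp$eeg
      if (is.character(eeg)) {
        if (!file.exists(eeg)) stop("EEG file not found: ", eeg)
        eeg <- readRDS(eeg)
      }
      events <- inp$events
      if (is.character(events)) {
        if (!file.exists(events)) stop("event file not found: ", events)
        events <- read_events_tsv(events)
      }
      blocks[[id]] <- list(subject = inp$subject, condition = inp$condition,
                           eeg = eeg, events = events)
    }
  }

  qc <- NULL
  if (config$channel_qc) {
    log_msg(config, "channel-selection QC (spatial PCA)")
    ests <- lapply(blocks, function(b) {
      cont <- eeg_bandpass(b$eeg, config$filter_band[1], config$filter_band[2])
      cont <- eeg_rereference(cont, "common_average")
      ep <- eeg_epoch(cont, b$events, channel = NULL,
                      window = config$epoch_window, baseline = config$baseline)
      bootstrap_channel_differences(
        ep, n_boot = config$n_boot,
        seed = derive_seed(config$seed, paste0("qc_", b$subject, b$condition)))
    })
    qc <- spatial_pca_loadings(ests)
  }

  surfaces <- list()
  cond_of <- character(0)
  info <- list()
  for (id in names(blocks)) {
    b <- blocks[[id]]
    log_msg(config, "processing block ", id, " (",
            nrow(b$events), " events)")
    res <- process_block(config, b$eeg, b$events,
                         block_seed = derive_seed(config$seed,
                                                  paste0("mmr_", id)),
                         id = id)
    surfaces[[id]] <- res$surface
    cond_of <- c(cond_of, b$condition)
    info[[id]] <- data.frame(block = id, subject = b$subject,
                             condition = b$condition,
                             n_trials = res$n_trials,
                             rejected_jointprob = res$n_rejected_jointprob,
                             rejected_magnitude = res$n_rejected_magnitude)
  }
  block_info <- do.call(rbind, info)
  rownames(block_info) <- NULL

  log_msg(config, "group DISTATIS over ", length(surfaces), " surfaces")
  group <- mmr_group(surfaces, cond_of, pvaf_min = config$pvaf_min)
  log_msg(config, "feature extraction (qLE threshold ",
          config$qle_threshold, ")")
  features <- mmr_features(group, threshold = config$qle_threshold,
                           cdf_method = config$cdf_method)

  out <- structure(list(group = group, features = features,
                        surfaces = surfaces, block_info = block_info,
                        channel_qc = qc, config = config),
                   class = "mmr_pipeline")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out)
  out
}

write_pipeline_outputs <- function(x) {
  dir.create(x$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- x$config$output_dir
  utils::write.csv(x$features$centroids, file.path(od, "centroids.csv"),
                   row.names = FALSE)
  utils::write.csv(x$block_info, file.path(od, "block_info.csv"),
                   row.names = FALSE)
  cfg <- x$config
  cfg$inputs <- NULL
  cfg$synth$noise <- unclass(cfg$synth$noise)
  yaml::write_yaml(unclass(cfg), file.path(od, "config_resolved.yaml"))
  saveRDS(x$group, file.path(od, "group.rds"))
  saveRDS(x$features, file.path(od, "features.rds"))
  rep <- utils::capture.output(print(x))
  writeLines(rep, file.path(od, "report.txt"))
  grDevices::png(file.path(od, "qle_map.png"), width = 900, height = 600)
  plot(x$features)
  grDevices::dev.off()
  invisible(od)
}

#' @export
print.mmr_pipeline <- function(x, ...) {
  cat("MMR-TF pipeline run (master seed ", x$config$seed, ")\n", sep = "")
  cat("Blocks:\n")
  print(x$block_info)
  print(x$group)
  print(x$features)
  invisible(x)
}
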