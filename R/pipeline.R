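# End-to-end runner: synthetic cohort (or on-disk signals) through
# epoching, envelope DFA, surrogate null, split-half reliability,
# questionnaire scoring and the identity association analysis, with all
# tables and a machine-readable summary written to a run directory.

#' Default pipeline configuration
#'
#' All stage parameters in one validated list. Values mirror the
#' measurement settings the pipeline is built around: 20-s epochs with
#' 75% overlap, 26 log-linear DFA windows between 1 and 20 s fitted over
#' 2-16 s, alpha band at a single frontocentral channel, an AAFT
#' surrogate null, and the age/gender/BMI/arousal/epoch-count control
#' set.
#'
#' @param seed Master seed (mandatory for any randomness).
#' @param n_subjects Number of synthetic subjects.
#' @param duration_s,fs Signal duration (s) and sampling rate (Hz).
#' @param bands Character vector of canonical band names to analyse.
#' @param focal_band,focal_channel Focal hypothesis site.
#' @param n_iterations Surrogate iterations.
#' @return Named list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L, n_subjects = 10L, duration_s = 300,
                           fs = 250, bands = "alpha", focal_band = "alpha",
                           focal_channel = "FCz", n_iterations = 100L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_subjects = as.integer(n_subjects),
                    duration_s = duration_s, fs = fs,
                    latent_confusion_correlation = -0.3,
                    item_noise_sd = 0.5,
                    exponent_range = c(0.55, 0.95)),
    input_dir = NULL,
    epoching = list(epoch_len_s = 20, overlap = 0.75, min_epochs = 10L),
    dfa = list(bands = bands, window_range_s = c(1, 20), n_windows = 26L,
               fit_range_s = c(2, 16), method = "sd"),
    surrogate = list(n_iterations = as.integer(n_iterations),
                     percentile = 0.99, prefilter = TRUE, refilter = TRUE),
    association = list(focal_band = focal_band,
                       focal_channel = focal_channel,
                       controls = c("age", "gender", "bmi", "arousal",
                                    "n_epochs"),
                       m = 2L),
    channel_label = focal_channel
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks the cross-module constraints (epoch grid integrality, fit range
#' inside the window range, band edges below Nyquist, iteration and
#' percentile bounds) and fails with a stage-labelled message.
#'
#' @param config A configuration list, e.g. from [default_config()] or
#'   [read_config()].
#' @return The config, invisibly, on success.
#' @export
validate_config <- function(config) {
  fs <- config$simulate$fs
  ep <- config$epoching
  step <- ep$epoch_len_s * (1 - ep$overlap) * fs
  if (abs(step - round(step)) > 1e-9) {
    stop("[epoching] epoch step is not an integer number of samples")
  }
  dfa <- config$dfa
  if (dfa$fit_range_s[1] < dfa$window_range_s[1] ||
      dfa$fit_range_s[2] > dfa$window_range_s[2]) {
    stop("[dfa] fit range must lie inside the window range")
  }
  for (b in dfa$bands) {
    bd <- as_band(b)
    if (bd$high_hz >= fs / 2) stop("[dfa] band ", b, " reaches Nyquist")
  }
  su <- config$surrogate
  if (su$n_iterations < 1L) stop("[surrogate] n_iterations must be >= 1")
  if (su$percentile <= 0 || su$percentile >= 1) {
    stop("[surrogate] percentile must be in (0, 1)")
  }
  if (is.null(config$seed)) stop("[config] seed is mandatory")
  invisible(config)
}

#' Read a YAML pipeline configuration
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else {
        upd[[nm]]
      }
    }
    base
  }
  structure(merge_into(unclass(config), user), class = "run_config")
}

#' Write a multi-channel signal as flat binary with a JSON sidecar
#'
#' Little-endian float64 samples (channels interleaved by column when a
#' matrix) plus `<path>.json` holding `fs` and `channels`.
#'
#' @param signal Numeric vector or matrix (samples x channels).
#' @param path Output `.bin` path.
#' @param fs Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_signal_bin <- function(signal, path, fs) {
  m <- if (is.matrix(signal)) signal else matrix(signal, ncol = 1L)
  channels <- if (!is.null(colnames(m))) colnames(m) else
    paste0("ch", seq_len(ncol(m)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(m), con, size = 8L, endian = "little")
  jsonlite::write_json(list(fs = fs, channels = channels,
                            n_samples = nrow(m)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a flat-binary signal written by [write_signal_bin()]
#'
#' @param path Path to the `.bin` file.
#' @return List with `signal` (matrix, samples x channels), `fs`,
#'   `channels`.
#' @export
read_signal_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$n_samples * length(meta$channels)
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  m <- matrix(x, ncol = length(meta$channels))
  colnames(m) <- meta$channels
  list(signal = m, fs = meta$fs, channels = meta$channels)
}

#' Run the full pipeline
#'
#' Executes epoching, envelope DFA, the AAFT surrogate null, split-half
#' reliability, questionnaire scoring and the association analysis, and
#' writes every stage's table plus a summary to `out_dir`. With
#' `config$input_dir = NULL` (default) a synthetic cohort is generated
#' from `config$simulate`; otherwise per-subject `.bin` signals plus
#' `questionnaire.csv` and `covariates.csv` are read from the directory.
#' Reruns with the same config and seed reproduce every output.
#'
#' @param config A validated `"run_config"`.
#' @param out_dir Output directory (created if needed).
#' @return List of in-memory results (`exclusion`, `dfae`, `surrogate`,
#'   `reliability`, `scores`, `association`, `summary`), invisibly; the
#'   same content is on disk in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- config$simulate$fs
  ep <- config$epoching

  if (is.null(config$input_dir)) {
    cs <- cohort_spec(
      n_subjects = config$simulate$n_subjects,
      latent_confusion_correlation =
        config$simulate$latent_confusion_correlation,
      item_noise_sd = config$simulate$item_noise_sd,
      exponent_range = config$simulate$exponent_range,
      seed = config$seed)
    st <- signal_spec(duration_s = config$simulate$duration_s, fs = fs)
    cohort <- generate_cohort(cs, st)
    signals <- lapply(cohort$signals, function(s) s$signal)
    questionnaire <- cohort$questionnaire
    covariates <- cohort$covariates
  } else {
    files <- list.files(config$input_dir, pattern = "\\.bin$",
                        full.names = TRUE)
    signals <- lapply(files, function(f) read_signal_bin(f)$signal[, 1L])
    names(signals) <- sub("\\.bin$", "", basename(files))
    questionnaire <- utils::read.csv(file.path(config$input_dir,
                                               "questionnaire.csv"))
    covariates <- utils::read.csv(file.path(config$input_dir,
                                            "covariates.csv"))
  }

  epoch_sets <- lapply(names(signals), function(id) {
    segment_epochs(signals[[id]], fs, ep$epoch_len_s, ep$overlap,
                   subject_id = id)
  })
  names(epoch_sets) <- names(signals)
  manifest <- do.call(rbind, lapply(epoch_sets, function(es) {
    if (es$n_epochs == 0L) return(NULL)
    data.frame(subject_id = es$subject_id,
               epoch_index = seq_len(es$n_epochs), start_sample = es$starts)
  }))
  utils::write.csv(manifest, file.path(out_dir, "epochs_manifest.csv"),
                   row.names = FALSE)

  incl <- apply_inclusion_rules(epoch_sets, questionnaire,
                                min_epochs = ep$min_epochs)
  jsonlite::write_json(unclass(incl$report),
                       file.path(out_dir, "exclusion_report.json"),
                       auto_unbox = TRUE)
  kept <- lapply(epoch_sets[incl$included], function(es) {
    es$channels <- config$channel_label
    es
  })

  sizes <- make_window_sizes(config$dfa$window_range_s[1],
                             config$dfa$window_range_s[2],
                             config$dfa$n_windows, fs)
  dfae <- do.call(rbind, lapply(kept, function(es) {
    dfa_per_subject(es, config$dfa$bands, sizes,
                    config$dfa$fit_range_s, config$dfa$method)
  }))
  rownames(dfae) <- NULL
  utils::write.csv(dfae, file.path(out_dir, "dfae.csv"), row.names = FALSE)

  su <- config$surrogate
  ensembles <- lapply(seq_along(kept), function(i) {
    surrogate_dfae_ensemble(kept[[i]], config$association$focal_band,
                            su$n_iterations,
                            seed = derive_seed(config$seed, 5000L + i),
                            sizes = sizes,
                            fit_range_s = config$dfa$fit_range_s,
                            method = config$dfa$method,
                            prefilter = su$prefilter,
                            refilter = su$refilter)
  })
  cohort_sur <- cohort_critical_value(ensembles, su$percentile)
  sur_tab <- data.frame(
    subject_id = vapply(ensembles, function(e) e$subject_id, character(1)),
    channel = config$channel_label,
    band = config$association$focal_band,
    per_subject_mean = cohort_sur$per_subject_means,
    original_dfae = vapply(ensembles, function(e) e$original_dfae, numeric(1)),
    n_iterations = su$n_iterations)
  utils::write.csv(sur_tab, file.path(out_dir, "surrogate_subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(critical_value = cohort_sur$critical_value,
         grand_mean = cohort_sur$grand_mean,
         percentile = su$percentile, n_iterations = su$n_iterations,
         quantile_type = cohort_sur$quantile_type),
    file.path(out_dir, "surrogate_cohort.json"),
    auto_unbox = TRUE, digits = 10)

  rel <- split_half_icc(kept, config$association$focal_band,
                        sizes = sizes,
                        fit_range_s = config$dfa$fit_range_s,
                        method = config$dfa$method)
  jsonlite::write_json(
    list(icc = rel$icc$icc, ci_low = rel$icc$ci_low,
         ci_high = rel$icc$ci_high, n_subjects = rel$icc$n_subjects,
         k = rel$icc$k),
    file.path(out_dir, "reliability.json"), auto_unbox = TRUE, digits = 10)

  epsi_items <- questionnaire[paste0("epsi_", 1:12)]
  epsi_scores <- score_epsi(cbind(questionnaire["subject_id"], epsi_items))
  cesd_scores <- score_cesd(questionnaire[paste0("cesd_", 1:20)])
  scores <- data.frame(subject_id = questionnaire$subject_id,
                       epsi_synthesis = epsi_scores$synthesis,
                       epsi_confusion = epsi_scores$confusion,
                       cesd = cesd_scores)
  alphas <- list(
    synthesis = cronbach_alpha(epsi_items[, 1:6]),
    confusion = cronbach_alpha(epsi_items[, 7:12]),
    cesd = cronbach_alpha(local({
      m <- as.matrix(questionnaire[paste0("cesd_", 1:20)])
      m[, c(4, 8, 12, 16)] <- 3 - m[, c(4, 8, 12, 16)]
      m
    })))
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  subjects <- merge(scores, covariates, by = "subject_id")
  assoc <- dfae_identity_analysis(
    dfae, subjects,
    focal = c(band = config$association$focal_band,
              channel = config$association$focal_channel),
    controls = config$association$controls, m = config$association$m)
  utils::write.csv(assoc$focal, file.path(out_dir, "association_focal.csv"),
                   row.names = FALSE)
  utils::write.csv(assoc$map, file.path(out_dir, "association_map.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = 10, null = "null")
  summary <- list(
    config_hash = config_hash(as.character(cfg_json)),
    n_included = incl$report$n_included,
    focal = list(
      synthesis_rho = assoc$focal$rho[1], synthesis_p = assoc$focal$p_adjusted[1],
      confusion_rho = assoc$focal$rho[2], confusion_p = assoc$focal$p_adjusted[2]),
    surrogate = list(grand_mean = cohort_sur$grand_mean,
                     critical_value = cohort_sur$critical_value),
    icc = rel$icc$icc,
    cronbach_alpha = alphas,
    mean_dfae_focal = mean(dfae$dfae[dfae$band ==
                                       config$association$focal_band]))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))

  invisible(list(exclusion = incl, dfae = dfae, surrogate = cohort_sur,
                 reliability = rel, scores = scores, association = assoc,
                 summary = summary))
}

#' Surrogate-floor simulation for a band-limited-noise cohort
#'
#' Simulates a cohort of subjects whose signals are pure band-limited
#' Gaussian noise, runs the AAFT surrogate ensemble on each subject's
#' 20-s epoch grid, and summarizes the cohort null distribution of the
#' envelope DFA exponent: the grand mean of surrogate exponents and the
#' upper-percentile critical value of the per-iteration cohort means.
#' This is the pipeline's measurement floor - the exponent level produced
#' by amplitude distribution and spectrum alone, with no long-range
#' temporal structure.
#'
#' @param n_subjects Number of simulated subjects. Default 30.
#' @param n_iterations AAFT iterations per subject. Default 100.
#' @param seed Master seed.
#' @param duration_s,fs Signal duration (s) and sampling rate (Hz).
#' @param band Band edges in Hz. Default alpha, 8-13.
#' @param percentile Critical-value percentile. Default 0.99.
#' @return A [cohort_critical_value()] summary.
#' @export
surrogate_floor_simulation <- function(n_subjects = 30L, n_iterations = 100L,
                                       seed = 1L, duration_s = 300, fs = 250,
                                       band = c(8, 13), percentile = 0.99) {
  ensembles <- lapply(seq_len(n_subjects), function(i) {
    sig <- generate_bandlimited_noise(duration_s, fs, band,
                                      seed = derive_seed(seed, 100000L + i))
    es <- segment_epochs(sig, fs, subject_id = sprintf("S%03d", i))
    surrogate_dfae_ensemble(es, band, n_iterations,
                            seed = derive_seed(seed, 200000L + i))
  })
  cohort_critical_value(ensembles, percentile)
}

#' Write a synthetic cohort to a directory of files
#'
#' Per-subject signals as flat binary + JSON sidecars
#' ([write_signal_bin()]), plus `questionnaire.csv` and `covariates.csv`.
#' The layout matches what [run_pipeline()] reads via `config$input_dir`.
#'
#' @param cohort A [generate_cohort()] result with signals.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (is.null(cohort$signals)) stop("cohort was generated without signals")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$signals)) {
    write_signal_bin(cohort$signals[[id]]$signal,
                     file.path(dir, paste0(id, ".bin")),
                     fs = cohort$signals[[id]]$fs)
  }
  utils::write.csv(cohort$questionnaire,
                   file.path(dir, "questionnaire.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates,
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  invisible(dir)
}
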