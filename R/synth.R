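# Synthetic signals and cohorts with known ground truth.
#
# Real resting-state recordings give no access to the true envelope
# exponent, so validation relies on signals constructed to carry a known
# one: a band-limited Gaussian carrier multiplied by a strictly positive,
# slowly varying envelope built from fractional Gaussian noise.

#' Specification of a synthetic band-limited signal
#'
#' @param duration_s Signal duration in seconds (default 300 s, i.e. the
#'   5-minute eyes-closed resting block the pipeline is designed around).
#' @param fs Sampling rate in Hz (default 250).
#' @param band Two-element numeric, carrier band edges in Hz (default
#'   alpha, 8-13 Hz).
#' @param envelope_exponent Target scaling exponent of the amplitude
#'   envelope, in `[0.5, 1]`. 0.5 means an uncorrelated envelope, values
#'   above 0.5 persistent long-range temporal correlation.
#' @param amplitude_scale Overall scale factor (arbitrary units); DFA is
#'   scale-invariant so this does not affect the measured exponent.
#' @param seed Integer seed.
#' @return An object of class `"signal_spec"`.
#' @export
signal_spec <- function(duration_s = 300, fs = 250, band = c(8, 13),
                        envelope_exponent = 0.75, amplitude_scale = 1,
                        seed = 1L) {
  stopifnot(length(band) == 2L)
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop("`band` must satisfy 0 < low < high < fs/2")
  }
  if (envelope_exponent < 0.5 || envelope_exponent > 1.0) {
    stop("`envelope_exponent` must lie in [0.5, 1.0]")
  }
  structure(list(duration_s = duration_s, fs = fs, band = band,
                 envelope_exponent = envelope_exponent,
                 amplitude_scale = amplitude_scale, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise passed through the pipeline's own zero-phase FIR
#' band-pass ([fir_bandpass()]): the stochastic stand-in for an
#' oscillation with no envelope structure beyond that of narrow-band
#' noise. Used both as the carrier of [generate_modulated_oscillation()]
#' and directly as the null cohort for surrogate-floor simulations.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param band Band edges in Hz.
#' @param seed Integer seed.
#' @param fir_order FIR filter order (default 62).
#' @return Numeric vector of `duration_s * fs` samples.
#' @export
generate_bandlimited_noise <- function(duration_s, fs, band, seed,
                                       fir_order = 62L) {
  h <- fir_bandpass(fs, band[1], band[2], fir_order)
  n <- round(duration_s * fs)
  with_seed(seed, zero_phase_filter(stats::rnorm(n), h))
}

#' Band-limited oscillation with a controllable envelope exponent
#'
#' Constructs `carrier * envelope`, where the carrier is band-limited
#' Gaussian noise and the envelope is `exp(modulation_depth * z)` with `z`
#' standardized fractional Gaussian noise of Hurst parameter
#' `envelope_exponent`, generated at `envelope_fs` and linearly
#' interpolated to `fs`. The exponentiation keeps the envelope strictly
#' positive while preserving the rank (and, for moderate depths, the
#' second-order scaling) of the fGn.
#'
#' The envelope rate of 5 Hz matches the ~2.5 Hz half-bandwidth of the
#' alpha-band analysis filter: modulator structure survives the band-pass,
#' while the smallest fitted DFA window (2 s) still spans >= 10 modulator
#' samples. The default modulation depth was fixed by a one-off
#' calibration of pipeline recovery across the exponent range (see the
#' package vignette) and is not meant to be tuned per run.
#'
#' @param spec A [signal_spec()].
#' @param envelope_fs Sample rate (Hz) at which the fGn envelope is
#'   generated before interpolation. Default 5.
#' @param modulation_depth Log-scale depth of the multiplicative envelope.
#'   Default 0.55.
#' @return A list of class `"sim_signal"` with elements `signal` (numeric
#'   vector), `envelope_true` (the modulator, at `fs`), `fs`, `band`, and
#'   `spec`.
#' @export
generate_modulated_oscillation <- function(spec, envelope_fs = 5,
                                           modulation_depth = 0.55) {
  stopifnot(inherits(spec, "signal_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  n_env <- max(16L, round(spec$duration_s * envelope_fs))
  z <- generate_fgn(spec$envelope_exponent, n_env, seed = spec$seed)
  z <- (z - mean(z)) / stats::sd(z)
  env <- stats::approx(seq_len(n_env) / envelope_fs, exp(modulation_depth * z),
                       xout = seq_len(n) / fs, rule = 2)$y
  carrier <- generate_bandlimited_noise(spec$duration_s, fs, spec$band,
                                        seed = derive_seed(spec$seed, 1L))
  structure(list(signal = spec$amplitude_scale * env * carrier,
                 envelope_true = env, fs = fs, band = spec$band, spec = spec),
            class = "sim_signal")
}

#' Specification of a synthetic questionnaire cohort
#'
#' @param n_subjects Number of subjects (>= 3). Default 68, the analysed
#'   sample size the pipeline is modelled on.
#' @param latent_confusion_correlation Target population Spearman
#'   correlation between the true envelope exponent and the identity
#'   confusion scale score, in `[-1, 1]`. Default -0.3.
#' @param item_noise_sd Standard deviation of item-specific noise added to
#'   the latent trait before Likert discretization (latent-trait units).
#'   Default 0.5.
#' @param covariate_ranges Named list of bounds: `age` (integer years),
#'   `bmi` (kg/m^2), `arousal` (integer rating). Gender is a balanced 0/1
#'   draw.
#' @param exponent_range Range of the per-subject true envelope exponents
#'   (uniform after Gaussian-copula transform). Default `c(0.55, 0.95)`.
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 68L, latent_confusion_correlation = -0.3,
                        item_noise_sd = 0.5,
                        covariate_ranges = list(age = c(18, 36),
                                                bmi = c(16, 35),
                                                arousal = c(1, 9)),
                        exponent_range = c(0.55, 0.95), seed = 1L) {
  if (n_subjects < 3L) stop("`n_subjects` must be at least 3")
  if (abs(latent_confusion_correlation) > 1) {
    stop("`latent_confusion_correlation` must lie in [-1, 1]")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 latent_confusion_correlation = latent_confusion_correlation,
                 item_noise_sd = item_noise_sd,
                 covariate_ranges = covariate_ranges,
                 exponent_range = exponent_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Spearman -> Pearson correlation for a bivariate Gaussian copula.
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# Latent Spearman correlation targets among (exponent, confusion,
# synthesis, depression). Confusion-synthesis, confusion-depression and
# synthesis-depression reproduce the questionnaire inter-correlations the
# cohort is meant to emulate; exponent-synthesis and exponent-depression
# are left at zero.
cohort_latent_spearman <- function(rho_conf) {
  m <- diag(4)
  dimnames(m) <- list(c("exponent", "confusion", "synthesis", "depression"),
                      c("exponent", "confusion", "synthesis", "depression"))
  m["exponent", "confusion"] <- m["confusion", "exponent"] <- rho_conf
  m["confusion", "synthesis"] <- m["synthesis", "confusion"] <- -0.56
  m["confusion", "depression"] <- m["depression", "confusion"] <- 0.54
  m["synthesis", "depression"] <- m["depression", "synthesis"] <- -0.51
  m
}

# Discretize a standardized latent column into Likert levels using fixed
# standard-normal cutpoints.
likert_cut <- function(latent, cutpoints, levels) {
  idx <- findInterval(latent, cutpoints) + 1L
  levels[idx]
}

#' Generate a synthetic cohort: signals, questionnaire items, covariates
#'
#' Subjects receive a true envelope exponent drawn uniformly on
#' `exponent_range` through a Gaussian copula that links it to latent
#' identity-confusion, identity-synthesis and depressive-tendency traits
#' with the target Spearman correlations. Items are noisy Likert
#' manifestations of the latent traits (EPSI items in 1..5, CES-D items in
#' 0..3 with the standard four reverse-keyed items stored in raw form), so
#' scale scores are exactly the keyed sums of their items. Likert
#' discretization attenuates the exponent-confusion correlation slightly
#' below the nominal target (a few percent at the default item noise).
#'
#' @param cohort A [cohort_spec()].
#' @param signal_template A [signal_spec()] providing duration, sampling
#'   rate and band of per-subject signals; its `envelope_exponent` and
#'   `seed` are overridden per subject.
#' @param generate_signals If `FALSE`, skip signal synthesis (fast path
#'   for purely statistical simulations).
#' @return A list of class `"synth_cohort"`: `truth` (data frame with
#'   `subject_id`, `envelope_exponent`, latent traits), `questionnaire`
#'   (item-level data frame: 12 EPSI + 20 CES-D columns), `covariates`
#'   (`age`, `gender`, `bmi`, `arousal`), and `signals` (named list of
#'   [generate_modulated_oscillation()] results, or `NULL`).
#' @export
generate_cohort <- function(cohort, signal_template = signal_spec(),
                            generate_signals = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_subjects
  rho_s <- cohort_latent_spearman(cohort$latent_confusion_correlation)
  rho_p <- spearman_to_pearson(rho_s)
  diag(rho_p) <- 1
  ch <- tryCatch(chol(rho_p), error = function(e) {
    stop("latent correlation structure is not positive definite; ",
         "latent_confusion_correlation = ",
         cohort$latent_confusion_correlation,
         " is incompatible with the fixed questionnaire inter-correlations ",
         "(confusion-synthesis -0.56, confusion-depression 0.54, ",
         "synthesis-depression -0.51)", call. = FALSE)
  })

  out <- with_seed(cohort$seed, {
    z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% ch
    colnames(z) <- colnames(rho_s)
    lo <- cohort$exponent_range[1]
    hi <- cohort$exponent_range[2]
    expo <- lo + (hi - lo) * stats::pnorm(z[, "exponent"])

    sdn <- cohort$item_noise_sd
    scale_fac <- sqrt(1 + sdn^2)
    item_block <- function(latent, k, cutpoints, levels) {
      sapply(seq_len(k), function(j) {
        y <- (latent + sdn * stats::rnorm(n)) / scale_fac
        likert_cut(y, cutpoints, levels)
      })
    }
    likert5 <- c(-1.5, -0.5, 0.5, 1.5)
    likert4 <- c(-0.25, 0.75, 1.5)
    syn <- item_block(z[, "synthesis"], 6L, likert5, 1:5)
    con <- item_block(z[, "confusion"], 6L, likert5, 1:5)
    dep <- item_block(z[, "depression"], 20L, likert4, 0:3)
    # store the four standard reverse-keyed CES-D items in raw (reflected)
    # form so that scoring with 3 - x recovers the keyed level
    rev_items <- c(4L, 8L, 12L, 16L)
    dep[, rev_items] <- 3L - dep[, rev_items]

    cr <- cohort$covariate_ranges
    covariates <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = sample(seq(cr$age[1], cr$age[2]), n, replace = TRUE),
      gender = sample(0:1, n, replace = TRUE),
      bmi = pmin(pmax(stats::rnorm(n, 21, 2.5), cr$bmi[1]), cr$bmi[2]),
      arousal = sample(seq(cr$arousal[1], cr$arousal[2]), n, replace = TRUE)
    )
    list(z = z, expo = expo, syn = syn, con = con, dep = dep,
         covariates = covariates)
  })

  ids <- out$covariates$subject_id
  questionnaire <- data.frame(subject_id = ids)
  questionnaire[paste0("epsi_", 1:6)] <- as.data.frame(out$syn)
  questionnaire[paste0("epsi_", 7:12)] <- as.data.frame(out$con)
  questionnaire[paste0("cesd_", 1:20)] <- as.data.frame(out$dep)

  truth <- data.frame(subject_id = ids, envelope_exponent = out$expo,
                      latent_confusion = out$z[, "confusion"],
                      latent_synthesis = out$z[, "synthesis"],
                      latent_depression = out$z[, "depression"])

  signals <- NULL
  if (generate_signals) {
    signals <- lapply(seq_along(ids), function(i) {
      sp <- signal_template
      sp$envelope_exponent <- out$expo[i]
      sp$seed <- derive_seed(cohort$seed, 1000L + i)
      generate_modulated_oscillation(sp)
    })
    names(signals) <- ids
  }

  structure(list(truth = truth, questionnaire = questionnaire,
                 covariates = out$covariates, signals = signals,
                 cohort = cohort),
            class = "synth_cohort")
}
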