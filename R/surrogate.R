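# Amplitude-adjusted Fourier transform surrogates and the cohort-level
# surrogate null for the envelope DFA exponent.

#' AAFT surrogate of a time series
#'
#' Amplitude-adjusted Fourier transform surrogate in three steps:
#' (1) Gaussian deviates are sorted and reordered to the rank order of
#' `x`; (2) the phases of that Gaussian series are randomized (each
#' positive-frequency Fourier coefficient is rotated by an independent
#' uniform phase, with the Hermitian mirror kept and the DC and Nyquist
#' coefficients untouched, so the periodogram is preserved exactly);
#' (3) the sorted values of `x` are reordered by the rank order of the
#' phase-randomized series. The output therefore has exactly the multiset
#' of values of `x`, approximately its spectrum, and no long-range
#' temporal structure beyond that implied by the amplitude distribution.
#'
#' @param x Numeric series of length at least 4.
#' @param seed Integer seed; the same `(x, seed)` always returns the same
#'   surrogate.
#' @param details If `TRUE`, also return the intermediate Gaussianized and
#'   phase-randomized series.
#' @return The surrogate series, or (with `details = TRUE`) a list with
#'   `surrogate`, `gaussian`, `phase_randomized`.
#' @export
aaft_surrogate <- function(x, seed, details = FALSE) {
  n <- length(x)
  if (n < 4L) stop("series must have length at least 4")
  if (max(x) == min(x)) {
    warning("constant series: AAFT surrogate equals the input")
    if (details) return(list(surrogate = x, gaussian = x, phase_randomized = x))
    return(x)
  }
  with_seed(seed, {
    out <- aaft_matrix(matrix(x, ncol = 1L), details = details)
    if (details) lapply(out, function(m) m[, 1L]) else out[, 1L]
  })
}

# Vectorized AAFT across epoch columns; consumes RNG draws column-wise.
# Used directly by the ensemble loop (one seeded call per iteration).
# `pre` optionally carries the iteration-invariant rank order and sorted
# values of each column (precomputed once per ensemble).
aaft_matrix <- function(E, details = FALSE, pre = NULL) {
  n <- nrow(E)
  m <- ncol(E)
  if (is.null(pre)) {
    pre <- list(ord = lapply(seq_len(m), function(j) order(E[, j])),
                sorted = lapply(seq_len(m), function(j) sort.int(E[, j])))
  }
  G <- matrix(0, n, m)
  for (j in seq_len(m)) {
    G[pre$ord[[j]], j] <- sort.int(stats::rnorm(n))
  }
  FG <- stats::mvfft(G)
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  R <- matrix(1 + 0i, n, m)
  if (half > 0L) {
    idx <- 2L:(half + 1L)
    R[idx, ] <- exp(1i * matrix(stats::runif(half * m, 0, 2 * pi), half, m))
    R[n + 2L - idx, ] <- Conj(R[idx, , drop = FALSE])
  }
  GP <- Re(stats::mvfft(FG * R, inverse = TRUE)) / n
  S <- matrix(0, n, m)
  for (j in seq_len(m)) {
    S[order(GP[, j]), j] <- pre$sorted[[j]]
  }
  if (details) list(surrogate = S, gaussian = G, phase_randomized = GP) else S
}

#' Surrogate DFA-exponent ensemble for one subject
#'
#' Per iteration, every epoch's band-filtered series is replaced by an
#' independent AAFT surrogate and the standard envelope-DFA path (band
#' pass, Hilbert envelope, fluctuation function, exponent fit) is rerun
#' unchanged, yielding one surrogate exponent per iteration. The surrogate
#' is built from the band-limited series (not the raw broadband epoch);
#' set `prefilter = FALSE` to surrogate raw epochs instead. Because AAFT
#' rank-remapping leaks some power outside the band, the surrogate is
#' passed through the band filter again on the standard path; `refilter =
#' FALSE` skips that and computes the envelope of the surrogate directly.
#'
#' Reproducibility: iteration `i` uses a seed derived from `seed` and `i`;
#' epochs within an iteration consume sequential draws from that stream.
#'
#' @param epochs An [segment_epochs()] result (one channel, or use
#'   `channel` to select one).
#' @param band Band definition, name, or numeric edges.
#' @param n_iterations Number of surrogate iterations (study-scale 2000;
#'   simulations here typically use 100-200).
#' @param seed Master integer seed.
#' @param channel Channel to use when the epoch set is multi-channel.
#' @param sizes,fit_range_s,method Passed to the DFA stage.
#' @param prefilter Surrogate the band-filtered epoch (default) or raw.
#' @param refilter Re-apply the band filter to the surrogate on the
#'   standard path (default `TRUE`).
#' @return Object of class `"surrogate_ensemble"`: list with
#'   `surrogate_dfae` (one exponent per iteration), `per_subject_mean`,
#'   `original_dfae`, `n_iterations`, `seed`, `subject_id`, `channel`,
#'   `band`.
#' @export
surrogate_dfae_ensemble <- function(epochs, band, n_iterations, seed,
                                    channel = NULL, sizes = NULL,
                                    fit_range_s = c(2, 16), method = "sd",
                                    prefilter = TRUE, refilter = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_iterations < 1L) stop("`n_iterations` must be at least 1")
  band <- as_band(band)
  fs <- epochs$fs
  if (is.null(sizes)) sizes <- make_window_sizes(1, 20, 26L, fs)
  E <- epoch_matrix(epochs, channel)
  h <- fir_bandpass(fs, band$low_hz, band$high_hz, band$fir_order)
  em <- envelope_mask(nrow(E), h)

  zp <- function(M) {  # zero-phase band filter of epoch columns
    g <- zero_phase_kernel(h)
    P <- rbind(M, matrix(0, em$npad - nrow(M), ncol(M)))
    mask <- stats::fft(c(g, numeric(em$npad - length(g))))
    Y <- Re(stats::mvfft(stats::mvfft(P) * mask, inverse = TRUE)) / em$npad
    Y[em$offset + seq_len(nrow(M)), , drop = FALSE]
  }
  base <- if (prefilter) zp(E) else E

  original <- dfae_from_epochs(E, em, sizes, fs, fit_range_s, method)$exponent
  pre <- list(ord = lapply(seq_len(ncol(base)), function(j) order(base[, j])),
              sorted = lapply(seq_len(ncol(base)),
                              function(j) sort.int(base[, j])))
  dfae <- vapply(seq_len(n_iterations), function(i) {
    S <- with_seed(derive_seed(seed, i), aaft_matrix(base, pre = pre))
    EN <- if (refilter) envelope_apply(S, em) else Mod_analytic_cols(S)
    fit_exponent(fluctuation_function(EN, sizes, fs, method = method),
                 fit_range_s)$exponent
  }, numeric(1))

  structure(list(surrogate_dfae = dfae, per_subject_mean = mean(dfae),
                 original_dfae = original, n_iterations = n_iterations,
                 seed = as.integer(seed), subject_id = epochs$subject_id,
                 channel = if (is.null(channel)) epochs$channels[1L] else channel,
                 band = band$name),
            class = "surrogate_ensemble")
}

# Envelope without refiltering: magnitude of the analytic signal per column.
Mod_analytic_cols <- function(S) {
  w <- analytic_weights(nrow(S))
  Mod(stats::mvfft(stats::mvfft(S) * w, inverse = TRUE)) / nrow(S)
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("<surrogate_ensemble>", x$subject_id, x$channel, x$band, ":",
      x$n_iterations, "iterations; mean surrogate DFAe",
      format(round(x$per_subject_mean, 4)), "(original",
      paste0(format(round(x$original_dfae, 4)), ")"), "\n")
  invisible(x)
}

#' Cohort-level surrogate summary and critical value
#'
#' For each surrogate iteration, the exponents are averaged across
#' subjects; the critical value is the empirical upper percentile (linear
#' interpolation convention, `stats::quantile` type 7) of those
#' per-iteration cohort means. An observed cohort-mean exponent above the
#' critical value cannot be explained by the amplitude distribution and
#' spectrum alone.
#'
#' @param ensembles List of [surrogate_dfae_ensemble()] results sharing
#'   `n_iterations`; at least 2 subjects.
#' @param percentile Upper percentile for the critical value. Default 0.99.
#' @return Object of class `"cohort_surrogate_summary"`: list with
#'   `per_iteration_cohort_means`, `critical_value`, `percentile`,
#'   `n_iterations`, `n_subjects`, `grand_mean`, `per_subject_means`,
#'   `quantile_type`.
#' @export
cohort_critical_value <- function(ensembles, percentile = 0.99) {
  if (length(ensembles) < 2L) stop("need at least 2 subjects")
  iters <- vapply(ensembles, function(e) e$n_iterations, numeric(1))
  if (length(unique(iters)) != 1L) {
    stop("ensembles have mismatched iteration counts: ",
         paste(unique(iters), collapse = ", "))
  }
  M <- sapply(ensembles, function(e) e$surrogate_dfae)  # iterations x subjects
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  means <- rowMeans(M)
  structure(list(
    per_iteration_cohort_means = means,
    critical_value = unname(stats::quantile(means, percentile, type = 7)),
    percentile = percentile,
    n_iterations = unique(iters),
    n_subjects = length(ensembles),
    grand_mean = mean(means),
    per_subject_means = vapply(ensembles, function(e) e$per_subject_mean,
                               numeric(1)),
    quantile_type = 7L
  ), class = "cohort_surrogate_summary")
}

#' @export
print.cohort_surrogate_summary <- function(x, ...) {
  cat("<cohort_surrogate_summary>", x$n_subjects, "subjects x",
      x$n_iterations, "iterations; grand mean",
      format(round(x$grand_mean, 4)), "; upper", 100 * (1 - x$percentile),
      "% critical value", format(round(x$critical_value, 4)), "\n")
  invisible(x)
}
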