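# Detrended fluctuation analysis of band-limited amplitude envelopes.
#
# Stages: zero-phase FIR band-pass and Hilbert envelope per epoch;
# mean-centering and cumulative summation into a profile; tiling with
# log-linearly spaced windows; least-squares detrending per window; the
# fluctuation function F(t) as the mean of per-window SDs; and the DFA
# exponent as the log10-log10 slope of F over the 2-16 s fit range.

#' Frequency band definition
#'
#' @param name Band label.
#' @param low_hz,high_hz Band edges in Hz.
#' @param fir_order FIR filter order used for extraction. Default 62.
#' @return Object of class `"band_definition"`.
#' @export
band_definition <- function(name, low_hz, high_hz, fir_order = 62L) {
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 fir_order = as.integer(fir_order)),
            class = "band_definition")
}

#' The four canonical analysis bands
#'
#' Theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#'
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) {
    b <- canonical_bands()[[band]]
    if (is.null(b)) stop("unknown band name: ", band)
    return(b)
  }
  if (is.numeric(band) && length(band) == 2L) {
    return(band_definition(paste0(band[1], "-", band[2], "Hz"),
                           band[1], band[2]))
  }
  stop("`band` must be a band_definition, a canonical band name, ",
       "or a numeric pair of edges")
}

#' Band-limited amplitude envelope of an epoch
#'
#' Applies a zero-phase (forward-backward equivalent) linear-phase FIR
#' band-pass of the band's stated order, then takes the magnitude of the
#' analytic signal. Both steps are evaluated on a zero-padded FFT, so the
#' band-pass is a true linear convolution; no edge trimming is applied
#' inside the epoch. Output length equals input length.
#'
#' @param epoch Numeric vector (one epoch, one channel).
#' @param fs Sampling rate in Hz.
#' @param band A [band_definition()], a canonical band name such as
#'   `"alpha"`, or a numeric pair of edges in Hz.
#' @return Numeric envelope, same length as `epoch`.
#' @export
bandpass_envelope <- function(epoch, fs, band) {
  band <- as_band(band)
  if (band$high_hz >= fs / 2) {
    stop("band edge ", band$high_hz, " Hz at or above Nyquist (", fs / 2, ")")
  }
  if (length(epoch) < 3L * band$fir_order) {
    stop("epoch too short: need at least 3 x fir_order = ",
         3L * band$fir_order, " samples")
  }
  h <- fir_bandpass(fs, band$low_hz, band$high_hz, band$fir_order)
  em <- envelope_mask(length(epoch), h)
  envelope_apply(matrix(epoch, ncol = 1L), em)[, 1L]
}

#' Log-linearly spaced DFA window sizes
#'
#' `n` window durations equally spaced in log between `min_s` and `max_s`
#' seconds, each rounded (half away from zero) to an integer number of
#' samples. Duplicate sizes after rounding are collapsed with a warning.
#'
#' @param min_s,max_s Smallest and largest window duration in seconds.
#' @param n Number of windows. Default 26.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of window sizes in samples, strictly increasing.
#' @examples
#' make_window_sizes(1, 20, 26, 250)
#' @export
make_window_sizes <- function(min_s = 1, max_s = 20, n = 26L, fs = 250) {
  if (!(min_s < max_s)) stop("`min_s` must be smaller than `max_s`")
  if (n < 2L) stop("`n` must be at least 2")
  sizes <- round_half_away(fs * min_s * (max_s / min_s)^((0:(n - 1L)) / (n - 1L)))
  sizes <- as.integer(sizes)
  if (anyDuplicated(sizes)) {
    warning("window sizes collapsed after rounding to integer samples (",
            n, " requested, ", length(unique(sizes)), " distinct)")
    sizes <- unique(sizes)
  }
  sizes
}

# Per-window detrended SDs from cumulative moments of the profile matrix.
# P: profile matrix (samples x epochs). Returns list of per-size vectors of
# SDs pooled across windows and epochs. Uses shift-adjusted moments (each
# window referenced to the profile value just before it) to avoid
# catastrophic cancellation in the RSS.
window_sds <- function(P, sizes, denom_offset) {
  N <- nrow(P)
  m <- ncol(P)
  # remove a global linear trend per column first: per-window linear
  # detrending is invariant to it, and the reduced dynamic range keeps
  # the cumulative-moment arithmetic below the oracle tolerance even for
  # strongly trending profiles
  tt <- seq_len(N) - (N + 1) / 2
  beta <- colSums(P * tt) / sum(tt * tt)
  P <- P - rep(colMeans(P), each = N) - tt %o% beta
  Pp <- rbind(0, P)
  col_cumsum <- function(M) {
    do.call(cbind, lapply(seq_len(ncol(M)), function(j) cumsum(M[, j])))
  }
  C1 <- col_cumsum(Pp)
  C2 <- col_cumsum(Pp * (c(0L, seq_len(N))))
  Cq <- col_cumsum(Pp * Pp)
  lapply(sizes, function(s) {
    nw <- N %/% s
    if (nw < 1L) return(numeric(0))
    a <- (0:(nw - 1L)) * s + 1L      # window start sample (1-based in P)
    St <- s * (s + 1) / 2
    Stt <- s * (s + 1) * (2 * s + 1) / 6
    Stt_c <- s * (s^2 - 1) / 12
    # reference each window to the secant line through its bracketing
    # profile values; the least-squares residual is invariant to
    # subtracting a linear function, and the small dynamic range keeps
    # the moment arithmetic numerically clean
    r <- Pp[a, , drop = FALSE]
    b0 <- (Pp[a + s, , drop = FALSE] - r) / s
    Sy <- C1[a + s, , drop = FALSE] - C1[a, , drop = FALSE] - s * r
    Sj <- C2[a + s, , drop = FALSE] - C2[a, , drop = FALSE]
    Sty <- Sj - outer(a - 1, rep(1, m)) * (Sy + s * r) - r * St
    Syy <- Cq[a + s, , drop = FALSE] - Cq[a, , drop = FALSE] -
      2 * r * (Sy + s * r) + s * r * r
    Sy2 <- Sy - b0 * St
    Sty2 <- Sty - b0 * Stt
    Syy2 <- Syy - 2 * b0 * Sty + b0 * b0 * Stt
    Sty_c <- Sty2 - St * Sy2 / s
    rss <- pmax((Syy2 - Sy2 * Sy2 / s) - Sty_c * Sty_c / Stt_c, 0)
    sqrt(as.vector(rss) / (s - denom_offset))
  })
}

#' Fluctuation function of cumulative-summed envelopes
#'
#' Each envelope (one per epoch) is mean-centered and cumulatively summed
#' into a profile. For every window size the profile is tiled with
#' non-overlapping windows from its first sample (a partial tail window is
#' discarded), each window is linearly detrended by least squares, and the
#' SD of the detrended samples is taken. `F(t)` at window size `t` is the
#' mean of these SDs over all windows of that size across all epochs.
#'
#' `method = "sd"` (default) averages per-window SDs, the aggregation the
#' pipeline is specified with; `method = "rms"` gives the canonical DFA
#' variant, the root of the mean per-window residual variance
#' (denominator `n` per window).
#'
#' @param envelopes Numeric vector, list of equal-length numeric vectors,
#'   or matrix with one epoch per column.
#' @param sizes Integer window sizes in samples ([make_window_sizes()]);
#'   all must be at most the epoch length.
#' @param fs Sampling rate in Hz (used to express sizes in seconds).
#' @param method `"sd"` or `"rms"`.
#' @return Object of class `"fluctuation_function"`: list with
#'   `sizes_samples`, `sizes_s`, `F`, `n_windows` (windows pooled per
#'   size), `fs`, `method`, `degenerate` (`TRUE` when all inputs were
#'   constant so `F` is identically zero).
#' @export
fluctuation_function <- function(envelopes, sizes, fs,
                                 method = c("sd", "rms")) {
  method <- match.arg(method)
  if (is.numeric(envelopes) && is.null(dim(envelopes))) {
    envelopes <- list(envelopes)
  }
  if (is.matrix(envelopes)) {
    E <- envelopes
  } else {
    lens <- lengths(envelopes)
    if (length(unique(lens)) != 1L) stop("all epochs must have equal length")
    E <- matrix(unlist(envelopes, use.names = FALSE), nrow = lens[1L])
  }
  if (ncol(E) < 1L) stop("need at least one epoch")
  N <- nrow(E)
  sizes <- as.integer(sizes)
  if (any(sizes > N)) stop("window size exceeds epoch length")
  if (any(sizes < 2L)) stop("window sizes must be at least 2 samples")

  Ec <- E - rep(colMeans(E), each = N)
  P <- do.call(cbind, lapply(seq_len(ncol(Ec)), function(j) cumsum(Ec[, j])))
  sds <- window_sds(P, sizes, denom_offset = if (method == "sd") 1 else 0)
  Fv <- vapply(sds, mean, numeric(1))
  if (method == "rms") Fv <- vapply(sds, function(v) sqrt(mean(v^2)), numeric(1))
  nw <- vapply(sds, length, integer(1))

  degenerate <- all(Fv == 0)
  if (degenerate) {
    warning("constant envelope(s): fluctuation function is identically ",
            "zero; downstream exponent fit will refuse this input")
  }
  structure(list(sizes_samples = sizes, sizes_s = sizes / fs, F = Fv,
                 n_windows = nw, fs = fs, method = method,
                 degenerate = degenerate),
            class = "fluctuation_function")
}

#' @export
print.fluctuation_function <- function(x, ...) {
  cat("<fluctuation_function>", length(x$sizes_samples), "window sizes,",
      format(min(x$sizes_s)), "-", format(max(x$sizes_s)), "s; method",
      x$method, if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Fit the DFA exponent from a fluctuation function
#'
#' Ordinary least squares of `log10 F` on `log10` window duration in
#' seconds, restricted to window sizes inside the closed fit range
#' (default 2-16 s). The slope is the DFA exponent: 0.5 for a temporally
#' uncorrelated envelope, values in (0.5, 1] for persistent long-range
#' temporal correlation.
#'
#' @param ff A [fluctuation_function()].
#' @param fit_range_s Closed fit range in seconds. Default `c(2, 16)`.
#' @return Object of class `"dfa_estimate"`: list with `exponent`,
#'   `intercept` (log10 units), `fit_window_count`, `fit_range_s`.
#' @export
fit_exponent <- function(ff, fit_range_s = c(2, 16)) {
  stopifnot(inherits(ff, "fluctuation_function"))
  if (ff$degenerate) stop("degenerate (constant) input: exponent undefined")
  keep <- ff$sizes_s >= fit_range_s[1] & ff$sizes_s <= fit_range_s[2]
  if (sum(keep) < 3L) {
    stop("fewer than 3 window sizes inside the fit range [",
         fit_range_s[1], ", ", fit_range_s[2], "] s")
  }
  if (any(ff$F[keep] <= 0)) stop("non-positive F inside the fit range")
  lx <- log10(ff$sizes_s[keep])
  ly <- log10(ff$F[keep])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  structure(list(exponent = slope, intercept = mean(ly) - slope * mean(lx),
                 fit_window_count = sum(keep), fit_range_s = fit_range_s),
            class = "dfa_estimate")
}

#' @export
print.dfa_estimate <- function(x, ...) {
  cat("<dfa_estimate> exponent", format(round(x$exponent, 4)), "over",
      x$fit_window_count, "window sizes in [",
      x$fit_range_s[1], ",", x$fit_range_s[2], "] s\n")
  invisible(x)
}

# Internal: stack an epoch_set's epochs for one channel as a matrix.
epoch_matrix <- function(epochs, channel = NULL) {
  if (epochs$n_epochs == 0L) stop("epoch set is empty")
  first <- epochs$epochs[[1L]]
  if (is.matrix(first)) {
    if (is.null(channel)) channel <- epochs$channels[1L]
    sapply(epochs$epochs, function(e) e[, channel])
  } else {
    sapply(epochs$epochs, identity)
  }
}

# Internal: envelope DFA for a matrix of raw epochs under a prebuilt mask.
dfae_from_epochs <- function(E, em, sizes, fs, fit_range_s, method = "sd") {
  EN <- envelope_apply(E, em)
  fit_exponent(fluctuation_function(EN, sizes, fs, method = method),
               fit_range_s)
}

#' Envelope DFA exponents for one subject across channels and bands
#'
#' Runs band-pass envelope extraction, fluctuation-function computation
#' and exponent fitting for every channel x band combination of an epoch
#' set, returning a long-format table.
#'
#' @param epochs An [segment_epochs()] result.
#' @param bands List of [band_definition()]s (default [canonical_bands()]),
#'   or a single band / band name.
#' @param sizes Window sizes in samples; default
#'   `make_window_sizes(1, 20, 26, fs)` capped implicitly by the epoch
#'   length.
#' @param fit_range_s Fit range in seconds. Default `c(2, 16)`.
#' @param method Fluctuation aggregation, `"sd"` (default) or `"rms"`.
#' @return Data frame with columns `subject_id`, `channel`, `band`,
#'   `dfae`, `intercept`, `n_epochs`, `fit_window_count`.
#' @export
dfa_per_subject <- function(epochs, bands = canonical_bands(), sizes = NULL,
                            fit_range_s = c(2, 16), method = "sd") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (inherits(bands, "band_definition")) {
    bands <- list(bands)
  } else if (is.character(bands)) {
    bands <- as.list(bands)
  } else if (is.numeric(bands)) {
    bands <- list(bands)
  }
  bands <- lapply(bands, as_band)
  fs <- epochs$fs
  if (is.null(sizes)) sizes <- make_window_sizes(1, 20, 26L, fs)
  rows <- list()
  for (ch in epochs$channels) {
    E <- epoch_matrix(epochs, if (length(epochs$channels) > 1L ||
                                  is.matrix(epochs$epochs[[1L]])) ch else NULL)
    for (b in bands) {
      h <- fir_bandpass(fs, b$low_hz, b$high_hz, b$fir_order)
      em <- envelope_mask(nrow(E), h)
      est <- tryCatch(
        dfae_from_epochs(E, em, sizes, fs, fit_range_s, method),
        error = function(e) {
          stop("subject ", epochs$subject_id, ", channel ", ch, ", band ",
               b$name, ": ", conditionMessage(e), call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = epochs$subject_id, channel = ch, band = b$name,
        dfae = est$exponent, intercept = est$intercept,
        n_epochs = epochs$n_epochs, fit_window_count = est$fit_window_count)
    }
  }
  do.call(rbind, rows)
}
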