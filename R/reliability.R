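# Split-half reliability of the envelope DFA exponent via the one-way
# random-effects, absolute-agreement, average-measures intraclass
# correlation coefficient, ICC(1,k).

#' Split an epoch set into two halves of non-overlapping epochs
#'
#' From the (possibly overlapping) epoch grid, the maximal set of
#' mutually non-overlapping epochs is selected greedily from the first
#' epoch onward (with the default 75% overlap this keeps every 4th
#' epoch). The first `m` and last `m` of the selected epochs form the two
#' halves, `m = floor(count / 2)`; with an odd count the middle epoch is
#' dropped, so both halves always contain the same number of epochs.
#'
#' @param epochs An [segment_epochs()] result.
#' @return List with elements `first` and `second`, both `"epoch_set"`
#'   objects.
#' @export
split_halves <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  len <- as.integer(round(epochs$epoch_len_s * epochs$fs))
  keep <- integer(0)
  last_end <- -Inf
  for (i in seq_along(epochs$starts)) {
    if (epochs$starts[i] > last_end) {
      keep <- c(keep, i)
      last_end <- epochs$starts[i] + len - 1L
    }
  }
  m <- length(keep) %/% 2L
  if (m < 1L) stop("fewer than 2 non-overlapping epochs available")
  subset_set <- function(idx) {
    out <- epochs
    out$epochs <- epochs$epochs[idx]
    out$starts <- epochs$starts[idx]
    out$n_epochs <- length(idx)
    out
  }
  list(first = subset_set(keep[seq_len(m)]),
       second = subset_set(keep[seq.int(length(keep) - m + 1L, length(keep))]))
}

#' One-way random-effects, average-measures intraclass correlation
#'
#' ICC(1,k) in the McGraw and Wong convention: from the one-way ANOVA
#' decomposition with subjects as the random factor,
#' `ICC(1,k) = (MSB - MSW) / MSB`, where MSB and MSW are the between- and
#' within-subject mean squares over `k` measurements per subject. The
#' confidence interval uses the F-distribution bounds for the one-way
#' average-measures case: with `F = MSB/MSW` and `q(p, d1, d2)` the F
#' quantile, the bounds are `1 - q(1 - a/2, n - 1, n(k - 1)) / F` and
#' `1 - 1 / (F * q(1 - a/2, n(k - 1), n - 1))`.
#'
#' @param measurements Numeric matrix, subjects in rows, the `k` repeated
#'   measurements in columns. No missing cells allowed.
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return Object of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `msb`, `msw`, `n_subjects`, `k`, `degenerate` (`TRUE` when the
#'   between-subject variance is zero, in which case `icc` is reported as
#'   0).
#' @export
icc_oneway <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 measurements per subject")

  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))

  degenerate <- msb <= 0 || (msb == 0 && msw == 0)
  icc <- if (msb > 0) (msb - msw) / msb else 0

  alpha <- 1 - conf_level
  if (msw > 0) {
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    ci <- c(icc, icc)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 msb = msb, msw = msw, n_subjects = n, k = k,
                 conf_level = conf_level, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ICC(1,", x$k, ") = ", format(round(x$icc, 4)),
      ", ", 100 * x$conf_level, "% CI [", format(round(x$ci_low, 4)), ", ",
      format(round(x$ci_high, 4)), "], n = ", x$n_subjects,
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Split-half reliability of the DFA exponent across a cohort
#'
#' For each subject the non-overlapping epochs are split into equal
#' halves ([split_halves()]), the envelope DFA exponent is computed on
#' each half, and the two-column matrix of half-exponents is fed to
#' [icc_oneway()].
#'
#' @param epoch_sets Named list of per-subject [segment_epochs()] results.
#' @param band Band definition, name, or numeric edges.
#' @param channel Optional channel for multi-channel epoch sets.
#' @param sizes,fit_range_s,method Passed to the DFA stage.
#' @param conf_level Confidence level. Default 0.95.
#' @return Object of class `"split_half_result"`: list with `halves` (data
#'   frame `subject_id`, `dfae_first_half`, `dfae_second_half`,
#'   `n_epochs_per_half`) and `icc` (an `"icc_result"`).
#' @export
split_half_icc <- function(epoch_sets, band, channel = NULL, sizes = NULL,
                           fit_range_s = c(2, 16), method = "sd",
                           conf_level = 0.95) {
  halves <- lapply(epoch_sets, function(ep) {
    hs <- split_halves(ep)
    d1 <- dfa_per_subject(hs$first, band, sizes, fit_range_s, method)
    d2 <- dfa_per_subject(hs$second, band, sizes, fit_range_s, method)
    if (!is.null(channel)) {
      d1 <- d1[d1$channel == channel, ]
      d2 <- d2[d2$channel == channel, ]
    }
    c(d1$dfae[1L], d2$dfae[1L], hs$first$n_epochs)
  })
  tab <- do.call(rbind, halves)
  out <- data.frame(subject_id = names(epoch_sets),
                    dfae_first_half = tab[, 1L],
                    dfae_second_half = tab[, 2L],
                    n_epochs_per_half = as.integer(tab[, 3L]))
  structure(list(halves = out,
                 icc = icc_oneway(tab[, 1:2], conf_level = conf_level)),
            class = "split_half_result")
}
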