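# Segmentation of cleaned continuous recordings into overlapping epochs,
# and the subject-inclusion bookkeeping applied before any analysis.

#' Segment a continuous signal into overlapping fixed-length epochs
#'
#' Epochs of `epoch_len_s` seconds are laid on a grid anchored at the
#' first sample, advancing by `epoch_len_s * (1 - overlap)` seconds (the
#' default 75% overlap advances 5 s). A candidate epoch that contains any
#' `boundaries` sample (e.g. a splice left by upstream artifact-segment
#' rejection) is dropped, because the signal is discontinuous there.
#'
#' @param signal Numeric vector, or numeric matrix with one column per
#'   channel (column names are taken as channel labels).
#' @param fs Sampling rate in Hz.
#' @param epoch_len_s Epoch length in seconds; `epoch_len_s * fs` must be
#'   an integer. Default 20.
#' @param overlap Fractional overlap in `[0, 1)`. Default 0.75. The step
#'   `epoch_len_s * (1 - overlap) * fs` must be a whole number of samples.
#' @param boundaries Integer vector of 1-based sample indices at which the
#'   recording is discontinuous.
#' @param subject_id Optional subject label carried through to outputs.
#' @return An object of class `"epoch_set"`: list with `epochs` (list of
#'   numeric vectors or matrices), `starts` (1-based start samples),
#'   `n_epochs`, `fs`, `epoch_len_s`, `channels`, `subject_id`. A signal
#'   shorter than one epoch yields an empty epoch set.
#' @export
segment_epochs <- function(signal, fs, epoch_len_s = 20, overlap = 0.75,
                           boundaries = integer(0), subject_id = NA_character_) {
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  len <- epoch_len_s * fs
  if (abs(len - round(len)) > 1e-9) {
    stop("`epoch_len_s * fs` must be an integer number of samples")
  }
  len <- as.integer(round(len))
  step <- epoch_len_s * (1 - overlap) * fs
  if (abs(step - round(step)) > 1e-9) {
    stop("epoch step (epoch_len_s * (1 - overlap) * fs) is not an integer ",
         "number of samples")
  }
  step <- as.integer(round(step))
  if (step < 1L) stop("epoch step must be at least one sample")

  is_mat <- is.matrix(signal)
  n <- if (is_mat) nrow(signal) else length(signal)
  channels <- if (is_mat) {
    if (is.null(colnames(signal))) paste0("ch", seq_len(ncol(signal)))
    else colnames(signal)
  } else "ch1"

  starts <- if (n >= len) seq.int(1L, n - len + 1L, by = step) else integer(0)
  if (length(boundaries) > 0L && length(starts) > 0L) {
    keep <- vapply(starts, function(s0) {
      !any(boundaries >= s0 & boundaries <= s0 + len - 1L)
    }, logical(1))
    starts <- starts[keep]
  }
  epochs <- lapply(starts, function(s0) {
    if (is_mat) signal[s0:(s0 + len - 1L), , drop = FALSE]
    else signal[s0:(s0 + len - 1L)]
  })
  structure(list(epochs = epochs, starts = as.integer(starts),
                 n_epochs = length(epochs), fs = fs,
                 epoch_len_s = epoch_len_s, channels = channels,
                 subject_id = subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", x$n_epochs, "epochs of", x$epoch_len_s, "s at",
      x$fs, "Hz;", length(x$channels), "channel(s)\n")
  invisible(x)
}

#' Apply the subject-inclusion rules and build an exclusion report
#'
#' Subjects are excluded if they retain fewer than `min_epochs` epochs
#' ("fewer than" is strict: exactly `min_epochs` epochs is included), if
#' flagged non-compliant (e.g. fell asleep during the recording), or if
#' questionnaire data are missing. A subject failing several rules is
#' counted once, in the first failing category, using the fixed precedence
#' low-epochs, then non-compliance, then missing questionnaire.
#'
#' @param epoch_counts Named integer vector of retained epoch counts per
#'   subject, or a named list of [segment_epochs()] results.
#' @param questionnaires Data frame with a `subject_id` column and item
#'   columns; a subject is "missing" if absent from the table or if any
#'   item is `NA`.
#' @param flags Named logical vector, `TRUE` for compliant subjects.
#'   Subjects not named are treated as compliant.
#' @param min_epochs Minimum retained epochs required. Default 10.
#' @return List with `included` (character vector of subject ids) and
#'   `report`, an `"exclusion_report"` with counts `n_recruited`,
#'   `excluded_low_epochs`, `excluded_non_compliance`,
#'   `excluded_missing_questionnaire`, `n_included`.
#' @export
apply_inclusion_rules <- function(epoch_counts, questionnaires = NULL,
                                  flags = NULL, min_epochs = 10L) {
  if (is.list(epoch_counts) && !is.data.frame(epoch_counts)) {
    epoch_counts <- vapply(epoch_counts, function(e) e$n_epochs, integer(1))
  }
  ids <- names(epoch_counts)
  if (is.null(ids)) stop("`epoch_counts` must be named by subject id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  low <- epoch_counts < min_epochs
  non_compliant <- rep(FALSE, length(ids))
  if (!is.null(flags)) {
    idx <- match(ids, names(flags))
    non_compliant <- !is.na(idx) & !unlist(flags)[idx]
  }
  missing_q <- rep(FALSE, length(ids))
  if (!is.null(questionnaires)) {
    qidx <- match(ids, questionnaires$subject_id)
    item_cols <- setdiff(names(questionnaires), "subject_id")
    has_na <- apply(questionnaires[item_cols], 1L, anyNA)
    missing_q <- is.na(qidx) | has_na[qidx]
    missing_q[is.na(missing_q)] <- TRUE
  }

  cat_low <- low
  cat_nc <- !low & non_compliant
  cat_mq <- !low & !non_compliant & missing_q
  included <- ids[!(cat_low | cat_nc | cat_mq)]

  report <- structure(list(
    n_recruited = length(ids),
    excluded_low_epochs = sum(cat_low),
    excluded_non_compliance = sum(cat_nc),
    excluded_missing_questionnaire = sum(cat_mq),
    n_included = length(included)
  ), class = "exclusion_report")
  list(included = included, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> recruited:", x$n_recruited,
      "| low-epochs:", x$excluded_low_epochs,
      "| non-compliance:", x$excluded_non_compliance,
      "| missing questionnaire:", x$excluded_missing_questionnaire,
      "| included:", x$n_included, "\n")
  invisible(x)
}
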