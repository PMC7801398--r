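# Scoring of the EPSI identity subscales and the CES-D depression scale,
# and Cronbach's alpha internal consistency.

#' Default EPSI identity-subscale scoring key
#'
#' Twelve items: items 1-6 keyed to identity synthesis, items 7-12 to
#' identity confusion. The assignment is configurable because instrument
#' versions order items differently; an editable copy ships in
#' `inst/extdata/epsi_key.csv`.
#'
#' @return Data frame with columns `item` and `subscale`.
#' @export
epsi_key <- function() {
  data.frame(item = paste0("epsi_", 1:12),
             subscale = rep(c("synthesis", "confusion"), each = 6L))
}

check_items <- function(items, k, lo, hi, what) {
  if (length(items) != k) stop("expected exactly ", k, " ", what, " items")
  bad <- is.na(items) | items < lo | items > hi | items != round(items)
  if (any(bad)) {
    warning(sum(bad), " missing/out-of-range ", what,
            " item(s): subject flagged for exclusion (scores set to NA)")
    return(FALSE)
  }
  TRUE
}

#' Score the EPSI identity subscales
#'
#' Subscale sums of the keyed items; responses are on a 1 (strongly
#' disagree) to 5 (strongly agree) scale, so each 6-item subscale score
#' lies in `[6, 30]`. The two subscales are scored separately (identity
#' synthesis and confusion coexist rather than being opposite poles), so
#' no reverse-coding is applied. Missing or out-of-range items yield `NA`
#' scores with a warning, flagging the subject for exclusion.
#'
#' @param items Numeric vector of 12 responses, ordered as in `key`, or a
#'   data frame / matrix with one subject per row and the key's item
#'   columns.
#' @param key Scoring key, as from [epsi_key()].
#' @return For a single vector, a named numeric `c(synthesis, confusion)`;
#'   for tabular input, a data frame with columns `synthesis` and
#'   `confusion`.
#' @examples
#' score_epsi(c(5, 4, 4, 3, 2, 5, 1, 2, 2, 3, 1, 2))
#' @export
score_epsi <- function(items, key = epsi_key()) {
  if (is.data.frame(items) || is.matrix(items)) {
    m <- as.matrix(as.data.frame(items)[, key$item])
    res <- t(apply(m, 1L, function(r) score_epsi(as.numeric(r), key)))
    return(data.frame(synthesis = res[, "synthesis"],
                      confusion = res[, "confusion"]))
  }
  names(items) <- key$item
  if (!check_items(items, 12L, 1, 5, "EPSI")) {
    return(c(synthesis = NA_real_, confusion = NA_real_))
  }
  c(synthesis = sum(items[key$subscale == "synthesis"]),
    confusion = sum(items[key$subscale == "confusion"]))
}

#' Score the CES-D depression scale
#'
#' Standard CES-D sum: 20 items rated 0 ("rarely or none of the time") to
#' 3 ("most or all of the time"); the four positively worded items
#' (default 4, 8, 12, 16) are reverse-scored as `3 - x` before summing.
#' Range 0-60. Missing or out-of-range items yield `NA` with a warning.
#'
#' @param items Numeric vector of 20 raw responses in `0..3`, or a data
#'   frame / matrix with one subject per row (columns `cesd_1..cesd_20` or
#'   the first 20 columns).
#' @param reverse_items Indices of the reverse-keyed items.
#' @return Numeric score (or vector of scores for tabular input).
#' @export
score_cesd <- function(items, reverse_items = c(4L, 8L, 12L, 16L)) {
  if (is.data.frame(items) || is.matrix(items)) {
    df <- as.data.frame(items)
    cols <- if (all(paste0("cesd_", 1:20) %in% names(df))) {
      paste0("cesd_", 1:20)
    } else {
      names(df)[seq_len(20L)]
    }
    return(apply(as.matrix(df[, cols]), 1L,
                 function(r) score_cesd(as.numeric(r), reverse_items)))
  }
  if (!check_items(items, 20L, 0, 3, "CES-D")) return(NA_real_)
  items[reverse_items] <- 3 - items[reverse_items]
  sum(items)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a sum scale:
#' `alpha = k/(k - 1) * (1 - sum(item variances) / var(item sums))`, with
#' all variances using the sample (`n - 1`) denominator.
#'
#' @param item_matrix Numeric matrix or data frame, subjects in rows,
#'   items in columns; at least 2 items and 2 subjects.
#' @return Alpha (dimensionless). Zero total variance is degenerate and
#'   returns `NA` with a warning.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(m) < 2L) stop("need at least 2 subjects")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    warning("zero total-score variance: alpha undefined")
    return(NA_real_)
  }
  item_vars <- apply(m, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
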