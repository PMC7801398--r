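# Spearman partial rank correlations between envelope DFA exponents and
# identity scores, with one-tailed Bonferroni-adjusted inference and
# descriptive band x channel correlation maps.

#' Spearman partial rank correlation
#'
#' All variables (including controls; gender should already be coded
#' numerically) are rank-transformed with average ranks for ties, then
#' the partial correlation of the ranked focal variables given the ranked
#' controls is computed. Two algebraically equivalent routes are
#' available: `"residuals"` (default) correlates the residuals of the
#' ranked `x` and `y` after least-squares regression on the ranked
#' controls; `"invcor"` uses the inverse-correlation-matrix identity.
#' The p-value uses the t approximation with `n - 2 - k` degrees of
#' freedom for `k` controls.
#'
#' With no controls this reduces exactly to the plain Spearman rank
#' correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls Optional numeric matrix or data frame of control
#'   variables (one column each).
#' @param method Computation route, `"residuals"` or `"invcor"`.
#' @return List with `rho`, `p_two_tailed`, `n`, `df`, `n_controls`.
#' @export
spearman_partial <- function(x, y, controls = NULL,
                             method = c("residuals", "invcor")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  Z <- NULL
  if (!is.null(controls)) {
    Z <- as.matrix(controls)
    if (nrow(Z) != n) stop("controls must have one row per observation")
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2L) stop("need n > number of controls + 2")

  vars <- c(list(x = x, y = y),
            if (!is.null(Z)) stats::setNames(as.list(as.data.frame(Z)),
                                             colnames(Z)))
  ranked <- lapply(vars, rank)  # average ranks for ties
  const <- vapply(ranked, function(r) stats::var(r) == 0, logical(1))
  if (any(const)) {
    nm <- names(ranked)[const]
    nm[nm == ""] <- paste0("control_", which(const)[nm == ""])
    stop("variable constant after ranking: ", paste(nm, collapse = ", "))
  }
  rx <- ranked$x
  ry <- ranked$y
  if (k == 0L) {
    rho <- stats::cor(rx, ry)
  } else {
    RZ <- do.call(cbind, ranked[-(1:2)])
    if (method == "residuals") {
      qr_z <- qr(cbind(1, RZ))
      rho <- stats::cor(qr.resid(qr_z, rx), qr.resid(qr_z, ry))
    } else {
      R <- stats::cor(cbind(rx, ry, RZ))
      Ri <- solve(R)
      rho <- -Ri[1L, 2L] / sqrt(Ri[1L, 1L] * Ri[2L, 2L])
    }
  }
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p_two_tailed = 2 * stats::pt(-abs(tval), df),
       n = n, df = df, n_controls = k)
}

#' One-tailed, Bonferroni-adjusted inference for a partial correlation
#'
#' One-tailed p in the hypothesized direction from the t approximation
#' with `n - 2 - k` degrees of freedom, Bonferroni adjustment over `m`
#' planned tests (`p_adj = min(1, m p)`), and a one-sided confidence
#' bound from the Fisher z transform with effective standard error
#' `1 / sqrt(n - k - 3)`: the lower bound for a positive-direction
#' hypothesis, the upper bound for a negative-direction one.
#'
#' @param rho Partial correlation estimate.
#' @param n Number of subjects.
#' @param controls_count Number of control variables `k`.
#' @param direction `"positive"` or `"negative"`, fixed a priori.
#' @param m Number of planned comparisons for the Bonferroni adjustment.
#'   Default 2.
#' @param conf_level One-sided confidence level. Default 0.95.
#' @return List with `p_one_tailed`, `p_adjusted`, `ci_bound`,
#'   `ci_side` (`"lower"` or `"upper"`), `m`, `degenerate` (`TRUE` when
#'   `|rho| = 1`, where the Fisher bound is infinite).
#' @export
one_tailed_inference <- function(rho, n, controls_count,
                                 direction = c("positive", "negative"),
                                 m = 2L, conf_level = 0.95) {
  direction <- match.arg(direction)
  df <- n - 2L - controls_count
  if (df < 1L) stop("non-positive degrees of freedom")
  degenerate <- abs(rho) >= 1
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p_one <- stats::pt(tval, df, lower.tail = (direction == "negative"))
  z_se <- 1 / sqrt(n - controls_count - 3)
  zq <- stats::qnorm(conf_level)
  bound <- if (direction == "negative") {
    tanh(atanh(min(rho, 1 - 1e-15)) + zq * z_se)
  } else {
    tanh(atanh(max(rho, -1 + 1e-15)) - zq * z_se)
  }
  if (degenerate) warning("|rho| = 1: confidence bound is degenerate")
  list(p_one_tailed = p_one, p_adjusted = min(1, m * p_one),
       ci_bound = bound,
       ci_side = if (direction == "negative") "upper" else "lower",
       m = m, degenerate = degenerate)
}

partial_result_row <- function(x_label, y_label, sp, inf, controls) {
  data.frame(x_label = x_label, y_label = y_label, rho = sp$rho,
             p_one_tailed = inf$p_one_tailed, p_adjusted = inf$p_adjusted,
             ci_bound = inf$ci_bound, ci_side = inf$ci_side,
             n = sp$n, n_controls = sp$n_controls,
             controls = paste(controls, collapse = ","))
}

#' Hypothesis tests and descriptive map linking DFA exponents to identity
#'
#' At the focal band and channel (default alpha at FCz), tests the two a
#' priori hypotheses - exponent positively correlated with identity
#' synthesis, negatively with identity confusion - using Spearman partial
#' correlations with the control set (age, gender, BMI, arousal, retained
#' epoch count, plus the respective other identity factor), one-tailed
#' p-values Bonferroni-adjusted over the two tests. For every band x
#' channel in the exponent table, descriptive (unadjusted, two-sided)
#' partial correlations against both identity scores are returned as a
#' long-format map with two-sided Fisher-z confidence intervals.
#'
#' Rows with missing values are dropped listwise; the number dropped is
#' reported in the `n_dropped` element.
#'
#' @param dfae_table Long-format data frame from [dfa_per_subject()]
#'   (columns `subject_id`, `channel`, `band`, `dfae`, `n_epochs`).
#' @param subjects Data frame with one row per subject: `subject_id`,
#'   `epsi_synthesis`, `epsi_confusion`, covariate columns, and optionally
#'   `cesd`.
#' @param focal Named character vector `c(band = , channel = )`. Default
#'   alpha at FCz.
#' @param controls Covariate column names used as controls. Default
#'   `c("age", "gender", "bmi", "arousal", "n_epochs")`; `n_epochs` is
#'   taken from `dfae_table`.
#' @param add_cesd_control If `TRUE`, append the CES-D score to the
#'   control set (sensitivity re-run).
#' @param m Bonferroni comparisons for the focal tests. Default 2.
#' @param conf_level Confidence level. Default 0.95.
#' @return Object of class `"dfae_identity_result"`: list with `focal`
#'   (two-row data frame: synthesis and confusion tests), `map`
#'   (descriptive long table), `n_dropped`, `controls`.
#' @export
dfae_identity_analysis <- function(dfae_table, subjects,
                                   focal = c(band = "alpha", channel = "FCz"),
                                   controls = c("age", "gender", "bmi",
                                                "arousal", "n_epochs"),
                                   add_cesd_control = FALSE, m = 2L,
                                   conf_level = 0.95) {
  if (add_cesd_control && !"cesd" %in% names(subjects)) {
    stop("`add_cesd_control = TRUE` requires a `cesd` column")
  }
  base_controls <- controls
  if (add_cesd_control) base_controls <- c(base_controls, "cesd")

  epoch_counts <- unique(dfae_table[c("subject_id", "n_epochs")])
  subj <- merge(subjects, epoch_counts, by = "subject_id")
  need <- unique(c("epsi_synthesis", "epsi_confusion",
                   setdiff(base_controls, "n_epochs"), "n_epochs"))
  complete <- stats::complete.cases(subj[need])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " subject(s) dropped listwise for missing values")
  }
  subj <- subj[complete, ]

  # a control that is constant across the analysed subjects (e.g. every
  # synthetic subject retains the same epoch count) carries no
  # confounding information and would make the rank regression singular
  constant_ctrl <- base_controls[vapply(base_controls, function(v) {
    stats::var(as.numeric(subj[[v]])) == 0
  }, logical(1))]
  if (length(constant_ctrl) > 0L) {
    message("dropping constant control(s): ",
            paste(constant_ctrl, collapse = ", "))
    base_controls <- setdiff(base_controls, constant_ctrl)
  }

  run_one <- function(band, channel, y_name, direction, m_use,
                      conf = conf_level) {
    d <- dfae_table[dfae_table$band == band & dfae_table$channel == channel,
                    c("subject_id", "dfae")]
    dd <- merge(d, subj, by = "subject_id")
    other <- if (y_name == "epsi_confusion") "epsi_synthesis" else "epsi_confusion"
    ctrl_names <- c(base_controls, other)
    Z <- as.matrix(dd[ctrl_names])
    sp <- spearman_partial(dd$dfae, dd[[y_name]], Z)
    inf <- one_tailed_inference(sp$rho, sp$n, sp$n_controls, direction,
                                m = m_use, conf_level = conf)
    list(sp = sp, inf = inf, ctrl = ctrl_names)
  }

  syn <- run_one(focal[["band"]], focal[["channel"]], "epsi_synthesis",
                 "positive", m)
  con <- run_one(focal[["band"]], focal[["channel"]], "epsi_confusion",
                 "negative", m)
  focal_label <- paste0(focal[["band"]], "-DFAe@", focal[["channel"]])
  focal_tab <- rbind(
    partial_result_row(focal_label, "synthesis", syn$sp, syn$inf, syn$ctrl),
    partial_result_row(focal_label, "confusion", con$sp, con$inf, con$ctrl))

  combos <- unique(dfae_table[c("band", "channel")])
  map_rows <- list()
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_len(nrow(combos))) {
    for (y_name in c("epsi_synthesis", "epsi_confusion")) {
      r <- run_one(combos$band[i], combos$channel[i], y_name,
                   if (y_name == "epsi_synthesis") "positive" else "negative",
                   m_use = 1L)
      se <- 1 / sqrt(r$sp$n - r$sp$n_controls - 3)
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        band = combos$band[i], channel = combos$channel[i],
        y = sub("epsi_", "", y_name), rho = r$sp$rho,
        p_two_tailed = r$sp$p_two_tailed,
        ci_low = tanh(atanh(r$sp$rho) - zq * se),
        ci_high = tanh(atanh(r$sp$rho) + zq * se),
        n = r$sp$n)
    }
  }
  structure(list(focal = focal_tab, map = do.call(rbind, map_rows),
                 n_dropped = n_dropped, controls = base_controls,
                 controls_dropped = constant_ctrl),
            class = "dfae_identity_result")
}

#' @export
print.dfae_identity_result <- function(x, ...) {
  cat("<dfae_identity_result> focal tests:\n")
  print(x$focal[c("x_label", "y_label", "rho", "p_adjusted", "ci_bound")],
        row.names = FALSE)
  cat("map:", nrow(x$map), "descriptive entries;", x$n_dropped,
      "subject(s) dropped\n")
  invisible(x)
}

#' Extrema of a descriptive correlation map
#'
#' Returns the strongest positive synthesis correlation and the strongest
#' negative confusion correlation, with their band and channel labels.
#' Ties are broken by (band, channel) lexicographic order.
#'
#' @param map Map data frame as produced by [dfae_identity_analysis()].
#' @return List with `max_synthesis` and `min_confusion`, each a one-row
#'   data frame (or `NULL` when the map has no rows for that role).
#' @export
descriptive_extrema <- function(map) {
  if (nrow(map) == 0L) stop("empty map")
  pick <- function(rows, decreasing) {
    if (nrow(rows) == 0L) return(NULL)
    ord <- order(if (decreasing) -rows$rho else rows$rho,
                 rows$band, rows$channel)
    rows[ord[1L], , drop = FALSE]
  }
  list(max_synthesis = pick(map[map$y == "synthesis", ], TRUE),
       min_confusion = pick(map[map$y == "confusion", ], FALSE))
}
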