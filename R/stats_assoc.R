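# Outcome-association layer: Wilcoxon group comparisons (exact when
# feasible), ROC curves with tie-aware AUC, and the joining of drift or
# promoter-methylation measurements to transplant outcomes (chimerism
# status, aGVHD severity).

#' Wilcoxon comparison of two groups
#'
#' Two-sided Wilcoxon test. For independent groups this is the rank-sum
#' (Mann-Whitney) test; `paired = TRUE` gives the signed-rank test for
#' subject-aligned measurements. The exact null distribution is used when
#' the combined sample size is at most 25 and the data are tie-free;
#' otherwise the normal approximation with tie correction is used. The mode
#' actually used is recorded in the result.
#'
#' @param x,y Numeric vectors; in paired mode, aligned by subject.
#' @param paired Use the signed-rank test on the differences.
#' @return List of class `group_comparison`: `statistic_name` ("W" rank-sum
#'   or "V" signed-rank), `statistic_value`, `p_value` (two-sided),
#'   `n_per_group`, `direction` (which input has the larger median), `mode`
#'   ("exact" or "normal_approx"), `paired`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired mode requires equal-length, subject-aligned vectors",
           call. = FALSE)
    }
    d <- x - y
    if (all(d == 0)) {
      stop("degenerate data: all paired differences are zero", call. = FALSE)
    }
    tied <- any(d == 0) || anyDuplicated(abs(d[d != 0])) > 0
    exact <- length(d) <= 25L && !tied
  } else {
    tied <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y)) <= 25L && !tied
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact,
                       correct = !exact, alternative = "two.sided"))
  med_x <- stats::median(x); med_y <- stats::median(y)
  structure(list(
    statistic_name = if (paired) "V" else "W",
    statistic_value = unname(wt$statistic),
    p_value = wt$p.value,
    n_per_group = c(x = length(x), y = length(y)),
    direction = if (med_x > med_y) "x" else if (med_y > med_x) "y" else "tie",
    mode = if (exact) "exact" else "normal_approx",
    paired = paired), class = "group_comparison")
}

#' ROC curve and tie-aware AUC
#'
#' Builds the full ROC curve from all distinct score thresholds and computes
#' the AUC by the tie-aware pair-counting (Mann-Whitney) formulation: each
#' positive/negative pair contributes 1 if the positive scores strictly
#' higher, 1/2 on a tie. The trapezoidal area of the stored curve equals
#' this AUC exactly.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) vector; TRUE = positive class.
#' @param positive_high If TRUE (default), larger scores indicate the
#'   positive class; if FALSE the score is negated before thresholding.
#' @return List of class `roc_result`: `thresholds` (decreasing, on the
#'   oriented score scale, bracketed by Inf/-Inf), `sensitivity`,
#'   `specificity`, `auc`, `positive_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive_high = TRUE) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  s <- if (positive_high) scores else -scores
  # tie-aware pair counting via midranks:
  # AUC = (sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos * n_neg)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(s[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!labels] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, positive_high = positive_high,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives, %s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (x$positive_high) "higher score = positive"
              else "lower score = positive"))
  invisible(x)
}

.pair_outcomes <- function(cohort) {
  rec <- cohort[cohort$role == "recipient", , drop = FALSE]
  out <- unique(rec[, c("pair_id", "chimerism", "agvhd_grade")])
  if (anyDuplicated(out$pair_id)) {
    stop("inconsistent chimerism/aGVHD annotation within a pair", call. = FALSE)
  }
  out
}

#' Associate per-pair measurements with a transplant outcome
#'
#' Joins pair-level measurements (delta-Met drift values or promoter percent
#' methylation) to outcome groups and emits the group summary, the unpaired
#' Wilcoxon comparison and the ROC curve. Groupings follow the clinical
#' analysis design: for `"chimerism"`, mixed-chimerism pairs versus a control
#' group of complete-chimerism pairs that never developed aGVHD; for
#' `"agvhd_severe"`, severe disease (grades II-V) versus all other graded
#' pairs (none or grade I); for `"agvhd_any"`, any aGVHD (I-V) versus none.
#' Pairs with unknown status are excluded.
#'
#' @param measurements Data.frame with columns `pair_id` and the value
#'   column; if it carries `timepoint_months`, rows are restricted to
#'   `timepoint`.
#' @param cohort A `cohort_table` supplying outcomes per pair.
#' @param outcome One of "chimerism", "agvhd_severe", "agvhd_any".
#' @param timepoint Month post-transplant to restrict to (default 1).
#' @param value_col Name of the measurement column (default "delta_met").
#' @param positive_high TRUE/FALSE fixes the ROC score orientation; NULL
#'   (default) auto-orients so the positive group's median scores higher,
#'   and the chosen orientation is recorded in the ROC result. Drift-based
#'   classifiers should pass TRUE (larger drift = adverse outcome).
#' @return List: `summary` (data.frame of group n/median/mean), `wilcoxon`
#'   (a `group_comparison`), `roc` (a `roc_result`), `data` (the joined
#'   per-pair table), `positive_group`.
#' @export
outcome_association <- function(measurements, cohort,
                                outcome = c("chimerism", "agvhd_severe",
                                            "agvhd_any"),
                                timepoint = 1L, value_col = "delta_met",
                                positive_high = NULL) {
  outcome <- match.arg(outcome)
  m <- as.data.frame(measurements)
  if (!value_col %in% names(m)) {
    stop("measurement column '", value_col, "' not found", call. = FALSE)
  }
  if ("timepoint_months" %in% names(m) && !is.null(timepoint)) {
    m <- m[!is.na(m$timepoint_months) & m$timepoint_months == timepoint, ,
           drop = FALSE]
  }
  po <- .pair_outcomes(cohort)
  m <- merge(m[, c("pair_id", value_col)], po, by = "pair_id")
  grp <- switch(outcome,
    chimerism = ifelse(m$chimerism == "mixed", "mixed",
                ifelse(m$chimerism == "complete" & m$agvhd_grade == "0",
                       "control", NA_character_)),
    agvhd_severe = ifelse(m$agvhd_grade == "II-V", "severe",
                   ifelse(m$agvhd_grade %in% c("0", "I"), "non_severe",
                          NA_character_)),
    agvhd_any = ifelse(m$agvhd_grade %in% c("I", "II-V"), "agvhd",
                ifelse(m$agvhd_grade == "0", "none", NA_character_)))
  positive <- switch(outcome, chimerism = "mixed", agvhd_severe = "severe",
                     agvhd_any = "agvhd")
  control <- switch(outcome, chimerism = "control",
                    agvhd_severe = "non_severe", agvhd_any = "none")
  keep <- !is.na(grp) & !is.na(m[[value_col]])
  m <- m[keep, , drop = FALSE]; grp <- grp[keep]
  for (g in c(positive, control)) {
    if (!any(grp == g)) {
      stop("empty group after joining: '", g, "' (outcome ", outcome, ")",
           call. = FALSE)
    }
  }
  v <- m[[value_col]]
  vp <- v[grp == positive]; vc <- v[grp == control]
  if (is.null(positive_high)) {
    positive_high <- stats::median(vp) >= stats::median(vc)
  }
  summary_df <- data.frame(
    group = c(positive, control),
    n = c(length(vp), length(vc)),
    median = c(stats::median(vp), stats::median(vc)),
    mean = c(mean(vp), mean(vc)))
  list(summary = summary_df,
       wilcoxon = wilcoxon_test(vp, vc, paired = FALSE),
       roc = roc_auc(v, grp == positive, positive_high = positive_high),
       data = cbind(m, group = grp),
       positive_group = positive)
}
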