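# The delta-Met drift statistic: Euclidean distance between two samples'
# multi-CpG methylation vectors on one amplicon. Each CpG site is one
# spatial dimension; the distance summarizes methylation drift in a single
# non-negative value that is unaffected by non-informative CpGs (equal in
# both samples) and does not cancel opposite-signed per-CpG drift the way a
# mean of differences would.

#' Compute the delta-Met drift between two methylation profiles
#'
#' Euclidean distance sqrt(sum_i (p_i - q_i)^2) over the CpG sites of one
#' amplicon, computed on the intersection of non-missing CpGs. Units are
#' percentage points; the value is bounded by 100 * sqrt(n).
#'
#' @param p,q `methylation_profile` objects for the same amplicon with
#'   identical CpG ordering.
#' @param normalize If TRUE, divide by sqrt(n_cpgs_used) (per-CpG scale).
#'   The default FALSE is the classical statistic; raw values from
#'   comparisons with different `n_cpgs_used` are not directly comparable.
#' @return Non-negative numeric scalar with attribute `n_cpgs_used`.
#' @examples
#' p <- methylation_profile("LINE1", c(80, 70, 60, 50))
#' q <- methylation_profile("LINE1", c(70, 60, 50, 40))
#' compute_delta_met(p, q)  # 20
#' @export
compute_delta_met <- function(p, q, normalize = FALSE) {
  stopifnot(inherits(p, "methylation_profile"),
            inherits(q, "methylation_profile"))
  if (!identical(p$amplicon_id, q$amplicon_id)) {
    stop("amplicon mismatch: '", p$amplicon_id, "' vs '", q$amplicon_id, "'",
         call. = FALSE)
  }
  if (p$n_cpgs != q$n_cpgs) {
    stop("profiles of amplicon '", p$amplicon_id,
         "' differ in CpG count: ", p$n_cpgs, " vs ", q$n_cpgs, call. = FALSE)
  }
  ok <- !is.na(p$cpg_values) & !is.na(q$cpg_values)
  n_used <- sum(ok)
  if (n_used < 1L) {
    stop("no shared non-missing CpG between the two profiles (amplicon '",
         p$amplicon_id, "')", call. = FALSE)
  }
  d <- sqrt(sum((p$cpg_values[ok] - q$cpg_values[ok])^2))
  if (normalize) d <- d / sqrt(n_used)
  structure(d, n_cpgs_used = as.integer(n_used))
}

.pair_samples <- function(cohort) {
  rec <- cohort[cohort$role == "recipient", , drop = FALSE]
  don <- cohort[cohort$role == "donor", , drop = FALSE]
  list(rec = rec, don = don, pair_ids = unique(rec$pair_id))
}

.find_sample <- function(df, pair_id, timepoint = NULL, role) {
  rows <- df$pair_id == pair_id
  if (!is.null(timepoint)) {
    rows <- rows & !is.na(df$timepoint_months) & df$timepoint_months == timepoint
  }
  ids <- df$sample_id[rows]
  if (length(ids) == 0L) return(NA_character_)
  ids[1]
}

.has_profile <- function(panel, sample_id, amplicon_id) {
  !is.na(sample_id) &&
    any(panel$sample_id == sample_id & panel$amplicon_id == amplicon_id &
          !is.na(panel$meth_pct))
}

#' Pairwise delta-Met across a cohort
#'
#' Computes one delta-Met value per donor/recipient pair for a chosen
#' comparison: donor vs pre-transplant recipient, donor vs post-transplant
#' recipient at a given month, or pre vs post. Pairs lacking one of the two
#' required samples are listed in the skip report, never silently dropped.
#'
#' @param cohort A `cohort_table`.
#' @param panel A `pyro_panel` with the measurements.
#' @param amplicon_id Amplicon to analyze; must exist in the panel spec.
#' @param comparison One of "donor_vs_pre", "donor_vs_post", "pre_vs_post".
#' @param timepoint Month post-transplant for the "post" sample (required for
#'   donor_vs_post and pre_vs_post).
#' @return List with `results` (data.frame: pair_id, comparison,
#'   timepoint_months, delta_met, n_cpgs_used) and `skipped` (data.frame:
#'   pair_id, reason).
#' @export
pairwise_delta_met <- function(cohort, panel, amplicon_id,
                               comparison = c("donor_vs_pre", "donor_vs_post",
                                              "pre_vs_post"),
                               timepoint = NULL) {
  comparison <- match.arg(comparison)
  spec <- attr(panel, "panel_spec")
  if (!is.null(spec) && !amplicon_id %in% names(spec)) {
    stop("unknown amplicon '", amplicon_id, "'", call. = FALSE)
  }
  if (comparison != "donor_vs_pre" && is.null(timepoint)) {
    stop("comparison '", comparison, "' requires a timepoint", call. = FALSE)
  }
  ps <- .pair_samples(cohort)
  res <- list(); skip <- list()
  for (pid in ps$pair_ids) {
    a_id <- switch(comparison,
                   donor_vs_pre = .find_sample(ps$don, pid),
                   donor_vs_post = .find_sample(ps$don, pid),
                   pre_vs_post = .find_sample(ps$rec, pid, timepoint = -1L))
    b_id <- switch(comparison,
                   donor_vs_pre = .find_sample(ps$rec, pid, timepoint = -1L),
                   donor_vs_post = .find_sample(ps$rec, pid, timepoint = timepoint),
                   pre_vs_post = .find_sample(ps$rec, pid, timepoint = timepoint))
    ok_a <- .has_profile(panel, a_id, amplicon_id)
    ok_b <- .has_profile(panel, b_id, amplicon_id)
    if (!ok_a || !ok_b) {
      skip[[pid]] <- data.frame(
        pair_id = pid,
        reason = paste0("missing ",
                        paste(c("first", "second")[!c(ok_a, ok_b)],
                              collapse = " and "),
                        " sample/profile for ", comparison),
        stringsAsFactors = FALSE)
      next
    }
    d <- compute_delta_met(get_profile(panel, a_id, amplicon_id),
                           get_profile(panel, b_id, amplicon_id))
    res[[pid]] <- data.frame(
      pair_id = pid, comparison = comparison,
      timepoint_months = if (is.null(timepoint)) NA_integer_
                         else as.integer(timepoint),
      delta_met = as.numeric(d),
      n_cpgs_used = attr(d, "n_cpgs_used"),
      stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(pair_id = character(), comparison = character(),
               timepoint_months = integer(), delta_met = numeric(),
               n_cpgs_used = integer(), stringsAsFactors = FALSE)
  skipped <- if (length(skip)) do.call(rbind, skip) else
    data.frame(pair_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL; rownames(skipped) <- NULL
  # comparisons computed over differing CpG subsets are flagged: raw
  # delta-Met grows with dimension, so mixed n is not directly comparable
  if (nrow(results) && length(unique(results$n_cpgs_used)) > 1L) {
    attr(results, "mixed_n_cpgs") <- TRUE
  }
  list(results = results, skipped = skipped)
}

#' Longitudinal delta-Met trajectory of a cohort
#'
#' Aggregates donor-vs-post delta-Met per month post-transplant. Both the
#' mean and the median are reported at every timepoint, with the number of
#' complete pairs; the 1-month aggregate is exposed as the reference level
#' (the horizontal reference line of trajectory plots).
#'
#' @param cohort A `cohort_table`.
#' @param panel A `pyro_panel`.
#' @param amplicon_id Amplicon to analyze.
#' @return Data.frame of class `delta_met_timeline` with columns
#'   `timepoint_months`, `mean`, `median`, `sd`, `n_pairs`, and attributes
#'   `reference_mean` / `reference_median` (the month-1 values, NA if no
#'   month-1 pairs).
#' @export
delta_met_timeline <- function(cohort, panel, amplicon_id) {
  tps <- sort(unique(cohort$timepoint_months[cohort$role == "recipient" &
                                             !is.na(cohort$timepoint_months) &
                                             cohort$timepoint_months > 0]))
  rows <- list()
  for (tp in tps) {
    pr <- pairwise_delta_met(cohort, panel, amplicon_id,
                             comparison = "donor_vs_post", timepoint = tp)
    if (nrow(pr$results) == 0L) next
    rows[[as.character(tp)]] <- data.frame(
      timepoint_months = tp,
      mean = mean(pr$results$delta_met),
      median = stats::median(pr$results$delta_met),
      sd = stats::sd(pr$results$delta_met),
      n_pairs = nrow(pr$results))
  }
  if (!length(rows)) {
    stop("empty timeline: no complete donor/post pair at any timepoint for '",
         amplicon_id, "'", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ref <- out[out$timepoint_months == 1L, , drop = FALSE]
  attr(out, "amplicon_id") <- amplicon_id
  attr(out, "reference_mean") <- if (nrow(ref)) ref$mean else NA_real_
  attr(out, "reference_median") <- if (nrow(ref)) ref$median else NA_real_
  class(out) <- c("delta_met_timeline", "data.frame")
  out
}

#' Estimate the recipient chimerism fraction from drift ratios
#'
#' Under DNA-level mixing, a post-transplant blood profile is a convex
#' combination m = f * pre + (1 - f) * donor of the recipient's own
#' (pre-transplant) profile and the donor's profile, where f is the fraction
#' of recipient-derived cells. Euclidean distance is linear along that
#' segment, so f = d(donor, post) / d(donor, pre) exactly in the noise-free
#' case. The estimate is clipped to [0, 1]; a quality flag marks estimates
#' whose unclipped ratio exceeds 1 + `tolerance` (post drifted beyond the
#' pre profile) or whose denominator is below `separability_floor`
#' (donor and recipient nearly indistinguishable on this panel, where assay
#' noise dominates the ratio).
#'
#' @param donor,pre,post `methylation_profile`s sharing amplicon and CpG order.
#' @param tolerance Slack above 1 before the overshoot flag fires.
#' @param separability_floor Minimum trusted d(donor, pre), percentage points.
#' @return List: `fraction` (clipped to [0, 1]), `unclipped`, `flag` (one of
#'   "ok", "overshoot", "low_separability"), `denominator`.
#' @export
estimate_chimerism_fraction <- function(donor, pre, post,
                                        tolerance = 0.1,
                                        separability_floor = 2.0) {
  d_pre <- as.numeric(compute_delta_met(donor, pre))
  if (d_pre == 0) {
    stop("non-identifiable: delta-Met(donor, pre) = 0 — donor and recipient ",
         "are epigenetically indistinguishable on this panel", call. = FALSE)
  }
  d_post <- as.numeric(compute_delta_met(donor, post))
  f_raw <- d_post / d_pre
  flag <- "ok"
  if (f_raw > 1 + tolerance) flag <- "overshoot"
  if (d_pre < separability_floor) flag <- "low_separability"
  list(fraction = min(max(f_raw, 0), 1), unclipped = f_raw, flag = flag,
       denominator = d_pre)
}
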