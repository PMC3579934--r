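test_that("delta-Met matches hand-computed distances and validates inputs", {
  p <- methylation_profile("LINE1", c(80, 70, 60, 50))
  q <- methylation_profile("LINE1", c(70, 60, 50, 40))
  d <- compute_delta_met(p, q)
  expect_equal(as.numeric(d), 20)  # sqrt(4 * 10^2)
  expect_equal(attr(d, "n_cpgs_used"), 4L)
  expect_equal(as.numeric(compute_delta_met(p, p)), 0)

  # single-CpG promoter assay reduces to the absolute difference
  expect_equal(as.numeric(compute_delta_met(
    methylation_profile("IFNG", 30), methylation_profile("IFNG", 42))), 12)

  expect_error(compute_delta_met(p, methylation_profile("NBL2", rep(50, 6))),
               "amplicon mismatch")
  expect_error(compute_delta_met(methylation_profile("IFNG", NA_real_),
                                 methylation_profile("IFNG", 42)),
               "non-missing")

  # missing CpGs: distance over the non-missing intersection, n recorded
  pm <- methylation_profile("LINE1", c(NA, 70, 60, 50))
  dm <- compute_delta_met(pm, q)
  expect_equal(as.numeric(dm), sqrt(300))
  expect_equal(attr(dm, "n_cpgs_used"), 3L)

  # optional per-CpG normalization divides by sqrt(n)
  expect_equal(as.numeric(compute_delta_met(p, q, normalize = TRUE)), 10)
})

test_that("pairwise delta-Met reports skipped pairs instead of dropping them", {
  cohort <- cohort_table(data.frame(
    sample_id = c("d1", "r1pre", "r1m1", "d2", "r2m1"),
    subject_id = c("D1", "R1", "R1", "D2", "R2"),
    role = c("donor", "recipient", "recipient", "donor", "recipient"),
    timepoint_months = c(NA, -1, 1, NA, 1),
    pair_id = c("p1", "p1", "p1", "p2", "p2"),
    chimerism = c("unknown", "complete", "complete", "unknown", "mixed"),
    agvhd_grade = c("unknown", "0", "0", "unknown", "I")))
  panel <- local({
    rows <- expand.grid(sample_id = c("d1", "r1pre", "r1m1", "d2", "r2m1"),
                        cpg_index = 1:4, stringsAsFactors = FALSE)
    rows$amplicon_id <- "LINE1"
    base <- c(d1 = 70, r1pre = 75, r1m1 = 71, d2 = 60, r2m1 = 66)
    rows$meth_pct <- base[rows$sample_id]
    rows <- rows[order(rows$sample_id, rows$cpg_index),
                 c("sample_id", "amplicon_id", "cpg_index", "meth_pct")]
    attr(rows, "panel_spec") <- c(LINE1 = 4L)
    class(rows) <- c("pyro_panel", "data.frame")
    rows
  })

  post <- pairwise_delta_met(cohort, panel, "LINE1", "donor_vs_post",
                             timepoint = 1)
  expect_equal(nrow(post$results), 2L)
  expect_equal(post$results$delta_met, c(sqrt(4), sqrt(4 * 36)))

  # pair 2 has no pre-transplant sample: skip report, not silence
  pre <- pairwise_delta_met(cohort, panel, "LINE1", "donor_vs_pre")
  expect_equal(pre$results$pair_id, "p1")
  expect_equal(pre$skipped$pair_id, "p2")
  expect_match(pre$skipped$reason, "missing")

  expect_error(pairwise_delta_met(cohort, panel, "NOPE", "donor_vs_pre"),
               "unknown amplicon")
  expect_error(pairwise_delta_met(cohort, panel, "LINE1", "donor_vs_post"),
               "timepoint")
})

test_that("timeline aggregates per month with a 1-month reference level", {
  cohort <- cohort_table(data.frame(
    sample_id = c("d1", "r1m1", "d2", "r2m1"),
    subject_id = c("D1", "R1", "D2", "R2"),
    role = c("donor", "recipient", "donor", "recipient"),
    timepoint_months = c(NA, 1, NA, 1),
    pair_id = c("p1", "p1", "p2", "p2"),
    chimerism = "unknown", agvhd_grade = "unknown"))
  # distances engineered to 4 and 6 on a single-CpG assay
  panel <- data.frame(
    sample_id = c("d1", "r1m1", "d2", "r2m1"), amplicon_id = "IFNG",
    cpg_index = 1L, meth_pct = c(50, 54, 50, 56))
  attr(panel, "panel_spec") <- c(IFNG = 1L)
  class(panel) <- c("pyro_panel", "data.frame")

  tl <- delta_met_timeline(cohort, panel, "IFNG")
  expect_equal(tl$mean, 5)
  expect_equal(tl$median, 5)
  expect_equal(tl$n_pairs, 2L)
  expect_equal(attr(tl, "reference_mean"), 5)

  # a cohort with no post-transplant samples has no timeline
  pre_only <- cohort_table(data.frame(
    sample_id = c("d1", "r1pre"), subject_id = c("D1", "R1"),
    role = c("donor", "recipient"), timepoint_months = c(NA, -1),
    pair_id = "p1", chimerism = "unknown", agvhd_grade = "unknown"))
  expect_error(delta_met_timeline(pre_only, panel, "IFNG"), "empty timeline")
})

test_that("chimerism fraction estimator hits the mixing limits exactly", {
  set.seed(7)
  donor <- random_profile()
  pre <- random_profile()

  expect_equal(estimate_chimerism_fraction(donor, pre, donor)$fraction, 0)
  expect_equal(estimate_chimerism_fraction(donor, pre, pre)$fraction, 1)

  mix <- methylation_profile("NBL2",
                             0.5 * pre$cpg_values + 0.5 * donor$cpg_values)
  est <- estimate_chimerism_fraction(donor, pre, mix)
  expect_equal(est$fraction, 0.5)
  expect_equal(est$flag, "ok")

  # drift beyond the pre profile -> clipped with overshoot flag
  don2 <- methylation_profile("NBL2", c(50, 60, 40, 55, 45, 65))
  pre2 <- methylation_profile("NBL2", c(60, 70, 50, 65, 55, 75))
  beyond <- methylation_profile("NBL2", c(65, 75, 55, 70, 60, 80))
  est2 <- estimate_chimerism_fraction(don2, pre2, beyond)
  expect_equal(est2$fraction, 1)
  expect_equal(est2$flag, "overshoot")
  expect_gt(est2$unclipped, 1.1)

  # near-identical donor and recipient -> low-separability flag
  close_pre <- methylation_profile("NBL2", pmin(donor$cpg_values + 0.1, 100))
  expect_equal(estimate_chimerism_fraction(donor, close_pre, donor)$flag,
               "low_separability")

  expect_error(estimate_chimerism_fraction(donor, donor, pre),
               "non-identifiable")
})
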