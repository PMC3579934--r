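# methdrift

Tools for quantifying DNA-methylation drift in whole blood after
hematopoietic cell transplant (HCT).

After a transplant, the recipient's blood is repopulated by donor-derived
cells. Because each hematopoietic cell type has its own CpG-methylation
signature, and a whole-blood DNA sample measures the composition-weighted
mixture of those signatures, blood methylation profiles carry clinically
useful signal: whether recipient cells persist (mixed vs complete
chimerism) and how immune reconstitution is proceeding — which acute
graft-versus-host disease (aGVHD) perturbs. `methdrift` is written for
transplant epigenetics groups analyzing bisulfite-pyrosequencing panels
over repetitive elements (LINE1, NBL2, D4Z4), single-CpG promoter assays
(IFN-γ, FASL, IL-10, PRF1) and 27k-class bead-array β-value exports.

## The drift statistic

For two samples measured on one amplicon with per-CpG percent methylation
p = (p₁…pₙ) and q = (q₁…qₙ), each CpG is one spatial dimension and the
drift is the Euclidean distance

    d(p, q) = sqrt( Σᵢ (pᵢ − qᵢ)² ),

bounded by 100·√n, unaffected by non-informative CpGs, and insensitive to
the sign-cancellation that breaks a mean of per-CpG differences. Because a
post-transplant blood sample is a DNA-level convex mixture
m = f·pre + (1−f)·donor of recipient- and donor-derived profiles, distance
is linear along that segment and the recipient fraction can be estimated as

    f̂ = d(donor, post) / d(donor, pre),  clipped to [0, 1],

with quality flags for overshoot and for donor/recipient pairs too similar
to separate. The package adds the bead-array altered-probe workflow
(detection-p filtering at 0.01; strict |Δβ| > 0.20 calls; gene collapsing
and cross-case overlap), exact Wilcoxon and tie-aware ROC/AUC outcome
association, and a synthetic cohort generator with cell-type signatures,
blood-composition mixing, chimerism fractions, aGVHD composition shifts
and assay noise, so every stage is testable without patient data. See the
vignette in `vignettes/methylation-drift.Rmd` for the full model account.

## Worked example

```r
library(methdrift)

cfg <- simulation_config(seed = 20, n_pairs = 20)
sim <- simulate_cohort(cfg)   # cohort table, pyro panel, beta matrix, truth

pre  <- pairwise_delta_met(sim$cohort, sim$panel, "NBL2", "donor_vs_pre")$results
post <- pairwise_delta_met(sim$cohort, sim$panel, "NBL2", "donor_vs_post",
                           timepoint = 1)$results
mean(pre$delta_met)   # 13.50
mean(post$delta_met)  #  4.48

assoc <- outcome_association(post, sim$cohort, "chimerism", timepoint = 1,
                             positive_high = TRUE)
assoc$summary
#>     group n   median     mean
#> 1   mixed 4 7.357856 7.341236
#> 2 control 3 3.719308 3.478204
assoc$roc
#> <roc_result> AUC = 1.0000 (4 positives, 3 negatives, higher score = positive)
```

The donor-vs-pre drift (13.5 percentage points on NBL2, which varies a lot
between individuals) collapses to 4.5 one month post-transplant: the
recipients' blood now carries the donors' methylation profile. Pairs with
mixed chimerism retain more drift than complete-chimerism controls, and
here the two groups separate perfectly (AUC = 1). For a single mixed pair
the fraction estimator recovers the simulated truth up to assay noise:

```r
est <- estimate_chimerism_fraction(
  get_profile(sim$panel, "P018_D",     "NBL2"),
  get_profile(sim$panel, "P018_R_pre", "NBL2"),
  get_profile(sim$panel, "P018_R_m1",  "NBL2"))
est$fraction                                  # 0.398 (flag "ok")
sim$truth$true_f[sim$truth$pair_id == "P018"] # 0.329
```

File-based workflows use `read_pyro_panel()`, `read_beta_matrix()`,
`read_cohort()` and `read_geo_series_matrix()` (CSV/TSV; result tables are
written with `write_*` counterparts in the same column order they read).

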