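---
title: "Quantifying whole-blood methylation drift after hematopoietic cell transplant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-blood methylation drift after hematopoietic cell transplant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdrift)
```

## The problem

After a hematopoietic cell transplant (HCT), the recipient's blood is
progressively repopulated by donor-derived cells. Because every
hematopoietic cell type carries its own DNA-methylation signature, and
because a whole-blood DNA sample measures the composition-weighted mixture
of those signatures, the methylation profile of post-transplant blood
carries information about two clinically important quantities: the
*chimerism status* (are recipient-derived cells still present?) and the
state of *immune reconstitution*, which is perturbed by acute
graft-versus-host disease (aGVHD).

`methdrift` implements an analysis pipeline for this setting around three
assay families:

* **bisulfite pyrosequencing panels** over repetitive DNA elements whose
  CpG methylation proxies genome-wide levels — LINE1 (4 CpGs), the
  pericentromeric repeat NBL2 (6 CpGs) and the subtelomeric repeat D4Z4
  (6 CpGs) — plus single-CpG promoter assays for the immune genes IFN-γ,
  FASL, IL-10 and PRF1;
* **bead-array β-value matrices** (probes × samples, values in $[0,1]$,
  with detection p-values), as exported from 27k-class methylation arrays;
* **clinical metadata** linking donor/recipient pairs, sampling timepoints,
  chimerism status and aGVHD grade.

## The drift statistic

The central quantity is a multi-CpG drift statistic. For two samples
measured on the same amplicon, with per-CpG percent methylation
$p = (p_1, \dots, p_n)$ and $q = (q_1, \dots, q_n)$, each CpG site is
treated as one spatial dimension and the drift is the Euclidean distance

$$ d(p, q) = \sqrt{\sum_{i=1}^{n} (p_i - q_i)^2 }. $$

Two properties make this a better drift summary than the mean of per-CpG
differences:

* **non-informative CpGs are neutral** — sites with identical values in
  both samples contribute nothing, so appending them never changes $d$;
* **opposite drift does not cancel** — per-CpG differences of mixed sign
  contribute their magnitudes symmetrically ($d$ over $(+\delta,-\delta)$
  equals $d$ over $(+\delta,+\delta)$), whereas a mean of differences
  would cancel them to zero.

Both properties, together with the metric axioms and the upper bound
$d \le 100\sqrt{n}$, are property-tested over 1,000 random profile triples
in the test suite.

`compute_delta_met()` evaluates $d$ over the intersection of non-missing
CpGs and records `n_cpgs_used`. No rescaling is applied by default — raw
$d$ grows with dimension, so results pooled across different `n_cpgs_used`
are flagged rather than silently mixed; an optional per-CpG normalization
($d/\sqrt{n}$) exists for cross-panel comparisons but is never used in the
standard workflow. Whether a cohort's assays dropped failed CpG positions
is generally unknowable from data files, so intersection handling is this
package's declared choice: one measurement per sample per amplicon, missing
values never imputed.

## Chimerism as mixture geometry

A post-transplant whole-blood sample is physically a pool of DNA from
recipient-derived and donor-derived cells. If a fraction $f$ of the DNA is
recipient-derived, the measured profile is the convex combination

$$ m = f \cdot \text{pre} + (1-f) \cdot \text{donor} $$

componentwise (this is exact for pooled DNA, whatever the cell-type
composition, as long as both contributions share it). Euclidean distance is
linear along a segment, so

$$ d(\text{donor}, m) = f \cdot d(\text{donor}, \text{pre}), $$

which yields the estimator implemented in `estimate_chimerism_fraction()`:

$$ \hat f = \frac{d(\text{donor}, \text{post})}{d(\text{donor}, \text{pre})},
   \quad \text{clipped to } [0,1]. $$

Two failure modes are flagged rather than hidden. When the unclipped ratio
exceeds $1 + 0.1$, the post-transplant profile has drifted beyond the
pre-transplant one (true biological drift, or assay artifact) and the
estimate carries an `overshoot` flag. When
$d(\text{donor}, \text{pre}) < 2$ percentage points (the separability
floor), donor and recipient are too similar on the panel for the ratio to
be trusted — its variance explodes as the denominator approaches assay
noise — and the estimate is flagged `low_separability`. The floor default
of 2.0 is roughly twice the per-CpG assay noise of a good pyrosequencing
run. Note also that because the numerator is a non-negative distance, the
estimator has a positive noise-floor bias at small true $f$: even at
$f = 0$, measurement noise produces $d(\text{donor}, \text{post}) > 0$.
The zero-noise recovery test and the monotone-degradation test in the
suite characterize exactly this behavior.

## The bead-array workflow

Promoter-level analysis uses the standard two-step rule for 27k-class
arrays, in `filter_detected()` and `call_altered_probes()`:

1. probes with detection p-value $> 0.01$ are excluded — the package
   requires the probe to pass in *both* compared samples (the conservative
   choice; per-sample exports do not say which rule produced published
   counts);
2. a probe is *altered* iff $|\beta_\text{recipient} - \beta_\text{donor}|
   > 0.20$, a **strict** inequality — a difference of exactly 0.20 is not
   a call.

"Differed more than 20%" is read as an absolute β-difference of 0.20 (20
percentage points), the standard Δβ criterion for these arrays and the one
consistent with donor-vs-recipient scatter plots; a relative reading
($|\Delta\beta| > 0.2\,\beta_\text{donor}$) is available behind
`relative = TRUE` for sensitivity analysis. Gene collapsing counts
distinct non-blank gene symbols; `overlap_genes()` intersects two
comparisons' gene lists case-sensitively. The caller is checked against a
brute-force oracle, including planted exact-boundary probes.

## Statistical layer

Group comparisons use the Wilcoxon test via `wilcoxon_test()`. For
independent groups (e.g. mixed vs complete chimerism, which have unequal
sizes) the unpaired rank-sum test is the only coherent choice, and it is
the package default; the signed-rank variant is reserved for genuinely
paired data such as donor vs pre-transplant recipient on the same pair.
The exact null distribution is used when the combined sample size is at
most 25 and the data are tie-free; otherwise the normal approximation with
tie correction is used, and the result records which mode ran. All
p-values are two-sided, and no multiple-testing correction is applied in
the standard workflow (the per-gene analyses are reported individually);
`p.adjust` can of course be applied downstream.

Classification performance is summarized by `roc_auc()`: the full curve
over all distinct thresholds, with AUC computed by tie-aware pair counting
(ties contribute ½) — identical, by construction, to the trapezoidal area
of the curve, which the suite verifies to $10^{-12}$ against two
independent oracle implementations. Drift-based classifiers score
positive-high (more drift = adverse outcome); promoter-methylation
classifiers auto-orient, because some genes associate with outcome through
*lower* methylation (IFN-γ, FASL in cytotoxic activation) and some through
higher (IL-10), and the chosen orientation is recorded.

`outcome_association()` joins measurements to outcome groups the way the
clinical design defines them: the chimerism analysis compares
mixed-chimerism pairs against a control group of complete-chimerism pairs
that never developed aGVHD; the severe-aGVHD analysis compares grades II–V
against everything milder (0 or I); grades are normalized into the
three-level grouping (0 / I / II–V) on input.

The Monte-Carlo calibration test uses two null groups of 8: at that size
the attainable two-sided exact level closest to 0.05 is 0.0499, so a
rejection-rate check within ±0.01 of nominal measures calibration rather
than the discreteness of the exact null distribution.

## The synthetic cohort generator

Patient-level pyrosequencing data for transplant cohorts is generally not
shareable, so every pipeline stage is exercised on synthetic cohorts from
`simulate_cohort()`. The generative model mirrors the physical account
above:

* five cell-type roles (neutrophil, monocyte, CD4 T, CD8 T, NK) with
  per-amplicon, per-CpG methylation signatures; promoter signatures encode
  the expected biology (IFN-γ and PRF1 hypomethylated in CD8/NK, IL-10
  relatively high in myeloid cells);
* a blood profile is the composition-weighted mixture of signatures plus a
  per-individual, per-CpG offset. Offsets are Gaussian with per-amplicon
  SD — by default 4 percentage points for NBL2 and 3.5 for D4Z4 (the
  repeats with large inter-individual variability, putting donor-vs-pre
  drift in the low-teens) against 2 for LINE1 (whose profiles differ
  little between individuals). Offsets are truncated so the latent profile
  stays inside $[0,100]$; convex mixing then never leaves the physical
  range, which keeps mixture linearity exact in the noise-free limit;
* a post-transplant sample at month $t$ mixes the recipient's and donor's
  intrinsic profiles at the pair's true fraction $f$ (complete-chimerism
  pairs have $f = 0$; mixed pairs draw $f$ from 0.3–0.7 by default);
* severe aGVHD shifts the composition toward cytotoxic populations
  (−10 pp neutrophils, +6 pp CD8, +4 pp NK at month 1; half of that for
  grade I), decaying exponentially at the reconstitution rate (0.3/month)
  — this is what makes altered-probe counts contract between months 1
  and 6;
* truncated-Gaussian measurement noise is added last on the native scale
  (default 1 percentage point for pyrosequencing, 0.02 β for the array),
  values are clipped to the valid range, and the clipped fraction is
  reported (tests assert it stays below 1% at default noise). A Beta
  noise model would also be defensible; the truncated Gaussian was chosen
  because the pipeline never assumes a likelihood, and it is swappable.

The master seed expands into per-stream substreams (signatures, array
design, one stream per pair), so the same seed gives bitwise-identical
cohorts and enlarging a cohort never perturbs its earlier pairs. A truth
table records every latent quantity, which is what the recovery tests
compare against.

**What the generator does not emulate.** Probes are exchangeable draws
from signature distributions, not real 27k probe biology; there is no
genotype-linked epipolymorphism, no batch or chip effect, no age/sex/
environmental drift, and cell-type signatures are stylized rather than
deconvolution-grade references. Passing tests therefore demonstrate that
the pipeline's logic and estimators behave as designed under the model's
assumptions — not that any particular clinical effect size will replicate
in real cohorts.

## Problem sizes and numerical choices

The test suite runs at desk scale by design: 1,000 random cases for the
drift-statistic properties and the AUC dual-implementation check, a
200-pair cohort for estimator recovery, 10,000 replicates for type-I
calibration, 40 pairs for the end-to-end chimerism classification, and 30
replicate null cohorts for the null-AUC check. `scripts/acceptance.R`
simulates one 47-pair cohort (the default configuration) and reports the
pipeline's headline quantities from it.

Degenerate inputs fail loudly with typed messages: profiles with no shared
non-missing CpG, identical donor and recipient (non-identifiable fraction),
single-class ROC labels, all-zero paired differences, empty outcome groups,
recipients whose pair resolves to no donor. Ties in ROC scores contribute
½ by construction; ties in Wilcoxon data switch the mode to the corrected
normal approximation; the donor timepoint is an NA sentinel so that
"months post-HCT" stays literally interpretable for recipients (−1 = the
pre-transplant draw).
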