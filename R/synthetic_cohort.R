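# Synthetic donor/recipient cohort generator. Whole-blood methylation is
# modeled physically: each hematopoietic cell type carries its own CpG
# methylation signature, a blood sample measures the composition-weighted
# DNA-level mixture of those signatures, individuals differ by amplicon-
# specific offsets, and a post-transplant sample mixes recipient-derived and
# donor-derived cells at the chimerism fraction f. Acute graft-versus-host
# disease perturbs the blood composition toward cytotoxic populations and
# the perturbation decays as immune reconstitution proceeds. Measurement
# noise (truncated Gaussian on the native scale) is added last.

.celltypes <- c("neutrophil", "monocyte", "CD4T", "CD8T", "NK")

.default_promoter_signatures <- function() {
  # percent methylation per cell type; cytokine/effector promoters are
  # hypomethylated in the cell types that express them (IFNG/PRF1 in
  # cytotoxic CD8/NK cells, FASL in T/NK, IL10 relatively high in myeloid)
  rbind(
    IFNG = c(neutrophil = 85, monocyte = 80, CD4T = 60, CD8T = 30, NK = 25),
    FASL = c(neutrophil = 80, monocyte = 75, CD4T = 45, CD8T = 35, NK = 30),
    IL10 = c(neutrophil = 70, monocyte = 50, CD4T = 60, CD8T = 65, NK = 65),
    PRF1 = c(neutrophil = 90, monocyte = 85, CD4T = 70, CD8T = 25, NK = 20))
}

#' Build a simulation configuration
#'
#' Collects and validates every knob of the cohort generator. Defaults match
#' the study design the package targets: 47 donor/recipient pairs, the
#' LINE1/NBL2/D4Z4 repeat panels plus four single-CpG promoter assays,
#' five blood cell types, about a quarter of pairs with mixed chimerism,
#' aGVHD grades in roughly the observed 0 / I / II-V proportions, large
#' inter-individual variability for NBL2 and small for LINE1, and 1
#' percentage point of pyrosequencing noise.
#'
#' @param seed Integer master seed; expands into per-stream substreams so
#'   that enlarging the cohort never perturbs earlier pairs.
#' @param n_pairs Number of donor/recipient pairs.
#' @param panel_spec Amplicon-to-CpG-count map.
#' @param baseline_composition Named fractions per cell type, summing to 1.
#' @param inter_individual_sd Named per-amplicon SD (percentage points) of
#'   the per-CpG individual offsets.
#' @param assay_noise_sd Pyrosequencing measurement noise SD, percentage
#'   points.
#' @param beta_noise_sd Array measurement noise SD, beta units.
#' @param beta_indiv_sd Per-probe individual offset SD, beta units.
#' @param prob_mixed Probability a pair has mixed chimerism.
#' @param mixed_f_range Range the recipient fraction f is drawn from for
#'   mixed pairs; complete-chimerism pairs have f = 0.
#' @param chimerism_fractions Optional explicit vector of f per pair
#'   (overrides `prob_mixed`/`mixed_f_range`).
#' @param agvhd_probs Named probabilities over grades "0", "I", "II-V".
#' @param agvhd_grades Optional explicit grade per pair.
#' @param agvhd_shift_severe Composition shift (summing to 0) applied at
#'   month 1 under severe aGVHD; grade I pairs get half of it.
#' @param reconstitution_rate Per-month exponential decay rate of the
#'   aGVHD composition shift.
#' @param promoter_signatures Matrix (promoter x cell type) of percent
#'   methylation signatures.
#' @param timepoints Months post-transplant at which recipients are sampled.
#' @param n_probes Number of array probes to simulate.
#' @param prop_informative_probes Fraction of probes with cell-type-specific
#'   signatures (the rest are constitutive).
#' @param detection_fail_rate Fraction of probe/sample measurements whose
#'   detection p-value indicates a failed probe.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_pairs = 47L,
                              panel_spec = default_panel_spec(),
                              baseline_composition = c(neutrophil = 0.55,
                                                       monocyte = 0.08,
                                                       CD4T = 0.18,
                                                       CD8T = 0.12,
                                                       NK = 0.07),
                              inter_individual_sd = c(LINE1 = 2, NBL2 = 4,
                                                      D4Z4 = 3.5, IFNG = 4,
                                                      FASL = 4, IL10 = 4,
                                                      PRF1 = 4),
                              assay_noise_sd = 1,
                              beta_noise_sd = 0.02,
                              beta_indiv_sd = 0.03,
                              prob_mixed = 0.25,
                              mixed_f_range = c(0.3, 0.7),
                              chimerism_fractions = NULL,
                              agvhd_probs = c("0" = 0.25, "I" = 0.27,
                                              "II-V" = 0.48),
                              agvhd_grades = NULL,
                              agvhd_shift_severe = c(neutrophil = -0.10,
                                                     monocyte = 0,
                                                     CD4T = 0,
                                                     CD8T = 0.06,
                                                     NK = 0.04),
                              reconstitution_rate = 0.3,
                              promoter_signatures = .default_promoter_signatures(),
                              timepoints = c(1L, 3L, 6L, 12L),
                              n_probes = 400L,
                              prop_informative_probes = 0.3,
                              detection_fail_rate = 0.02) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (abs(sum(baseline_composition) - 1) > 1e-8) {
    stop("config error: baseline_composition must sum to 1", call. = FALSE)
  }
  if (any(baseline_composition < 0)) {
    stop("config error: negative cell-type fraction", call. = FALSE)
  }
  if (abs(sum(agvhd_shift_severe)) > 1e-8) {
    stop("config error: agvhd_shift_severe must sum to 0 so compositions ",
         "remain on the simplex", call. = FALSE)
  }
  if (assay_noise_sd < 0 || beta_noise_sd < 0 || beta_indiv_sd < 0) {
    stop("config error: noise SDs must be >= 0", call. = FALSE)
  }
  if (!is.null(chimerism_fractions)) {
    if (length(chimerism_fractions) != n_pairs ||
        any(chimerism_fractions < 0 | chimerism_fractions > 1)) {
      stop("config error: chimerism_fractions must be n_pairs values in [0,1]",
           call. = FALSE)
    }
  }
  if (!is.null(agvhd_grades) && length(agvhd_grades) != n_pairs) {
    stop("config error: agvhd_grades must have one grade per pair",
         call. = FALSE)
  }
  missing_sd <- setdiff(names(panel_spec), names(inter_individual_sd))
  if (length(missing_sd)) {
    stop("config error: inter_individual_sd lacks amplicon(s): ",
         paste(missing_sd, collapse = ", "), call. = FALSE)
  }
  agvhd_probs <- agvhd_probs / sum(agvhd_probs)
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 panel_spec = panel_spec,
                 baseline_composition = baseline_composition,
                 inter_individual_sd = inter_individual_sd,
                 assay_noise_sd = assay_noise_sd,
                 beta_noise_sd = beta_noise_sd, beta_indiv_sd = beta_indiv_sd,
                 prob_mixed = prob_mixed, mixed_f_range = mixed_f_range,
                 chimerism_fractions = chimerism_fractions,
                 agvhd_probs = agvhd_probs, agvhd_grades = agvhd_grades,
                 agvhd_shift_severe = agvhd_shift_severe,
                 reconstitution_rate = reconstitution_rate,
                 promoter_signatures = promoter_signatures,
                 timepoints = as.integer(timepoints),
                 n_probes = as.integer(n_probes),
                 prop_informative_probes = prop_informative_probes,
                 detection_fail_rate = detection_fail_rate),
            class = "simulation_config")
}

# substream seeding: a small bijective-ish hash of (master seed, stream id,
# unit index), kept below 2^31 so R's 32-bit set.seed accepts it
.stream_seed <- function(seed, stream, unit = 0L) {
  ((as.double(seed) %% 1e6) * 1009 + stream * 7919 + unit * 104729) %% 2147483647
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# cell-type signature matrices (n_cpgs x n_celltypes, percent scale) for the
# repeat-element amplicons; promoter assays use the configured signatures
.make_signatures <- function(config) {
  set.seed(.stream_seed(config$seed, 1L))
  base_level <- c(LINE1 = 72, NBL2 = 68, D4Z4 = 60)
  sigs <- list()
  for (a in names(config$panel_spec)) {
    n <- config$panel_spec[[a]]
    if (a %in% rownames(config$promoter_signatures)) {
      sigs[[a]] <- matrix(rep(config$promoter_signatures[a, ], each = n),
                          nrow = n, dimnames = list(NULL, .celltypes))
    } else {
      mu <- if (a %in% names(base_level)) base_level[[a]] else 65
      cpg_dev <- stats::rnorm(n, 0, 4)          # fixed per-CpG level
      ct_dev <- stats::rnorm(length(.celltypes), 0, 3)  # cell-type identity
      s <- outer(cpg_dev, ct_dev, "+") + mu +
        matrix(stats::rnorm(n * length(.celltypes), 0, 1.5), nrow = n)
      sigs[[a]] <- .clip(s, 2, 98)
      colnames(sigs[[a]]) <- .celltypes
    }
  }
  sigs
}

.composition_at <- function(config, grade, month) {
  shift <- switch(grade,
                  "II-V" = config$agvhd_shift_severe,
                  "I" = config$agvhd_shift_severe / 2,
                  config$baseline_composition * 0)
  decay <- exp(-config$reconstitution_rate * (month - 1))
  comp <- config$baseline_composition + shift * decay
  comp <- pmax(comp, 0)
  comp / sum(comp)
}

#' Simulate a donor/recipient transplant cohort
#'
#' Draws a complete synthetic cohort under the generative model described in
#' the package vignette: cohort metadata, pyrosequencing panel measurements
#' for every amplicon/sample, a bead-array beta matrix with detection
#' p-values, and a truth table holding every latent quantity. Identical seed
#' and configuration give bitwise-identical output, and pair-level
#' randomness is substreamed so the first k pairs of a larger cohort equal
#' the k pairs of a smaller one.
#'
#' @param config A [simulation_config()].
#' @return List with elements `cohort` (a `cohort_table`), `panel` (a
#'   `pyro_panel`), `beta` (a `beta_matrix`), `truth` (per-pair data.frame
#'   with true fraction, grade, chimerism label), `clipped_fraction`
#'   (named: pyro, beta) and `latents` (signatures and per-subject offsets).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sigs <- .make_signatures(config)
  amplicons <- names(config$panel_spec)
  tps <- config$timepoints

  pair_ids <- sprintf("P%03d", seq_len(config$n_pairs))
  truth <- vector("list", config$n_pairs)
  offsets <- list()
  panel_rows <- list()
  cohort_rows <- list()

  # array signatures: per-probe per-celltype beta
  set.seed(.stream_seed(config$seed, 2L))
  probe_ids <- sprintf("cg%06d", seq_len(config$n_probes))
  gene_symbols <- sprintf("GENE%04d", seq_len(config$n_probes))
  probe_base <- stats::runif(config$n_probes, 0.05, 0.95)
  informative <- stats::runif(config$n_probes) < config$prop_informative_probes
  probe_sig <- matrix(probe_base, nrow = config$n_probes,
                      ncol = length(.celltypes))
  if (any(informative)) {
    probe_sig[informative, ] <- .clip(
      probe_sig[informative, , drop = FALSE] +
        matrix(stats::rnorm(sum(informative) * length(.celltypes), 0, 0.15),
               nrow = sum(informative), ncol = length(.celltypes)),
      0.01, 0.99)
  }
  colnames(probe_sig) <- .celltypes

  beta_cols <- list()
  detp_cols <- list()
  n_clip_pyro <- 0; n_tot_pyro <- 0
  n_clip_beta <- 0; n_tot_beta <- 0

  blood_profile <- function(amp, comp, offset) {
    drop(sigs[[amp]] %*% comp) + offset[[amp]]
  }
  measure_pyro <- function(values, noise_rng) {
    raw <- values + noise_rng
    n_clip_pyro <<- n_clip_pyro + sum(raw < 0 | raw > 100)
    n_tot_pyro <<- n_tot_pyro + length(raw)
    .clip(raw, 0, 100)
  }

  for (i in seq_len(config$n_pairs)) {
    pid <- pair_ids[i]
    set.seed(.stream_seed(config$seed, 3L, i))

    f <- if (!is.null(config$chimerism_fractions)) {
      config$chimerism_fractions[i]
    } else if (stats::runif(1) < config$prob_mixed) {
      stats::runif(1, config$mixed_f_range[1], config$mixed_f_range[2])
    } else 0
    grade <- if (!is.null(config$agvhd_grades)) {
      normalize_agvhd_grade(config$agvhd_grades[i])
    } else {
      sample(names(config$agvhd_probs), 1L, prob = config$agvhd_probs)
    }
    chim <- if (f > 0) "mixed" else "complete"

    # individual offsets are truncated so that every latent blood profile
    # (signature mixture + offset) stays within the physical range; convex
    # donor/recipient mixing then never leaves it, keeping DNA-level mixture
    # linearity exact in the noise-free limit
    draw_offset <- function(a) {
      lo <- -apply(sigs[[a]], 1L, min)
      hi <- 100 - apply(sigs[[a]], 1L, max)
      .clip(stats::rnorm(config$panel_spec[[a]], 0,
                         config$inter_individual_sd[[a]]), lo, hi)
    }
    off_d <- lapply(amplicons, draw_offset)
    off_r <- lapply(amplicons, draw_offset)
    names(off_d) <- names(off_r) <- amplicons
    blo <- -apply(probe_sig, 1L, min)
    bhi <- 1 - apply(probe_sig, 1L, max)
    boff_d <- .clip(stats::rnorm(config$n_probes, 0, config$beta_indiv_sd),
                    blo, bhi)
    boff_r <- .clip(stats::rnorm(config$n_probes, 0, config$beta_indiv_sd),
                    blo, bhi)
    offsets[[pid]] <- list(donor = off_d, recipient = off_r)

    don_id <- paste0(pid, "_D")
    pre_id <- paste0(pid, "_R_pre")
    post_ids <- paste0(pid, "_R_m", tps)

    cohort_rows[[pid]] <- data.frame(
      sample_id = c(don_id, pre_id, post_ids),
      subject_id = c(paste0(pid, "_donor"),
                     rep(paste0(pid, "_recipient"), 1L + length(tps))),
      role = c("donor", rep("recipient", 1L + length(tps))),
      timepoint_months = c(NA_integer_, -1L, tps),
      pair_id = pid,
      chimerism = c("unknown", rep(chim, 1L + length(tps))),
      agvhd_grade = c("unknown", rep(grade, 1L + length(tps))),
      stringsAsFactors = FALSE)

    base_comp <- config$baseline_composition
    for (a in amplicons) {
      n <- config$panel_spec[[a]]
      don_true <- blood_profile(a, base_comp, off_d)
      pre_true <- blood_profile(a, base_comp, off_r)
      post_true <- vapply(tps, function(tp) {
        comp_t <- .composition_at(config, grade, tp)
        f * blood_profile(a, comp_t, off_r) +
          (1 - f) * blood_profile(a, comp_t, off_d)
      }, numeric(n))
      vals <- cbind(don_true, pre_true, matrix(post_true, nrow = n))
      noise <- matrix(stats::rnorm(length(vals), 0, config$assay_noise_sd),
                      nrow = n)
      meas <- measure_pyro(vals, noise)
      colnames(meas) <- c(don_id, pre_id, post_ids)
      panel_rows[[paste(pid, a)]] <- data.frame(
        sample_id = rep(colnames(meas), each = n),
        amplicon_id = a,
        cpg_index = rep(seq_len(n), times = ncol(meas)),
        meth_pct = as.vector(meas),
        stringsAsFactors = FALSE)
    }

    # bead-array measurements for every sample of the pair
    don_b <- .clip(drop(probe_sig %*% base_comp) + boff_d, 0, 1)
    pre_b <- .clip(drop(probe_sig %*% base_comp) + boff_r, 0, 1)
    post_b <- vapply(tps, function(tp) {
      comp_t <- .composition_at(config, grade, tp)
      .clip(f * (drop(probe_sig %*% comp_t) + boff_r) +
              (1 - f) * (drop(probe_sig %*% comp_t) + boff_d), 0, 1)
    }, numeric(config$n_probes))
    bvals <- cbind(don_b, pre_b, matrix(post_b, nrow = config$n_probes))
    bnoise <- matrix(stats::rnorm(length(bvals), 0, config$beta_noise_sd),
                     nrow = config$n_probes)
    braw <- bvals + bnoise
    n_clip_beta <- n_clip_beta + sum(braw < 0 | braw > 1)
    n_tot_beta <- n_tot_beta + length(braw)
    bmeas <- .clip(braw, 0, 1)
    colnames(bmeas) <- c(don_id, pre_id, post_ids)
    fail <- matrix(stats::runif(length(bvals)) < config$detection_fail_rate,
                   nrow = config$n_probes)
    dp <- matrix(stats::runif(length(bvals), 0, 0.005),
                 nrow = config$n_probes)
    dp[fail] <- stats::runif(sum(fail), 0.02, 0.5)
    colnames(dp) <- colnames(bmeas)
    for (s in colnames(bmeas)) {
      beta_cols[[s]] <- bmeas[, s]
      detp_cols[[s]] <- dp[, s]
    }

    truth[[i]] <- data.frame(pair_id = pid, true_f = f, chimerism = chim,
                             agvhd_grade = grade, stringsAsFactors = FALSE)
  }

  cohort <- cohort_table(do.call(rbind, cohort_rows))
  panel <- do.call(rbind, panel_rows)
  panel <- panel[order(panel$sample_id, panel$amplicon_id, panel$cpg_index), ]
  rownames(panel) <- NULL
  attr(panel, "panel_spec") <- config$panel_spec
  class(panel) <- c("pyro_panel", "data.frame")

  beta <- beta_matrix(do.call(cbind, beta_cols)[, , drop = FALSE],
                      gene_symbols = gene_symbols,
                      detection_p = do.call(cbind, detp_cols),
                      probe_ids = probe_ids,
                      samples = names(beta_cols))

  list(cohort = cohort, panel = panel, beta = beta,
       truth = do.call(rbind, truth),
       clipped_fraction = c(pyro = n_clip_pyro / max(n_tot_pyro, 1),
                            beta = n_clip_beta / max(n_tot_beta, 1)),
       latents = list(signatures = sigs, offsets = offsets,
                      probe_signatures = probe_sig))
}

#' Construct a toy beta matrix with a known altered-probe answer key
#'
#' Builds a two-sample (donor/recipient) beta matrix in which exactly
#' `n_altered` probes exceed the strict alteration threshold. When there is
#' room, one of the unaltered probes sits at |delta beta| exactly equal to
#' the threshold — the boundary case a strict caller must not call.
#'
#' @param n_probes Total probes.
#' @param n_altered Probes that must be called altered (<= n_probes).
#' @param threshold Alteration threshold in (0, 1).
#' @param seed Seed for the sub-threshold jitter.
#' @return List: `beta` (a `beta_matrix` with permissive detection
#'   p-values), `answer` (probe ids that are truly altered), `boundary_probe`
#'   (the exactly-at-threshold probe id, or NA).
#' @export
make_toy_beta_fixture <- function(n_probes, n_altered, threshold = 0.20,
                                  seed = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (n_altered > n_probes) {
    stop("n_altered must not exceed n_probes", call. = FALSE)
  }
  set.seed(seed)
  probe_ids <- sprintf("cg%06d", seq_len(n_probes))
  bd <- rep(0.5, n_probes)
  delta <- numeric(n_probes)
  sgn <- rep_len(c(1, -1), n_probes)
  altered <- seq_len(n_altered)
  margin <- min(0.1, (1 - threshold) / 2)
  if (n_altered > 0) {
    delta[altered] <- sgn[altered] *
      (threshold + stats::runif(n_altered, margin / 10, margin))
  }
  boundary <- NA_character_
  if (n_probes > n_altered) {
    bidx <- n_altered + 1L
    delta[bidx] <- sgn[bidx] * threshold  # exactly at threshold: not a call
    boundary <- probe_ids[bidx]
    rest <- setdiff(seq_len(n_probes), c(altered, bidx))
    delta[rest] <- sgn[rest] * stats::runif(length(rest), 0, threshold * 0.9)
  }
  br <- bd + delta
  beta <- cbind(donor = bd, recipient = br)
  rownames(beta) <- probe_ids
  bm <- beta_matrix(beta,
                    gene_symbols = sprintf("GENE%04d", seq_len(n_probes)),
                    detection_p = matrix(0.001, n_probes, 2,
                                         dimnames = list(probe_ids,
                                                         c("donor",
                                                           "recipient"))))
  list(beta = bm, answer = probe_ids[altered], boundary_probe = boundary)
}
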