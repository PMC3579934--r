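#' Default pyrosequencing panel specification
#'
#' Amplicon-to-CpG-count map for the assays the package targets: the
#' repetitive elements LINE1 (4 CpGs), NBL2 and D4Z4 (6 CpGs each), whose
#' methylation proxies genome-wide levels, and four single-CpG promoter
#' assays for immune genes (IFNG, FASL, IL10, PRF1).
#'
#' @return Named integer vector mapping amplicon id to number of CpG sites.
#' @export
default_panel_spec <- function() {
  c(LINE1 = 4L, NBL2 = 6L, D4Z4 = 6L,
    IFNG = 1L, FASL = 1L, IL10 = 1L, PRF1 = 1L)
}

#' Construct a methylation profile
#'
#' An ordered vector of percent-methylation values for the CpG sites of one
#' amplicon in one sample. CpG ordering is fixed per amplicon and must be
#' identical across samples; values are percent in [0, 100] or NA.
#'
#' @param amplicon_id Amplicon identifier (e.g. "NBL2").
#' @param cpg_values Numeric vector of percent methylation, NA allowed.
#' @param n_cpgs Expected panel size; defaults to `length(cpg_values)`.
#' @return An object of class `methylation_profile`.
#' @export
methylation_profile <- function(amplicon_id, cpg_values,
                                n_cpgs = length(cpg_values)) {
  cpg_values <- as.numeric(cpg_values)
  if (length(cpg_values) != n_cpgs) {
    stop("schema error: amplicon '", amplicon_id, "' expects ", n_cpgs,
         " CpG values, got ", length(cpg_values), call. = FALSE)
  }
  bad <- which(!is.na(cpg_values) & (cpg_values < 0 | cpg_values > 100))
  if (length(bad)) {
    stop("range error: percent methylation outside [0, 100] at CpG position",
         if (length(bad) > 1) "s " else " ", paste(bad, collapse = ", "),
         " (amplicon '", amplicon_id, "')", call. = FALSE)
  }
  structure(list(amplicon_id = as.character(amplicon_id),
                 cpg_values = cpg_values,
                 n_cpgs = as.integer(n_cpgs)),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat("<methylation_profile> amplicon", x$amplicon_id,
      sprintf("(%d CpGs):", x$n_cpgs),
      paste(formatC(x$cpg_values, digits = 4, format = "fg"), collapse = " "),
      "\n")
  invisible(x)
}

#' Construct a probes-by-samples beta-value matrix
#'
#' Container for bead-array methylation exports: beta values in [0, 1] with
#' optional per-probe-per-sample detection p-values and a one-gene-per-probe
#' annotation (blank allowed).
#'
#' @param beta Numeric matrix, probes in rows, samples in columns. Row names
#'   are probe ids, column names sample ids (or supply `probe_ids`/`samples`).
#' @param gene_symbols Character vector, one gene symbol per probe ("" allowed).
#' @param detection_p Optional numeric matrix of detection p-values with the
#'   same dimensions as `beta`, or NULL when the export lacked them.
#' @param probe_ids,samples Optional explicit dimension names.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, gene_symbols, detection_p = NULL,
                        probe_ids = rownames(beta), samples = colnames(beta)) {
  beta <- as.matrix(beta)
  if (is.null(probe_ids) || is.null(samples)) {
    stop("beta matrix requires probe and sample identifiers", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  samples <- as.character(samples)
  if (anyDuplicated(probe_ids)) {
    stop("schema error: duplicated probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(gene_symbols) != nrow(beta)) {
    stop("schema error: gene_symbols must have one entry per probe",
         call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("range error: beta outside [0, 1] at probe '",
         probe_ids[bad[1, 1]], "', sample '", samples[bad[1, 2]], "'",
         call. = FALSE)
  }
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(beta))) {
      stop("schema error: detection_p dimensions differ from beta",
           call. = FALSE)
    }
    dimnames(detection_p) <- list(probe_ids, samples)
  }
  dimnames(beta) <- list(probe_ids, samples)
  structure(list(probe_ids = probe_ids,
                 gene_symbols = as.character(gene_symbols),
                 samples = samples,
                 beta = beta,
                 detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix>", length(x$probe_ids), "probes x",
      length(x$samples), "samples;",
      if (is.null(x$detection_p)) "detection p-values absent"
      else "detection p-values present", "\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

.chimerism_levels <- c("complete", "mixed", "unknown")
.agvhd_levels <- c("0", "I", "II-V", "unknown")

#' Normalize an aGVHD grade token into the study grouping
#'
#' Grades are analyzed in three groups: none (0), moderate (I) and severe
#' (II-V). Individual grades II, III, IV, V collapse into "II-V"; en-dash
#' and hyphen spellings are accepted.
#'
#' @param grade Character vector of grade tokens.
#' @return Character vector over {"0", "I", "II-V", "unknown"}.
#' @export
normalize_agvhd_grade <- function(grade) {
  g <- trimws(as.character(grade))
  g[g %in% c("II", "III", "IV", "V", "II-V", "II–V", "2", "3", "4", "5")] <- "II-V"
  g[g %in% c("0", "none")] <- "0"
  g[g %in% c("I", "1")] <- "I"
  g[is.na(g) | g == "" | g == "NA"] <- "unknown"
  bad <- setdiff(unique(g), .agvhd_levels)
  if (length(bad)) {
    stop("vocabulary error: unknown aGVHD grade token(s) ",
         paste(sQuote(bad), collapse = ", "),
         "; allowed: 0, I, II, III, IV, V, II-V, unknown", call. = FALSE)
  }
  g
}

#' Construct and validate a cohort metadata table
#'
#' One row per sample. Donor samples carry `pair_id` linking them to their
#' recipient's samples and an NA timepoint; recipient samples use
#' `timepoint_months = -1` for the pre-transplant draw and positive integers
#' for months post-transplant. Chimerism status and aGVHD grade are recipient
#' attributes repeated on each of the recipient's rows.
#'
#' @param df A data.frame with columns `sample_id`, `subject_id`, `role`
#'   (donor/recipient), `timepoint_months`, `pair_id`, `chimerism`
#'   (complete/mixed/unknown) and `agvhd_grade` (0, I, II-V or a raw grade).
#' @return The validated data.frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  required <- c("sample_id", "subject_id", "role", "timepoint_months",
                "pair_id", "chimerism", "agvhd_grade")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: cohort table lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$role <- as.character(df$role)
  df$pair_id <- as.character(df$pair_id)
  df$timepoint_months <- suppressWarnings(as.integer(df$timepoint_months))
  if (anyDuplicated(df$sample_id)) {
    stop("schema error: duplicated sample id(s)", call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("donor", "recipient"))
  if (length(bad_role)) {
    stop("vocabulary error: unknown role token(s) ",
         paste(sQuote(bad_role), collapse = ", "),
         "; allowed: donor, recipient", call. = FALSE)
  }
  chim <- trimws(as.character(df$chimerism))
  chim[is.na(chim) | chim == "" | chim == "NA"] <- "unknown"
  bad_chim <- setdiff(unique(chim), .chimerism_levels)
  if (length(bad_chim)) {
    stop("vocabulary error: unknown chimerism token(s) ",
         paste(sQuote(bad_chim), collapse = ", "),
         "; allowed: ", paste(.chimerism_levels, collapse = ", "),
         call. = FALSE)
  }
  df$chimerism <- chim
  df$agvhd_grade <- normalize_agvhd_grade(df$agvhd_grade)

  rec <- df[df$role == "recipient", , drop = FALSE]
  don <- df[df$role == "donor", , drop = FALSE]
  donor_pairs <- unique(don$pair_id)
  orphans <- setdiff(unique(rec$pair_id), donor_pairs)
  if (length(orphans)) {
    stop("linkage error: recipient pair id(s) with no donor sample: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  multi <- names(which(tapply(don$subject_id, don$pair_id,
                              function(s) length(unique(s))) > 1))
  if (length(multi)) {
    stop("linkage error: pair id(s) resolving to more than one donor: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  bad_tp <- !is.na(rec$timepoint_months) & rec$timepoint_months < -1
  if (any(bad_tp)) {
    stop("range error: recipient timepoint_months below -1", call. = FALSE)
  }
  for (sid in unique(rec$subject_id)) {
    tp <- rec$timepoint_months[rec$subject_id == sid]
    tp <- tp[!is.na(tp)]
    if (anyDuplicated(tp) || is.unsorted(sort(tp))) {
      if (anyDuplicated(tp)) {
        stop("schema error: duplicated timepoint for recipient '", sid, "'",
             call. = FALSE)
      }
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
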