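# Bead-array differential methylation workflow: detection-p filtering,
# altered-probe calling against the donor at a strict |delta-beta| > 0.20
# criterion, gene collapsing, and cross-case gene overlap.

#' Filter a beta matrix by detection p-value
#'
#' Retains exactly the probes whose detection p-value is <= `alpha` in every
#' named sample (probes with p > alpha in any one of them are excluded, the
#' conservative both-samples rule). Excluded probe ids are attached as the
#' `excluded_probes` attribute.
#'
#' @param bm A `beta_matrix` with detection p-values.
#' @param samples Sample ids the filter must hold in; default all samples.
#' @param alpha Detection p-value cutoff (default 0.01).
#' @return The filtered `beta_matrix` with attribute `excluded_probes`.
#' @export
filter_detected <- function(bm, samples = bm$samples, alpha = 0.01) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (is.null(bm$detection_p)) {
    stop("detection p-values absent from this beta matrix; re-run with the ",
         "detection filter waived if the export carries none", call. = FALSE)
  }
  missing_s <- setdiff(samples, bm$samples)
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  p <- bm$detection_p[, samples, drop = FALSE]
  keep <- apply(p, 1L, function(r) all(!is.na(r) & r <= alpha))
  out <- beta_matrix(bm$beta[keep, , drop = FALSE],
                     bm$gene_symbols[keep],
                     detection_p = bm$detection_p[keep, , drop = FALSE],
                     probe_ids = bm$probe_ids[keep], samples = bm$samples)
  attr(out, "excluded_probes") <- bm$probe_ids[!keep]
  out
}

#' Call altered probes in a donor-vs-recipient comparison
#'
#' A probe is altered iff |beta_recipient - beta_donor| > `threshold`
#' (strict inequality: a difference of exactly the threshold is not a call).
#' The default 0.20 is the absolute beta-difference reading of the
#' "more than 20%" criterion, the standard delta-beta rule for 27k-class
#' arrays; `relative = TRUE` switches to the relative reading
#' (|delta| > threshold * beta_donor) for sensitivity analysis. The signed
#' delta-beta is retained (positive = hypermethylated relative to donor).
#' Probes with missing beta in either sample are excluded and reported in
#' the `skipped_probes` attribute; gene collapsing counts distinct non-blank
#' gene symbols.
#'
#' @param bm A `beta_matrix` (detection-filtered, or explicitly not).
#' @param donor,recipient Sample ids of the two columns to compare.
#' @param threshold Alteration threshold in beta units, in (0, 1).
#' @param relative If TRUE, threshold is relative to the donor beta.
#' @return Data.frame of class `altered_probe_set` with columns `probe_id`,
#'   `gene_symbol`, `beta_donor`, `beta_recipient`, `delta_beta`, sorted by
#'   probe id; attributes `n_probes`, `n_genes`, `comparison_id`,
#'   `skipped_probes`.
#' @export
call_altered_probes <- function(bm, donor, recipient, threshold = 0.20,
                                relative = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (threshold <= 0 || threshold >= 1) {
    stop("alteration threshold must lie in (0, 1)", call. = FALSE)
  }
  for (s in c(donor, recipient)) {
    if (!s %in% bm$samples) {
      stop("sample '", s, "' absent from beta matrix", call. = FALSE)
    }
  }
  bd <- bm$beta[, donor]
  br <- bm$beta[, recipient]
  usable <- !is.na(bd) & !is.na(br)
  delta <- br - bd
  cut <- if (relative) threshold * bd else threshold
  hit <- usable & abs(delta) > cut
  out <- data.frame(probe_id = bm$probe_ids[hit],
                    gene_symbol = bm$gene_symbols[hit],
                    beta_donor = unname(bd[hit]),
                    beta_recipient = unname(br[hit]),
                    delta_beta = unname(delta[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "comparison_id") <- paste0(donor, "_vs_", recipient)
  attr(out, "n_probes") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene_symbol[out$gene_symbol != ""]))
  attr(out, "skipped_probes") <- bm$probe_ids[!usable]
  attr(out, "threshold") <- threshold
  class(out) <- c("altered_probe_set", "data.frame")
  out
}

#' Genes altered in both of two comparisons
#'
#' Sorted distinct gene symbols present in both altered-probe sets
#' (case-sensitive exact match; blank symbols never overlap).
#'
#' @param a,b `altered_probe_set` objects.
#' @return Character vector, sorted.
#' @export
overlap_genes <- function(a, b) {
  ga <- unique(a$gene_symbol[a$gene_symbol != ""])
  gb <- unique(b$gene_symbol[b$gene_symbol != ""])
  sort(intersect(ga, gb))
}
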