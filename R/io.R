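# Delimited-text readers/writers for the three input schemas and the result
# tables. Dialect: comma- or tab-delimited (auto-detected from the header
# line), header row required, UTF-8, missing values as empty field or "NA".
# Readers never impute; output is canonically sorted so it is independent of
# input row order.

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_delim <- function(path) {
  sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, encoding = "UTF-8",
                    na.strings = c("", "NA"))
}

.as_num <- function(x, what, rows) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("parse error: malformed numeric field in column '", what,
         "' at file line", if (length(bad) > 1) "s " else " ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a pyrosequencing panel file
#'
#' Expects one row per sample per amplicon: columns `sample_id`,
#' `amplicon_id`, then `cpg_1 ... cpg_K` with one percent-methylation value
#' per CpG position (trailing columns beyond the amplicon's panel size must
#' be empty). Values are validated against [0, 100] and against the declared
#' panel sizes; offending rows are reported by file line number.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @param panel_spec Named integer vector, amplicon id to CpG count.
#' @return A long-format data.frame of class `pyro_panel` with columns
#'   `sample_id`, `amplicon_id`, `cpg_index`, `meth_pct`, sorted by sample,
#'   amplicon and CpG index, carrying `panel_spec` as an attribute.
#' @export
read_pyro_panel <- function(path, panel_spec = default_panel_spec()) {
  df <- .read_delim(path)
  if (!all(c("sample_id", "amplicon_id") %in% names(df))) {
    stop("schema error: panel file needs 'sample_id' and 'amplicon_id' columns",
         call. = FALSE)
  }
  cpg_cols <- grep("^cpg_[0-9]+$", names(df), value = TRUE)
  cpg_cols <- cpg_cols[order(as.integer(sub("^cpg_", "", cpg_cols)))]
  if (nrow(df) == 0L) {
    out <- data.frame(sample_id = character(), amplicon_id = character(),
                      cpg_index = integer(), meth_pct = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "panel_spec") <- panel_spec
    class(out) <- c("pyro_panel", "data.frame")
    return(out)
  }
  lines <- seq_len(nrow(df)) + 1L  # header is file line 1
  unknown <- setdiff(unique(df$amplicon_id), names(panel_spec))
  if (length(unknown)) {
    stop("schema error: amplicon(s) not in panel_spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_need <- panel_spec[df$amplicon_id]
  if (length(cpg_cols) < max(n_need)) {
    stop("schema error: file has ", length(cpg_cols),
         " CpG columns but panel_spec requires up to ", max(n_need),
         call. = FALSE)
  }
  vals <- sapply(cpg_cols, function(cn) .as_num(df[[cn]], cn, lines))
  vals <- matrix(vals, nrow = nrow(df))
  # values present beyond the amplicon's declared size -> schema error
  over <- which(matrix(rep(seq_along(cpg_cols), each = nrow(df)),
                       nrow = nrow(df)) > n_need & !is.na(vals),
                arr.ind = TRUE)
  if (nrow(over)) {
    stop("schema error: value beyond declared panel size at file line",
         if (nrow(over) > 1) "s " else " ",
         paste(sort(unique(lines[over[, 1]])), collapse = ", "),
         call. = FALSE)
  }
  in_panel <- matrix(rep(seq_along(cpg_cols), each = nrow(df)),
                     nrow = nrow(df)) <= n_need
  oob <- !is.na(vals) & in_panel & (vals < 0 | vals > 100)
  if (any(oob)) {
    stop("range error: percent methylation outside [0, 100]; rejected file line",
         if (sum(rowSums(oob) > 0) > 1) "s " else " ",
         paste(lines[rowSums(oob) > 0], collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    n <- n_need[i]
    data.frame(sample_id = df$sample_id[i], amplicon_id = df$amplicon_id[i],
               cpg_index = seq_len(n), meth_pct = vals[i, seq_len(n)],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$amplicon_id, out$cpg_index), ]
  rownames(out) <- NULL
  attr(out, "panel_spec") <- panel_spec
  class(out) <- c("pyro_panel", "data.frame")
  out
}

#' Write a pyrosequencing panel to delimited text
#'
#' Inverse of [read_pyro_panel()]: emits the wide one-row-per-sample-per-
#' amplicon layout with `cpg_1 ... cpg_K` columns.
#'
#' @param panel A `pyro_panel` long-format data.frame.
#' @param path Output path; `sep` is "," or "\t".
#' @param sep Field separator.
#' @export
write_pyro_panel <- function(panel, path, sep = ",") {
  spec <- attr(panel, "panel_spec")
  kmax <- if (nrow(panel)) max(panel$cpg_index) else max(spec, 1L)
  keys <- unique(panel[, c("sample_id", "amplicon_id")])
  wide <- matrix(NA_real_, nrow = nrow(keys), ncol = kmax)
  if (nrow(keys)) {
    idx <- match(paste(panel$sample_id, panel$amplicon_id),
                 paste(keys$sample_id, keys$amplicon_id))
    wide[cbind(idx, panel$cpg_index)] <- panel$meth_pct
  }
  out <- cbind(keys, as.data.frame(wide))
  names(out) <- c("sample_id", "amplicon_id", paste0("cpg_", seq_len(kmax)))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Extract one sample's profile from a panel
#'
#' @param panel A `pyro_panel`.
#' @param sample_id,amplicon_id Identifiers of the wanted profile.
#' @return A [methylation_profile()].
#' @export
get_profile <- function(panel, sample_id, amplicon_id) {
  rows <- panel$sample_id == sample_id & panel$amplicon_id == amplicon_id
  if (!any(rows)) {
    stop("no profile for sample '", sample_id, "', amplicon '", amplicon_id,
         "'", call. = FALSE)
  }
  sub <- panel[rows, ]
  sub <- sub[order(sub$cpg_index), ]
  methylation_profile(amplicon_id, sub$meth_pct)
}

#' Read a bead-array beta matrix
#'
#' Expects columns `probe_id`, `gene_symbol`, then per sample a
#' `<sample>_beta` column and, optionally, a `<sample>_pval` detection
#' p-value column (all samples must agree on whether p-values are present).
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A [beta_matrix()]; `detection_p` is NULL when the file has no
#'   p-value columns. Probes are sorted by probe id.
#' @export
read_beta_matrix <- function(path) {
  df <- .read_delim(path)
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    stop("schema error: beta file needs 'probe_id' and 'gene_symbol' columns",
         call. = FALSE)
  }
  beta_cols <- grep("_beta$", names(df), value = TRUE)
  pval_cols <- grep("_pval$", names(df), value = TRUE)
  if (!length(beta_cols)) {
    stop("schema error: no '<sample>_beta' columns found", call. = FALSE)
  }
  samples <- sub("_beta$", "", beta_cols)
  lines <- seq_len(nrow(df)) + 1L
  beta <- sapply(beta_cols, function(cn) .as_num(df[[cn]], cn, lines))
  beta <- matrix(beta, nrow = nrow(df), dimnames = list(df$probe_id, samples))
  detection_p <- NULL
  if (length(pval_cols)) {
    psamples <- sub("_pval$", "", pval_cols)
    if (!setequal(psamples, samples)) {
      stop("schema error: detection p-value columns do not match beta columns",
           call. = FALSE)
    }
    detection_p <- sapply(paste0(samples, "_pval"),
                          function(cn) .as_num(df[[cn]], cn, lines))
    detection_p <- matrix(detection_p, nrow = nrow(df),
                          dimnames = list(df$probe_id, samples))
  }
  bm <- beta_matrix(beta, gene_symbols = ifelse(is.na(df$gene_symbol), "",
                                                df$gene_symbol),
                    detection_p = detection_p)
  ord <- order(bm$probe_ids)
  beta_matrix(bm$beta[ord, , drop = FALSE], bm$gene_symbols[ord],
              detection_p = if (is.null(bm$detection_p)) NULL
                            else bm$detection_p[ord, , drop = FALSE])
}

#' Write a beta matrix to delimited text
#'
#' @param bm A `beta_matrix`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_beta_matrix <- function(bm, path, sep = ",") {
  out <- data.frame(probe_id = bm$probe_ids, gene_symbol = bm$gene_symbols,
                    stringsAsFactors = FALSE)
  for (s in bm$samples) {
    out[[paste0(s, "_beta")]] <- bm$beta[, s]
    if (!is.null(bm$detection_p)) out[[paste0(s, "_pval")]] <- bm$detection_p[, s]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a cohort metadata table
#'
#' @param path Path to a delimited file with the [cohort_table()] columns.
#' @return A validated `cohort_table`, sorted by pair, role and timepoint.
#' @export
read_cohort <- function(path) {
  df <- .read_delim(path)
  ct <- cohort_table(df)
  ct <- ct[order(ct$pair_id, ct$role, ct$timepoint_months, ct$sample_id), ]
  rownames(ct) <- NULL
  ct
}

#' Write a cohort table to delimited text
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Flatten a GEO series-matrix export into the beta-matrix schema
#'
#' Adapter for series-matrix text files as distributed by NCBI GEO for
#' bead-array methylation series: metadata lines starting with `!`, then a
#' probe-by-sample value table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` with an `ID_REF` column. Series matrices carry
#' beta values only, so `detection_p` is absent in the result; gene symbols
#' can be supplied from a platform annotation.
#'
#' @param path Path to a series-matrix text file (uncompressed).
#' @param gene_map Optional data.frame with columns `probe_id`,
#'   `gene_symbol` used to annotate probes; unannotated probes get "".
#' @return A [beta_matrix()] with `detection_p = NULL`.
#' @export
read_geo_series_matrix <- function(path, gene_map = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("parse error: series-matrix table delimiters not found", call. = FALSE)
  }
  tbl <- utils::read.table(text = lines[(begin + 1L):(end - 1L)],
                           header = TRUE, sep = "\t", quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "null"))
  if (names(tbl)[1] != "ID_REF") {
    stop("parse error: series-matrix table lacks ID_REF column", call. = FALSE)
  }
  probe_ids <- as.character(tbl$ID_REF)
  beta <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(beta) <- probe_ids
  genes <- rep("", length(probe_ids))
  if (!is.null(gene_map)) {
    idx <- match(probe_ids, gene_map$probe_id)
    genes[!is.na(idx)] <- gene_map$gene_symbol[idx[!is.na(idx)]]
  }
  bm <- beta_matrix(beta, gene_symbols = genes, detection_p = NULL)
  ord <- order(bm$probe_ids)
  beta_matrix(bm$beta[ord, , drop = FALSE], bm$gene_symbols[ord])
}

#' Convert between percent (pyrosequencing) and beta-fraction (array) scales
#'
#' The single sanctioned bridge between the two native unit conventions:
#' pyrosequencing percent in [0, 100] and array beta in [0, 1].
#'
#' @param x Numeric vector.
#' @param to Target scale, "beta" (divide by 100) or "percent" (multiply).
#' @return Converted numeric vector.
#' @export
convert_meth_units <- function(x, to = c("beta", "percent")) {
  to <- match.arg(to)
  if (to == "beta") x / 100 else x * 100
}
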