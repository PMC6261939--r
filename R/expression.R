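#' Filter genes by detection p-value
#'
#' Keeps the genes detected (p-value strictly below `alpha`) in at least one
#' sample, mirroring the usual bead-array preprocessing step. Gene order is
#' preserved.
#'
#' @param m An [expr_matrix()] carrying `detection_p`.
#' @param alpha Detection threshold (strict inequality).
#'
#' @return The filtered `expr_mat`.
#' @export
filter_detected <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "expr_mat"))
  if (is.null(m$detection_p)) {
    stop("`m` has no detection p-values; nothing to filter on", call. = FALSE)
  }
  keep <- apply(m$detection_p < alpha, 1, any)
  subset_genes(m, keep)
}

#' Collapse probes to genes by signal-to-noise ratio
#'
#' For genes measured by several probes, keeps the probe with the highest
#' signal-to-noise ratio, defined as mean / SD of its expression across all
#' samples; a probe with zero SD has infinite SNR. Ties are broken by input
#' order. Rows are renamed from probe to gene identifiers.
#'
#' @param m An [expr_matrix()] whose rows are probes and which carries a
#'   `probe_map`.
#'
#' @return An `expr_mat` with one row per gene.
#' @export
collapse_probes <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (is.null(m$probe_map)) {
    stop("`m` has no probe_map; cannot collapse probes", call. = FALSE)
  }
  map <- m$probe_map[m$probe_map$probe_id %in% rownames(m$values), ]
  snr <- apply(m$values[map$probe_id, , drop = FALSE], 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) Inf else mean(v) / s
  })
  chosen <- map |>
    dplyr::mutate(snr = snr, .ord = dplyr::row_number()) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$snr, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$.ord, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  out <- subset_genes(m, match(chosen$probe_id, rownames(m$values)))
  rownames(out$values) <- chosen$gene_id
  if (!is.null(out$detection_p)) rownames(out$detection_p) <- chosen$gene_id
  out$probe_map <- NULL
  out
}

#' Intra-cell-line log2 fold-change normalization
#'
#' Removes cell-line-specific expression programs by expressing every
#' treated-PDS and PDR sample as the log2 ratio to the matched untreated PDS
#' sample of the same cell line: `FC(g, s) = log2 x(g, s) - log2 x(g, PDS(s))`.
#' Linear-scale input is log2-transformed first. Untreated PDS columns are
#' excluded from the result (their fold change is identically zero).
#'
#' @param m An [expr_matrix()] whose metadata contains exactly one `PDS`
#'   sample per cell line.
#'
#' @return An object of class `fc_mat`: list with `values` (gene x sample
#'   log2 FC matrix), `sample_meta` (non-PDS samples) and `reference_map`
#'   (tibble `sample_id`, `reference_id`).
#' @export
normalize_fc <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  lv <- log2_values(m)
  meta <- m$sample_meta
  pds <- meta[meta$condition == "PDS", ]
  if (anyDuplicated(pds$cell_line)) {
    stop("more than one untreated PDS sample per cell line", call. = FALSE)
  }
  query <- meta[meta$condition != "PDS", ]
  ref_idx <- match(query$cell_line, pds$cell_line)
  if (anyNA(ref_idx)) {
    orphans <- query$sample_id[is.na(ref_idx)]
    stop("no matched untreated PDS sample for: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  fc <- lv[, query$sample_id, drop = FALSE] -
    lv[, pds$sample_id[ref_idx], drop = FALSE]
  colnames(fc) <- query$sample_id
  structure(
    list(values = fc, sample_meta = query,
         reference_map = tibble::tibble(sample_id = query$sample_id,
                                        reference_id = pds$sample_id[ref_idx])),
    class = "fc_mat")
}

#' @export
print.fc_mat <- function(x, ...) {
  cat(sprintf("<fc_mat> %d genes x %d samples (log2 fold change vs matched PDS)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

fc_condition_cols <- function(fc, conditions) {
  meta <- fc$sample_meta
  if (identical(conditions, "PDR")) {
    meta$sample_id[is_pdr_condition(meta$condition)]
  } else {
    meta$sample_id[meta$condition %in% conditions]
  }
}

#' Select the most variable genes with a minimum resistant-state effect
#'
#' Within `gene_subset` (e.g. a cell-cycle pathway list), takes the top
#' `variability_quantile` fraction by SD of fold change across all
#' treated-PDS and PDR columns (`ceiling(q * n)` genes), then keeps those
#' whose absolute mean fold change across PDR columns exceeds
#' `min_abs_avg_fc`. The two filters intersect; results are ordered by
#' descending SD.
#'
#' @param fc An `fc_mat` from [normalize_fc()].
#' @param gene_subset Genes to consider (must be present in `fc`).
#' @param variability_quantile Fraction retained by the SD cut (0.25 keeps
#'   the 25% most variable genes).
#' @param min_abs_avg_fc Minimum |mean PDR fold change| (log2 units, strict).
#'
#' @return Character vector of selected genes, descending SD order.
#' @export
select_top_variable <- function(fc, gene_subset, variability_quantile = 0.25,
                                min_abs_avg_fc = 0.2) {
  stopifnot(inherits(fc, "fc_mat"))
  if (length(gene_subset) == 0) {
    stop("`gene_subset` is empty", call. = FALSE)
  }
  gene_subset <- intersect(gene_subset, rownames(fc$values))
  if (length(gene_subset) == 0) {
    stop("no genes of `gene_subset` present in `fc`", call. = FALSE)
  }
  cols <- union(fc_condition_cols(fc, "PDS_treated"),
                fc_condition_cols(fc, "PDR"))
  sds <- apply(fc$values[gene_subset, cols, drop = FALSE], 1, stats::sd)
  k <- ceiling(variability_quantile * length(gene_subset))
  top <- names(sort(sds, decreasing = TRUE))[seq_len(k)]
  pdr_cols <- fc_condition_cols(fc, "PDR")
  avg_pdr <- rowMeans(fc$values[gene_subset, pdr_cols, drop = FALSE])
  keep <- top[abs(avg_pdr[top]) > min_abs_avg_fc]
  keep[order(sds[keep], decreasing = TRUE)]
}

#' Average fold change across the samples of one condition
#'
#' @param fc An `fc_mat`.
#' @param condition `"PDS_treated"`, `"PDR"` (pools `PDR_early`/`PDR_late`),
#'   or an exact condition label.
#'
#' @return Tibble `gene_id`, `avg_fc` (genes with any missing value are
#'   dropped, with a message).
#' @export
average_fc <- function(fc, condition) {
  stopifnot(inherits(fc, "fc_mat"))
  cols <- fc_condition_cols(fc, condition)
  if (length(cols) == 0) {
    stop("no samples with condition ", condition, call. = FALSE)
  }
  v <- fc$values[, cols, drop = FALSE]
  avg <- rowMeans(v)
  bad <- is.na(avg)
  if (any(bad)) {
    message("dropping ", sum(bad), " gene(s) with missing fold changes")
  }
  tibble::tibble(gene_id = rownames(v)[!bad], avg_fc = unname(avg[!bad]))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of expression (or fold-change) profiles with
#' distance `1 - Pearson correlation` between sample columns and average
#' linkage — the standard recipe for microarray sample dendrograms.
#'
#' @param m An [expr_matrix()] or `fc_mat`.
#'
#' @return An [stats::hclust] object; leaves are sample ids.
#' @export
cluster_samples <- function(m) {
  stopifnot(inherits(m, c("expr_mat", "fc_mat")))
  v <- if (inherits(m, "expr_mat")) log2_values(m) else m$values
  d <- stats::as.dist(1 - stats::cor(v, method = "pearson"))
  stats::hclust(d, method = "average")
}
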