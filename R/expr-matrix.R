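#' Gene-by-sample expression container
#'
#' Light container for a normalized expression matrix together with its
#' sample metadata, optional per-probe detection p-values and an optional
#' probe-to-gene map. Values may be stored on the `log2` or `linear` scale;
#' every downstream operation consults the `scale` flag rather than guessing.
#'
#' @param values Numeric matrix, genes (or probes) in rows, samples in
#'   columns. Row and column names are required and become `gene_ids` /
#'   `sample_ids`.
#' @param sample_meta Data frame with one row per sample: columns
#'   `sample_id`, `cell_line`, `condition`. Conditions follow the panel
#'   vocabulary: `PDS` (parental, palbociclib-sensitive), `PDS_treated`,
#'   and `PDR_early` / `PDR_late` (resistant derivatives).
#' @param scale Either `"log2"` or `"linear"`.
#' @param detection_p Optional matrix of detection p-values, same dimensions
#'   and dimnames as `values`.
#' @param probe_map Optional data frame `probe_id`, `gene_id` mapping matrix
#'   rows (probes) to genes; required by [collapse_probes()].
#'
#' @return An object of class `expr_mat`.
#' @export
expr_matrix <- function(values, sample_meta, scale = c("log2", "linear"),
                        detection_p = NULL, probe_map = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row names (genes) and column names (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample_ids in `values`", call. = FALSE)
  }
  sample_meta <- tibble::as_tibble(sample_meta)
  req <- c("sample_id", "cell_line", "condition")
  if (!all(req %in% names(sample_meta))) {
    stop("`sample_meta` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(sample_meta$sample_id, colnames(values))) {
    stop("`sample_meta$sample_id` must match the matrix columns", call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values))) {
      stop("`detection_p` must have the same shape as `values`", call. = FALSE)
    }
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
      stop("detection p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(probe_map)) {
    probe_map <- tibble::as_tibble(probe_map)
    if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
      stop("`probe_map` needs columns probe_id, gene_id", call. = FALSE)
    }
  }
  if (scale == "linear" && any(values <= 0)) {
    stop("linear-scale expression must be strictly positive (cannot log2)",
         call. = FALSE)
  }
  structure(
    list(values = values, sample_meta = sample_meta, scale = scale,
         detection_p = detection_p, probe_map = probe_map),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("conditions:",
      paste(sprintf("%s=%d", names(table(x$sample_meta$condition)),
                    table(x$sample_meta$condition)), collapse = ", "), "\n")
  if (!is.null(x$detection_p)) cat("detection p-values: present\n")
  if (!is.null(x$probe_map)) cat("probe map: present\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

# values on the log2 scale regardless of storage scale
log2_values <- function(m) {
  if (m$scale == "log2") m$values else log2(m$values)
}

# subset genes (rows), keeping metadata congruent
subset_genes <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$detection_p)) {
    m$detection_p <- m$detection_p[keep, , drop = FALSE]
  }
  if (!is.null(m$probe_map)) {
    m$probe_map <- m$probe_map[m$probe_map$probe_id %in% rownames(m$values), ]
  }
  m
}

is_pdr_condition <- function(condition) startsWith(condition, "PDR")
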