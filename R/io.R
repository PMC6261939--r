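#' Read and write the package's plain-text formats
#'
#' Expression matrices travel as a pair of TSVs: the matrix (genes in rows,
#' a `gene_id` first column, one column per sample) and a sample-metadata
#' sidecar (`sample_id`, `cell_line`, `condition`). Detection p-values use
#' the same matrix layout. Gene sets use GMT (set name, description, then
#' tab-separated gene ids). Dose-response series use a CSV with columns
#' `sample`, `dose_nM` (0 encodes the vehicle control), `signal`, `is_T0`.
#' Cohorts are ordinary TSVs read with [readr::read_tsv()].
#'
#' @param m An [expr_matrix()].
#' @param path,meta_path,detection_path File paths; `detection_path` is
#'   optional.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an `expr_mat`.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression_tsv <- function(m, path, meta_path,
                                 detection_path = NULL) {
  stopifnot(inherits(m, "expr_mat"))
  df <- tibble::as_tibble(m$values, rownames = "gene_id")
  readr::write_tsv(df, path)
  readr::write_tsv(m$sample_meta, meta_path)
  if (!is.null(detection_path) && !is.null(m$detection_p)) {
    readr::write_tsv(tibble::as_tibble(m$detection_p, rownames = "gene_id"),
                     detection_path)
  }
  invisible(path)
}

#' @rdname expression_io
#' @param scale Scale flag of the stored values.
#' @export
read_expression_tsv <- function(path, meta_path, detection_path = NULL,
                                scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$gene_id
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  det <- NULL
  if (!is.null(detection_path)) {
    dd <- readr::read_tsv(detection_path, show_col_types = FALSE)
    det <- as.matrix(dd[, -1])
    rownames(det) <- dd$gene_id
    det <- det[rownames(values), colnames(values), drop = FALSE]
  }
  expr_matrix(values, meta, scale = scale, detection_p = det)
}

#' Read or write gene sets in GMT format
#'
#' @param sets Named list of character vectors (gene ids); names are the
#'   set names.
#' @param path File path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to `"na"`).
#'
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` a named
#'   list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Read or write dose-response series as CSV
#'
#' One row per observation; the vehicle control is encoded as `dose_nM = 0`
#' with `is_T0 = FALSE`, and the time-zero anchor as `is_T0 = TRUE`.
#'
#' @param series A `dose_response` tibble with anchor attributes.
#' @param path File path.
#' @param sample Sample label written into the file.
#'
#' @return `write_dose_response_csv()` returns `path` invisibly;
#'   `read_dose_response_csv()` a named list of `dose_response` tibbles
#'   (one per sample) with anchor attributes restored.
#' @export
write_dose_response_csv <- function(series, path, sample = "S1") {
  t0 <- attr(series, "t0_signal")
  veh <- attr(series, "vehicle_signal")
  if (is.null(t0) || is.null(veh)) {
    stop("series lacks T0/vehicle anchor attributes", call. = FALSE)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(sample = sample, dose_nM = 0, signal = t0, is_T0 = TRUE),
    tibble::tibble(sample = sample, dose_nM = 0, signal = veh, is_T0 = FALSE),
    tibble::tibble(sample = sample, dose_nM = series$dose_nM,
                   signal = series$signal, is_T0 = FALSE))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lapply(split(df, df$sample), function(sub) {
    t0 <- sub$signal[sub$is_T0][1]
    veh <- sub$signal[!sub$is_T0 & sub$dose_nM == 0][1]
    obs <- sub[!sub$is_T0 & sub$dose_nM > 0, ]
    out <- tibble::tibble(dose_nM = obs$dose_nM, signal = obs$signal)
    attr(out, "t0_signal") <- t0
    attr(out, "vehicle_signal") <- veh
    class(out) <- c("dose_response", class(out))
    out
  })
}
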