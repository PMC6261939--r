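#' RBsig loss-of-Rb-function signature score
#'
#' Scores each sample against a signature gene list by reference-anchored
#' median/MAD standardization. For each signature gene `i` present in the
#' matrix, the median and median absolute deviation of its expression over
#' the reference samples (the untreated PDS cell lines) are estimated; the
#' score of sample `j` is the mean over usable genes of
#' `(g_ij - median_i) / mad_i`. Genes whose reference MAD is zero are
#' excluded (division undefined) and reported.
#'
#' By default the MAD is the raw median absolute deviation, with no
#' 1.4826 normal-consistency constant; set `mad_constant = 1.4826` to use
#' the conventional scaled MAD as a sensitivity check. Scores are computed
#' on the matrix's stored scale.
#'
#' @param m An [expr_matrix()].
#' @param reference_samples Sample ids of the reference (untreated PDS)
#'   profiles; at least two.
#' @param signature Character vector of signature genes; its overlap with
#'   the matrix genes must be non-empty.
#' @param mad_constant Consistency constant passed to the MAD (default 1,
#'   the literal median of absolute deviations).
#'
#' @return An object of class `rbsig_result`: list with `scores` (tibble
#'   `sample_id`, `score`), `n_genes_used`, and `genes_excluded` (tibble
#'   `gene_id`, `reason`).
#' @export
rbsig_score <- function(m, reference_samples, signature, mad_constant = 1) {
  stopifnot(inherits(m, "expr_mat"))
  if (!all(reference_samples %in% colnames(m$values))) {
    stop("`reference_samples` not all present in the matrix", call. = FALSE)
  }
  if (length(reference_samples) < 2) {
    stop("need at least two reference samples", call. = FALSE)
  }
  genes <- intersect(signature, rownames(m$values))
  if (length(genes) == 0) {
    stop("signature has no overlap with the matrix genes", call. = FALSE)
  }
  ref <- m$values[genes, reference_samples, drop = FALSE]
  med <- apply(ref, 1, stats::median)
  mads <- apply(ref, 1, stats::mad, constant = mad_constant)
  usable <- mads > 0
  if (!any(usable)) {
    stop("all signature genes have zero reference MAD; score undefined",
         call. = FALSE)
  }
  excluded <- tibble::tibble(gene_id = genes[!usable],
                             reason = rep("zero reference MAD", sum(!usable)))
  if (nrow(excluded) > 0) {
    warning(nrow(excluded), " signature gene(s) excluded (zero reference MAD)",
            call. = FALSE)
  }
  z <- (m$values[genes[usable], , drop = FALSE] - med[usable]) / mads[usable]
  structure(
    list(scores = tibble::tibble(sample_id = colnames(m$values),
                                 score = unname(colMeans(z))),
         n_genes_used = sum(usable),
         genes_excluded = excluded),
    class = "rbsig_result")
}

#' @export
print.rbsig_result <- function(x, ...) {
  cat(sprintf("<rbsig_result> %d samples scored on %d genes (%d excluded)\n",
              nrow(x$scores), x$n_genes_used, nrow(x$genes_excluded)))
  print(x$scores, ...)
  invisible(x)
}

#' @rdname rbsig_score
#' @param x An `rbsig_result`.
#' @param ... Unused.
#' @method tidy rbsig_result
#' @export
tidy.rbsig_result <- function(x, ...) x$scores

#' Compare signature scores between two sample groups
#'
#' Two-sided Wilcoxon-Mann-Whitney test of the scores between the two
#' labelled groups, via [wmw_test()].
#'
#' @param scores An `rbsig_result` from [rbsig_score()].
#' @param groups Named character vector or tibble (`sample_id`, `group`)
#'   mapping samples to exactly two group labels; unmapped samples are
#'   ignored.
#'
#' @return A `test_result` tibble (see [wmw_test()]).
#' @export
compare_score_groups <- function(scores, groups) {
  stopifnot(inherits(scores, "rbsig_result"))
  if (is.data.frame(groups)) {
    map <- stats::setNames(groups$group, groups$sample_id)
  } else {
    map <- groups
  }
  s <- scores$scores
  s <- s[s$sample_id %in% names(map), ]
  lab <- map[s$sample_id]
  lv <- unique(lab)
  if (length(lv) != 2) {
    stop("`groups` must define exactly two groups (got ", length(lv), ")",
         call. = FALSE)
  }
  wmw_test(s$score[lab == lv[1]], s$score[lab == lv[2]])
}

#' Box plot of signature scores by condition
#'
#' @param object An `rbsig_result`.
#' @param sample_meta Tibble with `sample_id` and `condition` used to group
#'   the samples.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot rbsig_result
#' @export
autoplot.rbsig_result <- function(object, sample_meta, ...) {
  df <- dplyr::left_join(object$scores, sample_meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "RBsig score") +
    ggplot2::theme_minimal()
}
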