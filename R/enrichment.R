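#' Build a ranked gene list
#'
#' Orders genes by descending ranking metric (here typically the averaged
#' log2 fold change), breaking ties by input order, deterministically.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param metric Numeric ranking metric, finite, same length.
#'
#' @return A tibble of class `ranked_list` with columns `gene_id`, `metric`,
#'   sorted by descending metric.
#' @export
ranked_list <- function(gene_ids, metric) {
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (length(gene_ids) != length(metric)) {
    stop("`gene_ids` and `metric` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(metric))) stop("metric must be finite", call. = FALSE)
  ord <- order(-metric)  # stable: ties keep input order
  out <- tibble::tibble(gene_id = gene_ids[ord], metric = metric[ord])
  class(out) <- c("ranked_list", class(out))
  out
}

as_ranked_list <- function(x) {
  if (inherits(x, "ranked_list")) return(x)
  if (is.data.frame(x) && all(c("gene_id", "metric") %in% names(x))) {
    return(ranked_list(x$gene_id, x$metric))
  }
  if (is.data.frame(x) && all(c("gene_id", "avg_fc") %in% names(x))) {
    return(ranked_list(x$gene_id, x$avg_fc))
  }
  stop("cannot interpret `ranking`; supply ranked_list() or a tibble with ",
       "gene_id + metric/avg_fc", call. = FALSE)
}

# core weighted-KS running sum; returns list(es, running_sum)
ks_running_sum <- function(metric, hit, weight_exponent) {
  n <- length(metric)
  m <- sum(hit)
  w <- abs(metric)^weight_exponent
  wh <- w * hit
  tot <- sum(wh)
  p_hit <- if (tot > 0) cumsum(wh) / tot else cumsum(0 * wh)
  p_miss <- if (n > m) cumsum(!hit) / (n - m) else rep(0, n)
  dev <- p_hit - p_miss
  es <- dev[which.max(abs(dev))]
  list(es = es, running_sum = dev)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The pre-ranked GSEA statistic: walking down the ranked list, genes in the
#' set increment a running sum by their `|metric|^weight_exponent`
#' (normalized by the sum over set genes) and genes outside decrement it by
#' `1/(N - m)`. The enrichment score ES is the signed maximum deviation from
#' zero. `weight_exponent = 1` is the classic GSEA weighting; `0` gives the
#' unweighted KS statistic. A metric of exactly 0 contributes zero hit
#' weight under exponent 1.
#'
#' @param ranking A `ranked_list` (or a tibble with `gene_id` and `metric`
#'   or `avg_fc` columns, e.g. the output of [average_fc()]).
#' @param gene_set Character vector; overlap with the ranking must be
#'   non-empty.
#' @param weight_exponent Hit-weight exponent (default 1).
#'
#' @return An object of class `gsea_result`: list with `es`,
#'   `n_set_genes_present`, and `running_sum` (tibble `position`, `gene_id`,
#'   `hit`, `running_sum`).
#' @export
enrichment_score <- function(ranking, gene_set, weight_exponent = 1) {
  ranking <- as_ranked_list(ranking)
  hit <- ranking$gene_id %in% gene_set
  if (!any(hit)) {
    stop("gene set has no overlap with the ranking", call. = FALSE)
  }
  ks <- ks_running_sum(ranking$metric, hit, weight_exponent)
  structure(
    list(es = ks$es, n_set_genes_present = sum(hit),
         weight_exponent = weight_exponent,
         running_sum = tibble::tibble(position = seq_along(hit),
                                      gene_id = ranking$gene_id,
                                      hit = hit,
                                      running_sum = ks$running_sum)),
    class = "gsea_result")
}

#' Enrichment score with gene-permutation p-value and FDR
#'
#' Builds the null distribution of ES from `n_perm` random gene sets of the
#' same size drawn without replacement from the ranking's genes
#' (gene-set permutation, the pre-ranked convention — there are no sample
#' labels to permute on an averaged fold-change ranking). The permutation
#' p-value uses the add-one convention `(r + 1) / (n_perm + 1)` over
#' same-sign null scores with `|ES|` at least as extreme; NES divides ES by
#' the mean |null ES| of the same sign; FDR is the same-sign null-NES tail
#' fraction, truncated to `[0, 1]`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of random gene sets (>= 1).
#' @param seed Integer seed; same seed gives identical p-values and FDR.
#'
#' @return A `gsea_result` with additional elements `nes`, `p_perm`, `fdr`,
#'   `n_perm`.
#' @export
permutation_fdr <- function(ranking, gene_set, weight_exponent = 1,
                            n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  ranking <- as_ranked_list(ranking)
  obs <- enrichment_score(ranking, gene_set, weight_exponent)
  m <- obs$n_set_genes_present
  n <- nrow(ranking)
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i) {
    hit <- logical(n)
    hit[sample.int(n, m)] <- TRUE
    ks_running_sum(ranking$metric, hit, weight_exponent)$es
  }, numeric(1))

  same_sign <- sign(null_es) == sign(obs$es)
  r <- sum(same_sign & abs(null_es) >= abs(obs$es))
  obs$p_perm <- (r + 1) / (n_perm + 1)
  denom <- mean(abs(null_es[same_sign]))
  obs$nes <- if (isTRUE(denom > 0)) obs$es / denom else NA_real_
  if (is.na(obs$nes)) {
    obs$fdr <- obs$p_perm
  } else {
    null_nes <- null_es[same_sign] / denom
    obs$fdr <- min(1, (sum(abs(null_nes) >= abs(obs$nes)) + 1) /
                     (sum(same_sign) + 1))
  }
  obs$n_perm <- n_perm
  obs
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.4f (%d set genes, weight %g)\n",
              x$es, x$n_set_genes_present, x$weight_exponent))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  NES = %.3f, p_perm = %.4g, FDR = %.4g (%d permutations)\n",
                x$nes, x$p_perm, x$fdr, x$n_perm))
  }
  invisible(x)
}

#' @rdname enrichment_score
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) x$running_sum

#' @rdname enrichment_score
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(es = x$es,
                 nes = x$nes %||% NA_real_,
                 p_perm = x$p_perm %||% NA_real_,
                 fdr = x$fdr %||% NA_real_,
                 n_set_genes_present = x$n_set_genes_present)
}

#' Running-sum (mountain) plot of an enrichment result
#'
#' @param object A `gsea_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  rs <- object$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in ordered gene list", y = "running enrichment score") +
    ggplot2::theme_minimal()
}
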