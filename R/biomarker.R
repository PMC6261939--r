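#' Per-sample CCNE1/RB1 expression ratio
#'
#' The ratio is always taken on the linear expression scale; log2 input is
#' exponentiated first (a cutoff of 1 then corresponds to equal expression
#' on either scale).
#'
#' @param x Either an [expr_matrix()] containing genes `CCNE1` and `RB1`,
#'   or a tibble with `CCNE1` and `RB1` columns.
#' @param scale For tibble input, the scale of the two columns (`"linear"`
#'   or `"log2"`); `expr_mat` input carries its own flag.
#'
#' @return A tibble (`marker table`): sample identifier column plus
#'   `CCNE1`, `RB1` (linear scale) and `ratio = CCNE1 / RB1`.
#' @export
ccne1_rb1_ratio <- function(x, scale = c("linear", "log2")) {
  if (inherits(x, "expr_mat")) {
    need <- c("CCNE1", "RB1")
    if (!all(need %in% rownames(x$values))) {
      stop("matrix must contain CCNE1 and RB1", call. = FALSE)
    }
    v <- if (x$scale == "log2") 2^x$values[need, , drop = FALSE] else
      x$values[need, , drop = FALSE]
    out <- tibble::tibble(sample_id = colnames(v),
                          CCNE1 = v["CCNE1", ], RB1 = v["RB1", ])
  } else {
    out <- tibble::as_tibble(x)
    if (!all(c("CCNE1", "RB1") %in% names(out))) {
      stop("need CCNE1 and RB1 columns", call. = FALSE)
    }
    if (match.arg(scale) == "log2") {
      out$CCNE1 <- 2^out$CCNE1
      out$RB1 <- 2^out$RB1
    }
  }
  if (any(out$RB1 == 0)) {
    stop("RB1 = 0 on the linear scale: ratio undefined", call. = FALSE)
  }
  dplyr::mutate(out, ratio = .data$CCNE1 / .data$RB1)
}

#' Correlate biomarkers with drug sensitivity across cell lines
#'
#' For each marker and each compound, the Pearson correlation of marker
#' value versus IC50 across the shared cell lines, with BH-FDR across the
#' compound axis per marker and, per compound, the rank of |r| among
#' compounds for each marker (rank 1 = strongest association).
#'
#' @param markers Tibble with a `cell_line` column plus one column per
#'   marker (e.g. `CCNE1`, `RB1`, `ratio`).
#' @param ic50_table Tibble with `cell_line` plus one column per compound;
#'   IC50 values are correlated as provided (log-transform upstream if your
#'   dataset's convention calls for it).
#' @param min_lines Minimum shared cell lines per compound; compounds with
#'   fewer are skipped with a message.
#'
#' @return A tibble: `marker`, `compound`, `n`, `r`, `p_value`, `fdr`,
#'   `abs_r_rank` (rank of |r| across compounds, within marker).
#' @export
correlation_screen <- function(markers, ic50_table, min_lines = 3) {
  markers <- tibble::as_tibble(markers)
  ic50_table <- tibble::as_tibble(ic50_table)
  stopifnot("cell_line" %in% names(markers),
            "cell_line" %in% names(ic50_table))
  marker_names <- setdiff(names(markers), "cell_line")
  compounds <- setdiff(names(ic50_table), "cell_line")
  shared <- dplyr::inner_join(markers, ic50_table, by = "cell_line")
  res <- tidyr::expand_grid(marker = marker_names, compound = compounds) |>
    purrr::pmap(function(marker, compound) {
      ok <- stats::complete.cases(shared[[marker]], shared[[compound]])
      if (sum(ok) < min_lines) {
        message("skipping ", compound, " x ", marker,
                ": only ", sum(ok), " shared cell lines")
        return(NULL)
      }
      ct <- pearson_cor_test(shared[[marker]][ok], shared[[compound]][ok])
      tibble::tibble(marker = marker, compound = compound, n = sum(ok),
                     r = ct$statistic, p_value = ct$p_value)
    }) |>
    dplyr::bind_rows()
  res |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value),
                  abs_r_rank = rank(-abs(.data$r), ties.method = "first")) |>
    dplyr::ungroup()
}

#' Discriminate resistant from sensitive patients per timepoint
#'
#' For each biopsy timepoint and each of the markers CCNE1/RB1 ratio, CCNE1
#' and RB1: the two-sided WMW p-value between resistant and sensitive
#' patients and the ROC AUC for predicting resistance. All markers are
#' oriented "higher score = predicted resistant"; since RB1 loss marks
#' resistance, RB1 is negated before the AUC (`orientation` column records
#' this).
#'
#' @param cohort Tibble with `timepoint`, `resistant` (0/1), `CCNE1`, `RB1`
#'   (linear scale), e.g. from [generate_neoadjuvant_cohort()].
#'
#' @return A tibble: `timepoint`, `marker`, `n_resistant`, `n_sensitive`,
#'   `auc`, `p_wmw`, `orientation`.
#' @export
discriminate_patients <- function(cohort) {
  cohort <- ccne1_rb1_ratio(cohort)
  stopifnot(all(c("timepoint", "resistant") %in% names(cohort)))
  markers <- c(ratio = 1, CCNE1 = 1, RB1 = -1)  # sign orients toward resistance
  tidyr::expand_grid(timepoint = unique(cohort$timepoint),
                     marker = names(markers)) |>
    purrr::pmap(function(timepoint, marker) {
      sub <- cohort[cohort$timepoint == timepoint, ]
      score <- sub[[marker]] * markers[[marker]]
      res <- sub$resistant == 1
      tibble::tibble(
        timepoint = timepoint, marker = marker,
        n_resistant = sum(res), n_sensitive = sum(!res),
        auc = roc_auc(score, res),
        p_wmw = wmw_test(sub[[marker]][res], sub[[marker]][!res])$p_value,
        orientation = if (markers[[marker]] < 0) "inverted" else "direct")
    }) |>
    dplyr::bind_rows()
}

#' Survival stratification by the CCNE1/RB1 ratio
#'
#' Splits patients into high (ratio >= cutoff) and low groups and computes,
#' overall and within ER strata when an `er_status` column is present: both
#' Kaplan-Meier curves, the log-rank test, and the hazard ratio of the
#' low-ratio group relative to the high-ratio group (`hr_low_vs_high` < 1
#' means a high ratio is adverse, the clinical reporting direction).
#'
#' @param cohort Tibble with `time`, `event`, `CCNE1`, `RB1` (linear scale)
#'   and optionally `er_status` (`"ER+"` / `"ERneg"`).
#' @param cutoff_mode `"fixed_1"` (ratio dichotomized at 1, i.e. equal
#'   CCNE1 and RB1 expression) or `"median"` (cohort median ratio).
#'
#' @return A tibble with one row per subset (`overall`, `ER+`, `ERneg`):
#'   `cutoff`, `n_high`, `n_low`, `logrank_chisq`, `logrank_p`,
#'   `hr_low_vs_high`, `hr_ci_lower`, `hr_ci_upper`, and a `km` list-column
#'   of per-group curves.
#' @export
stratify_survival <- function(cohort, cutoff_mode = c("fixed_1", "median")) {
  cutoff_mode <- match.arg(cutoff_mode)
  cohort <- ccne1_rb1_ratio(cohort)
  cohort <- check_survival_cohort(cohort)
  cutoff <- if (cutoff_mode == "fixed_1") 1 else stats::median(cohort$ratio)
  cohort$group <- ifelse(cohort$ratio >= cutoff, "high", "low")

  subsets <- list(overall = cohort)
  if ("er_status" %in% names(cohort)) {
    for (s in unique(cohort$er_status)) {
      subsets[[s]] <- cohort[cohort$er_status == s, ]
    }
  }
  purrr::imap(subsets, function(sub, name) {
    if (length(unique(sub$group)) < 2) {
      stop("cutoff ", signif(cutoff, 4), " leaves a single group in subset '",
           name, "'", call. = FALSE)
    }
    lr <- logrank_test(sub)
    hr <- hazard_ratio(sub, reference_group = "high")
    tibble::tibble(subset = name, cutoff = cutoff,
                   n_high = sum(sub$group == "high"),
                   n_low = sum(sub$group == "low"),
                   logrank_chisq = lr$statistic, logrank_p = lr$p_value,
                   hr_low_vs_high = hr$hr, hr_ci_lower = hr$ci_lower,
                   hr_ci_upper = hr$ci_upper,
                   km = list(purrr::map_dfr(c("high", "low"), function(g) {
                     dplyr::mutate(km_estimate(sub, group = g), group = g)
                   })))
  }) |>
    dplyr::bind_rows()
}
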