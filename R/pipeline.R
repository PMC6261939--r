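#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Every stochastic stage has an
#' explicit seed derived from `seed`; unknown keys are rejected.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Stages to run, in dependency order; any subset of
#'   `"simulate"`, `"expression"`, `"rbsig"`, `"gsea"`, `"ic50"`, `"cnv"`,
#'   `"biomarker"`, `"survival"`. `"simulate"` is always implied.
#' @param detection_alpha Detection p-value threshold.
#' @param variability_quantile,min_abs_avg_fc Variable-gene selection
#'   parameters.
#' @param weight_exponent,n_perm Enrichment parameters.
#' @param cutoff_mode Ratio cutoff for survival stratification.
#' @param panel A [panel_config()]; its seed is overridden.
#' @param cohort A [cohort_config()]; its seed is overridden.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "expression", "rbsig",
                                       "gsea", "ic50", "cnv", "biomarker",
                                       "survival"),
                            detection_alpha = 0.05,
                            variability_quantile = 0.25,
                            min_abs_avg_fc = 0.2,
                            weight_exponent = 1, n_perm = 1000,
                            cutoff_mode = "fixed_1",
                            panel = panel_config(),
                            cohort = cohort_config()) {
  known <- c("simulate", "expression", "rbsig", "gsea", "ic50", "cnv",
             "biomarker", "survival")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), stages = union("simulate", stages),
                 detection_alpha = detection_alpha,
                 variability_quantile = variability_quantile,
                 min_abs_avg_fc = min_abs_avg_fc,
                 weight_exponent = weight_exponent, n_perm = n_perm,
                 cutoff_mode = cutoff_mode, panel = panel, cohort = cohort),
            class = c("pipeline_config", "list"))
}

fmt_tsv <- function(df, path) {
  # 10 significant digits: deterministic output without bit-level brittleness
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  readr::write_tsv(df, path)
}

#' Run the full analysis pipeline on synthetic fixtures
#'
#' Executes the requested stages in dependency order — simulate the inputs,
#' preprocess expression and compute fold changes, score the RBsig
#' signature, run the E2F-target enrichment, fit dose-response curves and
#' IC50s, call ddPCR copy numbers, and evaluate the CCNE1/RB1 biomarker
#' (discrimination and survival stratification) — writing each stage's
#' outputs under `outdir` plus a JSON run manifest (seeds, parameter echo,
#' per-stage record counts). Two runs with the same configuration produce
#' byte-identical result files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#'
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("panel", "cohort"))],
                   stages = list())
  record <- function(stage, counts, files) {
    manifest$stages[[stage]] <<- list(records = counts, files = files)
  }

  # -- simulate ---------------------------------------------------------
  pcfg <- config$panel; pcfg$seed <- config$seed
  panel <- generate_panel(pcfg)
  ccfg <- config$cohort
  ccfg$seed <- config$seed + 1L
  surv_cohort <- generate_survival_cohort(ccfg, er_positive_fraction = 0.75)
  ccfg$seed <- config$seed + 2L
  neo_cohort <- generate_neoadjuvant_cohort(ccfg)
  f_expr <- file.path(outdir, "expression.tsv")
  write_expression_tsv(panel$expr, f_expr,
                       file.path(outdir, "sample_meta.tsv"),
                       file.path(outdir, "detection_p.tsv"))
  write_gmt(list(E2F_TARGETS = panel$truth$e2f_set),
            file.path(outdir, "gene_sets.gmt"))
  fmt_tsv(surv_cohort, file.path(outdir, "survival_cohort.tsv"))
  fmt_tsv(neo_cohort, file.path(outdir, "neoadjuvant_cohort.tsv"))
  record("simulate",
         c(genes = nrow(panel$expr$values),
           samples = ncol(panel$expr$values),
           survival_patients = nrow(surv_cohort),
           neoadjuvant_rows = nrow(neo_cohort)),
         c("expression.tsv", "sample_meta.tsv", "detection_p.tsv",
           "gene_sets.gmt", "survival_cohort.tsv", "neoadjuvant_cohort.tsv"))

  fc <- NULL
  if (any(c("expression", "rbsig", "gsea") %in% stages)) {
    detected <- filter_detected(panel$expr, config$detection_alpha)
    fc <- normalize_fc(detected)
  }
  if ("expression" %in% stages) {
    avg_pdr <- average_fc(fc, "PDR")
    fmt_tsv(avg_pdr, file.path(outdir, "avg_fc_pdr.tsv"))
    top <- select_top_variable(fc, panel$truth$e2f_set,
                               config$variability_quantile,
                               config$min_abs_avg_fc)
    writeLines(top, file.path(outdir, "top_variable_genes.txt"))
    record("expression",
           c(detected_genes = nrow(fc$values), top_variable = length(top)),
           c("avg_fc_pdr.tsv", "top_variable_genes.txt"))
  }

  if ("rbsig" %in% stages) {
    meta <- panel$expr$sample_meta
    # proxy signature: the simulated E2F-target genes (Rb loss de-represses
    # E2F output); a real RBsig list can be supplied via rbsig_score()
    sig <- panel$truth$e2f_targets
    sc <- rbsig_score(panel$expr,
                      reference_samples =
                        meta$sample_id[meta$condition == "PDS"],
                      signature = sig)
    fmt_tsv(sc$scores, file.path(outdir, "rbsig_scores.tsv"))
    record("rbsig", c(samples_scored = nrow(sc$scores)), "rbsig_scores.tsv")
  }

  if ("gsea" %in% stages) {
    res <- lapply(c(PDS_treated = "PDS_treated", PDR = "PDR"),
                  function(cond) {
      permutation_fdr(average_fc(fc, cond), panel$truth$e2f_set,
                      weight_exponent = config$weight_exponent,
                      n_perm = config$n_perm, seed = config$seed + 3L)
    })
    gl <- dplyr::bind_rows(lapply(res, glance), .id = "condition")
    fmt_tsv(gl, file.path(outdir, "enrichment.tsv"))
    fmt_tsv(dplyr::bind_rows(lapply(res, tidy), .id = "condition"),
            file.path(outdir, "enrichment_running_sum.tsv"))
    record("gsea", c(gene_sets_tested = nrow(gl)),
           c("enrichment.tsv", "enrichment_running_sum.tsv"))
  }

  if ("ic50" %in% stages) {
    fits <- lapply(c(PDS = 50, PDR = 800), function(ic, nm) {
      ser <- generate_dose_response(ic50_true = ic, seed = config$seed + 4L)
      fit_4pl(ser$dose_nM, to_proportions(ser)$yp, seed = config$seed)
    })
    summ <- dplyr::bind_rows(lapply(fits, glance), .id = "sample")
    fmt_tsv(summ, file.path(outdir, "ic50_fits.tsv"))
    record("ic50", c(curves_fit = nrow(summ)), "ic50_fits.tsv")
  }

  if ("cnv" %in% stages) {
    assays <- list(
      list(sample = "PDR", copies = 42, seed = config$seed + 5L),
      list(sample = "PDS", copies = 2, seed = config$seed + 6L))
    calls <- lapply(assays, function(a) {
      # high-copy samples are run dilute so the target assay stays off
      # droplet saturation
      cn_ratio(generate_ddpcr(a$copies, 2, mean_ref_copies_per_droplet = 0.05,
                              seed = a$seed, sample_id = a$sample))
    })
    l2 <- pdr_vs_pds_log2(calls[[1]], calls[[2]])
    cn <- tibble::tibble(sample = c("PDR", "PDS"),
                         ratio = c(calls[[1]]$ratio, calls[[2]]$ratio),
                         log2_pdr_vs_pds = c(l2, NA),
                         copy_difference = c(copy_difference(l2), NA))
    fmt_tsv(cn, file.path(outdir, "cnv_calls.tsv"))
    record("cnv", c(samples_called = nrow(cn)), "cnv_calls.tsv")
  }

  if ("biomarker" %in% stages) {
    disc <- discriminate_patients(neo_cohort)
    fmt_tsv(disc, file.path(outdir, "discrimination.tsv"))
    record("biomarker", c(marker_timepoint_rows = nrow(disc)),
           "discrimination.tsv")
  }

  if ("survival" %in% stages) {
    strat <- stratify_survival(surv_cohort, config$cutoff_mode)
    fmt_tsv(dplyr::select(strat, -"km"),
            file.path(outdir, "survival_stratification.tsv"))
    km <- tidyr::unnest(dplyr::select(strat, "subset", "km"), "km")
    fmt_tsv(km, file.path(outdir, "km_curves.tsv"))
    record("survival", c(subsets = nrow(strat)),
           c("survival_stratification.tsv", "km_curves.tsv"))
  }

  manifest$n_stages_run <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
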