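test_that("CCNE1/RB1 ratio handles both scales", {
  tb <- tibble::tibble(CCNE1 = c(4, 2), RB1 = c(4, 1))
  expect_equal(ccne1_rb1_ratio(tb)$ratio, c(1, 2))
  # log2 values (3, 1): ratio 2^(3-1) = 4
  lg <- tibble::tibble(CCNE1 = 3, RB1 = 1)
  expect_equal(ccne1_rb1_ratio(lg, scale = "log2")$ratio, 4)
  expect_error(ccne1_rb1_ratio(tibble::tibble(CCNE1 = 1, RB1 = 0)),
               "undefined")
  # from an expression matrix, respecting its scale flag
  p <- generate_panel(panel_config(seed = 3), output_scale = "log2")
  mt <- ccne1_rb1_ratio(p$expr)
  expect_equal(mt$ratio,
               2^(p$expr$values["CCNE1", ] - p$expr$values["RB1", ]),
               ignore_attr = TRUE)
  # generator truth: resistant samples shift the ratio up
  meta <- p$expr$sample_meta
  pdr <- mt$ratio[meta$condition == "PDR_early"]
  pds <- mt$ratio[meta$condition == "PDS"]
  expect_gt(median(pdr), median(pds))
})

test_that("ratio invariance: common rescaling of both genes cancels", {
  tb <- tibble::tibble(CCNE1 = c(3, 8, 1), RB1 = c(2, 4, 5))
  expect_equal(ccne1_rb1_ratio(dplyr::mutate(tb, CCNE1 = CCNE1 * 7,
                                             RB1 = RB1 * 7))$ratio,
               ccne1_rb1_ratio(tb)$ratio)
})

test_that("correlation screen ranks the driving compound first", {
  set.seed(11)
  n <- 100
  marker <- rnorm(n)
  ic50 <- tibble::tibble(cell_line = paste0("L", 1:n),
                         drugA = 2 * marker + rnorm(n, sd = 0.5))
  for (j in 1:50) ic50[[paste0("null", j)]] <- rnorm(n)
  markers <- tibble::tibble(cell_line = paste0("L", 1:n), m1 = marker)
  res <- correlation_screen(markers, ic50)
  expect_equal(res$abs_r_rank[res$compound == "drugA"], 1)
  expect_true(all(res$fdr >= res$p_value - 1e-15))
  # null compounds: significant fraction at FDR 0.05 near zero
  expect_lt(mean(res$fdr[res$compound != "drugA"] < 0.05), 0.1)
})

test_that("single marker/compound screen reduces to the Pearson test", {
  set.seed(12)
  markers <- tibble::tibble(cell_line = paste0("L", 1:8), m = rnorm(8))
  ic50 <- tibble::tibble(cell_line = paste0("L", 1:8), d = rnorm(8))
  scr <- correlation_screen(markers, ic50)
  ct <- pearson_cor_test(markers$m, ic50$d)
  expect_equal(scr$r, ct$statistic)
  expect_equal(scr$p_value, ct$p_value)
  expect_equal(scr$fdr, ct$p_value)
})

test_that("compounds with insufficient shared lines are skipped", {
  markers <- tibble::tibble(cell_line = paste0("L", 1:5), m = rnorm(5))
  ic50 <- tibble::tibble(cell_line = paste0("L", 1:5),
                         d1 = c(1, 2, 3, 4, 5),
                         d2 = c(1, NA, NA, NA, 2))
  expect_message(res <- correlation_screen(markers, ic50), "skipping")
  expect_identical(unique(res$compound), "d1")
})

test_that("ratio outperforms single markers under a joint resistance signal", {
  aucs <- purrr::map_dfr(1:30, function(i) {
    neo <- generate_neoadjuvant_cohort(
      cohort_config(n_patients = 120, seed = 3000 + i), timepoints = "C0D1")
    discriminate_patients(neo)
  })
  med <- tapply(aucs$auc, aucs$marker, median)
  expect_gte(med[["ratio"]], med[["CCNE1"]])
  expect_gte(med[["ratio"]], med[["RB1"]])
})

test_that("discrimination AUC delegates to roc_auc with the stated orientation", {
  neo <- generate_neoadjuvant_cohort(cohort_config(seed = 9),
                                     timepoints = "C1D1")
  d <- discriminate_patients(neo)
  mt <- ccne1_rb1_ratio(neo)
  expect_equal(d$auc[d$marker == "ratio"],
               roc_auc(mt$ratio, neo$resistant))
  expect_equal(d$auc[d$marker == "RB1"],
               roc_auc(-neo$RB1, neo$resistant))
  expect_equal(d$orientation[d$marker == "RB1"], "inverted")
  # AUC on log2(ratio) equals AUC on the ratio (monotone invariance)
  expect_equal(roc_auc(log2(mt$ratio), neo$resistant),
               d$auc[d$marker == "ratio"])
})

test_that("survival stratification reports the adverse high-ratio effect", {
  ch <- generate_survival_cohort(
    cohort_config(n_patients = 1000, true_group_hr = 0.63, seed = 14),
    er_positive_fraction = 0.75)
  st <- stratify_survival(ch, cutoff_mode = "fixed_1")
  expect_setequal(st$subset, c("overall", "ER+", "ERneg"))
  erp <- st[st$subset == "ER+", ]
  ern <- st[st$subset == "ERneg", ]
  expect_lt(erp$logrank_p, 0.05)        # effect present in ER+
  expect_lt(erp$hr_low_vs_high, 1)      # low ratio protective
  expect_gt(ern$logrank_p, erp$logrank_p)
  km <- erp$km[[1]]
  expect_true(all(c("high", "low") %in% km$group))
  expect_true(all(diff(km$survival[km$group == "high"]) <= 1e-12))
})

test_that("stratification cutoffs behave and degenerate splits error", {
  ch <- generate_survival_cohort(cohort_config(n_patients = 200, seed = 15))
  one_side <- dplyr::mutate(ch, CCNE1 = RB1 * 3)  # all ratios = 3 >= 1
  expect_error(stratify_survival(one_side, "fixed_1"), "single group")
  # fixed_1 and median agree when the cohort median ratio is 1
  mt <- ccne1_rb1_ratio(ch)
  ch2 <- dplyr::mutate(ch, CCNE1 = CCNE1 / median(mt$ratio))
  s1 <- stratify_survival(ch2, "fixed_1")
  s2 <- stratify_survival(ch2, "median")
  expect_equal(s1$n_high, s2$n_high)
  expect_equal(s1$logrank_p, s2$logrank_p)
})
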