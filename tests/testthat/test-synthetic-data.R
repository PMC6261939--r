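test_that("panel generation is deterministic under a fixed seed", {
  a <- generate_panel(panel_config(seed = 42))
  b <- generate_panel(panel_config(seed = 42))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$expr$detection_p, b$expr$detection_p)
  expect_identical(a$truth, b$truth)
})

test_that("zero-noise zero-treatment panel differs from PDS only in CCNE1/RB1", {
  cfg <- panel_config(n_cell_lines = 2, n_genes = 20, e2f_set_size = 5,
                      noise_sd = 0, delta_treat = 0,
                      restoration_fraction = 0.7, undetected_fraction = 0,
                      seed = 3)
  p <- generate_panel(cfg, output_scale = "log2")
  v <- p$expr$values
  meta <- p$expr$sample_meta
  for (cl in unique(meta$cell_line)) {
    pds <- v[, meta$sample_id[meta$cell_line == cl & meta$condition == "PDS"]]
    trt <- v[, meta$sample_id[meta$cell_line == cl &
                                meta$condition == "PDS_treated"]]
    pdr <- v[, meta$sample_id[meta$cell_line == cl &
                                startsWith(meta$condition, "PDR")]]
    expect_equal(trt, pds)
    other <- setdiff(rownames(v), c("CCNE1", "RB1"))
    expect_equal(pdr[other], pds[other])
    expect_equal(pdr["CCNE1"], pds["CCNE1"] + cfg$delta_ccne1_up)
    expect_equal(pdr["RB1"], pds["RB1"] - cfg$delta_rb1_down)
  }
})

test_that("treated E2F-target mean fold change recovers -delta_treat", {
  cfg <- panel_config(seed = 11)
  p <- generate_panel(cfg, output_scale = "log2")
  fc <- normalize_fc(p$expr)
  trt <- fc$sample_meta$sample_id[fc$sample_meta$condition == "PDS_treated"]
  fcs <- fc$values[p$truth$e2f_targets, trt]
  # FC = treated - PDS carries two independent noise draws
  se <- sqrt(2) * cfg$noise_sd / sqrt(length(fcs))
  expect_lt(abs(mean(fcs) - (-cfg$delta_treat)), 3 * se)
})

test_that("expression values are finite and detection p-values lie in [0,1]", {
  p <- generate_panel(panel_config(n_genes = 200, e2f_set_size = 40, seed = 5))
  expect_true(all(is.finite(p$expr$values)))
  expect_true(all(p$expr$detection_p >= 0 & p$expr$detection_p <= 1))
})

test_that("panel config invariants are enforced", {
  expect_error(panel_config(e2f_set_size = 999, n_genes = 1000), "e2f_set_size")
  expect_error(panel_config(restoration_fraction = 1.5), "restoration_fraction")
  expect_error(panel_config(n_cell_lines = 0), "n_cell_lines")
})

test_that("noise-free dose-response series lies on the generating curve", {
  s <- generate_dose_response(b = 0, t = 1, ic50_true = 50, slope = 1,
                              noise_sd = 0, seed = 1)
  yp <- to_proportions(s)$yp
  tr <- attr(s, "truth")
  expect_equal(yp, fourpl_curve(s$dose_nM, tr$b, tr$t, tr$log10_xmid,
                                tr$slope), tolerance = 1e-12)
  # b = 0, t = 1: the curve crosses yp = 0.5 exactly at the true IC50
  expect_equal(fourpl_curve(50, 0, 1, tr$log10_xmid, tr$slope), 0.5,
               tolerance = 1e-12)
  expect_error(generate_dose_response(doses = c(-1, 10)), "positive")
  expect_identical(generate_dose_response(seed = 9)$signal,
                   generate_dose_response(seed = 9)$signal)
})

test_that("ddPCR generator follows Poisson occupancy", {
  z <- generate_ddpcr(copies_target = 0, copies_reference = 2, seed = 1)
  expect_true(all(z$n_positive[z$assay == "target"] == 0))
  # lambda = ln 2: half the droplets positive in expectation
  s <- generate_ddpcr(2, 2, n_droplets = 20000,
                      mean_ref_copies_per_droplet = log(2),
                      n_wells = 20, seed = 2)
  expect_equal(mean(s$n_positive), 10000, tolerance = 0.01)
  # equal copies: estimated ratio ~ 1 within Poisson error
  r <- cn_ratio(generate_ddpcr(2, 2, n_wells = 8, seed = 3))
  expect_equal(r$ratio, 1, tolerance = 0.05)
})

test_that("survival cohort honors censoring rate and group hazards", {
  none <- generate_survival_cohort(cohort_config(censoring_rate = 0, seed = 4))
  expect_true(all(none$event == 1))
  half <- generate_survival_cohort(
    cohort_config(n_patients = 4000, censoring_rate = 0.5, seed = 4))
  expect_equal(mean(half$event == 0), 0.5, tolerance = 0.05)
  # large-n HR recovery near the generating value
  ch <- generate_survival_cohort(
    cohort_config(n_patients = 4000, true_group_hr = 0.63, seed = 8))
  ch$group <- ifelse(attr(ch, "truth")$high_ratio, "high", "low")
  hr <- hazard_ratio(ch, reference_group = "high")
  expect_gt(hr$ci_lower, 0.5)
  expect_lt(hr$ci_upper, 0.8)
  expect_equal(hr$hr, 0.63, tolerance = 0.1)
})

test_that("neoadjuvant shift controls marker discrimination", {
  flat <- generate_neoadjuvant_cohort(
    cohort_config(n_patients = 500, ratio_shift_resistant = 0, seed = 6),
    timepoints = "C0D1")
  d0 <- discriminate_patients(flat)
  expect_true(all(abs(d0$auc - 0.5) < 0.08))
  big <- generate_neoadjuvant_cohort(
    cohort_config(n_patients = 100, ratio_shift_resistant = 50, seed = 6),
    timepoints = "C0D1")
  d1 <- discriminate_patients(big)
  expect_equal(d1$auc[d1$marker == "ratio"], 1)
})
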