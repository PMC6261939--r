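test_that("detection filter keeps genes detected in at least one sample", {
  v <- matrix(1:12, nrow = 4)
  all_det <- make_expr(v, detection_p = matrix(0, 4, 3))
  expect_equal(nrow(filter_detected(all_det)$values), 4)

  dp <- matrix(0.01, 4, 3)
  dp[2, ] <- 0.05  # exactly alpha everywhere: strict inequality removes it
  m <- make_expr(v, detection_p = dp)
  kept <- filter_detected(m, alpha = 0.05)
  expect_identical(rownames(kept$values), c("G1", "G3", "G4"))

  expect_error(filter_detected(make_expr(v)), "detection")
})

test_that("synthetic undetected fraction is removed exactly", {
  p <- generate_panel(panel_config(n_genes = 200, e2f_set_size = 40,
                                   undetected_fraction = 0.1, seed = 2))
  kept <- filter_detected(p$expr)
  expect_equal(nrow(kept$values), 180)
  expect_length(intersect(rownames(kept$values), p$truth$undetected_genes), 0)
})

test_that("probe collapse keeps the highest signal-to-noise probe", {
  v <- rbind(P1 = c(10, 10, 10), P2 = c(10, 1, 19),   # SD 0 => infinite SNR
             P3 = c(5, 5.5, 4.5), P4 = c(16, 20, 12), # SNR 10 vs 4
             P5 = c(7, 7, 8))                          # single-probe gene
  pm <- tibble::tibble(probe_id = paste0("P", 1:5),
                       gene_id = c("A", "A", "B", "B", "C"))
  m <- make_expr(v, probe_map = pm)
  out <- collapse_probes(m)
  expect_identical(rownames(out$values), c("A", "B", "C"))
  expect_equal(unname(out$values["A", ]), c(10, 10, 10))
  expect_equal(unname(out$values["B", ]), c(5, 5.5, 4.5))
  expect_equal(unname(out$values["C", ]), c(7, 7, 8))
  expect_error(collapse_probes(make_expr(v)), "probe_map")
})

test_that("probe collapse breaks SNR ties by input order", {
  v <- rbind(P1 = c(1, 2, 3), P2 = c(2, 4, 6))  # identical SNR (scaled copy)
  pm <- tibble::tibble(probe_id = c("P1", "P2"), gene_id = c("A", "A"))
  out <- collapse_probes(make_expr(v, probe_map = pm))
  expect_equal(unname(out$values["A", ]), c(1, 2, 3))
})

fc_fixture <- function(vals_log2) {
  make_expr(vals_log2,
            conditions = rep(c("PDS", "PDS_treated", "PDR_early"), 2),
            cell_lines = rep(c("CL1", "CL2"), each = 3))
}

test_that("fold-change normalization subtracts the matched PDS profile", {
  v <- matrix(rnorm(5 * 6), nrow = 5)
  m <- fc_fixture(v)
  fc <- normalize_fc(m)
  expect_equal(ncol(fc$values), 4)  # PDS columns excluded
  expect_equal(unname(fc$values[, "S2"]), unname(v[, 2] - v[, 1]))
  expect_equal(unname(fc$values[, "S6"]), unname(v[, 6] - v[, 4]))

  # identical PDR and PDS: all-zero column
  v2 <- v; v2[, 3] <- v2[, 1]
  expect_true(all(normalize_fc(fc_fixture(v2))$values[, "S3"] == 0))

  # doubled linear expression = FC of exactly 1
  lin <- fc_fixture(matrix(4, nrow = 1, ncol = 6))
  lin$values[1, 3] <- 8
  lin$scale <- "linear"
  expect_equal(unname(normalize_fc(lin)$values[1, "S3"]), 1)
})

test_that("orphan samples without a PDS reference are named in the error", {
  v <- matrix(rnorm(12), nrow = 2)
  m <- make_expr(v, conditions = c("PDS", "PDS_treated", "PDR_early",
                                   "PDS", "PDS_treated", "PDR_late"),
                 cell_lines = c(rep("CL1", 3), rep("CL2", 2), "CL3"))
  expect_error(normalize_fc(m), "S6")
})

test_that("adding a cell-line constant leaves fold changes unchanged", {
  v <- matrix(rnorm(5 * 6), nrow = 5)
  m1 <- fc_fixture(v)
  v2 <- v
  v2[, 1:3] <- v2[, 1:3] + 2.7  # shift every CL1 sample
  m2 <- fc_fixture(v2)
  expect_equal(normalize_fc(m1)$values, normalize_fc(m2)$values)
})

test_that("panel CCNE1 fold change in PDR recovers delta_ccne1_up", {
  cfg <- panel_config(seed = 13)
  p <- generate_panel(cfg)
  fc <- normalize_fc(p$expr)
  pdr <- fc$sample_meta$sample_id[startsWith(fc$sample_meta$condition, "PDR")]
  x <- fc$values["CCNE1", pdr]
  se <- sqrt(2) * cfg$noise_sd / sqrt(length(x))
  expect_lt(abs(mean(x) - cfg$delta_ccne1_up), 3 * se)
})

test_that("top-variable selection intersects SD cut with PDR effect filter", {
  # 16 genes; brute-force the expected answer on a constructed matrix
  set.seed(1)
  n_genes <- 16
  v <- matrix(rnorm(n_genes * 6, sd = 0.05), nrow = n_genes)
  rownames(v) <- paste0("G", 1:n_genes)
  colnames(v) <- paste0("S", 1:6)
  v[1:4, ] <- v[1:4, ] * 40                # high-SD genes
  v[c(1, 2, 9), c(3, 6)] <- 5              # strong PDR average FC
  meta <- fc_fixture(v)$sample_meta
  fcv <- v[, c(2, 3, 5, 6)]
  fc <- structure(list(values = fcv, sample_meta = meta[c(2, 3, 5, 6), ],
                       reference_map = NULL), class = "fc_mat")

  got <- select_top_variable(fc, rownames(v), 0.25, 0.2)
  # oracle: top ceiling(0.25*16)=4 by SD, then |mean PDR FC| > 0.2
  sds <- apply(fcv, 1, sd)
  top4 <- names(sort(sds, decreasing = TRUE))[1:4]
  pdr_cols <- c("S3", "S6")
  expected <- top4[abs(rowMeans(fcv[top4, pdr_cols])) > 0.2]
  expected <- expected[order(sds[expected], decreasing = TRUE)]
  expect_identical(got, expected)
  expect_gt(length(got), 0)

  # constant matrix: nothing passes the effect filter
  fc0 <- fc; fc0$values <- fcv * 0
  expect_length(select_top_variable(fc0, rownames(v), 0.25, 0.2), 0)

  # no-op thresholds return every gene with non-zero average PDR FC
  all_g <- select_top_variable(fc, rownames(v), 1, 0)
  expect_setequal(all_g, rownames(v)[rowMeans(fcv[, pdr_cols]) != 0])

  # invariant: column order does not matter
  fc_perm <- fc
  perm <- c(3, 1, 4, 2)
  fc_perm$values <- fc$values[, perm]
  fc_perm$sample_meta <- fc$sample_meta[perm, ]
  expect_identical(select_top_variable(fc_perm, rownames(v), 0.25, 0.2), got)

  expect_error(select_top_variable(fc, character(0)), "empty")
})

test_that("average fold change is the arithmetic mean per condition", {
  v <- matrix(0, nrow = 2, ncol = 6)
  v[1, c(2, 5)] <- c(1, -1)   # the two treated columns
  v[2, c(3, 6)] <- c(3, 5)    # the two PDR columns
  fc <- normalize_fc(fc_fixture(v))
  trt <- average_fc(fc, "PDS_treated")
  expect_equal(trt$avg_fc[trt$gene_id == "G1"], 0)
  pdr <- average_fc(fc, "PDR")
  expect_equal(pdr$avg_fc[pdr$gene_id == "G2"], 4)
  one <- average_fc(fc, "PDR_early")
  expect_equal(one$avg_fc, unname(fc$values[, "S3"] + fc$values[, "S6"]) / 2)
})

test_that("samples cluster by cell line when baselines dominate", {
  p <- generate_panel(panel_config(n_cell_lines = 4, n_genes = 300, e2f_set_size = 50,
                                   baseline_sd_between_lines = 3,
                                   noise_sd = 0.2, seed = 21))
  hc <- cluster_samples(p$expr)
  cl <- cutree(hc, k = 4)
  lines <- p$expr$sample_meta$cell_line[match(names(cl),
                                              p$expr$sample_meta$sample_id)]
  # clusters pure by cell line
  expect_equal(unname(apply(table(cl, lines) > 0, 1, sum)), rep(1, 4))

  # permuting sample order leaves the merge structure invariant
  perm <- sample(ncol(p$expr$values))
  m2 <- p$expr
  m2$values <- m2$values[, perm]
  m2$detection_p <- m2$detection_p[, perm]
  m2$sample_meta <- m2$sample_meta[perm, ]
  hc2 <- cluster_samples(m2)
  expect_equal(sort(hc$height), sort(hc2$height), tolerance = 1e-12)

  # identical samples merge at height zero
  v <- matrix(rnorm(20), ncol = 2)
  v <- cbind(v, v[, 2])
  hc3 <- cluster_samples(make_expr(v))
  expect_equal(min(hc3$height), 0, tolerance = 1e-12)
})
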