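# small in-code fixtures shared across test files

# minimal expression matrix: values gene x sample, one cell line per sample
# unless meta is supplied
make_expr <- function(values, conditions = NULL, cell_lines = NULL,
                      scale = "log2", detection_p = NULL, probe_map = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("S", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- paste0("G", seq_len(nrow(values)))
  meta <- tibble::tibble(
    sample_id = colnames(values),
    cell_line = cell_lines %||% rep("CL1", n),
    condition = conditions %||% rep("PDS", n))
  expr_matrix(values, meta, scale = scale, detection_p = detection_p,
              probe_map = probe_map)
}

# brute-force weighted-KS running sum, written as an explicit per-position
# loop; independent oracle for the vectorized implementation
oracle_run <- function(metric, hit, weight_exponent) {
  n <- length(metric)
  m <- sum(hit)
  nr <- sum(abs(metric[hit])^weight_exponent)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      acc <- acc + (if (nr > 0) abs(metric[i])^weight_exponent / nr else 0)
    } else {
      acc <- acc - 1 / (n - m)
    }
    run[i] <- acc
  }
  run
}

oracle_es <- function(metric, hit, weight_exponent) {
  run <- oracle_run(metric, hit, weight_exponent)
  run[which.max(abs(run))]
}

# hand risk-table log-rank oracle: loop over distinct event times summing
# observed - expected for group 1 with hypergeometric variance
oracle_logrank <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
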