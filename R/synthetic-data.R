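#' Configuration for the synthetic cell-line panel
#'
#' Defines the expression-panel generator. Defaults emulate the structure of
#' a hormone receptor-positive breast cancer cell-line panel with conditioned
#' palbociclib resistance: strong cell-line-specific baselines, E2F-target
#' down-regulation under treatment with partial restoration at resistance,
#' and CCNE1 up / RB1 down at resistance. All effect sizes are on the log2
#' scale.
#'
#' @param n_cell_lines Number of cell lines (the study panel had 7 models
#'   that acquired resistance).
#' @param n_genes Total genes, including the dedicated `CCNE1` and `RB1`.
#' @param e2f_set_size Number of simulated E2F-target genes suppressed by
#'   treatment (must leave room for CCNE1 and RB1).
#' @param baseline_sd_between_lines SD (log2 units) of per-gene baseline
#'   differences between cell lines; large values make samples cluster by
#'   cell line.
#' @param noise_sd SD (log2 units) of i.i.d. Gaussian measurement noise.
#' @param delta_treat Mean down-regulation (log2 units, positive) of
#'   E2F-target genes in treated samples.
#' @param restoration_fraction Fraction of `delta_treat` recovered in
#'   resistant (PDR) samples, in \[0, 1\].
#' @param delta_ccne1_up,delta_rb1_down CCNE1 up- and RB1 down-regulation
#'   (log2 units, positive numbers) applied in PDR samples only.
#' @param undetected_fraction Fraction of genes flagged undetected (detection
#'   p-value >= 0.05) in every sample.
#' @param seed Integer seed; same seed gives bit-identical output.
#'
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_cell_lines = 7, n_genes = 1000, e2f_set_size = 100,
                         baseline_sd_between_lines = 2, noise_sd = 0.25,
                         delta_treat = 1, restoration_fraction = 0.5,
                         delta_ccne1_up = 1.5, delta_rb1_down = 1,
                         undetected_fraction = 0.1, seed = 1L) {
  cfg <- list(n_cell_lines = n_cell_lines, n_genes = n_genes,
              e2f_set_size = e2f_set_size,
              baseline_sd_between_lines = baseline_sd_between_lines,
              noise_sd = noise_sd, delta_treat = delta_treat,
              restoration_fraction = restoration_fraction,
              delta_ccne1_up = delta_ccne1_up,
              delta_rb1_down = delta_rb1_down,
              undetected_fraction = undetected_fraction,
              seed = as.integer(seed))
  counts <- c("n_cell_lines", "n_genes", "e2f_set_size")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(sprintf("`%s` must be >= 1", f), call. = FALSE)
  }
  if (cfg$e2f_set_size > cfg$n_genes - 2) {
    stop("`e2f_set_size` must be <= n_genes - 2 (CCNE1 and RB1 are dedicated)",
         call. = FALSE)
  }
  if (cfg$restoration_fraction < 0 || cfg$restoration_fraction > 1) {
    stop("`restoration_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$undetected_fraction < 0 || cfg$undetected_fraction > 1) {
    stop("`undetected_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$baseline_sd_between_lines < 0) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  structure(cfg, class = c("panel_config", "list"))
}

#' Configuration for synthetic patient cohorts
#'
#' Shared by the survival-cohort and neoadjuvant-cohort generators.
#'
#' @param n_patients Cohort size.
#' @param true_group_hr Hazard ratio of the low-ratio (CCNE1/RB1 < 1) group
#'   relative to the high-ratio group; 0.63 reproduces the prognostic effect
#'   size seen in large ER+ breast cancer cohorts.
#' @param baseline_hazard Event hazard (1/time units) in the low-ratio group.
#' @param censoring_rate Target fraction of censored patients, achieved with
#'   independent uniform censoring on `[0, tau]` (tau solved numerically).
#' @param ratio_shift_resistant Mean shift (log2 units) of log2(CCNE1/RB1)
#'   in resistant patients; split half onto CCNE1 (up) and half onto RB1
#'   (down) so the ratio combines two weaker single-marker signals. The
#'   default 2.6 with unit marker SD gives a ratio AUC near 0.9, the
#'   discrimination reported for neoadjuvant palbociclib cohorts.
#' @param fraction_resistant Fraction of resistant patients.
#' @param marker_sd SD (log2 units) of patient-to-patient marker variation.
#' @param seed Integer seed.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 200, true_group_hr = 0.63,
                          baseline_hazard = 0.1, censoring_rate = 0.3,
                          ratio_shift_resistant = 2.6,
                          fraction_resistant = 0.3, marker_sd = 1,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, true_group_hr = true_group_hr,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              ratio_shift_resistant = ratio_shift_resistant,
              fraction_resistant = fraction_resistant,
              marker_sd = marker_sd, seed = as.integer(seed))
  if (cfg$n_patients < 1) stop("`n_patients` must be >= 1", call. = FALSE)
  if (cfg$baseline_hazard <= 0 || cfg$true_group_hr <= 0) {
    stop("hazards must be > 0", call. = FALSE)
  }
  for (f in c("censoring_rate", "fraction_resistant")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  structure(cfg, class = c("cohort_config", "list"))
}

#' Simulate a palbociclib-sensitive / treated / resistant cell-line panel
#'
#' Generates three samples per cell line (untreated PDS, treated PDS, PDR)
#' on the log2 scale: per-gene global means, cell-line-specific baseline
#' offsets (SD `baseline_sd_between_lines`), treatment suppression of the
#' E2F-target genes by `delta_treat` with `restoration_fraction` of it
#' recovered at resistance, CCNE1 up / RB1 down at resistance only, and
#' additive Gaussian noise. Detection p-values are emitted per gene, with a
#' configurable fraction of genes undetected in all samples.
#'
#' @param config A [panel_config()].
#' @param output_scale Scale of the returned matrix; the simulation itself is
#'   on the log2 scale, `"linear"` exponentiates before export.
#'
#' @return A list with elements
#'   * `expr`: an [expr_matrix()] with sample metadata and detection p-values;
#'   * `truth`: ground-truth list — `e2f_targets` (the suppressed genes),
#'     `e2f_set` (the exported gene set: suppressed genes plus CCNE1, since
#'     cyclin E1 is itself an E2F target), `undetected_genes`, and the
#'     generating effect sizes — so tests never re-infer parameters.
#' @export
generate_panel <- function(config = panel_config(),
                           output_scale = c("linear", "log2")) {
  stopifnot(inherits(config, "panel_config"))
  output_scale <- match.arg(output_scale)
  set.seed(config$seed)
  n_other <- config$n_genes - 2 - config$e2f_set_size
  genes <- c("CCNE1", "RB1",
             sprintf("E2FT%04d", seq_len(config$e2f_set_size)),
             if (n_other > 0) sprintf("GENE%04d", seq_len(n_other)))
  e2f_targets <- genes[startsWith(genes, "E2FT")]
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  conditions <- c("PDS", "PDS_treated", "PDR_early")

  meta <- tidyr::expand_grid(cell_line = lines, condition = conditions)
  meta$sample_id <- paste(meta$cell_line, meta$condition, sep = "_")
  meta <- meta[, c("sample_id", "cell_line", "condition")]

  gene_mean <- stats::rnorm(length(genes), mean = 8, sd = 1.5)
  # cell-line baseline offsets: gene x line
  baseline <- matrix(
    stats::rnorm(length(genes) * length(lines),
                 sd = config$baseline_sd_between_lines),
    nrow = length(genes), dimnames = list(genes, lines))

  vals <- matrix(0, nrow = length(genes), ncol = nrow(meta),
                 dimnames = list(genes, meta$sample_id))
  is_e2f <- genes %in% e2f_targets
  for (j in seq_len(nrow(meta))) {
    mu <- gene_mean + baseline[, meta$cell_line[j]]
    cond <- meta$condition[j]
    if (cond == "PDS_treated") {
      mu[is_e2f] <- mu[is_e2f] - config$delta_treat
    } else if (is_pdr_condition(cond)) {
      mu[is_e2f] <- mu[is_e2f] -
        config$delta_treat * (1 - config$restoration_fraction)
      mu[genes == "CCNE1"] <- mu[genes == "CCNE1"] + config$delta_ccne1_up
      mu[genes == "RB1"] <- mu[genes == "RB1"] - config$delta_rb1_down
    }
    vals[, j] <- mu + stats::rnorm(length(genes), sd = config$noise_sd)
  }

  n_undet <- round(config$undetected_fraction * length(genes))
  # never silence the biomarker genes or the E2F set
  eligible <- genes[!(genes %in% c("CCNE1", "RB1", e2f_targets))]
  n_undet <- min(n_undet, length(eligible))
  undetected <- sample(eligible, n_undet)
  det_p <- matrix(stats::runif(length(vals), 0, 0.049),
                  nrow = length(genes), dimnames = dimnames(vals))
  det_p[genes %in% undetected, ] <-
    stats::runif(length(undetected) * ncol(vals), 0.05, 1)

  values <- if (output_scale == "linear") 2^vals else vals
  expr <- expr_matrix(values, meta, scale = output_scale,
                      detection_p = det_p)
  truth <- list(e2f_targets = e2f_targets,
                e2f_set = c(e2f_targets, "CCNE1"),
                undetected_genes = undetected,
                delta_treat = config$delta_treat,
                restoration_fraction = config$restoration_fraction,
                delta_ccne1_up = config$delta_ccne1_up,
                delta_rb1_down = config$delta_rb1_down,
                noise_sd = config$noise_sd)
  list(expr = expr, truth = truth)
}

#' Simulate a dose-response viability series
#'
#' Raw signals follow the four-parameter logistic model on the adjusted
#' proportion (`yp`) scale, converted to raw absorbance via fixed time-zero
#' and vehicle anchors: `y = t0 + yp * (vehicle - t0)`. Noise is Gaussian on
#' the proportion scale. The default dose ladder mirrors doubling dilutions
#' of palbociclib from 64 uM down to about 1 nM.
#'
#' @param b,t Bottom and top asymptotes on the proportion scale.
#' @param ic50_true True concentration (nM) at which `yp` crosses 0.5; for
#'   `b = 0, t = 1` this is the curve midpoint.
#' @param slope Hill slope of the 4PL in the `10^(slope * (log10 x - xmid))`
#'   parameterization (positive = decreasing viability with dose).
#' @param doses Concentrations in nM, strictly positive.
#' @param noise_sd Noise SD on the proportion scale.
#' @param t0_signal,vehicle_signal Anchor signals (raw units).
#' @param seed Integer seed.
#'
#' @return A tibble of class `dose_response` with columns `dose_nM`,
#'   `signal`, plus attributes `t0_signal`, `vehicle_signal` and the
#'   generating truth.
#' @export
generate_dose_response <- function(b = 0, t = 1, ic50_true = 50, slope = 1,
                                   doses = 64000 / 2^(0:16),
                                   noise_sd = 0.05,
                                   t0_signal = 0.2, vehicle_signal = 1,
                                   seed = 1L) {
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  set.seed(as.integer(seed))
  # xmid such that yp crosses 0.5 at ic50_true
  if (0.5 <= min(b, t) || 0.5 >= max(b, t)) {
    stop("generating curve never crosses yp = 0.5; choose b < 0.5 < t",
         call. = FALSE)
  }
  xmid <- log10(ic50_true) - (1 / slope) * log10((t - b) / (0.5 - b) - 1)
  yp <- fourpl_curve(doses, b, t, xmid, slope) +
    stats::rnorm(length(doses), sd = noise_sd)
  out <- tibble::tibble(dose_nM = sort(doses),
                        signal = t0_signal +
                          yp[order(doses)] * (vehicle_signal - t0_signal))
  attr(out, "t0_signal") <- t0_signal
  attr(out, "vehicle_signal") <- vehicle_signal
  attr(out, "truth") <- list(b = b, t = t, ic50 = ic50_true, slope = slope,
                             log10_xmid = xmid)
  class(out) <- c("dose_response", class(out))
  out
}

#' Simulate droplet digital PCR wells
#'
#' Droplet occupancy is Poisson: a droplet is positive with probability
#' `1 - exp(-lambda)`, where `lambda` (template copies per droplet) scales
#' with the genomic copy number of the assayed locus relative to the
#' reference.
#'
#' @param copies_target,copies_reference Genomic copy numbers of the target
#'   and reference loci in the sample.
#' @param n_droplets Accepted droplets per well.
#' @param mean_ref_copies_per_droplet `lambda` of the reference assay; the
#'   target's lambda is scaled by `copies_target / copies_reference`.
#' @param n_wells Replicate wells per assay.
#' @param sample_id Sample label carried into the output.
#' @param seed Integer seed.
#'
#' @return A tibble (columns `sample`, `well`, `assay`, `n_positive`,
#'   `n_negative`) with a `truth` attribute holding the generating lambdas.
#' @export
generate_ddpcr <- function(copies_target, copies_reference,
                           n_droplets = 20000,
                           mean_ref_copies_per_droplet = 0.5,
                           n_wells = 2, sample_id = "S1", seed = 1L) {
  stopifnot(copies_target >= 0, copies_reference > 0, n_droplets >= 1)
  set.seed(as.integer(seed))
  lam <- c(target = mean_ref_copies_per_droplet *
             copies_target / copies_reference,
           reference = mean_ref_copies_per_droplet)
  rows <- tidyr::expand_grid(assay = c("target", "reference"),
                             well = seq_len(n_wells))
  rows$n_positive <- stats::rbinom(nrow(rows), n_droplets,
                                   1 - exp(-lam[rows$assay]))
  out <- tibble::tibble(sample = sample_id, well = rows$well,
                        assay = rows$assay, n_positive = rows$n_positive,
                        n_negative = n_droplets - rows$n_positive)
  attr(out, "truth") <- list(lambda_target = unname(lam["target"]),
                             lambda_reference = unname(lam["reference"]),
                             ratio = copies_target / copies_reference)
  out
}

# censoring horizon tau for uniform censoring on [0, tau] against a mixture
# of exponential event times; P(censored) = sum_g p_g (1 - exp(-l_g tau))/(l_g tau)
solve_censoring_tau <- function(rates, weights, target) {
  p_cens <- function(tau) {
    sum(weights * (1 - exp(-rates * tau)) / (rates * tau))
  }
  stats::uniroot(function(tau) p_cens(tau) - target,
                 lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a survival cohort stratified by the CCNE1/RB1 ratio
#'
#' Each patient receives log2 marker values whose ratio determines the risk
#' group: the high-ratio group (CCNE1/RB1 >= 1) has its hazard multiplied by
#' `1 / true_group_hr` relative to the low-ratio group, so the low-ratio
#' group's hazard ratio versus high is `true_group_hr` (< 1 means a high
#' ratio is adverse). Event times are exponential; censoring is independent
#' uniform on `[0, tau]` with `tau` solved numerically to achieve the
#' requested censoring rate.
#'
#' @param config A [cohort_config()].
#' @param er_positive_fraction If non-`NULL`, adds an `er_status` column
#'   (`"ER+"` / `"ERneg"`); the group hazard effect is applied in the ER+
#'   stratum only, ERneg patients follow the baseline hazard regardless of
#'   ratio (no prognostic effect there).
#'
#' @return A tibble: `patient_id`, `CCNE1`, `RB1` (linear scale), `time`,
#'   `event` (1 = event, 0 = censored), optional `er_status`; attribute
#'   `truth` records group membership and generating parameters.
#' @export
generate_survival_cohort <- function(config = cohort_config(),
                                     er_positive_fraction = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  log2_rb1 <- stats::rnorm(n, mean = 5, sd = config$marker_sd)
  log2_ratio <- stats::rnorm(n, mean = 0, sd = config$marker_sd)
  log2_ccne1 <- log2_rb1 + log2_ratio
  high <- log2_ratio >= 0

  er_status <- NULL
  effect_on <- rep(TRUE, n)
  if (!is.null(er_positive_fraction)) {
    er_status <- ifelse(stats::runif(n) < er_positive_fraction, "ER+", "ERneg")
    effect_on <- er_status == "ER+"
  }
  rate <- ifelse(high & effect_on,
                 config$baseline_hazard / config$true_group_hr,
                 config$baseline_hazard)
  time_event <- stats::rexp(n, rate = rate)
  if (config$censoring_rate > 0) {
    tau <- solve_censoring_tau(unique(rate),
                               as.numeric(table(factor(rate, unique(rate)))) / n,
                               config$censoring_rate)
    cens <- stats::runif(n, 0, tau)
    time <- pmin(time_event, cens)
    event <- as.integer(time_event <= cens)
  } else {
    time <- time_event
    event <- rep(1L, n)
  }
  out <- tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)),
                        CCNE1 = 2^log2_ccne1, RB1 = 2^log2_rb1,
                        time = time, event = event)
  if (!is.null(er_status)) out$er_status <- er_status
  attr(out, "truth") <- list(high_ratio = high,
                             true_group_hr = config$true_group_hr)
  out
}

#' Simulate a neoadjuvant cohort with per-timepoint marker measurements
#'
#' Emulates serial biopsies from a neoadjuvant CDK4/6-inhibitor trial:
#' resistant patients' log2(CCNE1/RB1) is shifted by
#' `ratio_shift_resistant`, realised as half the shift up on CCNE1 and half
#' down on RB1 at every timepoint, so the ratio pools two weaker
#' single-marker signals.
#'
#' @param config A [cohort_config()].
#' @param timepoints Character vector of biopsy timepoints.
#'
#' @return A tibble: `patient_id`, `timepoint`, `resistant` (0/1), `CCNE1`,
#'   `RB1` (linear scale).
#' @export
generate_neoadjuvant_cohort <- function(config = cohort_config(),
                                        timepoints = c("C0D1", "C1D1", "C1D15")) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  resistant <- as.integer(stats::runif(n) < config$fraction_resistant)
  out <- tidyr::expand_grid(patient_id = sprintf("P%04d", seq_len(n)),
                            timepoint = timepoints)
  out$resistant <- resistant[match(out$patient_id,
                                   sprintf("P%04d", seq_len(n)))]
  half <- config$ratio_shift_resistant / 2
  m <- nrow(out)
  log2_ccne1 <- stats::rnorm(m, 4, config$marker_sd) + half * out$resistant
  log2_rb1 <- stats::rnorm(m, 5, config$marker_sd) - half * out$resistant
  out$CCNE1 <- 2^log2_ccne1
  out$RB1 <- 2^log2_rb1
  tibble::as_tibble(out)
}
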