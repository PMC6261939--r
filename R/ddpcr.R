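#' Poisson occupancy concentration of a ddPCR well
#'
#' Droplet digital PCR partitions the template into ~20,000 droplets; under
#' Poisson occupancy the fraction of negative droplets estimates
#' `exp(-lambda)`, so the maximum-likelihood template concentration is
#' `lambda = -ln(n_negative / (n_positive + n_negative))` copies per
#' droplet. A fully saturated well (no negative droplets) carries no upper
#' information and is rejected.
#'
#' @param n_positive,n_negative Droplet counts (non-negative integers,
#'   `n_negative >= 1`).
#'
#' @return `lambda`, copies per droplet (0 when no droplet is positive).
#' @export
droplet_concentration <- function(n_positive, n_negative) {
  if (any(n_positive < 0) || any(n_negative < 0)) {
    stop("droplet counts must be non-negative", call. = FALSE)
  }
  if (any(n_negative == 0)) {
    stop("saturated well (no negative droplets): concentration unbounded",
         call. = FALSE)
  }
  -log(n_negative / (n_positive + n_negative))
}

#' Target-to-reference copy-number ratio of a sample
#'
#' Estimates per-well concentrations for the target (e.g. CCNE1 or RB1) and
#' reference (e.g. EIF2C1) assays, averages lambda across replicate wells
#' per assay, and reports the target/reference ratio; the droplet volume
#' cancels. A `pool` mode sums raw droplets across wells before estimating,
#' for sensitivity checks when wells differ in droplet totals.
#'
#' @param wells Tibble with columns `assay` (`"target"` / `"reference"`),
#'   `n_positive`, `n_negative`; one sample's wells.
#' @param merge `"average"` (default: mean lambda over wells) or `"pool"`.
#'
#' @return A tibble of class `cn_call`: `lambda_target`, `lambda_reference`
#'   (copies/droplet) and `ratio`.
#' @export
cn_ratio <- function(wells, merge = c("average", "pool")) {
  merge <- match.arg(merge)
  wells <- tibble::as_tibble(wells)
  if (!all(c("assay", "n_positive", "n_negative") %in% names(wells))) {
    stop("`wells` needs columns assay, n_positive, n_negative", call. = FALSE)
  }
  if (!any(wells$assay == "target") || !any(wells$assay == "reference")) {
    stop("need at least one target and one reference well", call. = FALSE)
  }
  lam_of <- function(sub) {
    if (merge == "average") {
      mean(droplet_concentration(sub$n_positive, sub$n_negative))
    } else {
      droplet_concentration(sum(sub$n_positive), sum(sub$n_negative))
    }
  }
  lt <- lam_of(wells[wells$assay == "target", ])
  lr <- lam_of(wells[wells$assay == "reference", ])
  if (lr == 0) {
    stop("zero reference concentration: ratio undefined", call. = FALSE)
  }
  out <- tibble::tibble(lambda_target = lt, lambda_reference = lr,
                        ratio = lt / lr)
  class(out) <- c("cn_call", class(out))
  out
}

#' Check a no-template negative control well
#'
#' Any positive droplets in a no-DNA control indicate contamination; a
#' warning (not an error) is raised, mirroring bench practice.
#'
#' @param n_positive,n_negative Droplet counts of the control well.
#'
#' @return `TRUE` (clean) or `FALSE` (contaminated), invisibly informative.
#' @export
check_negative_control <- function(n_positive, n_negative) {
  if (n_positive > 0) {
    warning("negative control has ", n_positive,
            " positive droplet(s): possible contamination", call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Resistant-versus-parental log2 copy-number ratio
#'
#' @param pdr,pds `cn_call` results (or their `ratio` values) for the
#'   resistant and matched parental sample.
#'
#' @return `log2(ratio_PDR / ratio_PDS)`.
#' @export
pdr_vs_pds_log2 <- function(pdr, pds) {
  r1 <- if (is.data.frame(pdr)) pdr$ratio else pdr
  r0 <- if (is.data.frame(pds)) pds$ratio else pds
  log2(r1 / r0)
}

#' Acquired DNA copies implied by a log2 copy-number ratio
#'
#' Converts a resistant-vs-parental log2 copy-number ratio into an absolute
#' copy difference under the stated assumption that the parental line
#' carries `pds_copies` (default 2, diploid) copies of the locus:
#' `pds_copies * 2^r - pds_copies`. The conversion is asymmetric in `r`
#' (gains and losses of equal |r| do not mirror).
#'
#' @param log2_ratio Resistant-vs-parental log2 ratio (from
#'   [pdr_vs_pds_log2()]).
#' @param pds_copies Copies assumed in the parental sample.
#'
#' @return DNA copies gained (negative = lost).
#' @export
copy_difference <- function(log2_ratio, pds_copies = 2) {
  pds_copies * 2^log2_ratio - pds_copies
}
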