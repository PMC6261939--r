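#' Kaplan-Meier product-limit survival curve
#'
#' @param cohort Tibble with columns `time` (> 0), `event` (1 = event, 0 =
#'   censored) and, when `group` is given, `group`.
#' @param group Optional group label: restrict the estimate to that group.
#'
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, S(0) = 1 implicitly); censored-only times
#'   reduce the risk set without a step.
#' @export
km_estimate <- function(cohort, group = NULL) {
  cohort <- check_survival_cohort(cohort)
  if (!is.null(group)) {
    cohort <- cohort[cohort$group == group, ]
    if (nrow(cohort) == 0) stop("no patients in group ", group, call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  out <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                        n_event = sf$n.event, survival = sf$surv)
  class(out) <- c("km_curve", class(out))
  out
}

check_survival_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (!all(c("time", "event") %in% names(cohort))) {
    stop("cohort needs `time` and `event` columns", call. = FALSE)
  }
  if (any(cohort$time <= 0)) {
    stop("times must be strictly positive (time = 0 has no risk set)",
         call. = FALSE)
  }
  if (!all(cohort$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  cohort
}

#' Two-group log-rank test
#'
#' Chi-square statistic on 1 degree of freedom from the summed
#' observed-minus-expected events over distinct event times, with the
#' hypergeometric variance.
#'
#' @param cohort Tibble with `time`, `event` and a binary `group` column.
#'
#' @return A one-row `test_result` tibble: `statistic` (chi-square),
#'   `p_value`, `method`, `n1`, `n2`.
#' @export
logrank_test <- function(cohort) {
  cohort <- check_survival_cohort(cohort)
  g <- unique(cohort$group)
  if (length(g) != 2) {
    stop("log-rank test needs exactly two groups (got ", length(g), ")",
         call. = FALSE)
  }
  if (sum(cohort$event) < 1) stop("no events in the cohort", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = cohort)
  tibble::tibble(statistic = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 method = "logrank",
                 n1 = sum(cohort$group == g[1]),
                 n2 = sum(cohort$group == g[2]))
}

#' Hazard ratio between two groups
#'
#' Proportional-hazards estimate for a single binary covariate
#' (partial likelihood, Breslow tie handling), with a Wald 95% confidence
#' interval from the observed information. The reported HR is the hazard of
#' the non-reference group relative to `reference_group`.
#'
#' @param cohort Tibble with `time`, `event`, binary `group`.
#' @param reference_group The group whose hazard is the denominator.
#'
#' @return A one-row tibble: `hr`, `ci_lower`, `ci_upper`, `log_hr`,
#'   `se_log_hr`, `p_value`, `diverged` (TRUE when a group has no events
#'   and the estimate is only a one-sided bound).
#' @export
hazard_ratio <- function(cohort, reference_group) {
  cohort <- check_survival_cohort(cohort)
  g <- unique(cohort$group)
  if (length(g) != 2) stop("need exactly two groups", call. = FALSE)
  if (!reference_group %in% g) {
    stop("`reference_group` not found in cohort", call. = FALSE)
  }
  other <- setdiff(g, reference_group)
  cohort$x <- as.integer(cohort$group == other)
  events_by_group <- tapply(cohort$event, cohort$x, sum)
  diverged <- any(events_by_group == 0)
  fit_call <- function() {
    survival::coxph(survival::Surv(time, event) ~ x, data = cohort,
                    ties = "breslow")
  }
  # when a group has no events the partial likelihood is monotone and the
  # optimizer's non-convergence warning is expected; `diverged` reports it
  fit <- if (diverged) suppressWarnings(fit_call()) else fit_call()
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  tibble::tibble(hr = exp(beta),
                 ci_lower = exp(beta - stats::qnorm(0.975) * se),
                 ci_upper = exp(beta + stats::qnorm(0.975) * se),
                 log_hr = beta, se_log_hr = se,
                 p_value = summary(fit)$coefficients[1, "Pr(>|z|)"],
                 diverged = diverged)
}

#' Kaplan-Meier plot for a two-group cohort
#'
#' @param object A cohort tibble with `time`, `event`, `group`.
#' @param ... Unused.
#'
#' @return A ggplot step-function plot of the per-group survival curves.
#' @export
plot_km <- function(object, ...) {
  cohort <- check_survival_cohort(object)
  curves <- dplyr::bind_rows(lapply(unique(cohort$group), function(g) {
    km <- km_estimate(cohort, group = g)
    dplyr::bind_rows(tibble::tibble(time = 0, n_risk = NA, n_event = NA,
                                    survival = 1), km) |>
      dplyr::mutate(group = g)
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}
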