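#' Four-parameter logistic curve
#'
#' `f(x) = B + (T - B) / (1 + 10^(s * (log10 x - log10_xmid)))`, the
#' parameterization used for dose-response viability curves throughout the
#' package. With `s > 0` viability decreases with dose; `f(xmid) = (B+T)/2`.
#'
#' @param dose Concentrations (strictly positive, nM).
#' @param b,t Bottom and top asymptotes (proportion scale).
#' @param log10_xmid Curve midpoint on the log10-dose scale.
#' @param slope Hill slope `s`.
#'
#' @return Predicted adjusted survival proportions.
#' @export
fourpl_curve <- function(dose, b, t, log10_xmid, slope) {
  b + (t - b) / (1 + 10^(slope * (log10(dose) - log10_xmid)))
}

#' Convert raw viability signals to adjusted survival proportions
#'
#' `yp = (y - T0) / (vehicle - T0)`, anchoring each observation between the
#' time-zero signal (yp = 0, no net growth) and the untreated vehicle
#' control (yp = 1, full growth). Values outside `[0, 1]` (cytotoxicity or
#' super-growth) are retained.
#'
#' @param series A `dose_response` tibble (from [generate_dose_response()]
#'   or [read_dose_response_csv()]) or any tibble with `dose_nM` and
#'   `signal` columns.
#' @param t0_signal,vehicle_signal Anchor signals; taken from the series
#'   attributes when omitted.
#'
#' @return The series with a `yp` column added.
#' @export
to_proportions <- function(series, t0_signal = NULL, vehicle_signal = NULL) {
  t0 <- t0_signal %||% attr(series, "t0_signal")
  veh <- vehicle_signal %||% attr(series, "vehicle_signal")
  if (is.null(t0) || is.null(veh)) {
    stop("T0 and vehicle anchor signals required", call. = FALSE)
  }
  if (veh == t0) {
    stop("degenerate anchors: vehicle signal equals T0 (no growth occurred)",
         call. = FALSE)
  }
  dplyr::mutate(series, yp = (.data$signal - t0) / (veh - t0))
}

fourpl_start <- function(doses, yp) {
  b0 <- min(yp); t0 <- max(yp)
  mid_target <- (b0 + t0) / 2
  xmid0 <- log10(doses[which.min(abs(yp - mid_target))])
  # slope sign from the overall dose trend (decreasing yp => s > 0)
  trend <- if (stats::sd(yp) == 0) 0 else stats::cor(log10(doses), yp)
  s0 <- if (trend <= 0) 1 else -1
  c(b = b0, t = t0, log10_xmid = xmid0, slope = s0)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of [fourpl_curve()] to adjusted proportions by
#' Levenberg-Marquardt, with data-driven starting values and up to five
#' seeded, jittered restarts on failure. `weighting = "residual"` performs a
#' two-stage fit: an unweighted fit, then weights
#' `w_i = 1 / max(r_i^2, 1e-6)` from the stage-one residuals and a single
#' refit. Reported are a weighted standard error
#' `sqrt(sum(w r^2) / (n - 4))` and a weighted goodness-of-fit
#' `1 - wRSS / wTSS`.
#'
#' @param doses Concentrations (nM, strictly positive); vehicle (dose 0) is
#'   not part of the fit — it only anchors the proportion transform.
#' @param yp Adjusted survival proportions from [to_proportions()].
#' @param weighting `"none"` or `"residual"`.
#' @param seed Seed for the jittered restarts.
#'
#' @return An object of class `fourpl_fit`: list with `b`, `t`,
#'   `log10_xmid`, `slope`, `weighted_se`, `goodness`, `converged`,
#'   `n`, `doses`, `yp`, `message`.
#' @export
fit_4pl <- function(doses, yp, weighting = c("none", "residual"), seed = 1L) {
  weighting <- match.arg(weighting)
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (length(unique(doses)) < 5) {
    stop("need at least 5 distinct doses to fit 4 parameters", call. = FALSE)
  }
  df <- data.frame(dose = doses, yp = yp)
  start <- fourpl_start(doses, yp)

  fit_once <- function(start, weights) {
    args <- list(
      yp ~ fourpl_curve(dose, b, t, log10_xmid, slope),
      data = df, start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(weights)) args$weights <- weights
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  }

  run_with_restarts <- function(weights) {
    set.seed(as.integer(seed))
    fit <- fit_once(start, weights)
    tries <- 0
    while (inherits(fit, "error") && tries < 5) {
      tries <- tries + 1
      jit <- start + stats::rnorm(4, sd = c(0.1, 0.1, 0.5, 0.5))
      fit <- fit_once(jit, weights)
    }
    fit
  }

  w <- rep(1, nrow(df))
  fit <- run_with_restarts(NULL)
  if (weighting == "residual" && !inherits(fit, "error")) {
    r1 <- stats::residuals(fit)
    w <- 1 / pmax(r1^2, 1e-6)
    refit <- run_with_restarts(w)
    if (!inherits(refit, "error")) fit <- refit else w <- rep(1, nrow(df))
  }

  if (inherits(fit, "error")) {
    return(structure(list(b = NA_real_, t = NA_real_, log10_xmid = NA_real_,
                          slope = NA_real_, weighted_se = NA_real_,
                          goodness = NA_real_, converged = FALSE,
                          n = nrow(df), doses = doses, yp = yp,
                          message = conditionMessage(fit)),
                     class = "fourpl_fit"))
  }
  cf <- stats::coef(fit)
  # orient so t is the top asymptote: the model is symmetric under
  # (b, t, slope) -> (t, b, -slope)
  if (cf["t"] < cf["b"]) {
    cf[c("b", "t")] <- cf[c("t", "b")]
    cf["slope"] <- -cf["slope"]
  }
  r <- stats::residuals(fit)
  wrss <- sum(w * r^2)
  wtss <- sum(w * (yp - stats::weighted.mean(yp, w))^2)
  structure(list(b = unname(cf["b"]), t = unname(cf["t"]),
                 log10_xmid = unname(cf["log10_xmid"]),
                 slope = unname(cf["slope"]),
                 weighted_se = sqrt(wrss / (nrow(df) - 4)),
                 goodness = if (wtss > 0) 1 - wrss / wtss else NA_real_,
                 converged = TRUE, n = nrow(df), doses = doses, yp = yp,
                 message = "converged"),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<fourpl_fit> B = %.4f, T = %.4f, log10 xmid = %.4f, slope = %.4f\n",
    x$b, x$t, x$log10_xmid, x$slope))
  ic <- ic50(x)
  cat(sprintf("  IC50 = %s nM (%s); weighted SE = %.4g, goodness = %.4f\n",
              formatC(ic$ic50, digits = 4), ic$censor_flag,
              x$weighted_se, x$goodness))
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(term = c("b", "t", "log10_xmid", "slope"),
                 estimate = c(x$b, x$t, x$log10_xmid, x$slope))
}

#' @rdname fit_4pl
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  ic <- if (x$converged) ic50(x) else
    list(ic50 = NA_real_, censor_flag = "not_converged")
  tibble::tibble(ic50_nM = ic$ic50, censor_flag = ic$censor_flag,
                 weighted_se = x$weighted_se, goodness = x$goodness,
                 converged = x$converged, n = x$n)
}

#' Invert a fitted 4PL curve at a survival level
#'
#' Closed-form inversion
#' `x = 10^(log10_xmid + (1/s) * log10((T - B)/(level - B) - 1))`. The IC50
#' is the dose where the adjusted survival proportion crosses `level = 0.5`
#' — note this is not the curve's inflection point unless `B = 0, T = 1`.
#' When `level` lies outside the open interval `(B, T)` the crossing does
#' not exist and a censored bound relative to the tested dose range is
#' returned instead.
#'
#' @param fit A converged `fourpl_fit`.
#' @param level Survival level to invert at (default 0.5).
#'
#' @return List with `ic50` (nM; a range bound when censored) and
#'   `censor_flag` in `"none"`, `"above_range"`, `"below_range"`,
#'   `"undefined"`.
#' @export
ic50 <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  b <- fit$b; t <- fit$t; s <- fit$slope
  if (level == b || level == t) {
    return(list(ic50 = NA_real_, censor_flag = "undefined"))
  }
  if (level <= min(b, t) || level >= max(b, t)) {
    # curve never reaches the level within its asymptotes; for a decreasing
    # curve a level below B is never reached even at the highest dose
    if ((s > 0 && level < b) || (s < 0 && level > t)) {
      return(list(ic50 = max(fit$doses), censor_flag = "above_range"))
    }
    return(list(ic50 = min(fit$doses), censor_flag = "below_range"))
  }
  x <- 10^(fit$log10_xmid + (1 / s) * log10((t - b) / (level - b) - 1))
  list(ic50 = x, censor_flag = "none")
}

#' IC50 fold change between resistant and sensitive fits
#'
#' Ratio of the PDR IC50 to the PDS IC50. If either input is censored the
#' ratio is only a bound and the flags are propagated.
#'
#' @param pdr_fit,pds_fit Converged `fourpl_fit` objects for the resistant
#'   and parental lines.
#' @param level Survival level (default 0.5).
#'
#' @return List with `fold_change`, `censor_flag_pdr`, `censor_flag_pds`,
#'   and `is_bound` (TRUE when either IC50 was censored).
#' @export
ic50_fold_change <- function(pdr_fit, pds_fit, level = 0.5) {
  a <- ic50(pdr_fit, level)
  b <- ic50(pds_fit, level)
  list(fold_change = a$ic50 / b$ic50,
       censor_flag_pdr = a$censor_flag, censor_flag_pds = b$censor_flag,
       is_bound = a$censor_flag != "none" || b$censor_flag != "none")
}

#' Dose-response curve plot
#'
#' @param object A converged `fourpl_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object: observed proportions and the fitted curve on a
#'   log10 dose axis, with the IC50 crossing marked when defined.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  obs <- tibble::tibble(dose = object$doses, yp = object$yp)
  grid <- tibble::tibble(
    dose = 10^seq(log10(min(obs$dose)), log10(max(obs$dose)), length.out = 200))
  grid$yp <- fourpl_curve(grid$dose, object$b, object$t,
                          object$log10_xmid, object$slope)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose, y = .data$yp)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "adjusted survival proportion") +
    ggplot2::theme_minimal()
  ic <- ic50(object)
  if (ic$censor_flag == "none") {
    p <- p + ggplot2::geom_vline(xintercept = ic$ic50, linetype = "dashed")
  }
  p
}
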