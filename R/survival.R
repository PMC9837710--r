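# Survival summarisation of simulated records: Kaplan-Meier curves,
# log-rank comparisons and Cox proportional-hazards ratios, computed with
# the survival package. Simulated event times live on a discrete grid, so
# ties are heavy: curves and log-rank statistics are computed on the grid
# as-is, and Cox models use the Efron tie approximation. Mirroring the
# model's intended use, no P values or confidence intervals are attached to
# simulation output; they are meaningful only for real data.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with at-risk and event
#' counts. With `times` supplied, the curve is evaluated on that grid
#' (useful for stepped simulation output); otherwise the distinct event
#' times are returned.
#'
#' @param time Non-negative follow-up times.
#' @param event Logical (or 0/1) event indicators; `FALSE` = censored.
#' @param times Optional numeric grid on which to evaluate the curve.
#' @return Data frame with columns `time`, `survival`, `at_risk`, `events`
#'   and `std_err` (Greenwood standard error of the survival estimate).
#' @export
km_curve <- function(time, event, times = NULL) {
  if (length(time) == 0L) stop("no records supplied")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be non-negative")
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  if (is.null(times)) {
    s <- summary(fit, censored = FALSE)
    if (length(s$time) == 0L) { # censored-only input: flat curve at 1
      return(data.frame(time = max(time), survival = 1,
                        at_risk = length(time), events = 0L, std_err = 0))
    }
  } else {
    s <- summary(fit, times = times, extend = TRUE)
  }
  se <- s$std.err
  se[!is.finite(se)] <- 0
  data.frame(time = s$time, survival = s$surv,
             at_risk = s$n.risk, events = s$n.event, std_err = se)
}

#' Log-rank comparison of two or more groups
#'
#' Chi-square-form log-rank statistic with per-group observed and expected
#' event counts. On simulated cohorts the statistic is a descriptive
#' separation measure; its P value is not interpretable as evidence and is
#' not returned.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Group labels (at least two distinct values).
#' @return List with `statistic`, `df`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank comparison needs at least two groups")
  }
  fit <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  list(statistic = unname(fit$chisq),
       df = length(fit$n) - 1L,
       observed = as.vector(fit$obs),
       expected = as.vector(fit$exp))
}

#' Cox proportional-hazards ratios against a reference level
#'
#' Fits a Cox model with the grouping variable as sole covariate (Efron tie
#' handling) and returns hazard-ratio point estimates per non-reference
#' level. Levels without events are flagged non-estimable (`NA`).
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Covariate with at least two levels; the first level is the
#'   reference (HR = 1).
#' @return List with `hr` (named vector, reference included at 1), `log_hr`
#'   and `se` (standard errors of the log hazard ratios).
#' @export
cox_hr <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("Cox comparison needs at least two covariate levels")
  }
  events_by_level <- tapply(as.integer(event), group, sum)
  fit_call <- function() survival::coxph(
    survival::Surv(time, as.integer(event)) ~ group, ties = "efron")
  # a level without events has an infinite MLE; silence the inevitable
  # non-convergence warning and flag the level instead
  fit <- if (any(events_by_level == 0 | is.na(events_by_level))) {
    suppressWarnings(fit_call())
  } else {
    fit_call()
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  lev <- levels(group)
  hr <- c(1, exp(beta))
  log_hr <- c(0, beta)
  se_out <- c(0, se)
  names(hr) <- names(log_hr) <- names(se_out) <- lev
  no_events <- lev[which(events_by_level == 0 | is.na(events_by_level))]
  hr[no_events] <- NA_real_
  list(hr = hr, log_hr = log_hr, se = se_out,
       non_estimable = no_events)
}
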