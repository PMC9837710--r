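# Evidence-to-hazard conversion layer.
#
# Published risks arrive as cumulative probabilities over some horizon
# ("p% within o years"), as hazard ratios against a reference survival, or
# as piecewise cumulative-incidence schedules.  Everything the network
# builder consumes is a per-step event probability on the simulation grid,
# obtained under a piecewise-constant-hazard assumption.

#' Convert a cumulative risk to a constant annual event rate
#'
#' Under a constant-hazard model, a cumulative probability `p` of an event
#' within `o` years corresponds to the annual rate `-ln(1 - p) / o`.
#'
#' @param p Cumulative probability of the event within `o` years; must lie in
#'   `[0, 1)`.
#' @param o Horizon in years over which `p` was observed; must be positive.
#' @return Event rate per year (non-negative; zero iff `p == 0`).
#' @examples
#' annual_rate(0.27, 10) # 10-year contralateral risk in BRCA1 carriers
#' @export
annual_rate <- function(p, o) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be a probability in [0, 1): got ", paste(p, collapse = ", "))
  }
  if (any(!is.finite(o)) || any(o <= 0)) {
    stop("`o` must be a positive horizon in years: got ", paste(o, collapse = ", "))
  }
  -log1p(-p) / o
}

#' Convert an annual rate to an event probability over an interval
#'
#' The probability of at least one event in `c` years at constant rate
#' `rate` is `1 - exp(-rate * c)`.
#'
#' @param rate Event rate per year (non-negative).
#' @param c Interval length in years (positive).
#' @return Probability in `[0, 1)`.
#' @examples
#' interval_probability(annual_rate(0.19, 10), 10) # round-trips to 0.19
#' @export
interval_probability <- function(rate, c) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("`rate` must be non-negative: got ", paste(rate, collapse = ", "))
  }
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("`c` must be a positive interval in years: got ", paste(c, collapse = ", "))
  }
  -expm1(-rate * c)
}

#' Adjust a reference survival probability by a hazard ratio
#'
#' Under proportional hazards, the survival of a group with hazard ratio
#' `hr` against a reference with survival `ref_survival` is
#' `ref_survival ^ hr`.
#'
#' @param ref_survival Survival probability of the reference group, in
#'   `(0, 1]`.
#' @param hr Hazard ratio (non-negative); `hr = 1` returns the reference.
#' @return Adjusted survival probability in `(0, 1]`.
#' @examples
#' apply_hazard_ratio(0.9, 2) # 0.81
#' @export
apply_hazard_ratio <- function(ref_survival, hr) {
  if (any(!is.finite(ref_survival)) || any(ref_survival <= 0) ||
      any(ref_survival > 1)) {
    stop("`ref_survival` must lie in (0, 1]")
  }
  if (any(!is.finite(hr)) || any(hr < 0)) {
    stop("`hr` must be a non-negative hazard ratio")
  }
  ref_survival^hr
}

#' Construct a cumulative-risk schedule
#'
#' A schedule is a set of (horizon, cumulative probability) segments with a
#' piecewise-constant hazard inside each segment; e.g. a 5-year and a
#' 10-year cumulative incidence. Horizons must be strictly increasing and
#' cumulative probabilities non-decreasing.
#'
#' @param horizon Numeric vector of segment end points in years, strictly
#'   increasing and positive.
#' @param cum_prob Cumulative event probabilities at each horizon,
#'   non-decreasing, in `[0, 1)`.
#' @return A `risk_schedule`: a data frame with columns `horizon` and
#'   `cum_prob`.
#' @export
risk_schedule <- function(horizon, cum_prob) {
  if (length(horizon) == 0L) stop("schedule must have at least one segment")
  if (length(horizon) != length(cum_prob)) {
    stop("`horizon` and `cum_prob` must have equal length")
  }
  if (any(!is.finite(horizon)) || any(horizon <= 0) ||
      any(diff(horizon) <= 0)) {
    stop("schedule horizons must be positive and strictly increasing")
  }
  if (any(!is.finite(cum_prob)) || any(cum_prob < 0) || any(cum_prob >= 1)) {
    stop("schedule cumulative probabilities must lie in [0, 1)")
  }
  if (any(diff(cum_prob) < 0)) {
    stop("schedule cumulative probabilities must be non-decreasing")
  }
  structure(data.frame(horizon = as.numeric(horizon),
                       cum_prob = as.numeric(cum_prob)),
            class = c("risk_schedule", "data.frame"))
}

#' @keywords internal
is_risk_schedule <- function(x) inherits(x, "risk_schedule")

# Cumulative hazard of a schedule at arbitrary times, piecewise linear in t
# (constant rate within segments, last segment's rate extended beyond the
# final horizon).
schedule_cumhaz <- function(schedule, t) {
  h <- c(0, schedule$horizon)
  H <- c(0, -log1p(-schedule$cum_prob))
  rates <- diff(H) / diff(h)
  n_seg <- length(rates)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    acc <- 0
    for (j in seq_len(n_seg)) {
      lo <- h[j]; hi <- h[j + 1]
      if (ti <= lo) break
      top <- if (j == n_seg) ti else min(ti, hi) # extend last segment
      acc <- acc + rates[j] * (top - lo)
    }
    out[i] <- acc
  }
  out
}

# Average rate within each step interval of the simulation grid.
schedule_step_rates <- function(schedule, step, n_steps) {
  bounds <- seq(0, n_steps * step, by = step)
  H <- schedule_cumhaz(schedule, bounds)
  diff(H) / step
}

#' Per-step event probabilities from a cumulative-risk schedule
#'
#' Converts a piecewise cumulative-incidence schedule into conditional
#' per-step event probabilities on a regular grid, such that composing the
#' steps reproduces the schedule's cumulative probability at every segment
#' boundary that falls on the grid.
#'
#' @param schedule A [risk_schedule()].
#' @param step Step length in years; must divide `horizon`.
#' @param horizon Total follow-up in years. If the schedule ends earlier,
#'   its final hazard is extended.
#' @return Numeric vector of length `horizon / step`: the probability of the
#'   event in each step, conditional on no event in previous steps.
#' @examples
#' q <- stepwise_probabilities(risk_schedule(10, 0.27), step = 1, horizon = 10)
#' 1 - prod(1 - q) # reproduces 0.27
#' @export
stepwise_probabilities <- function(schedule, step, horizon) {
  if (!is_risk_schedule(schedule)) {
    schedule <- risk_schedule(schedule$horizon, schedule$cum_prob)
  }
  if (step <= 0 || horizon <= 0) stop("`step` and `horizon` must be positive")
  n_steps <- horizon / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("`step` must divide `horizon`: ", step, " does not divide ", horizon)
  }
  n_steps <- as.integer(round(n_steps))
  rates <- schedule_step_rates(schedule, step, n_steps)
  -expm1(-rates * step)
}
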