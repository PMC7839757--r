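## Economics: reward accrual over a trajectory, ICERs, threshold verdicts.
## Rewards follow the cycle-start convention: the occupancy at the start of
## cycle t earns that year's utility and cost; the final (horizon-th) vector
## closes the last cycle and earns nothing. No half-cycle correction.

discount_factors <- function(horizon, rate) {
  if (rate == 0) rep(1, horizon) else (1 + rate)^-(seq_len(horizon) - 1L)
}

#' Accrue lifetime QALYs over a cohort trajectory
#'
#' Sums, over cycles, the utility-weighted occupancy at the start of each
#' cycle. Undiscounted by default (the base analysis applies no discounting);
#' a positive annual rate discounts cycle t by `(1+rate)^-t`.
#'
#' @param trajectory A [cohort_trajectory][run_cohort()].
#' @param utilities A [utility_set][derive_utilities()].
#' @param discount_rate Annual discount rate (default 0).
#' @return Total QALYs per cohort member (scalar).
#' @export
accrue_qalys <- function(trajectory, utilities, discount_rate = 0) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  h <- attr(trajectory, "horizon")
  if (h == 0L) return(0)
  u <- utility_vector(utilities)
  w <- discount_factors(h, discount_rate)
  sum(w * (trajectory[seq_len(h), , drop = FALSE] %*% u))
}

#' Accrue lifetime costs over a cohort trajectory
#'
#' State costs are the cost-weighted occupancy at the start of each cycle.
#' The intervention program cost is added per the rule: `"all-cycles"` charges
#' the per-person-year amount for every cycle of the horizon (survival-
#' unweighted, the default used for the published results), `"alive-cycles"`
#' weights it by the living occupancy, `"none"` charges nothing (comparator
#' arm).
#'
#' @param trajectory A [cohort_trajectory][run_cohort()].
#' @param cost A [cost_model()] object.
#' @param program_cost_per_person_year Annual per-person program cost in ZAR.
#' @param rule Program-cost accrual rule (see above).
#' @param cost_level Which state-cost column to use: `"central"`, `"low"` or
#'   `"high"` (the +/-15% bounds).
#' @param discount_rate Annual discount rate (default 0).
#' @return A list of class `cost_accrual`: `total`, `state_component`,
#'   `program_component` (ZAR per cohort member).
#' @export
accrue_costs <- function(trajectory, cost, program_cost_per_person_year = 0,
                         rule = c("all-cycles", "alive-cycles", "none"),
                         cost_level = c("central", "low", "high"),
                         discount_rate = 0) {
  stopifnot(inherits(trajectory, "cohort_trajectory"), inherits(cost, "cost_model"))
  rule <- match.arg(rule)
  cost_level <- match.arg(cost_level)
  if (program_cost_per_person_year < 0) stop("negative program cost", call. = FALSE)
  h <- attr(trajectory, "horizon")
  cvec <- state_cost_vector(cost, cost_level)
  if (any(cvec < 0)) stop("negative state cost", call. = FALSE)
  if (h == 0L) {
    out <- list(total = 0, state_component = 0, program_component = 0)
    class(out) <- "cost_accrual"
    return(out)
  }
  w <- discount_factors(h, discount_rate)
  occ <- trajectory[seq_len(h), , drop = FALSE]
  state_component <- sum(w * (occ %*% cvec))
  program_component <- switch(rule,
    "all-cycles" = program_cost_per_person_year * sum(w),
    "alive-cycles" = program_cost_per_person_year * sum(w * rowSums(occ[, 1:3, drop = FALSE])),
    "none" = 0)
  out <- list(total = state_component + program_component,
              state_component = state_component,
              program_component = program_component)
  class(out) <- "cost_accrual"
  out
}

#' Bundle one arm's lifetime outcomes
#'
#' @param qalys Lifetime QALYs per cohort member.
#' @param costs A `cost_accrual` from [accrue_costs()].
#' @param arm Label (e.g. `"baseline"`, `"intervention"`).
#' @param trajectory Optionally, the underlying trajectory.
#' @return An object of class `arm_outcome`.
#' @export
arm_outcome <- function(qalys, costs, arm = "arm", trajectory = NULL) {
  stopifnot(inherits(costs, "cost_accrual"))
  if (qalys < 0) stop("negative QALY total", call. = FALSE)
  structure(list(arm = arm, lifetime_qalys = qalys, lifetime_cost_zar = costs$total,
                 state_cost_zar = costs$state_component,
                 program_cost_zar = costs$program_component,
                 trajectory = trajectory),
            class = "arm_outcome")
}

#' Classify an ICER against the cost-effectiveness thresholds
#'
#' @param icer_intl_dollar ICER in international dollars per QALY.
#' @param thresholds A [thresholds()] object.
#' @return Named logical vector: `below_wtp` (at or under the willingness-to-
#'   pay threshold) and `below_gdp` (at or under one-times GDP per capita).
#'   Comparisons are inclusive.
#' @examples
#' classify_threshold(1494, thresholds())
#' @export
classify_threshold <- function(icer_intl_dollar, thresholds) {
  stopifnot(inherits(thresholds, "cea_thresholds"))
  c(below_wtp = icer_intl_dollar <= thresholds$wtp_intl_dollar,
    below_gdp = icer_intl_dollar <= thresholds$gdp_threshold_intl_dollar)
}

#' Incremental cost-effectiveness of one arm over another
#'
#' Deltas are intervention minus comparator. When both deltas share a sign the
#' ICER is their ratio (ZAR per QALY, also converted to international
#' dollars); a cheaper-and-better intervention is flagged `dominant`, a
#' costlier-and-worse one `dominated`, and a zero QALY difference yields an
#' undefined ICER flagged `zero-effect` (no error).
#'
#' @param comparator,intervention [arm_outcome()] objects from the same
#'   demography and horizon.
#' @param cost A [cost_model()] (for the currency conversion).
#' @param thresholds A [thresholds()] object.
#' @return An object of class `cea_result` with the deltas, ICERs, dominance
#'   flag and threshold verdicts.
#' @export
compute_icer <- function(comparator, intervention, cost, thresholds) {
  stopifnot(inherits(comparator, "arm_outcome"), inherits(intervention, "arm_outcome"))
  dc <- intervention$lifetime_cost_zar - comparator$lifetime_cost_zar
  dq <- intervention$lifetime_qalys - comparator$lifetime_qalys
  if (dq == 0) {
    flag <- "zero-effect"; icer <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    flag <- "dominant"; icer <- dc / dq
  } else if (dc >= 0 && dq < 0) {
    flag <- "dominated"; icer <- dc / dq
  } else {
    flag <- "tradeoff"; icer <- dc / dq
  }
  icer_intl <- if (is.na(icer)) NA_real_ else convert_currency(icer, cost)
  verdicts <- if (is.na(icer_intl)) c(below_wtp = NA, below_gdp = NA)
              else classify_threshold(icer_intl, thresholds)
  structure(list(comparator = comparator, intervention = intervention,
                 delta_cost_zar = dc, delta_qalys = dq,
                 icer_zar_per_qaly = icer, icer_intl_dollar_per_qaly = icer_intl,
                 dominance_flag = flag, threshold_verdicts = verdicts),
            class = "cea_result")
}
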