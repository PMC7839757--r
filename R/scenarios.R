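## Scenarios, paired cost-effectiveness runs, one-way sensitivity analyses,
## and calibration of the unreported adherence dynamics against the published
## incremental outcomes.

#' Construct a scenario
#'
#' A scenario fixes the adherence trajectory (initial share, target share,
#' linear ramp), the adherent-to-nonadherent switching probability, and the
#' intervention program cost with its accrual rule. Sensitivity multipliers
#' scale the program cost (`cost_multiplier`) and the adherence-share gain
#' (`effect_multiplier`: the effective target is
#' `initial + effect_multiplier * (target - initial)`).
#'
#' @param name Scenario label.
#' @param initial_adherent_share,target_adherent_share Fractions in \[0, 1\];
#'   the target must not be below the initial share.
#' @param ramp_years Years over which the share ramps linearly to the target.
#' @param prob_B_to_A Fixed adherent-to-nonadherent switching probability.
#' @param program_cost_per_person_year Annual per-person program cost in ZAR.
#' @param program_cost_rule See [accrue_costs()].
#' @param cost_multiplier,effect_multiplier Sensitivity multipliers.
#' @param share_denominator See [share_schedule_to_dynamics()].
#' @return An object of class `cea_scenario`.
#' @seealso [make_baseline()], [make_intervention()]
#' @export
scenario <- function(name, initial_adherent_share, target_adherent_share,
                     ramp_years = 0L, prob_B_to_A = 0,
                     program_cost_per_person_year = 0,
                     program_cost_rule = c("none", "all-cycles", "alive-cycles"),
                     cost_multiplier = 1, effect_multiplier = 1,
                     share_denominator = c("epilepsy", "living")) {
  program_cost_rule <- match.arg(program_cost_rule)
  share_denominator <- match.arg(share_denominator)
  s0 <- initial_adherent_share; s1 <- target_adherent_share
  if (s0 < 0 || s0 > 1 || s1 < 0 || s1 > 1)
    stop("adherent shares must lie in [0,1]", call. = FALSE)
  if (s1 < s0) stop("target adherent share below initial share", call. = FALSE)
  if (ramp_years < 0) stop("ramp_years must be non-negative", call. = FALSE)
  if (cost_multiplier <= 0) stop("cost_multiplier must be positive", call. = FALSE)
  if (effect_multiplier < 0 || effect_multiplier > 1)
    stop("effect_multiplier must lie in [0,1]", call. = FALSE)
  structure(list(name = name,
                 initial_adherent_share = s0,
                 target_adherent_share = s1,
                 ramp_years = as.integer(ramp_years),
                 prob_B_to_A = prob_B_to_A,
                 program_cost_per_person_year = program_cost_per_person_year,
                 program_cost_rule = program_cost_rule,
                 cost_multiplier = cost_multiplier,
                 effect_multiplier = effect_multiplier,
                 share_denominator = share_denominator),
            class = "cea_scenario")
}

#' Baseline (current-practice) scenario
#'
#' No program cost; the adherent share is held at its initial level through
#' stationary switching probabilities.
#'
#' @param params A `cea_params` object (for the defaults).
#' @param initial_adherent_share Adherent share at entry and throughout
#'   (default: the 68% reported-treatment figure in the packaged fixture).
#' @param prob_B_to_A Adherent-to-nonadherent switching probability.
#' @param share_denominator See [share_schedule_to_dynamics()].
#' @return A `cea_scenario`.
#' @export
make_baseline <- function(params = default_parameters(),
                          initial_adherent_share = params$defaults$initial_adherent_share,
                          prob_B_to_A = 0,
                          share_denominator = "epilepsy") {
  scenario("baseline", initial_adherent_share, initial_adherent_share,
           ramp_years = 0L, prob_B_to_A = prob_B_to_A,
           program_cost_per_person_year = 0, program_cost_rule = "none",
           share_denominator = share_denominator)
}

#' CHW intervention scenario
#'
#' The adherent share ramps linearly from its initial level to the target
#' (default 90% within 2 years) and is then held; the program cost (default
#' 443 ZAR per person-year) accrues for the full horizon.
#'
#' @inheritParams make_baseline
#' @param target_adherent_share Post-ramp adherent share (default 0.90).
#' @param ramp_years Ramp duration in years (default 2).
#' @param program_cost_per_person_year Annual program cost per person with
#'   epilepsy, ZAR.
#' @param program_cost_rule See [accrue_costs()]; the default
#'   `"all-cycles"` charges every cycle unweighted by survival, which is the
#'   accrual consistent with the published cost-sensitivity arithmetic.
#' @param cost_multiplier,effect_multiplier Sensitivity multipliers (see
#'   [scenario()]).
#' @return A `cea_scenario`.
#' @export
make_intervention <- function(params = default_parameters(),
                              initial_adherent_share = params$defaults$initial_adherent_share,
                              target_adherent_share = params$defaults$target_adherent_share,
                              ramp_years = params$defaults$ramp_years,
                              program_cost_per_person_year =
                                params$defaults$program_cost_per_person_year_zar,
                              prob_B_to_A = 0, cost_multiplier = 1, effect_multiplier = 1,
                              program_cost_rule = "all-cycles",
                              share_denominator = "epilepsy") {
  if (target_adherent_share < initial_adherent_share)
    stop("target adherent share below initial share", call. = FALSE)
  scenario("intervention", initial_adherent_share, target_adherent_share,
           ramp_years = ramp_years, prob_B_to_A = prob_B_to_A,
           program_cost_per_person_year = program_cost_per_person_year,
           program_cost_rule = program_cost_rule,
           cost_multiplier = cost_multiplier, effect_multiplier = effect_multiplier,
           share_denominator = share_denominator)
}

#' Adherent-share schedule implied by a scenario
#'
#' @param scn A `cea_scenario`.
#' @param horizon Number of cycles.
#' @return Numeric vector of length `horizon + 1`: the target adherent share
#'   at the start of each cycle, after applying the effect multiplier.
#' @export
share_schedule <- function(scn, horizon = 100L) {
  stopifnot(inherits(scn, "cea_scenario"))
  s0 <- scn$initial_adherent_share
  target <- s0 + scn$effect_multiplier * (scn$target_adherent_share - s0)
  tt <- 0:horizon
  if (scn$ramp_years == 0L) {
    sched <- rep(target, horizon + 1L)
    sched[1L] <- s0
    if (target == s0) sched[] <- s0
    return(sched)
  }
  pmin(s0 + tt / scn$ramp_years * (target - s0), target)
}

# Evaluate one arm: derive tracking dynamics, propagate, accrue.
# Fast scalar recursion; numerically identical to the public
# share_schedule_to_dynamics() + run_cohort() + accrue_*() route (tested).
evaluate_arm <- function(scn, params, sex, entry_age, horizon = 100L,
                         cost_level = "central", discount_rate = 0,
                         keep_trajectory = TRUE) {
  stopifnot(inherits(scn, "cea_scenario"), inherits(params, "cea_params"))
  sched <- share_schedule(scn, horizon)
  rates <- cycle_rates(params$rates, entry_age, sex, horizon)
  init <- c(1 - sched[1L], sched[1L], 0, 0)
  rec <- cohort_recursion(rates, init, horizon, pBA_sched = scn$prob_B_to_A,
                          share_target = sched,
                          share_denominator = scn$share_denominator)
  traj <- structure(rec$occupancy, entry_age = entry_age, sex = sex, horizon = horizon,
                    class = c("cohort_trajectory", "matrix", "array"))
  qalys <- accrue_qalys(traj, params$utilities, discount_rate)
  costs <- accrue_costs(traj, params$costs,
                        program_cost_per_person_year =
                          scn$program_cost_per_person_year * scn$cost_multiplier,
                        rule = scn$program_cost_rule, cost_level = cost_level,
                        discount_rate = discount_rate)
  out <- arm_outcome(qalys, costs, arm = scn$name,
                     trajectory = if (keep_trajectory) traj)
  attr(out, "dynamics") <- adherence_dynamics(rec$prob_A_to_B, scn$prob_B_to_A)
  attr(out, "sex") <- sex
  attr(out, "entry_age") <- entry_age
  out
}

#' Run a paired cost-effectiveness analysis
#'
#' Evaluates the comparator and intervention scenarios on the same demography
#' (sex, entry age, horizon) and returns their incremental comparison.
#'
#' @param baseline,intervention `cea_scenario` objects.
#' @param params A `cea_params` object.
#' @param sex `"male"` or `"female"`.
#' @param entry_age Integer entry age.
#' @param horizon Number of one-year cycles (default 100).
#' @param cost_level State-cost level: `"central"`, `"low"` or `"high"`.
#' @param discount_rate Annual discount rate for both QALYs and costs
#'   (default 0).
#' @return A [cea_result][compute_icer()], with attributes `sex` and
#'   `entry_age`.
#' @export
run_cea <- function(baseline, intervention, params = default_parameters(),
                    sex, entry_age, horizon = 100L, cost_level = "central",
                    discount_rate = 0) {
  b <- evaluate_arm(baseline, params, sex, entry_age, horizon, cost_level, discount_rate)
  i <- evaluate_arm(intervention, params, sex, entry_age, horizon, cost_level, discount_rate)
  res <- compute_icer(b, i, params$costs, params$thresholds)
  attr(res, "sex") <- sex
  attr(res, "entry_age") <- entry_age
  res
}

## Calibration ----------------------------------------------------------------

#' Published incremental outcomes used as calibration targets
#'
#' The per-sex lifetime incremental QALYs and costs reported for the base-case
#' analysis; these are model inputs for [calibrate()].
#'
#' @return Data frame with columns `sex`, `delta_qalys`, `delta_cost_zar`.
#' @export
calibration_targets <- function() {
  data.frame(sex = c("male", "female"),
             delta_qalys = c(5.90, 4.09),
             delta_cost_zar = c(47480, 40969))
}

# per-sex (dQ, dC) for a candidate configuration; rates precomputed
sex_deltas <- function(rates, s0, pba, target, ramp, program, horizon, u, cvec,
                       denominator) {
  base_sched <- rep(s0, horizon + 1L)
  eff_target <- max(target, s0)
  tt <- 0:horizon
  int_sched <- if (ramp > 0) pmin(s0 + tt / ramp * (eff_target - s0), eff_target)
               else rep(eff_target, horizon + 1L)
  run1 <- function(sched, program_cost) {
    init <- c(1 - sched[1L], sched[1L], 0, 0)
    rec <- cohort_recursion(rates, init, horizon, pBA_sched = pba,
                            share_target = sched, share_denominator = denominator)
    occ <- rec$occupancy[seq_len(horizon), , drop = FALSE]
    c(Q = sum(occ %*% u), C = sum(occ %*% cvec) + program_cost * horizon)
  }
  b <- run1(base_sched, 0)
  i <- run1(int_sched, program)
  c(dQ = unname(i["Q"] - b["Q"]), dC = unname(i["C"] - b["C"]))
}

#' Calibrate the adherence dynamics against the published outcomes
#'
#' The published analysis reports per-sex incremental QALYs and costs but not
#' the cohort entry age, the exact arm-specific adherence dynamics, or the
#' switching probabilities behind them. `calibrate()` resolves these by
#' deterministic grid search followed by per-sex Nelder-Mead refinement: a
#' shared entry age is searched over `entry_ages`, and for each sex the
#' initial adherent share and the adherent-to-nonadherent switching
#' probability minimise the summed squared relative error to that sex's
#' (delta-QALY, delta-cost) pair. The loss over all four targets is the sum of
#' the two per-sex losses; ties are broken by lower entry age, then lower
#' switching probability.
#'
#' The initial adherent share and switching probability are calibrated per
#' sex: the four published targets are not jointly attainable under fully
#' shared adherence behaviour (see the methods vignette).
#'
#' @param params A `cea_params` object.
#' @param targets Data frame as [calibration_targets()] (the default).
#' @param entry_ages Integer grid of candidate shared entry ages.
#' @param shares Grid of initial adherent shares (per sex).
#' @param switch_probs Grid of adherent-to-nonadherent probabilities (per sex).
#' @param target_adherent_share,ramp_years Intervention adherence target and
#'   ramp (defaults from the parameter fixture: 0.90 within 2 years).
#' @param program_cost_per_person_year Program cost, ZAR per person-year.
#' @param horizon Cycles (default 100).
#' @param share_denominator See [share_schedule_to_dynamics()].
#' @param refine Run Nelder-Mead refinement from the best grid point of each
#'   candidate entry age (default TRUE); without it the result is the best
#'   grid point.
#' @param n_candidate_ages How many top entry ages to refine.
#' @return An object of class `cea_fit`; see [coef.cea_fit()],
#'   [predict.cea_fit()], [run_sensitivity()].
#' @examples
#' \donttest{
#' fit <- calibrate(default_parameters())
#' summary(fit)
#' }
#' @export
calibrate <- function(params = default_parameters(),
                      targets = calibration_targets(),
                      entry_ages = 0:45,
                      shares = seq(0.45, 0.81, by = 0.03),
                      switch_probs = seq(0, 0.30, by = 0.05),
                      target_adherent_share = params$defaults$target_adherent_share,
                      ramp_years = params$defaults$ramp_years,
                      program_cost_per_person_year =
                        params$defaults$program_cost_per_person_year_zar,
                      horizon = params$defaults$horizon_cycles,
                      share_denominator = c("epilepsy", "living"),
                      refine = TRUE, n_candidate_ages = 4L) {
  stopifnot(inherits(params, "cea_params"))
  share_denominator <- match.arg(share_denominator)
  if (!length(entry_ages) || !length(shares) || !length(switch_probs))
    stop("calibration grids must be nonempty", call. = FALSE)
  if (!all(c("sex", "delta_qalys", "delta_cost_zar") %in% names(targets)))
    stop("targets must have columns sex, delta_qalys, delta_cost_zar", call. = FALSE)
  u <- utility_vector(params$utilities)
  cvec <- state_cost_vector(params$costs, "central")
  sexes <- targets$sex

  sex_loss <- function(d, sex) {
    tg <- targets[targets$sex == sex, ]
    as.numeric(((d[["dQ"]] - tg$delta_qalys) / tg$delta_qalys)^2 +
                 ((d[["dC"]] - tg$delta_cost_zar) / tg$delta_cost_zar)^2)
  }

  # stage 1: per-sex grid, best (share, switch) for every candidate age
  grid_best <- list()
  for (sex in sexes) grid_best[[sex]] <-
    data.frame(entry_age = entry_ages, share = NA_real_, prob_B_to_A = NA_real_,
               loss = NA_real_)
  for (sex in sexes) {
    for (k in seq_along(entry_ages)) {
      age <- entry_ages[k]
      rates <- cycle_rates(params$rates, age, sex, horizon)
      best <- c(loss = Inf, share = NA, pba = NA)
      for (s0 in shares) for (pba in switch_probs) {
        d <- sex_deltas(rates, s0, pba, target_adherent_share, ramp_years,
                        program_cost_per_person_year, horizon, u, cvec,
                        share_denominator)
        l <- sex_loss(d, sex)
        if (l < best["loss"]) best <- c(loss = l, share = s0, pba = pba)
      }
      grid_best[[sex]][k, c("share", "prob_B_to_A", "loss")] <-
        best[c("share", "pba", "loss")]
    }
  }
  age_loss <- Reduce(`+`, lapply(grid_best, function(g) g$loss))
  age_order <- order(age_loss, entry_ages)

  # stage 2: refine per sex at the leading candidate ages
  n_cand <- if (refine) min(n_candidate_ages, length(entry_ages)) else 1L
  cand <- entry_ages[age_order[seq_len(n_cand)]]
  best_fit <- NULL
  for (age in cand) {
    fits <- list(); tot <- 0
    for (sex in sexes) {
      rates <- cycle_rates(params$rates, age, sex, horizon)
      g <- grid_best[[sex]][grid_best[[sex]]$entry_age == age, ]
      par <- c(g$share, g$prob_B_to_A)
      val <- g$loss
      if (refine) {
        obj <- function(p) {
          if (p[1] < 0 || p[1] > 1 || p[2] < 0 || p[2] > 1) return(1e6)
          d <- sex_deltas(rates, p[1], p[2], target_adherent_share, ramp_years,
                          program_cost_per_person_year, horizon, u, cvec,
                          share_denominator)
          sex_loss(d, sex)
        }
        opt <- stats::optim(par, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-14, maxit = 600))
        par <- opt$par; val <- opt$value
      }
      fits[[sex]] <- list(par = par, loss = val)
      tot <- tot + val
    }
    cand_fit <- list(entry_age = age, fits = fits, loss = tot)
    better <- is.null(best_fit) ||
      tot < best_fit$loss - 1e-14 ||
      (abs(tot - best_fit$loss) <= 1e-14 &&
         (age < best_fit$entry_age ||
            (age == best_fit$entry_age &&
               sum(vapply(fits, function(f) f$par[2], 0)) <
                 sum(vapply(best_fit$fits, function(f) f$par[2], 0)))))
    if (better) best_fit <- cand_fit
  }

  settings <- list(target_adherent_share = target_adherent_share,
                   ramp_years = ramp_years,
                   program_cost_per_person_year = program_cost_per_person_year,
                   horizon = horizon,
                   share_denominator = share_denominator,
                   refined = refine)
  fit <- assemble_fit(params, best_fit$entry_age,
                      lapply(best_fit$fits, function(f)
                        c(initial_adherent_share = unname(f$par[1]),
                          prob_B_to_A = unname(f$par[2]))),
                      targets, settings)
  fit$loss <- best_fit$loss
  fit$per_sex_loss <- vapply(best_fit$fits, function(f) f$loss, 0)
  fit$age_profile <- data.frame(entry_age = entry_ages, loss = age_loss)
  fit$call <- match.call()
  fit
}

# Build a cea_fit at a fixed configuration (no search): evaluates both arms
# per sex, records achieved vs target outcomes, computes the loss.
assemble_fit <- function(params, entry_age, par, targets, settings) {
  achieved <- data.frame()
  arms <- list()
  loss <- 0
  for (sex in names(par)) {
    p <- par[[sex]]
    base <- make_baseline(params, initial_adherent_share = p[["initial_adherent_share"]],
                          prob_B_to_A = p[["prob_B_to_A"]],
                          share_denominator = settings$share_denominator)
    intv <- make_intervention(params,
                              initial_adherent_share = p[["initial_adherent_share"]],
                              target_adherent_share = settings$target_adherent_share,
                              ramp_years = settings$ramp_years,
                              program_cost_per_person_year =
                                settings$program_cost_per_person_year,
                              prob_B_to_A = p[["prob_B_to_A"]],
                              share_denominator = settings$share_denominator)
    res <- run_cea(base, intv, params, sex, entry_age, settings$horizon)
    arms[[sex]] <- list(baseline = base, intervention = intv, result = res)
    tg <- targets[targets$sex == sex, ]
    loss <- loss + ((res$delta_qalys - tg$delta_qalys) / tg$delta_qalys)^2 +
      ((res$delta_cost_zar - tg$delta_cost_zar) / tg$delta_cost_zar)^2
    achieved <- rbind(achieved, data.frame(
      sex = sex,
      delta_qalys = res$delta_qalys, target_delta_qalys = tg$delta_qalys,
      delta_cost_zar = res$delta_cost_zar, target_delta_cost_zar = tg$delta_cost_zar,
      icer_zar_per_qaly = res$icer_zar_per_qaly,
      icer_intl_dollar_per_qaly = res$icer_intl_dollar_per_qaly))
  }
  structure(list(entry_age = entry_age, par = par, loss = loss,
                 per_sex_loss = NULL, targets = targets, achieved = achieved,
                 arms = arms, age_profile = NULL, settings = settings,
                 params = params, call = NULL),
            class = "cea_fit")
}

#' Reconstruct a calibrated model at a known configuration
#'
#' Builds a `cea_fit` directly from a known entry age and per-sex adherence
#' parameters, without searching -- e.g. to rehydrate a saved calibration or
#' to inspect a hand-chosen configuration.
#'
#' @param params A `cea_params` object.
#' @param entry_age Integer entry age.
#' @param male,female Numeric vectors with elements `initial_adherent_share`
#'   and `prob_B_to_A`.
#' @param targets As [calibration_targets()].
#' @param target_adherent_share,ramp_years,program_cost_per_person_year,horizon,share_denominator
#'   Scenario settings, defaulting to the parameter fixture's.
#' @return A `cea_fit` (its `loss` is the loss of the supplied configuration).
#' @export
as_cea_fit <- function(params = default_parameters(), entry_age, male, female,
                       targets = calibration_targets(),
                       target_adherent_share = params$defaults$target_adherent_share,
                       ramp_years = params$defaults$ramp_years,
                       program_cost_per_person_year =
                         params$defaults$program_cost_per_person_year_zar,
                       horizon = params$defaults$horizon_cycles,
                       share_denominator = "epilepsy") {
  as_par <- function(x) {
    x <- unlist(x)
    if (!is.null(names(x)) && all(c("initial_adherent_share", "prob_B_to_A") %in% names(x)))
      x <- x[c("initial_adherent_share", "prob_B_to_A")]
    if (length(x) != 2L || any(!is.finite(x)))
      stop("sex parameters must supply initial_adherent_share and prob_B_to_A",
           call. = FALSE)
    stats::setNames(as.numeric(x), c("initial_adherent_share", "prob_B_to_A"))
  }
  par <- list(male = as_par(male), female = as_par(female))
  settings <- list(target_adherent_share = target_adherent_share,
                   ramp_years = ramp_years,
                   program_cost_per_person_year = program_cost_per_person_year,
                   horizon = horizon, share_denominator = share_denominator,
                   refined = FALSE)
  assemble_fit(params, entry_age, par, targets, settings)
}

## Sensitivity ----------------------------------------------------------------

#' One-way sensitivity analyses around a calibrated base case
#'
#' Re-runs the paired analysis for each sex under the published one-way
#' perturbations: intervention cost +50% (`cost_multiplier = 1.5`),
#' intervention effectiveness -50% (`effect_multiplier = 0.5`, halving the
#' adherence-share gain), and the state-cost bounds (-15% / +15%).
#'
#' @param fit A `cea_fit` from [calibrate()].
#' @param params A `cea_params` object (defaults to the fit's).
#' @param effect_mode How the effectiveness reduction is applied:
#'   `"adherence-gain"` (default) scales the adherence-share gain before the
#'   model runs; `"qaly-gain"` instead scales the incremental QALYs of the
#'   base run after the fact. The published report does not state its
#'   operationalisation; both are provided.
#' @return An object of class `sensitivity_report`: `table` (one row per sex
#'   and scenario) and `results` (the underlying `cea_result` objects).
#' @export
run_sensitivity <- function(fit, params = fit$params,
                            effect_mode = c("adherence-gain", "qaly-gain")) {
  stopifnot(inherits(fit, "cea_fit"))
  effect_mode <- match.arg(effect_mode)
  st <- fit$settings
  rows <- list(); results <- list()
  perturbations <- list(base = list(cost_multiplier = 1, effect_multiplier = 1, cost_level = "central"),
                `cost+50%` = list(cost_multiplier = 1.5, effect_multiplier = 1,
                                  cost_level = "central"),
                `effect-50%` = list(cost_multiplier = 1, effect_multiplier = 0.5,
                                    cost_level = "central"),
                `state costs -15%` = list(cost_multiplier = 1, effect_multiplier = 1,
                                          cost_level = "low"),
                `state costs +15%` = list(cost_multiplier = 1, effect_multiplier = 1,
                                          cost_level = "high"))
  for (sex in names(fit$par)) {
    p <- fit$par[[sex]]
    for (nm in names(perturbations)) {
      sp <- perturbations[[nm]]
      eff <- if (nm == "effect-50%" && effect_mode == "qaly-gain") 1 else sp$effect_multiplier
      base <- make_baseline(params, initial_adherent_share = p[["initial_adherent_share"]],
                            prob_B_to_A = p[["prob_B_to_A"]],
                            share_denominator = st$share_denominator)
      intv <- make_intervention(params,
                                initial_adherent_share = p[["initial_adherent_share"]],
                                target_adherent_share = st$target_adherent_share,
                                ramp_years = st$ramp_years,
                                program_cost_per_person_year = st$program_cost_per_person_year,
                                prob_B_to_A = p[["prob_B_to_A"]],
                                cost_multiplier = sp$cost_multiplier,
                                effect_multiplier = eff,
                                share_denominator = st$share_denominator)
      res <- run_cea(base, intv, params, sex, fit$entry_age, st$horizon,
                     cost_level = sp$cost_level)
      if (nm == "effect-50%" && effect_mode == "qaly-gain") {
        res$delta_qalys <- res$delta_qalys * 0.5
        res$icer_zar_per_qaly <- res$delta_cost_zar / res$delta_qalys
        res$icer_intl_dollar_per_qaly <- convert_currency(res$icer_zar_per_qaly,
                                                          params$costs)
        res$threshold_verdicts <- classify_threshold(res$icer_intl_dollar_per_qaly,
                                                     params$thresholds)
      }
      results[[paste(sex, nm, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sex, scenario = nm,
        delta_qalys = res$delta_qalys, delta_cost_zar = res$delta_cost_zar,
        icer_zar_per_qaly = res$icer_zar_per_qaly,
        icer_intl_dollar_per_qaly = res$icer_intl_dollar_per_qaly,
        below_wtp = res$threshold_verdicts[["below_wtp"]],
        below_gdp = res$threshold_verdicts[["below_gdp"]])
    }
  }
  structure(list(table = do.call(rbind, rows), results = results,
                 effect_mode = effect_mode, fit = fit),
            class = "sensitivity_report")
}
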