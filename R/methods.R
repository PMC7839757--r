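## S3 methods. Reporting convention: currency to whole ZAR / international
## dollars, QALYs to two decimals; full precision is kept in the objects.

fmt_zar <- function(x) formatC(round(x), format = "d", big.mark = " ")
fmt_q <- function(x) formatC(x, format = "f", digits = 2)

#' @export
print.rate_tables <- function(x, ...) {
  cat("Annual transition-probability tables\n")
  cat(sprintf("  epilepsy mortality bands : %d (nonadherent/adherent)\n",
              nrow(x$mortality_nonadherent)))
  cat(sprintf("  remission bands          : %d (by sex)\n", nrow(x$remission)))
  cat(sprintf("  background/relapse bands : %d (by sex / by age)\n",
              nrow(x$background_mortality)))
  cat(sprintf("  relapse split to adherent: %.2f\n", x$relapse_split_to_adherent))
  invisible(x)
}

#' @export
print.utility_set <- function(x, ...) {
  cat("Health-state utilities (1 = full health)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Parameter set: four-state adherence Markov model\n")
  cat(sprintf("  utilities            : %s\n",
              paste(sprintf("%s %.4g", .states, utility_vector(x$utilities)),
                    collapse = ", ")))
  cat(sprintf("  annual state costs   : %s ZAR\n",
              paste(fmt_zar(state_cost_vector(x$costs)), collapse = ", ")))
  cat(sprintf("  intervention budget  : %s ZAR/year (%d items)\n",
              fmt_zar(total_budget(x$costs)), nrow(x$costs$budget_items)))
  cat(sprintf("  exchange rate        : %.2f ZAR per international dollar\n",
              x$costs$exchange_rate_zar_per_intl_dollar))
  cat(sprintf("  horizon              : %d one-year cycles\n",
              x$defaults$horizon_cycles))
  invisible(x)
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$name))
  cat(sprintf("  adherent share : %.3f -> %.3f over %d year(s)\n",
              x$initial_adherent_share,
              x$initial_adherent_share +
                x$effect_multiplier * (x$target_adherent_share - x$initial_adherent_share),
              x$ramp_years))
  cat(sprintf("  B->A switching : %.4f\n", x$prob_B_to_A))
  cat(sprintf("  program cost   : %s ZAR/person-year (%s; x%.2f)\n",
              fmt_zar(x$program_cost_per_person_year), x$program_cost_rule,
              x$cost_multiplier))
  invisible(x)
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  h <- attr(x, "horizon")
  cat(sprintf("Cohort trajectory: %s, entry age %d, %d cycles\n",
              attr(x, "sex"), attr(x, "entry_age"), h))
  show <- unique(pmin(c(0, 1, 2, 5, 10, 25, 50, h), h))
  tab <- cbind(cycle = show, age = attr(x, "entry_age") + show,
               round(x[show + 1L, , drop = FALSE], 4))
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cohort_trajectory <- function(x, ...) {
  h <- attr(x, "horizon")
  data.frame(cycle = 0:h, age = attr(x, "entry_age") + 0:h,
             nonadherent = x[, 1], adherent = x[, 2],
             remission = x[, 3], death = x[, 4])
}

#' Plot a cohort trajectory
#'
#' State occupancies against cycle (base graphics).
#'
#' @param x A [cohort_trajectory][run_cohort()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_trajectory <- function(x, ...) {
  h <- attr(x, "horizon")
  graphics::matplot(0:h, unclass(x), type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "forestgreen", "steelblue", "grey30"),
                    xlab = "cycle (years since entry)", ylab = "occupancy",
                    main = sprintf("Cohort occupancy (%s, entry age %d)",
                                   attr(x, "sex"), attr(x, "entry_age")), ...)
  graphics::legend("right", legend = .states, lty = 1, lwd = 2,
                   col = c("firebrick", "forestgreen", "steelblue", "grey30"),
                   bty = "n")
  invisible(x)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm '%s': %s QALYs, %s ZAR (states %s + program %s)\n",
              x$arm, fmt_q(x$lifetime_qalys), fmt_zar(x$lifetime_cost_zar),
              fmt_zar(x$state_cost_zar), fmt_zar(x$program_cost_zar)))
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  sex <- attr(x, "sex")
  cat(sprintf("Incremental cost-effectiveness%s\n",
              if (!is.null(sex)) sprintf(" (%s, entry age %d)", sex, attr(x, "entry_age"))
              else ""))
  cat(sprintf("  delta QALYs : %s\n", fmt_q(x$delta_qalys)))
  cat(sprintf("  delta cost  : %s ZAR\n", fmt_zar(x$delta_cost_zar)))
  if (x$dominance_flag == "zero-effect") {
    cat("  ICER        : undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER        : %s ZAR ($%s) per QALY gained [%s]\n",
                fmt_zar(x$icer_zar_per_qaly), fmt_zar(x$icer_intl_dollar_per_qaly),
                x$dominance_flag))
    v <- x$threshold_verdicts
    cat(sprintf("  verdicts    : below WTP: %s; below 1x GDP: %s\n",
                v[["below_wtp"]], v[["below_gdp"]]))
  }
  invisible(x)
}

#' @export
as.data.frame.cea_result <- function(x, ...) {
  data.frame(sex = attr(x, "sex") %||% NA_character_,
             delta_qalys = x$delta_qalys, delta_cost_zar = x$delta_cost_zar,
             icer_zar_per_qaly = x$icer_zar_per_qaly,
             icer_intl_dollar_per_qaly = x$icer_intl_dollar_per_qaly,
             dominance = x$dominance_flag,
             below_wtp = x$threshold_verdicts[["below_wtp"]],
             below_gdp = x$threshold_verdicts[["below_gdp"]])
}

## cea_fit --------------------------------------------------------------------

#' @export
print.cea_fit <- function(x, ...) {
  cat("Calibrated adherence Markov model\n")
  cat(sprintf("  shared entry age : %d\n", x$entry_age))
  for (sex in names(x$par))
    cat(sprintf("  %-6s : initial adherent share %.4f, B->A switching %.4f\n",
                sex, x$par[[sex]][["initial_adherent_share"]],
                x$par[[sex]][["prob_B_to_A"]]))
  cat(sprintf("  calibration loss : %.3g (sum of squared relative errors)\n", x$loss))
  for (i in seq_len(nrow(x$achieved)))
    cat(sprintf("  %-6s ICER : %s ZAR ($%s) per QALY gained\n",
                x$achieved$sex[i], fmt_zar(x$achieved$icer_zar_per_qaly[i]),
                fmt_zar(x$achieved$icer_intl_dollar_per_qaly[i])))
  invisible(x)
}

#' Calibrated parameters
#'
#' @param object A `cea_fit` from [calibrate()].
#' @param ... Unused.
#' @return Named numeric vector: shared entry age and per-sex initial adherent
#'   share and switching probability.
#' @export
coef.cea_fit <- function(object, ...) {
  out <- c(entry_age = object$entry_age)
  for (sex in names(object$par)) {
    p <- object$par[[sex]]
    out[paste0(sex, ".initial_adherent_share")] <- p[["initial_adherent_share"]]
    out[paste0(sex, ".prob_B_to_A")] <- p[["prob_B_to_A"]]
  }
  out
}

#' Calibration residuals
#'
#' Relative errors of the fitted incremental outcomes against the published
#' targets (fitted minus target, over target).
#'
#' @param object A `cea_fit`.
#' @param ... Unused.
#' @return Named numeric vector of four relative errors.
#' @export
residuals.cea_fit <- function(object, ...) {
  a <- object$achieved
  out <- c((a$delta_qalys - a$target_delta_qalys) / a$target_delta_qalys,
           (a$delta_cost_zar - a$target_delta_cost_zar) / a$target_delta_cost_zar)
  names(out) <- c(paste0(a$sex, ".delta_qalys"), paste0(a$sex, ".delta_cost_zar"))
  out
}

#' @export
summary.cea_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cea_fit")
}

#' @export
print.summary.cea_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFit against published incremental outcomes:\n")
  a <- f$achieved
  tab <- data.frame(sex = a$sex,
                    dQALY = fmt_q(a$delta_qalys),
                    dQALY_target = fmt_q(a$target_delta_qalys),
                    dCost = fmt_zar(a$delta_cost_zar),
                    dCost_target = fmt_zar(a$target_delta_cost_zar))
  print(tab, row.names = FALSE)
  cat("\nRelative errors:\n")
  print(signif(residuals(f), 3))
  invisible(x)
}

#' Predict cost-effectiveness outcomes from a calibrated model
#'
#' Re-runs the paired analysis at the calibrated configuration, optionally
#' under one of the one-way sensitivity perturbations.
#'
#' @param object A `cea_fit`.
#' @param sex `"male"`, `"female"`, or both (default).
#' @param perturbation `"base"`, `"cost+50%"`, `"effect-50%"`,
#'   `"state costs -15%"` or `"state costs +15%"`.
#' @param ... Unused.
#' @return A [cea_result][compute_icer()] (or a named list of them when both
#'   sexes are requested).
#' @export
predict.cea_fit <- function(object, sex = c("male", "female"),
                            perturbation = "base", ...) {
  sex <- match.arg(sex, several.ok = TRUE)
  rep <- run_sensitivity(object)
  keys <- paste(sex, perturbation, sep = ".")
  missing <- setdiff(keys, names(rep$results))
  if (length(missing))
    stop(sprintf("unknown perturbation '%s'", perturbation), call. = FALSE)
  out <- rep$results[keys]
  if (length(out) == 1L) out[[1L]] else stats::setNames(out, sex)
}

#' Simulate individual trajectories from a calibrated model
#'
#' Draws microsimulated individuals from the calibrated configuration (the
#' synthetic-data generator behind the cohort model's cross-validation).
#'
#' @param object A `cea_fit`.
#' @param nsim Number of individuals.
#' @param seed Integer seed.
#' @param sex `"male"` or `"female"`.
#' @param arm `"baseline"` or `"intervention"`.
#' @param ... Unused.
#' @return A `microsim` object; see [simulate_individuals()].
#' @export
simulate.cea_fit <- function(object, nsim = 1000L, seed = 1L,
                             sex = c("male", "female"),
                             arm = c("intervention", "baseline"), ...) {
  sex <- match.arg(sex)
  arm <- match.arg(arm)
  scn <- object$arms[[sex]][[arm]]
  simulate_individuals(scn, object$params, sex, object$entry_age,
                       n = nsim, seed = seed,
                       horizon = object$settings$horizon)
}

#' Plot a calibrated model
#'
#' `type = "occupancy"` overlays baseline and intervention occupancy for one
#' sex; `type = "loss"` shows the calibration loss profile over candidate
#' entry ages.
#'
#' @param x A `cea_fit`.
#' @param type `"occupancy"` or `"loss"`.
#' @param sex Sex for the occupancy panel.
#' @param ... Passed to the underlying plotting call.
#' @export
plot.cea_fit <- function(x, type = c("occupancy", "loss"),
                         sex = c("male", "female"), ...) {
  type <- match.arg(type)
  sex <- match.arg(sex)
  if (type == "loss") {
    graphics::plot(x$age_profile$entry_age, pmin(x$age_profile$loss, 10),
                   type = "b", pch = 16, log = "y",
                   xlab = "entry age (years)", ylab = "grid calibration loss",
                   main = "Calibration loss by candidate entry age", ...)
    graphics::abline(v = x$entry_age, lty = 2)
    return(invisible(x))
  }
  res <- x$arms[[sex]]$result
  b <- res$comparator$trajectory
  i <- res$intervention$trajectory
  h <- attr(b, "horizon")
  graphics::matplot(0:h, cbind(unclass(b), unclass(i)), type = "l",
                    lty = rep(c(2, 1), each = 4), lwd = 1.5,
                    col = rep(c("firebrick", "forestgreen", "steelblue", "grey30"), 2),
                    xlab = "cycle (years since entry)", ylab = "occupancy",
                    main = sprintf("Baseline (dashed) vs intervention (solid), %s", sex),
                    ...)
  graphics::legend("right", legend = .states, lty = 1, lwd = 2,
                   col = c("firebrick", "forestgreen", "steelblue", "grey30"), bty = "n")
  invisible(x)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("One-way sensitivity report",
      sprintf("(effect mode: %s)\n", x$effect_mode))
  tab <- x$table
  tab$delta_qalys <- fmt_q(tab$delta_qalys)
  tab$delta_cost_zar <- fmt_zar(tab$delta_cost_zar)
  tab$icer_zar_per_qaly <- fmt_zar(tab$icer_zar_per_qaly)
  tab$icer_intl_dollar_per_qaly <- fmt_zar(tab$icer_intl_dollar_per_qaly)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sensitivity_report <- function(x, ...) x$table

#' @export
print.microsim_summary <- function(x, ...) {
  cat(sprintf("Microsimulation: n=%d, %s, '%s', entry age %d, seed %d\n",
              x$n, x$sex, x$scenario, x$entry_age, x$seed))
  cat(sprintf("  lifetime QALYs : %.3f (SE %.4f)\n", x$mean_qalys, x$se_qalys))
  cat(sprintf("  lifetime cost  : %s ZAR (SE %s)\n",
              fmt_zar(x$mean_cost_zar), fmt_zar(x$se_cost_zar)))
  invisible(x)
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf("Cohort vs microsimulation agreement (z = %g): %s\n",
              attr(x, "z"), if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
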