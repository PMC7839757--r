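## Individual-level Monte Carlo microsimulation: a synthetic-data generator
## and independent oracle for the deterministic cohort model. Individuals walk
## the same per-cycle transition matrices; their means converge to the cohort
## occupancies at rate ~1/sqrt(n).

# Per-individual RNG streams: each individual draws its whole uniform path
# under a seed at a fixed offset from the run seed, so enlarging n leaves
# existing paths unchanged.
individual_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Simulate individual annual state trajectories
#'
#' Draws `n` individual paths through the four states under a scenario's
#' per-cycle transition law -- the same matrices the cohort model applies --
#' and accrues each individual's lifetime QALYs and costs under the same
#' cycle-start reward convention.
#'
#' @param scn A [scenario()] (e.g. [make_baseline()] or [make_intervention()]).
#' @param params A `cea_params` object.
#' @param sex `"male"` or `"female"`.
#' @param entry_age Integer entry age.
#' @param n Number of individuals (0 allowed).
#' @param seed Integer run seed; identical seeds give bit-identical records.
#' @param horizon Number of one-year cycles.
#' @param cost_level State-cost level.
#' @return An object of class `microsim`: list with `states` (an
#'   `n x (horizon+1)` integer matrix of state indices, 1 = nonadherent ...
#'   4 = death), `qalys` and `cost_zar` (per-individual lifetime totals),
#'   plus the run metadata. Use [as.data.frame()] for one row per
#'   individual-cycle, [summarize_microsim()] for summaries.
#' @export
simulate_individuals <- function(scn, params = default_parameters(), sex, entry_age,
                                 n, seed = 1L, horizon = 100L,
                                 cost_level = "central") {
  stopifnot(inherits(scn, "cea_scenario"), inherits(params, "cea_params"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  # the cohort-derived dynamics fix the per-cycle matrices
  arm <- evaluate_arm(scn, params, sex, entry_age, horizon, cost_level)
  dyn <- attr(arm, "dynamics")
  rates <- cycle_rates(params$rates, entry_age, sex, horizon)
  u <- utility_vector(params$utilities)
  cvec <- state_cost_vector(params$costs, cost_level)
  split <- params$rates$relapse_split_to_adherent

  states <- matrix(4L, nrow = n, ncol = horizon + 1L)
  if (n > 0) {
    U <- matrix(NA_real_, n, horizon + 1L)  # col 1: entry-state draw
    for (i in seq_len(n)) {
      set.seed(individual_seed(seed, i))
      U[i, ] <- stats::runif(horizon + 1L)
    }
    s0 <- scn$initial_adherent_share
    states[, 1L] <- ifelse(U[, 1L] < s0, 2L, 1L)
    for (t in seq_len(horizon)) {
      # transition rows at this cycle (identical to transition_matrix())
      r <- rates$rem[t]; mA <- rates$mA[t]; mB <- rates$mB[t]
      rl <- rates$rl[t]; bg <- rates$bg[t]
      pAB <- min(schedule_at(dyn$prob_A_to_B, t - 1L), max(0, 1 - r - mA))
      pBA <- min(schedule_at(dyn$prob_B_to_A, t - 1L), max(0, 1 - r - mB))
      rows <- rbind(c(1 - pAB - r - mA, pAB, r, mA),
                    c(pBA, 1 - pBA - r - mB, r, mB),
                    c(rl * (1 - split), rl * split, 1 - rl - bg, bg),
                    c(0, 0, 0, 1))
      cum <- t(apply(rows, 1L, cumsum))
      cur <- states[, t]
      draw <- U[, t + 1L]
      nxt <- integer(length(cur))
      for (s in 1:4) {
        idx <- which(cur == s)
        if (length(idx))
          nxt[idx] <- 1L + findInterval(draw[idx], cum[s, 1:3])
      }
      states[, t + 1L] <- nxt
    }
  }
  alive_cols <- seq_len(horizon)  # cycle-start states earn the rewards
  qalys <- if (n > 0) rowSums(matrix(u[states[, alive_cols, drop = FALSE]], nrow = n))
           else numeric(0)
  state_cost <- if (n > 0) rowSums(matrix(cvec[states[, alive_cols, drop = FALSE]],
                                          nrow = n)) else numeric(0)
  program <- scn$program_cost_per_person_year * scn$cost_multiplier
  program_cost <- switch(scn$program_cost_rule,
    "all-cycles" = rep(program * horizon, n),
    "alive-cycles" = program * rowSums(states[, alive_cols, drop = FALSE] != 4L),
    "none" = rep(0, n))
  structure(list(states = states, qalys = qalys,
                 cost_zar = state_cost + program_cost,
                 sex = sex, entry_age = entry_age, horizon = horizon,
                 scenario = scn$name, seed = seed, n = n,
                 cohort = arm),
            class = "microsim")
}

#' @export
as.data.frame.microsim <- function(x, ...) {
  if (x$n == 0) return(data.frame(id = integer(), cycle = integer(),
                                  age = integer(), state = character()))
  data.frame(id = rep(seq_len(x$n), times = x$horizon + 1L),
             cycle = rep(0:x$horizon, each = x$n),
             age = rep(x$entry_age + 0:x$horizon, each = x$n),
             state = .states[as.vector(x$states)])
}

#' Summarise a microsimulation run
#'
#' @param sim A `microsim` object with at least one individual.
#' @return An object of class `microsim_summary`: `n`, mean and standard
#'   error (sample SD over sqrt(n)) of lifetime QALYs and costs, and the
#'   per-cycle state-occupancy estimates with their standard errors.
#' @export
summarize_microsim <- function(sim) {
  stopifnot(inherits(sim, "microsim"))
  if (sim$n < 1L) stop("cannot summarise an empty microsimulation", call. = FALSE)
  n <- sim$n
  se <- function(x) stats::sd(x) / sqrt(n)
  occ <- vapply(1:4, function(s) colMeans(sim$states == s), numeric(sim$horizon + 1L))
  colnames(occ) <- .states
  occ_se <- vapply(1:4, function(s) apply(sim$states == s, 2L, se),
                   numeric(sim$horizon + 1L))
  colnames(occ_se) <- .states
  structure(list(n = n, seed = sim$seed, sex = sim$sex, entry_age = sim$entry_age,
                 horizon = sim$horizon, scenario = sim$scenario,
                 mean_qalys = mean(sim$qalys), se_qalys = se(sim$qalys),
                 mean_cost_zar = mean(sim$cost_zar), se_cost_zar = se(sim$cost_zar),
                 occupancy = occ, occupancy_se = occ_se),
            class = "microsim_summary")
}

#' Cross-validate the cohort model against a microsimulation
#'
#' Law-of-large-numbers agreement check: each cohort quantity (lifetime QALYs,
#' lifetime cost, and the state occupancies midway through the horizon) must
#' lie within `z` Monte-Carlo standard errors of the microsimulation estimate
#' (plus a `2/n` allowance where the binomial standard error degenerates).
#'
#' @param arm An [arm_outcome()] with its trajectory (as produced by
#'   [evaluate_arm()] via [simulate_individuals()]'s `cohort` element, or
#'   [run_cea()]'s arms).
#' @param summary A [summarize_microsim()] result from the same scenario, sex,
#'   entry age and horizon.
#' @param z Number of standard errors (default 3).
#' @return A data frame of class `cross_validation` (quantity, cohort value,
#'   microsim mean, SE, pass), with attribute `pass` (overall).
#' @export
cross_validate <- function(arm, summary, z = 3) {
  stopifnot(inherits(arm, "arm_outcome"), inherits(summary, "microsim_summary"))
  traj <- arm$trajectory
  if (is.null(traj)) stop("arm outcome carries no trajectory", call. = FALSE)
  if (!identical(attr(traj, "sex"), summary$sex) ||
      !identical(attr(traj, "entry_age"), summary$entry_age) ||
      !identical(attr(traj, "horizon"), summary$horizon))
    stop("cohort and microsimulation configurations do not match", call. = FALSE)
  mid <- summary$horizon %/% 2L
  rows <- data.frame(
    quantity = c("lifetime_qalys", "lifetime_cost_zar",
                 paste0("occupancy_", .states, "_cycle", mid)),
    cohort = c(arm$lifetime_qalys, arm$lifetime_cost_zar, traj[mid + 1L, ]),
    microsim = c(summary$mean_qalys, summary$mean_cost_zar,
                 summary$occupancy[mid + 1L, ]),
    se = c(summary$se_qalys, summary$se_cost_zar, summary$occupancy_se[mid + 1L, ]))
  slack <- c(0, 0, rep(2 / summary$n, 4L))
  rows$pass <- abs(rows$cohort - rows$microsim) <= z * rows$se + slack
  structure(rows, pass = all(rows$pass), z = z,
            class = c("cross_validation", "data.frame"))
}

## Randomised fixtures for property tests -------------------------------------

#' Generate a randomised, valid parameter fixture
#'
#' Draws a random but structurally valid set of rate tables, utilities and
#' costs for property-style testing: random age-band systems covering 0-120,
#' probabilities within ranges that keep every matrix row feasible, and
#' (optionally) the orderings of the packaged fixture -- nonadherent mortality
#' above adherent, utilities decreasing from remission to death.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param bands Number of age bands (>= 1).
#' @param ordering_constraints Enforce the mortality and utility orderings.
#' @return A list with components `rates`, `dw`, `utilities`, `costs`,
#'   `thresholds`, `defaults` of class `cea_params`.
#' @export
generate_fixture <- function(seed = 1L, bands = 6L, ordering_constraints = TRUE) {
  if (bands < 1L) stop("bands must be >= 1", call. = FALSE)
  set.seed(seed)
  rnd <- function(n, lo, hi) round(stats::runif(n, lo, hi), 6)
  edges <- if (bands == 1L) integer(0) else sort(sample(1:119, bands - 1L))
  lower <- c(0, edges)
  upper <- c(lower[-1L] - 1L, Inf)
  mA <- rnd(bands, 0.005, 0.2)
  mB <- if (ordering_constraints) round(mA * rnd(bands, 0.1, 0.9), 6) else rnd(bands, 0.005, 0.2)
  tbl <- function(vals, what) age_band_table(lower, upper, vals, what = what)
  rates <- rate_tables(
    mortality_nonadherent = tbl(data.frame(value = pmax(mA, mB)), "mortality_nonadherent"),
    mortality_adherent = tbl(data.frame(value = pmin(mA, mB)), "mortality_adherent"),
    remission = tbl(data.frame(male = rnd(bands, 0, 0.3), female = rnd(bands, 0, 0.3)),
                    "remission"),
    background_mortality = tbl(data.frame(male = rnd(bands, 0.001, 0.2),
                                          female = rnd(bands, 0.001, 0.2)),
                               "background_mortality"),
    relapse = tbl(data.frame(value = rnd(bands, 0, 0.05)), "relapse"),
    relapse_split_to_adherent = rnd(1, 0, 1))
  dws <- sort(rnd(3, 0.02, 0.6))  # treated_seizure_free < with_seizures < untreated
  dw <- disability_weights(untreated = dws[3], treated_seizure_free = dws[1],
                           treated_with_seizures = dws[2],
                           adherent_seizure_free_share = rnd(1, 0.3, 0.9))
  if (!ordering_constraints)
    dw <- disability_weights(rnd(1, 0, 1), rnd(1, 0, 1), rnd(1, 0, 1), rnd(1, 0, 1))
  central <- c(round(stats::runif(2, 1000, 20000)), 0, 0)
  if (ordering_constraints) central[1:2] <- sort(central[1:2], decreasing = TRUE)
  costs <- cost_model(
    state_cost = data.frame(state = .states, central = central,
                            low = round(central * 0.85), high = round(central * 1.15)),
    budget_items = data.frame(item = paste0("item", 1:3),
                              amount_zar = round(stats::runif(3, 1000, 500000))),
    exchange_rate_zar_per_intl_dollar = rnd(1, 1, 20),
    gdp_per_capita_intl_dollar = round(stats::runif(1, 1000, 50000)),
    working_days_per_year_for_daily_gdp = 365L)
  structure(list(rates = rates, dw = dw, utilities = derive_utilities(dw),
                 costs = costs, thresholds = thresholds(),
                 defaults = list(initial_adherent_share = rnd(1, 0.3, 0.8),
                                 initial_adherent_share_blood_levels = NULL,
                                 target_adherent_share = rnd(1, 0.85, 0.95),
                                 ramp_years = sample(0:5, 1L),
                                 program_cost_per_person_year_zar =
                                   round(stats::runif(1, 0, 1000)),
                                 horizon_cycles = 100L)),
            class = "cea_params")
}
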