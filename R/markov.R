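## Markov engine: per-cycle 4x4 transition matrices and cohort propagation.
## State order everywhere: nonadherent (A), adherent (B), remission (C), death (D).

#' Per-cycle adherence-switching schedules
#'
#' The published model leaves the switching probabilities between the
#' nonadherent and adherent states unstated; they are scenario parameters. A
#' schedule shorter than the horizon is extended by holding its final value.
#'
#' @param prob_A_to_B,prob_B_to_A Numeric vectors of per-cycle switching
#'   probabilities in \[0, 1\] (recycled/held beyond their length).
#' @return An object of class `adherence_dynamics`.
#' @seealso [share_schedule_to_dynamics()] to derive a schedule that tracks a
#'   target adherent share.
#' @export
adherence_dynamics <- function(prob_A_to_B = 0, prob_B_to_A = 0) {
  if (any(prob_A_to_B < 0 | prob_A_to_B > 1) || any(prob_B_to_A < 0 | prob_B_to_A > 1))
    stop("switching probabilities must lie in [0,1]", call. = FALSE)
  structure(list(prob_A_to_B = as.numeric(prob_A_to_B),
                 prob_B_to_A = as.numeric(prob_B_to_A)),
            class = "adherence_dynamics")
}

# value of a held schedule at cycle (0-based)
schedule_at <- function(x, cycle) x[pmin(cycle + 1L, length(x))]

#' Build the transition matrix for one cycle
#'
#' Assembles the 4x4 annual transition matrix at a given age, sex and cycle.
#' Exits from the nonadherent state are remission, epilepsy (nonadherent)
#' mortality and switching to adherent; exits from adherent are remission,
#' epilepsy (adherent) mortality and switching back; exits from remission are
#' relapse (split between the two adherence states) and background mortality;
#' death is absorbing. Diagonals are the complements.
#'
#' If a row's exits sum to slightly more than 1 (at most `1e-6` over) they are
#' clipped with a warning; larger excesses up to 1.5 are proportionally
#' renormalised with a warning; beyond that the parameter set is rejected.
#'
#' @param tables A [rate_tables()] object.
#' @param dynamics An [adherence_dynamics()] object.
#' @param age Integer age in years.
#' @param sex `"male"` or `"female"`.
#' @param cycle Cycle index (0-based) into the switching schedules.
#' @return A 4x4 row-stochastic matrix with state dimnames and attributes
#'   `age`, `sex`, `cycle`.
#' @examples
#' p <- default_parameters()
#' transition_matrix(p$rates, adherence_dynamics(), age = 3, sex = "female", cycle = 0)
#' @export
transition_matrix <- function(tables, dynamics, age, sex, cycle = 0L) {
  stopifnot(inherits(tables, "rate_tables"), inherits(dynamics, "adherence_dynamics"))
  if (age < 0) stop("age must be non-negative", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  r <- lookup_rate(tables, "remission", age, sex)
  mA <- lookup_rate(tables, "mortality_nonadherent", age)
  mB <- lookup_rate(tables, "mortality_adherent", age)
  rl <- lookup_rate(tables, "relapse", age)
  bg <- lookup_rate(tables, "background_mortality", age, sex)
  split <- tables$relapse_split_to_adherent
  pAB <- schedule_at(dynamics$prob_A_to_B, cycle)
  pBA <- schedule_at(dynamics$prob_B_to_A, cycle)

  fix_row <- function(exits, label) {
    s <- sum(exits)
    if (s > 1.5)
      stop(sprintf("implausible parameter set: %s exits sum to %.3f", label, s),
           call. = FALSE)
    if (s > 1 + 1e-6) {
      warning(sprintf("%s exits sum to %.6f; proportionally renormalised", label, s),
              call. = FALSE)
      exits <- exits / s
    } else if (s > 1) {
      warning(sprintf("%s exits exceed 1 by %.2e; clipped", label, s - 1), call. = FALSE)
      exits <- exits / s
    }
    exits
  }
  exA <- fix_row(c(B = pAB, C = r, D = mA), "nonadherent row")
  exB <- fix_row(c(A = pBA, C = r, D = mB), "adherent row")
  exC <- fix_row(c(A = rl * (1 - split), B = rl * split, D = bg), "remission row")

  M <- rbind(c(1 - sum(exA), exA[["B"]], exA[["C"]], exA[["D"]]),
             c(exB[["A"]], 1 - sum(exB), exB[["C"]], exB[["D"]]),
             c(exC[["A"]], exC[["B"]], 1 - sum(exC), exC[["D"]]),
             c(0, 0, 0, 1))
  dimnames(M) <- list(.states, .states)
  structure(M, age = age, sex = sex, cycle = cycle)
}

#' Advance a cohort occupancy vector by one cycle
#'
#' @param occupancy Non-negative state-fraction vector over the four states,
#'   summing to 1.
#' @param matrix A 4x4 transition matrix (rows: from-state).
#' @return The occupancy vector after one cycle (`occupancy %*% matrix`).
#' @export
markov_step <- function(occupancy, matrix) {
  if (length(occupancy) != 4L || !all(dim(matrix) == c(4L, 4L)))
    stop("occupancy must have length 4 and matrix must be 4x4", call. = FALSE)
  if (any(occupancy < -1e-12)) stop("occupancy must be non-negative", call. = FALSE)
  as.numeric(occupancy %*% matrix)
}

#' Propagate a cohort over the lifetime horizon
#'
#' Runs the deterministic cohort recursion: the transition matrix is rebuilt
#' every cycle at the cohort's current age (entry age plus elapsed cycles) and
#' applied to the occupancy vector. One cycle is one year; the default horizon
#' of 100 cycles is a lifetime perspective. Cohorts enter in the nonadherent
#' and/or adherent states only (no initial remission or death).
#'
#' @param tables A [rate_tables()] object.
#' @param dynamics An [adherence_dynamics()] object.
#' @param entry_age Integer age at model entry.
#' @param sex `"male"` or `"female"`.
#' @param initial_occupancy State-fraction vector at entry; remission and death
#'   components must be 0.
#' @param horizon Number of one-year cycles (default 100).
#' @return An object of class `cohort_trajectory`: a `(horizon+1) x 4` matrix
#'   of occupancy vectors (row `t+1` is the state distribution at the start of
#'   cycle `t`), with attributes `entry_age`, `sex`, `horizon`.
#' @examples
#' p <- default_parameters()
#' tr <- run_cohort(p$rates, adherence_dynamics(0.1, 0.02), entry_age = 12,
#'                  sex = "male", initial_occupancy = c(0.32, 0.68, 0, 0))
#' head(as.data.frame(tr))
#' @export
run_cohort <- function(tables, dynamics, entry_age, sex,
                       initial_occupancy = c(0.5, 0.5, 0, 0), horizon = 100L) {
  stopifnot(inherits(tables, "rate_tables"))
  if (horizon < 0) stop("horizon must be non-negative", call. = FALSE)
  occ <- as.numeric(initial_occupancy)
  if (length(occ) != 4L || any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
    stop("initial_occupancy must be a non-negative 4-vector summing to 1", call. = FALSE)
  if (occ[3] != 0 || occ[4] != 0)
    stop("cohorts enter in the nonadherent/adherent states only", call. = FALSE)
  out <- matrix(NA_real_, horizon + 1L, 4L, dimnames = list(NULL, .states))
  out[1L, ] <- occ
  if (horizon > 0) for (t in seq_len(horizon)) {
    M <- transition_matrix(tables, dynamics, age = entry_age + t - 1L, sex = sex,
                           cycle = t - 1L)
    occ <- markov_step(occ, M)
    out[t + 1L, ] <- occ
  }
  structure(out, entry_age = entry_age, sex = sex, horizon = horizon,
            class = c("cohort_trajectory", "matrix", "array"))
}

## Fast scalar path -----------------------------------------------------------
## Used by scenario runs and calibration; numerically identical to
## transition_matrix() + markov_step() (tested), but avoids per-cycle matrix
## allocation and supports deriving the A->B schedule that tracks a target
## adherent share.

# Pre-resolve all per-cycle rates for a cohort aging from entry_age.
cycle_rates <- function(tables, entry_age, sex, horizon) {
  ages <- entry_age + seq_len(horizon) - 1L
  list(rem = lookup_rate(tables, "remission", ages, sex),
       mA = lookup_rate(tables, "mortality_nonadherent", ages),
       mB = lookup_rate(tables, "mortality_adherent", ages),
       rl = lookup_rate(tables, "relapse", ages),
       bg = lookup_rate(tables, "background_mortality", ages, sex),
       split = tables$relapse_split_to_adherent)
}

# Core recursion. If share_target is non-NULL (length horizon+1 schedule of
# adherent shares), prob_A_to_B is derived each cycle so that the share after
# the transition matches the schedule; otherwise pAB_sched is used as given.
# The adherent mass after one cycle is linear in prob_A_to_B, so the tracking
# probability is the exact root of a linear equation, clamped to the feasible
# interval [0, 1 - remission - mortality].
cohort_recursion <- function(rates, init, horizon, pAB_sched = NULL, pBA_sched = 0,
                             share_target = NULL, share_denominator = "epilepsy") {
  occ <- matrix(NA_real_, horizon + 1L, 4L, dimnames = list(NULL, .states))
  a <- init[1]; b <- init[2]; cc <- init[3]; d <- init[4]
  occ[1L, ] <- c(a, b, cc, d)
  pAB_out <- numeric(horizon)
  clamped <- logical(horizon)
  half <- rates$split
  for (t in seq_len(horizon)) {
    r <- rates$rem[t]; mA <- rates$mA[t]; mB <- rates$mB[t]
    rl <- rates$rl[t]; bg <- rates$bg[t]
    pBA <- min(schedule_at(pBA_sched, t - 1L), max(0, 1 - r - mB))
    # next-cycle masses before A->B switching is applied
    a0 <- a * (1 - r - mA) + b * pBA + cc * rl * (1 - half)
    b0 <- b * (1 - r - mB - pBA) + cc * rl * half
    c1 <- (a + b) * r + cc * (1 - rl - bg)
    d1 <- d + a * mA + b * mB + cc * bg
    cap <- max(0, 1 - r - mA)  # feasible A->B probability
    if (is.null(share_target)) {
      pAB <- min(schedule_at(pAB_sched, t - 1L), cap)
    } else {
      tgt <- share_target[t + 1L]
      den <- if (share_denominator == "epilepsy") a0 + b0 else a0 + b0 + c1
      pAB <- if (a > 1e-12) (tgt * den - b0) / a else 0
      if (pAB < 0 || pAB > cap) clamped[t] <- TRUE
      pAB <- min(max(pAB, 0), cap)
    }
    pAB_out[t] <- pAB
    switched <- a * pAB  # mass leaving A for B this cycle
    a <- a0 - switched
    b <- b0 + switched
    cc <- c1; d <- d1
    occ[t + 1L, ] <- c(a, b, cc, d)
  }
  list(occupancy = occ, prob_A_to_B = pAB_out, clamped = clamped)
}

#' Derive switching probabilities that track an adherent-share schedule
#'
#' The published scenarios are stated as adherent *shares* (68% at baseline,
#' 90% within two years under the intervention), not switching probabilities.
#' This resolves, cycle by cycle, the nonadherent-to-adherent switching
#' probability such that the cohort's adherent fraction follows the schedule,
#' given a fixed adherent-to-nonadherent probability. The adherent mass after
#' one cycle is linear in the switching probability, so each cycle's value is
#' solved exactly; values outside the feasible range are clamped to the
#' nearest feasible probability with a warning.
#'
#' @param schedule Numeric vector of length `horizon + 1`: target adherent
#'   shares at the start of each cycle (entry value first).
#' @param tables A [rate_tables()] object.
#' @param sex `"male"` or `"female"`.
#' @param entry_age Integer entry age.
#' @param prob_B_to_A Fixed (or per-cycle) adherent-to-nonadherent probability.
#' @param horizon Number of cycles; defaults to `length(schedule) - 1`.
#' @param share_denominator `"epilepsy"` (share of the diagnosed-epilepsy pool,
#'   states A+B; default) or `"living"` (share of all alive, A+B+C).
#' @param quiet Suppress the clamping warning.
#' @return An [adherence_dynamics()] object; attribute `achieved_share` gives
#'   the share realised each cycle and `clamped` flags cycles where the
#'   schedule was unreachable.
#' @export
share_schedule_to_dynamics <- function(schedule, tables, sex, entry_age,
                                       prob_B_to_A = 0, horizon = length(schedule) - 1L,
                                       share_denominator = c("epilepsy", "living"),
                                       quiet = FALSE) {
  stopifnot(inherits(tables, "rate_tables"))
  share_denominator <- match.arg(share_denominator)
  if (any(schedule < 0 | schedule > 1))
    stop("share schedule values must lie in [0,1]", call. = FALSE)
  if (length(schedule) < horizon + 1L)
    schedule <- c(schedule, rep(schedule[length(schedule)],
                                horizon + 1L - length(schedule)))
  init <- c(1 - schedule[1], schedule[1], 0, 0)
  rates <- cycle_rates(tables, entry_age, sex, horizon)
  rec <- cohort_recursion(rates, init, horizon, pBA_sched = prob_B_to_A,
                          share_target = schedule,
                          share_denominator = share_denominator)
  if (any(rec$clamped) && !quiet)
    warning(sprintf("share schedule unreachable in %d cycle(s); nearest feasible switching used",
                    sum(rec$clamped)), call. = FALSE)
  dyn <- adherence_dynamics(prob_A_to_B = rec$prob_A_to_B, prob_B_to_A = prob_B_to_A)
  attr(dyn, "achieved_share") <- adherent_share(rec$occupancy, share_denominator)
  attr(dyn, "clamped") <- rec$clamped
  dyn
}

# adherent share of an occupancy matrix/vector
adherent_share <- function(occ, denominator = "epilepsy") {
  if (is.null(dim(occ))) occ <- matrix(occ, 1L)
  den <- if (denominator == "epilepsy") occ[, 1] + occ[, 2]
         else occ[, 1] + occ[, 2] + occ[, 3]
  ifelse(den > 0, occ[, 2] / den, NA_real_)
}
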