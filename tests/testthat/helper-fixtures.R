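# Shared fixtures and memoised expensive objects.

.test_cache <- new.env(parent = emptyenv())

# Full grid calibration against the published targets; computed once per run.
cached_fit <- function() {
  if (is.null(.test_cache$fit)) .test_cache$fit <- calibrate(default_parameters())
  .test_cache$fit
}

cached_sensitivity <- function() {
  if (is.null(.test_cache$sens)) .test_cache$sens <- run_sensitivity(cached_fit())
  .test_cache$sens
}

# Single-band rate tables with constant rates; handy for hand oracles.
flat_tables <- function(mort_nonadherent = 0, mort_adherent = 0,
                        remission_male = 0, remission_female = remission_male,
                        background_male = 0, background_female = background_male,
                        relapse = 0, split = 0.5) {
  tbl <- function(vals, what) age_band_table(0, Inf, vals, what = what)
  rate_tables(
    mortality_nonadherent = tbl(data.frame(value = mort_nonadherent),
                                "mortality_nonadherent"),
    mortality_adherent = tbl(data.frame(value = mort_adherent), "mortality_adherent"),
    remission = tbl(data.frame(male = remission_male, female = remission_female),
                    "remission"),
    background_mortality = tbl(data.frame(male = background_male,
                                          female = background_female),
                               "background_mortality"),
    relapse = tbl(data.frame(value = relapse), "relapse"),
    relapse_split_to_adherent = split)
}

# Assemble a cohort_trajectory from an occupancy matrix.
mk_traj <- function(occ, sex = "male", entry_age = 0L) {
  occ <- as.matrix(occ)
  colnames(occ) <- unname(health_states())
  structure(occ, entry_age = entry_age, sex = sex, horizon = nrow(occ) - 1L,
            class = c("cohort_trajectory", "matrix", "array"))
}

mk_utilities <- function(nonadherent, adherent, remission, death = 0) {
  structure(c(nonadherent = nonadherent, adherent = adherent,
              remission = remission, death = death),
            class = "utility_set")
}

# Arm outcome with given totals (for ICER arithmetic tests).
mk_arm <- function(qalys, cost, arm = "arm") {
  ca <- structure(list(total = cost, state_component = cost, program_component = 0),
                  class = "cost_accrual")
  arm_outcome(qalys, ca, arm = arm)
}
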