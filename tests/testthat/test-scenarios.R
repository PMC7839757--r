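test_that("baseline and intervention scenarios encode the study assumptions", {
  p <- default_parameters()
  base <- make_baseline(p)
  expect_equal(base$initial_adherent_share, 0.68)
  expect_identical(base$program_cost_per_person_year, 0)
  expect_identical(base$program_cost_rule, "none")
  expect_true(all(share_schedule(base, 50) == 0.68))

  intv <- make_intervention(p)
  expect_equal(intv$target_adherent_share, 0.90)
  expect_identical(intv$ramp_years, 2L)
  expect_identical(intv$program_cost_per_person_year, 443L)
  sched <- share_schedule(intv, 10)
  expect_equal(sched[1:4], c(0.68, 0.79, 0.90, 0.90))
  expect_error(make_intervention(p, initial_adherent_share = 0.95,
                                 target_adherent_share = 0.9),
               "below initial")

  # halving the effect moves the target to the midpoint of the gain
  half <- make_intervention(p, effect_multiplier = 0.5)
  expect_equal(max(share_schedule(half, 10)), 0.79)
  # zero effect collapses the intervention dynamics onto the baseline
  none <- make_intervention(p, effect_multiplier = 0)
  expect_equal(share_schedule(none, 20), share_schedule(make_baseline(p), 20))

  # share 0: the cohort enters entirely nonadherent
  zero <- make_baseline(p, initial_adherent_share = 0)
  arm0 <- chwcea:::evaluate_arm(zero, p, "male", 12, 10)
  expect_identical(arm0$trajectory[1, ], c(nonadherent = 1, adherent = 0,
                                           remission = 0, death = 0))
  # share 1 with no B->A switching and all relapse returning to adherence:
  # the nonadherent state stays empty
  fx <- p
  fx$rates$relapse_split_to_adherent <- 1
  full <- make_baseline(fx, initial_adherent_share = 1)
  arm1 <- chwcea:::evaluate_arm(full, fx, "male", 12, 50)
  expect_true(all(arm1$trajectory[, "nonadherent"] <= 1e-12))
})

test_that("run_cea with identical arms is flagged zero-effect", {
  p <- default_parameters()
  base <- make_baseline(p, initial_adherent_share = 0.68, prob_B_to_A = 0.05)
  res <- run_cea(base, base, p, "female", 12)
  expect_identical(res$dominance_flag, "zero-effect")
  expect_equal(res$delta_qalys, 0)
  expect_equal(res$delta_cost_zar, 0)
})

test_that("calibration recovers an in-grid configuration to machine loss", {
  p <- default_parameters()
  truth <- as_cea_fit(p, entry_age = 10,
                      male = c(initial_adherent_share = 0.6, prob_B_to_A = 0.1),
                      female = c(initial_adherent_share = 0.5, prob_B_to_A = 0.0))
  targets <- data.frame(sex = c("male", "female"),
                        delta_qalys = truth$achieved$delta_qalys,
                        delta_cost_zar = truth$achieved$delta_cost_zar)
  fit <- calibrate(p, targets = targets, entry_ages = c(8, 10, 12),
                   shares = c(0.5, 0.6, 0.7), switch_probs = c(0, 0.1),
                   refine = FALSE)
  expect_identical(fit$entry_age, 10)
  expect_equal(unname(fit$par$male), c(0.6, 0.1))
  expect_equal(unname(fit$par$female), c(0.5, 0.0))
  expect_lte(fit$loss, 1e-12)
  # a one-point grid returns that point
  one <- calibrate(p, targets = targets, entry_ages = 10, shares = 0.6,
                   switch_probs = 0.1, refine = FALSE)
  expect_equal(unname(one$par$male), c(0.6, 0.1))
  expect_error(calibrate(p, entry_ages = integer(0)), "nonempty")
})

test_that("calibration is deterministic given identical grids", {
  p <- default_parameters()
  args <- list(p, entry_ages = c(10, 12, 14), shares = seq(0.5, 0.7, 0.1),
               switch_probs = c(0, 0.1), n_candidate_ages = 2L)
  f1 <- do.call(calibrate, args)
  f2 <- do.call(calibrate, args)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss, f2$loss)
})

test_that("the calibrated fit reproduces all four published incremental outcomes", {
  fit <- cached_fit()
  expect_true(all(abs(residuals(fit)) < 0.005))
  expect_s3_class(fit, "cea_fit")
  # the fitted object exposes the usual accessors
  cf <- coef(fit)
  expect_true(all(c("entry_age", "male.initial_adherent_share",
                    "female.prob_B_to_A") %in% names(cf)))
  pred <- predict(fit, sex = "male", perturbation = "base")
  expect_equal(pred$icer_zar_per_qaly, fit$achieved$icer_zar_per_qaly[1],
               tolerance = 1e-12)
})

test_that("unit multipliers reproduce the base case bit-exactly", {
  sens <- cached_sensitivity()
  fit <- cached_fit()
  base_rows <- sens$table[sens$table$scenario == "base", ]
  expect_equal(base_rows$icer_zar_per_qaly, fit$achieved$icer_zar_per_qaly,
               tolerance = 1e-14)
  expect_equal(base_rows$delta_qalys, fit$achieved$delta_qalys, tolerance = 1e-14)
})

test_that("costlier or less effective interventions strictly raise the ICER", {
  sens <- cached_sensitivity()
  tab <- sens$table
  for (s in c("male", "female")) {
    base <- tab[tab$sex == s & tab$scenario == "base", "icer_zar_per_qaly"]
    expect_gt(tab[tab$sex == s & tab$scenario == "cost+50%", "icer_zar_per_qaly"], base)
    expect_gt(tab[tab$sex == s & tab$scenario == "effect-50%", "icer_zar_per_qaly"], base)
  }
  # and on randomised ordered fixtures whenever both runs stay in the
  # positive-cost, positive-effect quadrant
  checked <- 0
  for (seed in 1:8) {
    fx <- generate_fixture(seed = seed, bands = 3, ordering_constraints = TRUE)
    fx$defaults$program_cost_per_person_year_zar <- 2000
    f <- as_cea_fit(fx, entry_age = 15,
                    male = c(initial_adherent_share = 0.5, prob_B_to_A = 0.05),
                    female = c(initial_adherent_share = 0.5, prob_B_to_A = 0.05),
                    target_adherent_share = 0.9, ramp_years = 2,
                    program_cost_per_person_year = 2000, horizon = 60)
    sr <- run_sensitivity(f)
    t2 <- sr$table
    for (s in c("male", "female")) {
      b <- t2[t2$sex == s & t2$scenario == "base", ]
      up <- t2[t2$sex == s & t2$scenario == "cost+50%", ]
      dn <- t2[t2$sex == s & t2$scenario == "effect-50%", ]
      if (b$delta_qalys > 1e-6 && b$delta_cost_zar > 0 && dn$delta_cost_zar > 0) {
        expect_gt(up$icer_zar_per_qaly, b$icer_zar_per_qaly)
        expect_gt(dn$icer_zar_per_qaly, b$icer_zar_per_qaly)
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 3)
})

test_that("the ICER declines as the adherence target rises on the packaged fixture", {
  fit <- cached_fit()
  p <- fit$params
  targets <- seq(0.75, 0.95, 0.05)
  icers <- vapply(targets, function(tgt) {
    f <- as_cea_fit(p, fit$entry_age, male = fit$par$male, female = fit$par$female,
                    target_adherent_share = tgt)
    f$achieved$icer_zar_per_qaly[f$achieved$sex == "male"]
  }, numeric(1))
  expect_true(all(diff(icers) <= 1e-9))
})

test_that("the qaly-gain operationalisation of reduced effect is also available", {
  fit <- cached_fit()
  sr <- run_sensitivity(fit, effect_mode = "qaly-gain")
  tab <- sr$table
  base <- tab[tab$scenario == "base" & tab$sex == "male", ]
  dn <- tab[tab$scenario == "effect-50%" & tab$sex == "male", ]
  expect_equal(dn$delta_qalys, base$delta_qalys / 2, tolerance = 1e-12)
  expect_equal(dn$delta_cost_zar, base$delta_cost_zar, tolerance = 1e-9)
})
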