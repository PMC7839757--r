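test_that("transition matrices reproduce hand-derived rows from the rate tables", {
  p <- default_parameters()
  # young female: remission 0.305, nonadherent mortality 0.030, no switching
  M <- transition_matrix(p$rates, adherence_dynamics(), age = 3, sex = "female")
  expect_equal(unname(M["nonadherent", ]), c(0.665, 0, 0.305, 0.030))
  # young-adult female remission row: relapse 0.004 split 50/50, background 0.006
  M2 <- transition_matrix(p$rates, adherence_dynamics(), age = 22, sex = "female")
  expect_equal(unname(M2["remission", ]), c(0.002, 0.002, 0.990, 0.006))
  # death is absorbing at any age
  for (a in c(0, 17, 60, 200))
    expect_identical(unname(transition_matrix(p$rates, adherence_dynamics(),
                                              a, "male")["death", ]),
                     c(0, 0, 0, 1))
  # switching enters the off-diagonals
  M3 <- transition_matrix(p$rates, adherence_dynamics(0.2, 0.05), 25, "male")
  expect_equal(M3[["nonadherent", "adherent"]], 0.2)
  expect_equal(M3[["adherent", "nonadherent"]], 0.05)
  expect_equal(unname(rowSums(M3)), rep(1, 4), tolerance = 1e-12)
})

test_that("overloaded rows are clipped, renormalised or rejected by severity", {
  dyn <- adherence_dynamics()
  # exits just over 1: clipped with a warning
  t1 <- flat_tables(mort_nonadherent = 5e-7, remission_male = 1)
  expect_warning(M <- transition_matrix(t1, dyn, 10, "male"), "clipped")
  expect_equal(sum(M["nonadherent", ]), 1, tolerance = 1e-12)
  # exits well over 1: proportional renormalisation with a warning
  t2 <- flat_tables(mort_nonadherent = 0.3, remission_male = 0.9)
  expect_warning(M2 <- transition_matrix(t2, dyn, 10, "male"), "renormalised")
  expect_equal(sum(M2["nonadherent", ]), 1, tolerance = 1e-12)
  expect_equal(M2[["nonadherent", "remission"]] / M2[["nonadherent", "death"]],
               0.9 / 0.3, tolerance = 1e-12)
  # exits beyond 1.5: implausible parameter set
  t3 <- flat_tables(mort_nonadherent = 0.9, mort_adherent = 0.1, remission_male = 0.9)
  expect_error(transition_matrix(t3, dyn, 10, "male"), "implausible")
})

test_that("markov_step propagates and conserves mass", {
  p <- default_parameters()
  M <- transition_matrix(p$rates, adherence_dynamics(), age = 3, sex = "female")
  expect_identical(markov_step(c(0, 0, 0, 1), M), c(0, 0, 0, 1))
  expect_equal(markov_step(c(1, 0, 0, 0), M), c(0.665, 0, 0.305, 0.030))
  expect_equal(sum(markov_step(c(0.25, 0.25, 0.25, 0.25), M)), 1, tolerance = 1e-12)
  expect_error(markov_step(c(0.5, 0.5), M), "length 4")
})

test_that("run_cohort matches the explicit two-cycle matrix product", {
  p <- default_parameters()
  dyn <- adherence_dynamics(prob_A_to_B = c(0.3, 0.1), prob_B_to_A = 0.05)
  init <- c(0.4, 0.6, 0, 0)
  tr <- run_cohort(p$rates, dyn, entry_age = 7, sex = "female", init, horizon = 2)
  M1 <- transition_matrix(p$rates, dyn, age = 7, sex = "female", cycle = 0)
  M2 <- transition_matrix(p$rates, dyn, age = 8, sex = "female", cycle = 1)
  expect_equal(unname(tr[2, ]), as.numeric(init %*% M1), tolerance = 1e-14)
  expect_equal(unname(tr[3, ]), as.numeric(init %*% M1 %*% M2), tolerance = 1e-14)
  # the two-cycle product is itself row-stochastic
  expect_equal(unname(rowSums(M1 %*% M2)), rep(1, 4), tolerance = 1e-12)
})

test_that("run_cohort honours entry rules, horizons and degenerate dynamics", {
  p <- default_parameters()
  dyn <- adherence_dynamics()
  tr0 <- run_cohort(p$rates, dyn, 10, "male", c(0.3, 0.7, 0, 0), horizon = 0)
  expect_identical(nrow(unclass(tr0)), 1L)
  expect_equal(unname(tr0[1, ]), c(0.3, 0.7, 0, 0))
  expect_error(run_cohort(p$rates, dyn, 10, "male", c(0.3, 0.5, 0.2, 0)),
               "nonadherent/adherent states only")
  expect_error(run_cohort(p$rates, dyn, 10, "male", c(0.3, 0.7, 0, 0), horizon = -1),
               "non-negative")
  # no flows at all: occupancy is constant over the century
  still <- flat_tables()
  tr <- run_cohort(still, dyn, 0, "male", c(0.4, 0.6, 0, 0), horizon = 100)
  expect_true(all(apply(unclass(tr), 1, function(r) all(r == c(0.4, 0.6, 0, 0)))))
})

test_that("occupancy conserves mass and death is monotone over the lifetime horizon", {
  p <- default_parameters()
  for (sex in c("male", "female")) {
    tr <- run_cohort(p$rates, adherence_dynamics(0.15, 0.05), 12, sex,
                     c(0.32, 0.68, 0, 0), horizon = 100)
    expect_true(all(abs(rowSums(unclass(tr)) - 1) < 1e-9))
    expect_true(all(unclass(tr) >= -1e-12))
    expect_true(all(diff(tr[, 4]) >= -1e-12))
  }
})

test_that("the scalar scenario path agrees with the public matrix path", {
  p <- default_parameters()
  scn <- make_intervention(p, initial_adherent_share = 0.6, prob_B_to_A = 0.1)
  arm <- chwcea:::evaluate_arm(scn, p, "female", 5, 100)
  dyn <- attr(arm, "dynamics")
  tr <- run_cohort(p$rates, dyn, 5, "female", c(0.4, 0.6, 0, 0), 100)
  expect_equal(unclass(arm$trajectory), unclass(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(arm$lifetime_qalys, accrue_qalys(tr, p$utilities), tolerance = 1e-12)
  costs <- accrue_costs(tr, p$costs, scn$program_cost_per_person_year,
                        rule = scn$program_cost_rule)
  expect_equal(arm$lifetime_cost_zar, costs$total, tolerance = 1e-12)
})

test_that("share-schedule tracking solves switching probabilities that replay exactly", {
  p <- default_parameters()
  # stationary fixed point at the baseline share
  base <- make_baseline(p, initial_adherent_share = 0.68, prob_B_to_A = 0.05)
  sched <- share_schedule(base, 100)
  dyn <- share_schedule_to_dynamics(sched, p$rates, "male", 12, prob_B_to_A = 0.05)
  expect_true(all(abs(attr(dyn, "achieved_share") - 0.68) <= 0.01))
  # intervention ramp replayed through the public engine reproduces the schedule
  scn <- make_intervention(p, initial_adherent_share = 0.53, prob_B_to_A = 0.02)
  sched2 <- share_schedule(scn, 100)
  dyn2 <- share_schedule_to_dynamics(sched2, p$rates, "male", 12, prob_B_to_A = 0.02)
  expect_identical(sum(attr(dyn2, "clamped")), 0L)
  tr <- run_cohort(p$rates, dyn2, 12, "male", c(1 - sched2[1], sched2[1], 0, 0), 100)
  replayed <- chwcea:::adherent_share(unclass(tr), "epilepsy")
  expect_true(all(abs(replayed - sched2) <= 0.01))
  # a one-cycle jump to full adherence needs (near-)certain switching
  jump <- share_schedule_to_dynamics(c(0, rep(1, 100)), flat_tables(), "male", 0,
                                     prob_B_to_A = 0)
  expect_equal(jump$prob_A_to_B[1], 1, tolerance = 1e-9)
  # unreachable schedules fall back to nearest-feasible with a warning
  hard <- flat_tables(mort_nonadherent = 0.2, mort_adherent = 0.1,
                      remission_male = 0.3)
  expect_warning(share_schedule_to_dynamics(c(0.5, rep(1, 50)), hard, "male", 0,
                                            prob_B_to_A = 0.2),
                 "nearest feasible")
})

test_that("raising A->B switching never lowers lifetime QALYs under ordered fixtures", {
  for (seed in 1:6) {
    fx <- generate_fixture(seed = seed, bands = 3, ordering_constraints = TRUE)
    set.seed(seed + 100)
    p1 <- runif(1, 0, 0.3); p2 <- p1 + runif(1, 0, 0.4)
    q <- vapply(c(p1, p2), function(pab) {
      tr <- run_cohort(fx$rates, adherence_dynamics(pab, 0.05), 20, "female",
                       c(0.5, 0.5, 0, 0), 60)
      accrue_qalys(tr, fx$utilities)
    }, numeric(1))
    expect_gte(q[2], q[1] - 1e-10)
  }
})
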