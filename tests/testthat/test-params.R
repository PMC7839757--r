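test_that("packaged fixture loads with the published rates accessible by age and sex", {
  p <- default_parameters()
  expect_s3_class(p$rates, "rate_tables")
  expect_identical(lookup_rate(p$rates, "mortality_nonadherent", 30), 0.060)
  expect_identical(lookup_rate(p$rates, "mortality_adherent", 30), 0.012)
  expect_identical(lookup_rate(p$rates, "remission", 35, "male"), 0.000)
  expect_identical(lookup_rate(p$rates, "remission", 35, "female"), 0.031)
  expect_identical(lookup_rate(p$rates, "background_mortality", 87, "female"), 0.107)
  expect_identical(lookup_rate(p$rates, "background_mortality", 87, "male"), 0.118)
  expect_identical(lookup_rate(p$rates, "relapse", 22), 0.004)
  # ages above the open-ended top band reuse it
  expect_identical(lookup_rate(p$rates, "mortality_nonadherent", 200), 0.074)
  expect_identical(lookup_rate(p$rates, "background_mortality", 130, "male"), 0.190)
  expect_error(lookup_rate(p$rates, "mortality_nonadherent", -1), "non-negative")
  expect_error(lookup_rate(p$rates, "no_such_rate", 10), "unknown rate")
})

test_that("age-band validation rejects gaps, overlaps and out-of-range probabilities", {
  expect_error(age_band_table(c(0, 7), c(5, Inf), data.frame(value = c(0.1, 0.2))),
               "gap in age bands")
  expect_error(age_band_table(c(0, 4), c(5, Inf), data.frame(value = c(0.1, 0.2))),
               "overlapping")
  expect_error(age_band_table(c(5, 20), c(19, Inf), data.frame(value = c(0.1, 0.2))),
               "start at age 0")
  expect_error(age_band_table(c(0, 20), c(19, 80), data.frame(value = c(0.1, 0.2))),
               "reach age 120")
  bad <- flat_tables()
  bad$remission$male <- 1.2
  expect_error(chwcea:::validate_rate_tables(bad), "outside \\[0,1\\]")
  # adherent mortality must not exceed nonadherent
  expect_error(flat_tables(mort_nonadherent = 0.01, mort_adherent = 0.02),
               "mortality_nonadherent below")
})

test_that("utilities derive from disability weights with the published values", {
  u <- derive_utilities(disability_weights())
  expect_equal(unname(u["nonadherent"]), 0.58)
  expect_equal(unname(u["adherent"]), 0.8292)
  expect_equal(unname(u["remission"]), 0.928)
  expect_identical(unname(u["death"]), 0)
  # ordering of the packaged fixture
  expect_true(u["remission"] > u["adherent"] &&
                u["adherent"] > u["nonadherent"] && u["nonadherent"] > 0)
  # identity case: no disability means full health in every living state
  u0 <- derive_utilities(disability_weights(0, 0, 0, 0.6))
  expect_equal(unname(u0[1:3]), c(1, 1, 1))
  expect_error(disability_weights(untreated = 1.2), "\\[0,1\\]")
})

test_that("increasing any disability weight weakly decreases the matching utility", {
  set.seed(42)
  for (i in 1:25) {
    w <- sort(runif(3, 0, 0.9))
    dw <- disability_weights(w[3], w[1], w[2], runif(1))
    u <- derive_utilities(dw)
    eps <- runif(1, 0, 1 - w[3])
    dw2 <- disability_weights(w[3] + eps, w[1], w[2], dw$adherent_seizure_free_share)
    expect_lte(derive_utilities(dw2)["nonadherent"], u["nonadherent"])
    eps2 <- runif(1, 0, (w[2] - w[1]))
    dw3 <- disability_weights(w[3], w[1] + eps2, w[2], dw$adherent_seizure_free_share)
    u3 <- derive_utilities(dw3)
    expect_lte(u3["remission"], u["remission"])
    expect_lte(u3["adherent"], u["adherent"])
  }
})

test_that("budget totals and currency conversion reproduce the published economics", {
  p <- default_parameters()
  expect_identical(total_budget(p$costs), 664320)
  expect_identical(round(convert_currency(664320, p$costs)), 123250)
  expect_identical(round(convert_currency(13215, p$costs, from = "intl")), 71229)
  expect_identical(convert_currency(0, p$costs), 0)
  # round trip at full precision
  x <- 12345.6789
  expect_equal(convert_currency(convert_currency(x, p$costs), p$costs, from = "intl"),
               x, tolerance = 1e-12)
  empty <- p$costs
  empty$budget_items <- empty$budget_items[0, ]
  expect_identical(total_budget(empty), 0)
  one <- p$costs
  one$budget_items <- data.frame(item = "x", amount_zar = 100)
  expect_identical(total_budget(one), 100)
  neg <- p$costs
  neg$budget_items$amount_zar[1] <- -5
  expect_error(total_budget(neg), "negative budget item")
  bad <- p$costs
  bad$exchange_rate_zar_per_intl_dollar <- 0
  expect_error(convert_currency(1, bad), "positive")
})

test_that("cost model invariants reject malformed inputs", {
  p <- default_parameters()
  sc <- p$costs$state_cost
  sc$low[sc$state == "nonadherent"] <- 17000  # central below low
  expect_error(cost_model(sc, p$costs$budget_items, 5.39, 13215), "low, high")
  sc2 <- p$costs$state_cost
  sc2$high[sc2$state == "adherent"] <- sc2$central[sc2$state == "adherent"] * 1.4
  expect_error(cost_model(sc2, p$costs$budget_items, 5.39, 13215), "15%")
  sc3 <- p$costs$state_cost
  sc3[sc3$state == "remission", c("central", "low", "high")] <- c(10, 8.5, 11.5)
  expect_error(cost_model(sc3, p$costs$budget_items, 5.39, 13215), "zero annual cost")
})

test_that("writing then loading a parameter set reproduces it bit-exactly", {
  dir1 <- withr::local_tempdir()
  p <- default_parameters()
  write_parameters(p, dir1)
  p2 <- load_parameters(dir1)
  expect_identical(p2$rates$mortality_nonadherent, p$rates$mortality_nonadherent)
  expect_identical(p2$rates$remission, p$rates$remission)
  expect_identical(p2$rates$background_mortality, p$rates$background_mortality)
  expect_identical(p2$rates$relapse, p$rates$relapse)
  expect_identical(p2$costs$state_cost, p$costs$state_cost)
  expect_identical(p2$costs$budget_items$amount_zar, p$costs$budget_items$amount_zar)
  expect_identical(unclass(p2$utilities), unclass(p$utilities))
  expect_identical(p2$defaults, p$defaults)
  # and for a randomised fixture
  fx <- generate_fixture(seed = 7, bands = 4)
  dir2 <- withr::local_tempdir()
  write_parameters(fx, dir2)
  fx2 <- load_parameters(dir2)
  expect_identical(fx2$rates$mortality_nonadherent, fx$rates$mortality_nonadherent)
  expect_identical(fx2$rates$background_mortality, fx$rates$background_mortality)
  expect_equal(fx2$rates$relapse_split_to_adherent, fx$rates$relapse_split_to_adherent)
})

test_that("loading reports missing files and malformed bands with context", {
  dir <- withr::local_tempdir()
  expect_error(load_parameters(file.path(dir, "nope")), "not found")
  p <- default_parameters()
  write_parameters(p, dir)
  tsv <- file.path(dir, "epilepsy_rates.tsv")
  lines <- readLines(tsv)
  lines[2] <- sub("^0-5", "banana", lines[2])
  writeLines(lines, tsv)
  expect_error(load_parameters(dir), "malformed age band 'banana'")
  expect_error(validate_parameters(structure(list(), class = "foo")))
})
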