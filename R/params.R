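#' @keywords internal
"_PACKAGE"

## Internal state bookkeeping ------------------------------------------------

# Canonical state order used everywhere: occupancy vectors, matrix rows/cols.
.states <- c("nonadherent", "adherent", "remission", "death")
.state_codes <- c(nonadherent = "A", adherent = "B", remission = "C", death = "D")

.pkg_env <- new.env(parent = emptyenv())

#' Health states of the adherence model
#'
#' The model distinguishes four states for a person already diagnosed with
#' epilepsy: nonadherent to anti-seizure medication (A), adherent (B),
#' remission -- off medication and seizure-free for a year (C), and death (D,
#' absorbing). The returned order is the canonical order of every occupancy
#' vector and transition matrix in the package.
#'
#' @return Named character vector of length four; names are the conventional
#'   single-letter state codes, values the state labels.
#' @examples
#' health_states()
#' @export
health_states <- function() {
  stats::setNames(.states, .state_codes)
}

## Age-band tables ------------------------------------------------------------

# "29-49" -> c(29, 49); "50+" -> c(50, Inf); "0" -> c(0, 0)
parse_band <- function(x) {
  x <- trimws(x)
  out <- matrix(NA_real_, length(x), 2, dimnames = list(NULL, c("lower", "upper")))
  for (i in seq_along(x)) {
    b <- x[i]
    if (grepl("^[0-9]+\\+$", b)) {
      out[i, ] <- c(as.numeric(sub("\\+$", "", b)), Inf)
    } else if (grepl("^[0-9]+-[0-9]+$", b)) {
      out[i, ] <- as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", b)) {
      out[i, ] <- c(as.numeric(b), as.numeric(b))
    } else {
      stop(sprintf("malformed age band '%s' (row %d)", b, i), call. = FALSE)
    }
  }
  out
}

format_band <- function(lower, upper) {
  ifelse(is.infinite(upper), paste0(lower, "+"),
         ifelse(lower == upper, as.character(lower), paste0(lower, "-", upper)))
}

#' Build an age-band lookup table
#'
#' @param lower,upper Integer vectors of inclusive band edges; the top band may
#'   be open-ended (`upper = Inf`). Bands must start at age 0, be disjoint and
#'   leave no gaps, so that ages 0--120 (and beyond, via the open top band) are
#'   jointly covered.
#' @param values A data frame (or coercible) of one or more numeric value
#'   columns, one row per band.
#' @param what Label used in validation messages.
#' @return A `data.frame` of class `age_band_table` with columns `lower`,
#'   `upper` and the value columns.
#' @export
age_band_table <- function(lower, upper, values, what = "table") {
  values <- as.data.frame(values)
  if (length(lower) != length(upper) || nrow(values) != length(lower))
    stop(sprintf("%s: band edges and values differ in length", what), call. = FALSE)
  df <- cbind(data.frame(lower = as.numeric(lower), upper = as.numeric(upper)), values)
  class(df) <- c("age_band_table", "data.frame")
  validate_age_bands(df, what)
  df
}

validate_age_bands <- function(df, what = "table") {
  n <- nrow(df)
  if (n < 1L) stop(sprintf("%s: no age bands", what), call. = FALSE)
  if (any(df$lower < 0)) stop(sprintf("%s: negative band edge", what), call. = FALSE)
  if (any(df$upper < df$lower))
    stop(sprintf("%s: band upper edge below lower edge", what), call. = FALSE)
  if (is.unsorted(df$lower, strictly = TRUE))
    stop(sprintf("%s: bands out of order", what), call. = FALSE)
  if (df$lower[1] != 0)
    stop(sprintf("%s: gap in age bands (coverage must start at age 0)", what), call. = FALSE)
  if (n > 1L) {
    step <- df$lower[-1] - df$upper[-n]
    if (any(step > 1)) {
      j <- which(step > 1)[1]
      stop(sprintf("%s: gap in age bands (after band %s)", what,
                   format_band(df$lower[j], df$upper[j])), call. = FALSE)
    }
    if (any(step < 1))
      stop(sprintf("%s: overlapping age bands", what), call. = FALSE)
  }
  if (is.finite(df$upper[n]) && df$upper[n] < 120)
    stop(sprintf("%s: gap in age bands (coverage must reach age 120)", what), call. = FALSE)
  invisible(df)
}

band_value <- function(df, age, col) {
  i <- findInterval(age, df$lower)
  df[[col]][i]
}

## Rate tables ----------------------------------------------------------------

#' Annual transition-probability tables
#'
#' Bundles the age-band tables driving the Markov model: epilepsy mortality for
#' nonadherent and adherent individuals, remission probability by age and sex
#' (identical from the adherent and nonadherent states), all-cause background
#' mortality by age and sex (applied in remission), and the annual relapse
#' probability out of remission, split between the adherent and nonadherent
#' states by `relapse_split_to_adherent`.
#'
#' All values are annual transition probabilities in \[0, 1\]; nonadherent
#' mortality must weakly dominate adherent mortality in every band (the model
#' assumes nonadherence raises epilepsy mortality).
#'
#' @param mortality_nonadherent,mortality_adherent `age_band_table`s with a
#'   `value` column.
#' @param remission,background_mortality `age_band_table`s with `male` and
#'   `female` columns.
#' @param relapse `age_band_table` with a `value` column.
#' @param relapse_split_to_adherent Fraction of relapses returning to the
#'   adherent state (0.5 in the packaged fixture).
#' @param mortality_multipliers Optional named numeric, the multipliers applied
#'   to the published epilepsy mortality to obtain the nonadherent/adherent
#'   rates (2.5 and 0.5 in the packaged fixture); carried as metadata.
#' @return An object of class `rate_tables`.
#' @seealso [lookup_rate()], [default_parameters()]
#' @export
rate_tables <- function(mortality_nonadherent, mortality_adherent, remission,
                        background_mortality, relapse,
                        relapse_split_to_adherent = 0.5,
                        mortality_multipliers = NULL) {
  obj <- structure(
    list(mortality_nonadherent = mortality_nonadherent,
         mortality_adherent = mortality_adherent,
         remission = remission,
         background_mortality = background_mortality,
         relapse = relapse,
         relapse_split_to_adherent = relapse_split_to_adherent,
         mortality_multipliers = mortality_multipliers),
    class = "rate_tables")
  validate_rate_tables(obj)
  obj
}

validate_rate_tables <- function(tables) {
  stopifnot(inherits(tables, "rate_tables"))
  check_prob <- function(df, cols, what) {
    validate_age_bands(df, what)
    for (cl in cols) {
      v <- df[[cl]]
      if (is.null(v)) stop(sprintf("%s: missing column '%s'", what, cl), call. = FALSE)
      bad <- which(!is.finite(v) | v < 0 | v > 1)
      if (length(bad))
        stop(sprintf("%s: probability outside [0,1] in band %s (column %s, value %s)",
                     what, format_band(df$lower[bad[1]], df$upper[bad[1]]), cl,
                     format(v[bad[1]])), call. = FALSE)
    }
  }
  check_prob(tables$mortality_nonadherent, "value", "mortality_nonadherent")
  check_prob(tables$mortality_adherent, "value", "mortality_adherent")
  check_prob(tables$remission, c("male", "female"), "remission")
  check_prob(tables$background_mortality, c("male", "female"), "background_mortality")
  check_prob(tables$relapse, "value", "relapse")
  s <- tables$relapse_split_to_adherent
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1)
    stop("relapse_split_to_adherent must be a fraction in [0,1]", call. = FALSE)
  # same band system required for the two epilepsy-mortality tables
  if (!identical(tables$mortality_nonadherent[c("lower", "upper")],
                 tables$mortality_adherent[c("lower", "upper")]))
    stop("mortality tables use different age bands", call. = FALSE)
  worse <- tables$mortality_nonadherent$value < tables$mortality_adherent$value
  if (any(worse))
    stop(sprintf(
      "mortality_nonadherent below mortality_adherent in band %s",
      format_band(tables$mortality_nonadherent$lower[which(worse)[1]],
                  tables$mortality_nonadherent$upper[which(worse)[1]])), call. = FALSE)
  invisible(tables)
}

#' Look up an annual transition probability by age (and sex)
#'
#' Returns the value of the age band containing `age`; ages above the top band
#' reuse the top (open-ended) band. Vectorised over `age`.
#'
#' @param tables A [rate_tables()] object.
#' @param quantity One of `"mortality_nonadherent"`, `"mortality_adherent"`,
#'   `"remission"`, `"background_mortality"`, `"relapse"`.
#' @param age Integer age(s) in years, non-negative.
#' @param sex `"male"` or `"female"`; required for the sex-specific tables
#'   (`remission`, `background_mortality`), ignored otherwise.
#' @return Numeric vector of annual probabilities.
#' @examples
#' p <- default_parameters()
#' lookup_rate(p$rates, "mortality_nonadherent", age = 30)  # 0.060
#' lookup_rate(p$rates, "background_mortality", age = 87, sex = "female")
#' @export
lookup_rate <- function(tables, quantity, age, sex = NULL) {
  stopifnot(inherits(tables, "rate_tables"))
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  sexed <- c("remission", "background_mortality")
  known <- c("mortality_nonadherent", "mortality_adherent", sexed, "relapse")
  if (!quantity %in% known)
    stop(sprintf("unknown rate quantity '%s'", quantity), call. = FALSE)
  col <- "value"
  if (quantity %in% sexed) {
    sex <- match.arg(sex, c("male", "female"))
    col <- sex
  }
  band_value(tables[[quantity]], age, col)
}

## Disability weights and utilities -------------------------------------------

#' Disability weights for epilepsy health states
#'
#' Global-burden-of-disease disability weights (DW, health loss in \[0, 1\])
#' for untreated epilepsy, treated seizure-free epilepsy and treated epilepsy
#' with seizures, plus the share of adherent individuals assumed seizure-free
#' (the remainder being treated but still experiencing seizures).
#'
#' @param untreated,treated_seizure_free,treated_with_seizures DWs in \[0, 1\].
#' @param adherent_seizure_free_share Fraction in \[0, 1\].
#' @return An object of class `disability_weights`.
#' @export
disability_weights <- function(untreated = 0.42, treated_seizure_free = 0.072,
                               treated_with_seizures = 0.319,
                               adherent_seizure_free_share = 0.60) {
  vals <- c(untreated = untreated, treated_seizure_free = treated_seizure_free,
            treated_with_seizures = treated_with_seizures,
            adherent_seizure_free_share = adherent_seizure_free_share)
  if (any(!is.finite(vals) | vals < 0 | vals > 1))
    stop("disability weights and shares must lie in [0,1]", call. = FALSE)
  structure(as.list(vals), class = "disability_weights")
}

#' Derive per-state utilities from disability weights
#'
#' Utility is one minus the disability weight. The adherent state mixes the
#' treated seizure-free and treated-with-seizures weights according to the
#' assumed seizure-free share; remission uses the treated seizure-free weight;
#' death has utility 0.
#'
#' @param dw A [disability_weights()] object.
#' @return A named numeric vector of class `utility_set` over the four states
#'   (in [health_states()] order).
#' @examples
#' derive_utilities(disability_weights())  # 0.58, 0.8292, 0.928, 0
#' @export
derive_utilities <- function(dw) {
  stopifnot(inherits(dw, "disability_weights"))
  s <- dw$adherent_seizure_free_share
  u <- c(nonadherent = 1 - dw$untreated,
         adherent = 1 - (s * dw$treated_seizure_free +
                           (1 - s) * dw$treated_with_seizures),
         remission = 1 - dw$treated_seizure_free,
         death = 0)
  structure(u, class = "utility_set")
}

utility_vector <- function(utilities) {
  stopifnot(inherits(utilities, "utility_set"))
  as.numeric(utilities[.states])
}

## Cost model -----------------------------------------------------------------

#' Annual cost model
#'
#' Per-state annual societal costs (central estimate with low/high bounds,
#' nominally +/-15%), the itemised annual intervention budget, and economic
#' constants: the ZAR per international-dollar exchange rate, GDP per capita in
#' international dollars, and the day count used to express GDP per capita per
#' day.
#'
#' @param state_cost Data frame with columns `state`, `central`, `low`, `high`
#'   (ZAR per annum); remission and death must cost 0.
#' @param budget_items Data frame with columns `item`, `amount_zar`.
#' @param exchange_rate_zar_per_intl_dollar Positive scalar.
#' @param gdp_per_capita_intl_dollar Positive scalar.
#' @param working_days_per_year_for_daily_gdp Positive integer (365 reproduces
#'   the published 195 ZAR/day).
#' @param cost_items Optional itemisation of the per-state costs (reporting
#'   only; the state totals are canonical).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(state_cost, budget_items,
                       exchange_rate_zar_per_intl_dollar,
                       gdp_per_capita_intl_dollar,
                       working_days_per_year_for_daily_gdp = 365L,
                       cost_items = NULL) {
  obj <- structure(
    list(state_cost = as.data.frame(state_cost),
         budget_items = as.data.frame(budget_items),
         exchange_rate_zar_per_intl_dollar = exchange_rate_zar_per_intl_dollar,
         gdp_per_capita_intl_dollar = gdp_per_capita_intl_dollar,
         working_days_per_year_for_daily_gdp = working_days_per_year_for_daily_gdp,
         cost_items = cost_items),
    class = "cost_model")
  validate_cost_model(obj)
  obj
}

validate_cost_model <- function(cost, band_tolerance = 2) {
  stopifnot(inherits(cost, "cost_model"))
  sc <- cost$state_cost
  need <- c("state", "central", "low", "high")
  if (!all(need %in% names(sc)))
    stop("state_cost must have columns state, central, low, high", call. = FALSE)
  if (!setequal(sc$state, .states))
    stop("state_cost must cover exactly the four model states", call. = FALSE)
  if (any(sc$central < 0 | sc$low < 0 | sc$high < 0))
    stop("state costs must be non-negative", call. = FALSE)
  if (any(sc$central < sc$low | sc$central > sc$high))
    stop("central state cost outside its [low, high] band", call. = FALSE)
  # the published bounds are +/-15% of the central value, up to rounding
  pos <- sc$central > 0
  if (any(abs(sc$low[pos] - 0.85 * sc$central[pos]) > band_tolerance) ||
      any(abs(sc$high[pos] - 1.15 * sc$central[pos]) > band_tolerance))
    stop("state cost bounds deviate from +/-15% beyond rounding", call. = FALSE)
  zero <- sc$state %in% c("remission", "death")
  if (any(sc$central[zero] != 0))
    stop("remission and death must have zero annual cost", call. = FALSE)
  bi <- cost$budget_items
  if (!all(c("item", "amount_zar") %in% names(bi)))
    stop("budget_items must have columns item, amount_zar", call. = FALSE)
  if (any(bi$amount_zar < 0)) stop("negative budget item amount", call. = FALSE)
  if (!is.numeric(cost$exchange_rate_zar_per_intl_dollar) ||
      cost$exchange_rate_zar_per_intl_dollar <= 0)
    stop("exchange rate must be positive", call. = FALSE)
  if (cost$gdp_per_capita_intl_dollar <= 0)
    stop("GDP per capita must be positive", call. = FALSE)
  if (cost$working_days_per_year_for_daily_gdp < 1)
    stop("working days per year must be a positive integer", call. = FALSE)
  invisible(cost)
}

state_cost_vector <- function(cost, level = c("central", "low", "high")) {
  level <- match.arg(level)
  sc <- cost$state_cost
  as.numeric(sc[[level]][match(.states, sc$state)])
}

#' Total annual intervention budget
#'
#' @param cost A [cost_model()] object.
#' @return Sum of the itemised annual budget, in ZAR.
#' @examples
#' total_budget(default_parameters()$costs)  # 664320
#' @export
total_budget <- function(cost) {
  stopifnot(inherits(cost, "cost_model"))
  if (any(cost$budget_items$amount_zar < 0))
    stop("negative budget item amount", call. = FALSE)
  sum(as.numeric(cost$budget_items$amount_zar))
}

#' Convert between ZAR and international dollars
#'
#' Divides by the exchange rate when converting ZAR to international dollars
#' and multiplies when converting back. Full precision is kept; rounding to
#' whole currency units happens only in the reporting layer.
#'
#' @param amount Numeric amount(s).
#' @param cost A [cost_model()] object carrying the exchange rate.
#' @param from Currency of `amount`: `"zar"` (default) or `"intl"`.
#' @return Converted amount(s).
#' @examples
#' p <- default_parameters()
#' convert_currency(664320, p$costs)            # ~123250 international dollars
#' convert_currency(13215, p$costs, from = "intl")  # ~71229 ZAR
#' @export
convert_currency <- function(amount, cost, from = c("zar", "intl")) {
  stopifnot(inherits(cost, "cost_model"))
  from <- match.arg(from)
  rate <- cost$exchange_rate_zar_per_intl_dollar
  if (!is.finite(rate) || rate <= 0) stop("exchange rate must be positive", call. = FALSE)
  if (from == "zar") amount / rate else amount * rate
}

#' Cost-effectiveness thresholds
#'
#' @param wtp_intl_dollar Willingness-to-pay per QALY in international dollars.
#' @param gdp_threshold_intl_dollar One-times-GDP-per-capita threshold.
#' @return An object of class `cea_thresholds`.
#' @export
thresholds <- function(wtp_intl_dollar = 2154, gdp_threshold_intl_dollar = 13215) {
  if (wtp_intl_dollar <= 0 || gdp_threshold_intl_dollar <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(wtp_intl_dollar = wtp_intl_dollar,
                 gdp_threshold_intl_dollar = gdp_threshold_intl_dollar),
            class = "cea_thresholds")
}

## Parameter file IO ----------------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
                             call. = FALSE),
    warning = function(w) stop(sprintf("parse error in %s: %s", path, conditionMessage(w)),
                               call. = FALSE))
}

band_table_from_file <- function(path, cols, what) {
  df <- read_tsv_checked(path)
  missing <- setdiff(c("band", names(cols)), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s in %s", what,
                 paste(missing, collapse = ", "), path), call. = FALSE)
  edges <- parse_band(df$band)
  vals <- df[names(cols)]
  names(vals) <- unname(cols)
  age_band_table(edges[, "lower"], edges[, "upper"], vals, what = what)
}

#' Load a parameter set from a directory
#'
#' Reads the delimited rate tables (`epilepsy_rates.tsv`,
#' `background_rates.tsv`), state costs (`state_costs.tsv`, optionally
#' `cost_items.tsv`), intervention budget (`budget.tsv`) and scalar
#' configuration (`economics.yaml`; schema in `config-schema.json`) and
#' validates every type invariant. Violations are reported with their table
#' and band context.
#'
#' @param dir Directory containing the parameter files.
#' @return A list of class `cea_params` with components `rates`
#'   ([rate_tables()]), `dw` ([disability_weights()]), `utilities` (derived
#'   [utility_set][derive_utilities()]), `costs` ([cost_model()]),
#'   `thresholds` ([thresholds()]) and `defaults` (scalar scenario defaults:
#'   adherence shares, ramp, program cost, horizon).
#' @seealso [default_parameters()], [write_parameters()]
#' @export
load_parameters <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("parameter directory not found: %s", dir), call. = FALSE)
  epi <- read_tsv_checked(file.path(dir, "epilepsy_rates.tsv"))
  edges <- parse_band(epi$band)
  need <- c("mortality_nonadherent", "mortality_adherent", "remission_male", "remission_female")
  missing <- setdiff(need, names(epi))
  if (length(missing))
    stop(sprintf("epilepsy_rates.tsv: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  mk <- function(vals, what) age_band_table(edges[, 1], edges[, 2], vals, what = what)
  bg <- band_table_from_file(file.path(dir, "background_rates.tsv"),
                             c(mortality_male = "male", mortality_female = "female"),
                             "background_mortality")
  rl <- band_table_from_file(file.path(dir, "background_rates.tsv"),
                             c(relapse = "value"), "relapse")

  cfg_path <- file.path(dir, "economics.yaml")
  if (!file.exists(cfg_path)) stop("parameter file not found: economics.yaml", call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(cfg_path),
                  error = function(e) stop(sprintf("parse error in %s: %s", cfg_path,
                                                   conditionMessage(e)), call. = FALSE))
  for (key in c("disability_weights", "relapse_split_to_adherent",
                "exchange_rate_zar_per_intl_dollar", "gdp_per_capita_intl_dollar",
                "thresholds", "adherence", "program_cost_per_person_year_zar",
                "horizon_cycles"))
    if (is.null(cfg[[key]]))
      stop(sprintf("economics.yaml: missing required key '%s'", key), call. = FALSE)

  mult <- NULL
  if (!is.null(cfg$mortality_multiplier_nonadherent))
    mult <- c(nonadherent = cfg$mortality_multiplier_nonadherent,
              adherent = cfg$mortality_multiplier_adherent)
  rates <- rate_tables(
    mortality_nonadherent = mk(data.frame(value = epi$mortality_nonadherent),
                               "mortality_nonadherent"),
    mortality_adherent = mk(data.frame(value = epi$mortality_adherent),
                            "mortality_adherent"),
    remission = mk(data.frame(male = epi$remission_male, female = epi$remission_female),
                   "remission"),
    background_mortality = bg,
    relapse = rl,
    relapse_split_to_adherent = cfg$relapse_split_to_adherent,
    mortality_multipliers = mult)

  dwc <- cfg$disability_weights
  dw <- disability_weights(dwc$untreated, dwc$treated_seizure_free,
                           dwc$treated_with_seizures, dwc$adherent_seizure_free_share)

  items_path <- file.path(dir, "cost_items.tsv")
  costs <- cost_model(
    state_cost = read_tsv_checked(file.path(dir, "state_costs.tsv")),
    budget_items = read_tsv_checked(file.path(dir, "budget.tsv")),
    exchange_rate_zar_per_intl_dollar = cfg$exchange_rate_zar_per_intl_dollar,
    gdp_per_capita_intl_dollar = cfg$gdp_per_capita_intl_dollar,
    working_days_per_year_for_daily_gdp = cfg$working_days_per_year_for_daily_gdp %||% 365L,
    cost_items = if (file.exists(items_path)) read_tsv_checked(items_path))

  th <- thresholds(cfg$thresholds$wtp_intl_dollar, cfg$thresholds$gdp_threshold_intl_dollar)

  structure(list(rates = rates, dw = dw, utilities = derive_utilities(dw),
                 costs = costs, thresholds = th,
                 defaults = list(
                   initial_adherent_share = cfg$adherence$initial_adherent_share,
                   initial_adherent_share_blood_levels =
                     cfg$adherence$initial_adherent_share_blood_levels,
                   target_adherent_share = cfg$adherence$target_adherent_share,
                   ramp_years = cfg$adherence$ramp_years,
                   program_cost_per_person_year_zar = cfg$program_cost_per_person_year_zar,
                   horizon_cycles = cfg$horizon_cycles)),
            class = "cea_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num_fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Write a parameter set to a directory
#'
#' Inverse of [load_parameters()]: writing then re-loading reproduces every
#' value bit-exactly (numbers are written with enough digits to round-trip the
#' packaged and generated fixtures).
#'
#' @param params A `cea_params` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(params, dir) {
  stopifnot(inherits(params, "cea_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- params$rates
  wtsv <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], num_fmt)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtsv(data.frame(band = format_band(r$mortality_nonadherent$lower,
                                     r$mortality_nonadherent$upper),
                  mortality_nonadherent = r$mortality_nonadherent$value,
                  mortality_adherent = r$mortality_adherent$value,
                  remission_male = r$remission$male,
                  remission_female = r$remission$female),
       "epilepsy_rates.tsv")
  wtsv(data.frame(band = format_band(r$background_mortality$lower,
                                     r$background_mortality$upper),
                  mortality_male = r$background_mortality$male,
                  mortality_female = r$background_mortality$female,
                  relapse = r$relapse$value),
       "background_rates.tsv")
  wtsv(params$costs$state_cost, "state_costs.tsv")
  wtsv(params$costs$budget_items, "budget.tsv")
  if (!is.null(params$costs$cost_items)) wtsv(params$costs$cost_items, "cost_items.tsv")
  d <- params$defaults
  cfg <- list(
    disability_weights = params$dw[c("untreated", "treated_seizure_free",
                                     "treated_with_seizures", "adherent_seizure_free_share")],
    relapse_split_to_adherent = r$relapse_split_to_adherent,
    exchange_rate_zar_per_intl_dollar = params$costs$exchange_rate_zar_per_intl_dollar,
    gdp_per_capita_intl_dollar = params$costs$gdp_per_capita_intl_dollar,
    working_days_per_year_for_daily_gdp = params$costs$working_days_per_year_for_daily_gdp,
    thresholds = unclass(params$thresholds),
    adherence = list(
      initial_adherent_share = d$initial_adherent_share,
      initial_adherent_share_blood_levels = d$initial_adherent_share_blood_levels,
      target_adherent_share = d$target_adherent_share,
      ramp_years = d$ramp_years),
    program_cost_per_person_year_zar = d$program_cost_per_person_year_zar,
    horizon_cycles = d$horizon_cycles)
  if (!is.null(r$mortality_multipliers)) {
    cfg$mortality_multiplier_nonadherent <- unname(r$mortality_multipliers["nonadherent"])
    cfg$mortality_multiplier_adherent <- unname(r$mortality_multipliers["adherent"])
  }
  yaml::write_yaml(cfg, file.path(dir, "economics.yaml"),
                   precision = 15L)
  invisible(dir)
}

#' Packaged parameter set
#'
#' Loads (and memoises) the parameter fixture shipped with the package: the
#' published age/sex rate tables, disability weights, state costs, intervention
#' budget and economic constants for the rural South African sub-district the
#' model describes.
#'
#' @return A `cea_params` object; see [load_parameters()].
#' @export
default_parameters <- function() {
  if (is.null(.pkg_env$default_params)) {
    dir <- system.file("extdata", package = "chwcea")
    .pkg_env$default_params <- load_parameters(dir)
  }
  .pkg_env$default_params
}

#' Validate a parameter set
#'
#' Re-runs every structural invariant check on an assembled parameter set and
#' returns a summary of the checks performed. Used by the command-line
#' `validate-params` stage.
#'
#' @param params A `cea_params` object.
#' @return Invisibly, a character vector describing the checks passed.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cea_params"))
  validate_rate_tables(params$rates)
  validate_cost_model(params$costs)
  u <- utility_vector(params$utilities)
  if (any(u < 0 | u > 1)) stop("utilities outside [0,1]", call. = FALSE)
  if (u[4] != 0) stop("death utility must be 0", call. = FALSE)
  checks <- c("age-band coverage (0-120, no gaps, no overlaps)",
              "transition probabilities within [0,1]",
              "nonadherent mortality dominates adherent mortality",
              "state cost bounds within +/-15% of central (up to rounding)",
              "remission and death cost zero",
              "utilities within [0,1], death at 0",
              "positive exchange rate, GDP and thresholds")
  invisible(checks)
}
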