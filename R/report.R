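## Human-readable results bundle: JSON + delimited tables + markdown report.
## Display rounding here only: whole currency units, QALYs to two decimals.

#' Write a results bundle for a calibrated analysis
#'
#' Produces, under `dir`: `results.json` (calibration, base-case and
#' sensitivity results at full precision), `sensitivity.tsv` (the sensitivity
#' table), `trajectory_<sex>.tsv` (per-cycle occupancies for both arms), and
#' `report.md` -- a markdown report mirroring the published presentation:
#' intervention budget, health-state utilities, per-sex base-case and
#' sensitivity ICERs (currency to whole units, QALYs to two decimals). The
#' report footer records the parameter-fixture checksums and the calibrated
#' configuration, so a run is auditable and reproducible.
#'
#' @param fit A `cea_fit` from [calibrate()].
#' @param dir Output directory (created if needed).
#' @param sens Optionally a precomputed [run_sensitivity()] report.
#' @param params_dir Directory of parameter files to checksum (defaults to the
#'   packaged fixture).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(fit, dir, sens = NULL,
                          params_dir = system.file("extdata", package = "chwcea")) {
  stopifnot(inherits(fit, "cea_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sens)) sens <- run_sensitivity(fit)
  params <- fit$params

  paths <- character(0)
  # JSON, full precision
  json_path <- file.path(dir, "results.json")
  payload <- list(
    calibration = list(entry_age = fit$entry_age,
                       parameters = lapply(fit$par, as.list),
                       loss = fit$loss, targets = fit$targets,
                       achieved = fit$achieved, settings = fit$settings),
    sensitivity = sens$table)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, json_path)

  tsv_path <- file.path(dir, "sensitivity.tsv")
  utils::write.table(sens$table, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tsv_path)

  for (sex in names(fit$arms)) {
    res <- fit$arms[[sex]]$result
    tr_path <- file.path(dir, sprintf("trajectory_%s.tsv", sex))
    b <- as.data.frame(res$comparator$trajectory)
    i <- as.data.frame(res$intervention$trajectory)
    names(b)[-(1:2)] <- paste0("baseline_", names(b)[-(1:2)])
    names(i)[-(1:2)] <- paste0("intervention_", names(i)[-(1:2)])
    utils::write.table(cbind(b, i[-(1:2)]), tr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, tr_path)
  }

  md <- c(
    "# Cost-effectiveness of CHW-supported medication adherence",
    "",
    "## Annual intervention budget",
    "",
    "| Item | ZAR per annum |",
    "| --- | ---: |",
    sprintf("| %s | %s |", params$costs$budget_items$item,
            fmt_zar(params$costs$budget_items$amount_zar)),
    sprintf("| **Total** | **%s** |", fmt_zar(total_budget(params$costs))),
    "",
    sprintf("Total in international dollars: $%s per annum.",
            fmt_zar(convert_currency(total_budget(params$costs), params$costs))),
    "",
    "## Health-state utilities",
    "",
    "| State | Utility |",
    "| --- | ---: |",
    sprintf("| %s | %.4g |", .states, utility_vector(params$utilities)),
    "",
    "## Calibrated configuration",
    "",
    sprintf("- Shared entry age: %d", fit$entry_age),
    vapply(names(fit$par), function(sex)
      sprintf("- %s: initial adherent share %.4f, B->A switching %.4f",
              sex, fit$par[[sex]][["initial_adherent_share"]],
              fit$par[[sex]][["prob_B_to_A"]]), character(1)),
    sprintf("- Calibration loss (sum squared relative error): %.3g", fit$loss),
    "",
    "## Base case and one-way sensitivity",
    "",
    "| Sex | Scenario | dQALYs | dCost (ZAR) | ICER (ZAR/QALY) | ICER ($/QALY) | below WTP | below 1x GDP |",
    "| --- | --- | ---: | ---: | ---: | ---: | --- | --- |",
    sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
            sens$table$sex, sens$table$scenario, fmt_q(sens$table$delta_qalys),
            fmt_zar(sens$table$delta_cost_zar), fmt_zar(sens$table$icer_zar_per_qaly),
            fmt_zar(sens$table$icer_intl_dollar_per_qaly),
            sens$table$below_wtp, sens$table$below_gdp),
    "",
    "## Provenance",
    "")
  files <- list.files(params_dir, full.names = TRUE)
  if (length(files)) {
    sums <- tools::md5sum(files)
    md <- c(md, "Parameter fixture checksums (md5):", "",
            sprintf("- `%s` %s", basename(names(sums)), unname(sums)))
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  paths <- c(paths, md_path)
  invisible(paths)
}
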