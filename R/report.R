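#' Incremental base-case summary table
#'
#' Incremental costs, revenues and outcomes of adding PCSK9 therapy, per
#' patient, from both perspectives: health-system and payer treatment cost
#' at the scenario price and at $15,000, avoided costs, payer premium
#' revenue, and incremental QALYs, life years and CVD events.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param prices two prices for the treatment-cost rows.
#' @return A tibble with columns `quantity`, `health_system`, `payer`.
#' @export
base_case_table <- function(params = model_parameters(),
                            insurance = insurance_parameters(),
                            prices = c(14000, 15000)) {
  traces <- cohort_pair(params)
  h1 <- cea(params, price = prices[1], traces = traces)
  h2 <- cea(params, price = prices[2], traces = traces)
  p1 <- payer_result(params, insurance, price = prices[1], traces = traces)
  p2 <- payer_result(params, insurance, price = prices[2], traces = traces)
  tibble::tibble(
    quantity = c(sprintf("treatment_cost_price_%d", prices[1]),
                 sprintf("treatment_cost_price_%d", prices[2]),
                 "avoided_cost", "premium_revenue", "qaly", "life_years",
                 "cvd_events"),
    health_system = c(h1$treatment_cost, h2$treatment_cost, -h1$avoided_cost,
                      NA, h1$delta_qaly, h1$delta_life_years,
                      h1$delta_events),
    payer = c(p1$treatment_cost, p2$treatment_cost, -p1$avoided_cost,
              p1$premium_revenue, NA, NA, NA)
  )
}

#' ICER, ROI and NPV across a price grid
#'
#' Cost-effectiveness and payer return at each price. Full-precision values
#' are kept alongside display columns rounded to whole dollars (ICER, NPV)
#' and 0.1 percentage points (ROI).
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param prices annual price grid.
#' @param scenario model scenario.
#' @return A tibble with columns `price`, `icer`, `roi`, `npv` and rounded
#'   display counterparts.
#' @export
price_grid_table <- function(params = model_parameters(),
                             insurance = insurance_parameters(),
                             prices = c(500, 1000, 2500, 5000, 7500, 10000,
                                        12500, 14000, 15000),
                             scenario = NULL) {
  traces <- cohort_pair(params, scenario)
  purrr::map_dfr(prices, function(p) {
    h <- cea(params, price = p, scenario = scenario, traces = traces)
    pay <- payer_result(params, insurance, price = p, traces = traces)
    tibble::tibble(price = p, icer = h$icer, roi = pay$roi, npv = pay$npv,
                   icer_rounded = round(h$icer),
                   roi_pct_rounded = round(100 * pay$roi, 1),
                   npv_rounded = round(pay$npv))
  })
}

#' Breakeven prices from both perspectives
#'
#' The payer breakeven (NPV = 0) and the health-system breakeven at a
#' willingness-to-pay threshold, each with the ICER, ROI and NPV evaluated
#' at that price.
#'
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param wtp willingness-to-pay threshold for the health-system breakeven.
#' @return A tibble with columns `perspective`, `price`, `icer`, `roi`,
#'   `npv`.
#' @export
breakeven_table <- function(params = model_parameters(),
                            insurance = insurance_parameters(), wtp = 1e5) {
  p_payer <- payer_breakeven_price(params, insurance)
  p_hs <- wtp_breakeven_price(params, wtp)
  traces <- cohort_pair(params)
  row <- function(perspective, p) {
    h <- cea(params, price = p, traces = traces)
    pay <- payer_result(params, insurance, price = p, traces = traces)
    tibble::tibble(perspective = perspective, price = p, icer = h$icer,
                   roi = pay$roi, npv = pay$npv)
  }
  dplyr::bind_rows(row("payer_npv_zero", p_payer),
                   row(sprintf("health_system_wtp_%d", as.integer(wtp)),
                       p_hs))
}

#' Write the full report to CSV
#'
#' Writes the base-case, price-grid, breakeven, acceptability and
#' validation tables as RFC-4180 CSVs into a directory, together with a
#' YAML run manifest (seed, scenario, grids, package version, timestamp)
#' recorded for reproducibility. Given the same configuration and seed the
#' CSVs are byte-identical across runs.
#'
#' @param out_dir output directory (created if missing).
#' @param params A `pcsk9_params` object.
#' @param insurance A `pcsk9_insurance` object.
#' @param prices price grid.
#' @param n_draws PSA draws per price for the acceptability table.
#' @param seed integer master seed.
#' @param n_validation microsimulation patients per arm.
#' @return Invisibly, the named list of written file paths.
#' @export
run_report <- function(out_dir, params = model_parameters(),
                       insurance = insurance_parameters(),
                       prices = c(500, 1000, 2500, 5000, 7500, 10000, 12500,
                                  14000, 15000),
                       n_draws = 1000, seed = 1, n_validation = 20000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    base_case = file.path(out_dir, "base_case.csv"),
    price_grid = file.path(out_dir, "price_grid.csv"),
    breakeven = file.path(out_dir, "breakeven.csv"),
    acceptability = file.path(out_dir, "acceptability.csv"),
    validation = file.path(out_dir, "validation.csv"),
    age_profiles = file.path(out_dir, "age_profiles.csv"),
    manifest = file.path(out_dir, "manifest.yml")
  )
  wcsv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)
  wcsv(base_case_table(params, insurance), paths$base_case)
  wcsv(price_grid_table(params, insurance, prices), paths$price_grid)
  wcsv(breakeven_table(params, insurance), paths$breakeven)
  wcsv(acceptability_surface(params, insurance, price_grid = prices,
                             n_draws = n_draws, seed = seed),
       paths$acceptability)
  wcsv(validation_report(params, n = n_validation, seed = seed),
       paths$validation)
  wcsv(age_profiles(params), paths$age_profiles)
  manifest <- list(
    package = "pcsk9cea",
    version = as.character(utils::packageVersion("pcsk9cea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, n_draws = n_draws, n_validation = n_validation,
    scenario = params$scenario, first_event_source = params$first_event_source,
    pcsk9_price = params$pcsk9_price, price_grid = prices
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
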