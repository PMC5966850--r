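#' Run the full country-level analysis and write result tables
#'
#' Chains the international stages — indicator scoring, level summary,
#' composite index construction, the inequality grid over every ranking
#' variable and mortality outcome, covariate correlations and the outlier
#' regression — and writes one CSV per stage to `outdir`.
#'
#' @param input Path to a country CSV, or a country data frame.
#' @param catalog A `geo_catalog`.
#' @param outdir Output directory (created if needed).
#' @param outcomes Mortality outcome columns to analyse.
#' @param ci_level Confidence level for slope-index intervals.
#' @param residual_threshold Studentised-residual outlier cutoff.
#' @param weighting `"equal"` or `"count"` (population-weighted units).
#' @inheritParams inequality_index
#' @return Invisibly, a named list of the written file paths.
#' @export
run_international <- function(input, catalog = default_catalog(),
                              outdir = ".",
                              outcomes = NULL,
                              ci_level = 0.95,
                              residual_threshold = 2,
                              weighting = c("equal", "count"),
                              method = c("wls", "bootstrap"),
                              n_boot = 1000, seed = NULL) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  data <- if (is.character(input)) {
    read_country_table(input, catalog)
  } else {
    validate_country_table(input, catalog)
  }
  outcomes <- outcomes %||% intersect(MORTALITY_OUTCOMES, names(data))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(msg, n) inform(sprintf("[international] %s (%d rows)", msg, n))

  scores <- score_indicators(data, catalog)
  stage("scored indicators", nrow(scores))
  levels_tbl <- summarise_levels(data, catalog)
  idx <- resource_index(scores)
  stage("resource index", nrow(idx))
  weights <- if (weighting == "count") "population_2015" else NULL
  ineq <- international_inequality(
    data, catalog,
    outcomes = outcomes, weights = weights,
    ci_level = ci_level, method = method, n_boot = n_boot, seed = seed
  )
  stage("inequality table", nrow(ineq))
  outliers <- log_regression_outliers(
    data, idx,
    outcome = outcomes[1], threshold = residual_threshold
  )
  corrs <- covariate_correlations(
    data, idx,
    covariates = intersect(c("internet_users_pct", "gdp_per_capita"), names(data))
  )
  stage("diagnostics", nrow(tidy(outliers)))

  paths <- list(
    scored_indicators = file.path(outdir, "scored_indicators.csv"),
    level_summary = file.path(outdir, "level_summary.csv"),
    resource_index = file.path(outdir, "resource_index.csv"),
    inequality = file.path(outdir, "inequality_table.csv"),
    outlier_report = file.path(outdir, "outlier_report.csv"),
    correlations = file.path(outdir, "covariate_correlations.csv")
  )
  write_results(scores, paths$scored_indicators)
  write_results(levels_tbl, paths$level_summary)
  write_results(idx, paths$resource_index)
  write_results(ineq, paths$inequality)
  write_results(tidy(outliers), paths$outlier_report)
  write_results(corrs, paths$correlations)
  invisible(paths)
}

#' Run the district-level case-study analysis and write result tables
#'
#' Builds the bespoke deprivation index, computes geocoding success
#' rates, and produces one inequality row per deprivation measure (the
#' bespoke index plus, when a `dlt_score` column is present, the
#' external development score).
#'
#' @param input Path to a district CSV, or a district data frame.
#' @param domain_map Data frame (or CSV path) with columns `indicator`,
#'   `domain`, `orientation`; see [deprivation_index()]. If missing and
#'   `input` carries a `"domain_map"` attribute (simulated data), that is
#'   used.
#' @param outdir Output directory.
#' @inheritParams subnational_inequality
#' @return Invisibly, a named list of the written file paths.
#' @export
run_subnational <- function(input, domain_map = NULL, outdir = ".",
                            weighting = c("equal", "count"),
                            ci_level = 0.95,
                            method = c("wls", "bootstrap"),
                            n_boot = 1000, seed = NULL) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  data <- if (is.character(input)) read_district_table(input) else validate_district_table(input)
  if (is.character(domain_map)) {
    domain_map <- readr::read_csv(domain_map, show_col_types = FALSE, progress = FALSE)
  }
  domain_map <- domain_map %||% attr(input, "domain_map")
  if (is.null(domain_map)) {
    abort("no domain map: supply `domain_map` before any scores are computed")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(msg, n) inform(sprintf("[subnational] %s (%d rows)", msg, n))

  dep <- deprivation_index(data, domain_map)
  stage("deprivation index", nrow(dep))
  rates <- success_rates(data)
  stage("success rates", nrow(rates))

  fits <- list(
    bespoke = subnational_inequality(
      rates, dep,
      ranking = "deprivation_total", direction = "higher_more_deprived",
      weighting = weighting, ci_level = ci_level, method = method,
      n_boot = n_boot, seed = seed
    )
  )
  if ("dlt_score" %in% names(data)) {
    fits$dlt <- subnational_inequality(
      rates, dplyr::select(data, "district_id", "dlt_score"),
      ranking = "dlt_score", direction = "higher_less_deprived",
      weighting = weighting, ci_level = ci_level, method = method,
      n_boot = n_boot, seed = seed
    )
  }
  ineq <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(tidy(f), deprivation_measure = nm, .before = 1)
  }) |>
    purrr::list_rbind()
  stage("inequality table", nrow(ineq))

  paths <- list(
    deprivation = file.path(outdir, "deprivation_scores.csv"),
    success_rates = file.path(outdir, "success_rates.csv"),
    inequality = file.path(outdir, "subnational_inequality.csv")
  )
  write_results(dep, paths$deprivation)
  write_results(rates, paths$success_rates)
  write_results(ineq, paths$inequality)
  invisible(paths)
}

#' Materialise simulated datasets as CSV files
#'
#' Writes the country and district tables plus their latent-truth and
#' domain-map sidecars, the inputs every other pipeline stage reads.
#'
#' @param outdir Output directory.
#' @param n_countries,n_districts Sizes of the two tables.
#' @param seed Integer seed controlling both tables.
#' @param ... Further arguments passed on to [simulate_countries()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(outdir = ".", n_countries = 183, n_districts = 25,
                         seed = 1, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  countries <- simulate_countries(n_countries = n_countries, seed = seed, ...)
  districts <- simulate_districts(n_districts = n_districts, seed = seed + 1)
  paths <- list(
    countries = file.path(outdir, "countries.csv"),
    countries_truth = file.path(outdir, "countries_truth.csv"),
    districts = file.path(outdir, "districts.csv"),
    districts_truth = file.path(outdir, "districts_truth.csv"),
    domain_map = file.path(outdir, "district_domain_map.csv")
  )
  write_results(
    dplyr::select(countries, -"latent_richness"), paths$countries
  )
  write_results(
    dplyr::select(countries, "country_id", "latent_richness"),
    paths$countries_truth
  )
  write_results(
    dplyr::select(districts, -"latent_deprivation"), paths$districts
  )
  write_results(
    dplyr::select(districts, "district_id", "latent_deprivation"),
    paths$districts_truth
  )
  write_results(attr(districts, "domain_map"), paths$domain_map)
  inform(sprintf(
    "[simulate] wrote %d countries and %d districts (seed %d)",
    n_countries, n_districts, seed
  ))
  invisible(paths)
}
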