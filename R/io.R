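#' Read a validated country-level input table
#'
#' Reads a CSV with one row per country and validates it against an
#' indicator catalog: country keys must be unique, mortality rates
#' non-negative, internet use within 0-100, and every categorical
#' indicator value must belong to that indicator's declared level set.
#' Missing cells stay missing; they are resolved later according to each
#' indicator's missing policy, never silently coerced to a level.
#'
#' @param path Path to a CSV file with a header row. Required columns:
#'   `country_id`, at least one mortality outcome, and `population_2015`.
#' @param catalog A `geo_catalog`, used to validate categorical columns.
#' @return A tibble, one row per country.
#' @export
read_country_table <- function(path, catalog = default_catalog()) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_country_table(dat, catalog)
}

#' @rdname read_country_table
#' @param data A data frame already in memory (e.g. from
#'   [simulate_countries()]); validated in place.
#' @export
validate_country_table <- function(data, catalog = default_catalog()) {
  data <- tibble::as_tibble(data)
  if (!"country_id" %in% names(data)) {
    abort("country table must have a `country_id` column")
  }
  dup <- unique(data$country_id[duplicated(data$country_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate country_id: ", paste(dup, collapse = ", ")
    ))
  }
  if (!"population_2015" %in% names(data)) {
    abort("country table must have a `population_2015` column")
  }
  if (any(data$population_2015 <= 0, na.rm = TRUE)) {
    abort("population_2015 must be positive")
  }
  for (col in intersect(MORTALITY_OUTCOMES, names(data))) {
    if (any(data[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("negative mortality in column `", col, "`"))
    }
  }
  if ("internet_users_pct" %in% names(data)) {
    bad <- data$internet_users_pct < 0 | data$internet_users_pct > 100
    if (any(bad, na.rm = TRUE)) {
      abort("internet_users_pct must lie in [0, 100]")
    }
  }
  for (ind in catalog_names(catalog, "ordinal")) {
    if (!ind %in% names(data)) next
    lv <- catalog_levels(catalog, ind)
    vals <- data[[ind]]
    bad <- !is.na(vals) & !(vals %in% lv)
    if (any(bad)) {
      rows <- which(bad)
      abort(paste0(
        "column `", ind, "`: value(s) not in the declared level set: ",
        paste(unique(vals[bad]), collapse = ", "),
        " (row ", paste(head(rows, 5), collapse = ", "), ")"
      ))
    }
  }
  data
}

#' Read a validated district-level input table
#'
#' One row per district/local-government-area, with census deprivation
#' indicator columns plus geocoding attempt and success counts.
#'
#' @param path CSV path. Required columns: `district_id`, `n_attempted`,
#'   `n_success`.
#' @return A tibble, one row per district.
#' @export
read_district_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_district_table(dat)
}

#' @rdname read_district_table
#' @param data A district data frame to validate in place.
#' @export
validate_district_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("district_id", "n_attempted", "n_success")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("district table missing column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- unique(data$district_id[duplicated(data$district_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate district_id: ", paste(dup, collapse = ", ")))
  }
  if (any(data$n_attempted < 1)) {
    abort("n_attempted must be >= 1 for every district")
  }
  if (any(data$n_success < 0 | data$n_success > data$n_attempted)) {
    abort("n_success must lie in [0, n_attempted]")
  }
  data
}

#' Write a result table to CSV
#'
#' Columns keep their order; numeric values are serialised at full
#' precision so a write/read round trip reproduces them.
#'
#' @param data A non-empty data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(data, path) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("refusing to write an empty result table")
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
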