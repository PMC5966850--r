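#' Score provider availability indicators
#'
#' Converts each country's raw provider coverage statement into a numeric
#' availability score. Scores are ordinal devices: only their ordering
#' matters downstream (the composite index is rank-based), so categorical
#' levels simply receive their 1-based position in the worst-to-best level
#' list. The returned long tibble carries one row per country x indicator
#' with the score's `direction` (`higher_better` except for mean
#' population per areal unit) and a `provenance` flag recording whether
#' the value was observed, imputed from the national population fallback,
#' or filled at the worst level / zero because the provider publishes no
#' statement for that country.
#'
#' @param data A validated country table (see [read_country_table()]).
#' @param catalog A `geo_catalog`.
#' @return A tibble with columns `country_id`, `indicator`, `domain`,
#'   `score`, `direction`, `provenance`.
#' @examples
#' countries <- simulate_countries(n_countries = 20, seed = 1)
#' score_indicators(countries)
#' @export
score_indicators <- function(data, catalog = default_catalog()) {
  data <- tibble::as_tibble(data)
  pieces <- purrr::imap(catalog$indicators, function(spec, nm) {
    switch(spec$kind,
      ordinal = score_ordinal_indicator(data, nm, catalog),
      travel_composite = score_google_travel(data, indicator = nm, catalog = catalog),
      numeric = score_neighbourhood_disaggregation(data, indicator = nm, catalog = catalog),
      count = score_neighbourhood_attributes(data, indicator = nm, catalog = catalog),
      availability_count = score_geodemographic_availability(data, indicator = nm, catalog = catalog),
      abort(paste0("unknown indicator kind: ", spec$kind))
    )
  })
  purrr::list_rbind(pieces)
}

scored_tibble <- function(data, indicator, domain, score, direction, provenance) {
  tibble::tibble(
    country_id = data$country_id,
    indicator = indicator,
    domain = domain,
    score = as.numeric(score),
    direction = direction,
    provenance = provenance
  )
}

#' @rdname score_indicators
#' @param indicator Name of the indicator column in `data` (and its entry
#'   in the catalog).
#' @export
score_ordinal_indicator <- function(data, indicator, catalog = default_catalog()) {
  spec <- catalog$indicators[[indicator]]
  if (is.null(spec)) abort(paste0("unknown indicator: ", indicator))
  lv <- catalog_levels(catalog, indicator)
  raw <- if (indicator %in% names(data)) data[[indicator]] else rep(NA_character_, nrow(data))
  unknown <- !is.na(raw) & !(raw %in% lv)
  if (any(unknown)) {
    abort(paste0(
      "column `", indicator, "`: value(s) not in the declared level set: ",
      paste(unique(raw[unknown]), collapse = ", ")
    ))
  }
  score <- match(raw, lv)
  provenance <- ifelse(is.na(raw), "missing_as_worst", "observed")
  policy <- spec$missing_policy %||% "worst"
  if (policy != "worst" && any(is.na(raw))) {
    abort(paste0("missing policy `", policy, "` not defined for ordinal indicator ", indicator))
  }
  score[is.na(score)] <- 1 # absence of a published service is the worst level
  scored_tibble(data, indicator, spec$domain, score, "higher_better", provenance)
}

#' @rdname score_indicators
#' @param components Named character vector mapping the five travel
#'   quality components (`traffic`, `speed_limits`, `cycling`, `walking`,
#'   `driving`) to columns of `data`; defaults to `google_<component>`.
#' @export
score_google_travel <- function(data, components = NULL, indicator = "google_travel",
                                catalog = default_catalog()) {
  comps <- google_component_names()
  columns <- components %||% setNames(paste0("google_", comps), comps)
  spec <- catalog$indicators[[indicator]]
  per_component <- purrr::map(comps, function(cp) {
    col <- columns[[cp]]
    vals <- if (col %in% names(data)) data[[col]] else rep(NA_character_, nrow(data))
    vals[is.na(vals)] <- "none"
    bad <- !vals %in% c("good", "approximate", "none")
    if (any(bad)) {
      abort(paste0(
        "column `", col, "`: unknown travel component label(s): ",
        paste(unique(vals[bad]), collapse = ", ")
      ))
    }
    c(good = 2, approximate = 1, none = 0)[vals]
  })
  total <- Reduce(`+`, per_component)
  scored_tibble(data, indicator, spec$domain, total, "higher_better", "observed")
}

#' @rdname score_indicators
#' @export
score_neighbourhood_disaggregation <- function(data, indicator = "mb_mean_population",
                                               catalog = default_catalog()) {
  spec <- catalog$indicators[[indicator]]
  raw <- if (indicator %in% names(data)) data[[indicator]] else rep(NA_real_, nrow(data))
  fallback <- is.na(raw)
  value <- ifelse(fallback, data$population_2015, raw)
  if (any(is.na(value))) {
    bad <- data$country_id[is.na(value)]
    abort(paste0(
      "no areal population and no national population for: ",
      paste(bad, collapse = ", ")
    ))
  }
  scored_tibble(
    data, indicator, spec$domain, value,
    spec$direction %||% "lower_better",
    ifelse(fallback, "fallback", "observed")
  )
}

#' @rdname score_indicators
#' @export
score_neighbourhood_attributes <- function(data, indicator = "mb_attribute_groups",
                                           catalog = default_catalog()) {
  spec <- catalog$indicators[[indicator]]
  raw <- if (indicator %in% names(data)) data[[indicator]] else rep(NA_real_, nrow(data))
  if (any(raw < 0, na.rm = TRUE)) {
    abort(paste0("negative attribute-group count in `", indicator, "`"))
  }
  provenance <- ifelse(is.na(raw), "missing_as_worst", "observed")
  raw[is.na(raw)] <- 0
  scored_tibble(data, indicator, spec$domain, raw, "higher_better", provenance)
}

#' @rdname score_indicators
#' @export
score_geodemographic_availability <- function(data, indicator = "geodemographic",
                                              catalog = default_catalog()) {
  spec <- catalog$indicators[[indicator]]
  cols <- names(spec$components)
  flags <- purrr::map(cols, function(col) {
    vals <- if (col %in% names(data)) data[[col]] else rep(NA, nrow(data))
    vals <- as.logical(vals)
    vals[is.na(vals)] <- FALSE
    as.numeric(vals)
  })
  total <- Reduce(`+`, flags)
  scored_tibble(data, indicator, spec$domain, total, "higher_better", "observed")
}

#' Summarise categorical availability by level
#'
#' Counts countries at each coverage level of every categorical indicator
#' and expresses each count as a percentage of the country total, the
#' standard marginal summary of an availability table.
#'
#' @inheritParams score_indicators
#' @return A tibble with columns `indicator`, `domain`, `level`
#'   (worst-to-best order preserved), `n` and `pct`.
#' @export
summarise_levels <- function(data, catalog = default_catalog()) {
  data <- tibble::as_tibble(data)
  n_total <- nrow(data)
  purrr::map(catalog_names(catalog, "ordinal"), function(ind) {
    lv <- catalog_levels(catalog, ind)
    raw <- data[[ind]]
    n <- purrr::map_int(lv, ~ sum(raw == .x, na.rm = TRUE))
    tibble::tibble(
      indicator = ind,
      domain = catalog$indicators[[ind]]$domain,
      level = lv,
      n = n,
      pct = 100 * n / n_total
    )
  }) |>
    purrr::list_rbind()
}
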