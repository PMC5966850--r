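#' International inequality analysis
#'
#' End-to-end country-level analysis: scores every availability indicator,
#' builds the domain and overall resource indices, then computes the
#' relative concentration index and slope index of inequality of each
#' mortality outcome against every ranking variable — each provider
#' indicator (via its availability rank, so direction is already
#' harmonised), each of the three domain indices, and the overall index.
#'
#' @param data A validated country table.
#' @param catalog A `geo_catalog`.
#' @param outcomes Outcome column names present in `data`.
#' @inheritParams inequality_index
#' @return A tibble with columns `domain`, `ranking`, `outcome`, `rci`,
#'   `sii`, `sii_lo`, `sii_hi`, `n`.
#' @examples
#' countries <- simulate_countries(n_countries = 40, seed = 7)
#' international_inequality(countries, outcomes = "mortality_all")
#' @export
international_inequality <- function(data, catalog = default_catalog(),
                                     outcomes = intersect(MORTALITY_OUTCOMES, names(data)),
                                     weights = NULL, ci_level = 0.95,
                                     method = c("wls", "bootstrap"),
                                     n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  scores <- score_indicators(data, catalog)
  ranked <- rank_countries(scores)
  rank_wide <- ranked |>
    tidyr::pivot_wider(
      id_cols = "country_id", names_from = "indicator", values_from = "rank"
    )
  idx <- resource_index(scores)
  full <- data |>
    dplyr::select(dplyr::all_of(c("country_id", outcomes, weights))) |>
    dplyr::inner_join(rank_wide, by = "country_id") |>
    dplyr::inner_join(idx, by = "country_id")
  indicator_domains <- scores |>
    dplyr::distinct(.data$indicator, .data$domain)
  rankings <- c(
    indicator_domains$indicator,
    "geocoding_index", "travel_index", "neighbourhood_index", "overall_index"
  )
  domain_of <- c(
    setNames(indicator_domains$domain, indicator_domains$indicator),
    geocoding_index = "geocoding", travel_index = "travel",
    neighbourhood_index = "neighbourhood", overall_index = "overall"
  )
  inequality_table(
    full,
    outcomes = outcomes, rankings = rankings,
    weights = weights, ci_level = ci_level,
    method = method, n_boot = n_boot, seed = seed
  ) |>
    dplyr::mutate(domain = unname(domain_of[.data$ranking])) |>
    dplyr::relocate("domain")
}
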