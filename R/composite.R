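#' Rank countries on each availability indicator
#'
#' Assigns availability ranks 1..n per indicator, with rank n = best
#' availability after the indicator's direction is applied (so for mean
#' population per areal unit, the smallest value gets the top rank).
#' Tied scores share the mean of their tied positions, which keeps the
#' rank total at exactly n(n+1)/2 regardless of ties.
#'
#' @param scores Long scored tibble from [score_indicators()].
#' @return The input with a `rank` column added.
#' @export
rank_countries <- function(scores) {
  if (nrow(scores) == 0) abort("cannot rank an empty country set")
  scores |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(
      rank = rank(
        ifelse(.data$direction == "lower_better", -.data$score, .data$score),
        ties.method = "average"
      )
    ) |>
    dplyr::ungroup()
}

#' Per-domain and overall geospatial resource indices
#'
#' For each of the three domains, each country's availability ranks are
#' summed over the domain's K indicators and divided by the maximum
#' possible summed rank K*n, giving a domain index in (0, 1] where 1
#' means ranked (tied-)best on every indicator. The overall resource
#' index is the sum of the three domain indices, in (0, 3]; summing at
#' domain level stops domains with many indicators from dominating.
#'
#' @param scores Long scored tibble from [score_indicators()] (ranks are
#'   computed internally if absent).
#' @return `domain_indices()`: a tibble `country_id`, `domain`, `index`,
#'   `n_indicators`. `resource_index()`: a wide tibble with one row per
#'   country and columns `geocoding_index`, `travel_index`,
#'   `neighbourhood_index`, `overall_index`.
#' @examples
#' countries <- simulate_countries(n_countries = 20, seed = 1)
#' resource_index(score_indicators(countries))
#' @export
domain_indices <- function(scores) {
  if (!"rank" %in% names(scores)) scores <- rank_countries(scores)
  check_common_country_set(scores)
  n <- dplyr::n_distinct(scores$country_id)
  scores |>
    dplyr::group_by(.data$domain, .data$country_id) |>
    dplyr::summarise(
      rank_sum = sum(.data$rank),
      n_indicators = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(index = .data$rank_sum / (.data$n_indicators * n)) |>
    dplyr::select("country_id", "domain", "index", "n_indicators")
}

#' @rdname domain_indices
#' @export
resource_index <- function(scores) {
  di <- domain_indices(scores)
  missing_domains <- setdiff(c("geocoding", "travel", "neighbourhood"), di$domain)
  if (length(missing_domains) > 0) {
    abort(paste0(
      "no indicators for domain(s): ", paste(missing_domains, collapse = ", ")
    ))
  }
  di |>
    dplyr::mutate(domain = paste0(.data$domain, "_index")) |>
    tidyr::pivot_wider(
      id_cols = "country_id", names_from = "domain", values_from = "index"
    ) |>
    dplyr::mutate(
      overall_index = .data$geocoding_index + .data$travel_index +
        .data$neighbourhood_index
    )
}

# every indicator must cover the same countries: a partial indicator would
# silently shrink the rank denominator
check_common_country_set <- function(scores) {
  sets <- scores |>
    dplyr::distinct(.data$indicator, .data$country_id) |>
    dplyr::count(.data$indicator)
  n <- dplyr::n_distinct(scores$country_id)
  bad <- sets$indicator[sets$n != n]
  if (length(bad) > 0) {
    abort(paste0(
      "indicator(s) do not cover the full country set: ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(scores)
}
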