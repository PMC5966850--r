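#' Bespoke district deprivation index
#'
#' Builds an area deprivation score from census indicators grouped into
#' six domains (information access, education, energy, employment, water
#' and sanitation, living conditions). Each indicator is first oriented so
#' that larger values mean more deprived, then standardised to a z-score
#' across districts (population standard deviation); z-scores are averaged
#' within each domain and the six domain means summed into the composite
#' score. By construction district totals average zero, and the score is
#' invariant to affine rescaling of any raw indicator.
#'
#' @param data District table, one row per district, with a `district_id`
#'   column and one numeric column per census indicator.
#' @param domain_map A data frame with columns `indicator`, `domain`
#'   (one of the six domain keys) and `orientation` (+1 if a larger raw
#'   value means more deprived, -1 otherwise). The orientation must be
#'   supplied explicitly: census indicators point both ways and a wrong
#'   default would silently corrupt the index.
#' @return A tibble with `district_id`, one mean-z column per domain, and
#'   `deprivation_total` (higher = more deprived).
#' @examples
#' sim <- simulate_districts(n_districts = 10, seed = 3)
#' deprivation_index(sim, attr(sim, "domain_map"))
#' @export
deprivation_index <- function(data, domain_map) {
  data <- tibble::as_tibble(data)
  domain_map <- tibble::as_tibble(domain_map)
  need <- c("indicator", "domain", "orientation")
  if (!all(need %in% names(domain_map))) {
    abort("domain_map needs columns indicator, domain, orientation")
  }
  if (nrow(data) < 2) abort("deprivation index needs at least 2 districts")
  missing_cols <- setdiff(domain_map$indicator, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "indicator column(s) absent from district table: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!all(domain_map$orientation %in% c(-1, 1))) {
    abort("orientation must be +1 (more = deprived) or -1 per indicator")
  }
  bad_domain <- setdiff(domain_map$domain, DEPRIVATION_DOMAINS)
  if (length(bad_domain) > 0) {
    abort(paste0(
      "unknown domain(s): ", paste(bad_domain, collapse = ", "),
      " (expected: ", paste(DEPRIVATION_DOMAINS, collapse = ", "), ")"
    ))
  }
  m <- nrow(data)
  long <- domain_map |>
    dplyr::mutate(
      z = purrr::map2(.data$indicator, .data$orientation, function(ind, sgn) {
        x <- sgn * data[[ind]]
        s <- sd(x) * sqrt((m - 1) / m) # population SD across districts
        if (!is.finite(s) || s == 0) {
          abort(paste0("indicator `", ind, "` has zero variance across districts"))
        }
        (x - mean(x)) / s
      })
    ) |>
    tidyr::unnest_longer("z", indices_to = "row") |>
    dplyr::mutate(district_id = data$district_id[.data$row])
  domain_scores <- long |>
    dplyr::group_by(.data$district_id, .data$domain) |>
    dplyr::summarise(domain_z = mean(.data$z), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "domain_z")
  present <- intersect(DEPRIVATION_DOMAINS, names(domain_scores))
  domain_scores |>
    dplyr::mutate(
      deprivation_total = rowSums(dplyr::pick(dplyr::all_of(present)))
    ) |>
    dplyr::arrange(match(.data$district_id, data$district_id))
}

#' Geocoding success rates by district
#'
#' @param data District table with `district_id`, `n_attempted` (>= 1)
#'   and `n_success` counts.
#' @return A tibble `district_id`, `n_attempted`, `n_success`,
#'   `success_rate` (exact proportion, no smoothing).
#' @export
success_rates <- function(data) {
  data <- validate_district_table(
    tibble::as_tibble(data)[, intersect(
      c("district_id", "name", "n_attempted", "n_success"), names(data)
    )]
  )
  data |>
    dplyr::mutate(success_rate = .data$n_success / .data$n_attempted) |>
    dplyr::select("district_id", "n_attempted", "n_success", "success_rate")
}

#' District-level inequality in geocoding success
#'
#' Ranks districts most-deprived first and computes the concentration
#' index and slope index of inequality of the geocoding success rate
#' against the deprivation measure. A positive concentration index means
#' success is concentrated among the less deprived districts.
#'
#' @param rates Output of [success_rates()] (or any tibble with
#'   `district_id` and `success_rate`).
#' @param deprivation A data frame with `district_id` and the deprivation
#'   column named by `ranking`, e.g. the output of [deprivation_index()]
#'   or a table of external district development scores.
#' @param ranking Name of the deprivation column (default
#'   `"deprivation_total"`).
#' @param direction `"higher_more_deprived"` (bespoke deprivation index)
#'   or `"higher_less_deprived"` (development scores such as district
#'   league tables, where a larger value means better-off).
#' @param weighting `"equal"` (each district one unit) or `"count"`
#'   (weight districts by geocoding attempts, damping rate noise from
#'   districts with very few facilities).
#' @inheritParams inequality_index
#' @return A `geo_ineq` object (see [inequality_index()]).
#' @examples
#' sim <- simulate_districts(n_districts = 12, seed = 5)
#' dep <- deprivation_index(sim, attr(sim, "domain_map"))
#' tidy(subnational_inequality(success_rates(sim), dep))
#' @export
subnational_inequality <- function(rates, deprivation,
                                   ranking = "deprivation_total",
                                   direction = c(
                                     "higher_more_deprived",
                                     "higher_less_deprived"
                                   ),
                                   weighting = c("equal", "count"),
                                   ci_level = 0.95,
                                   method = c("wls", "bootstrap"),
                                   n_boot = 1000, seed = NULL) {
  direction <- match.arg(direction)
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  joined <- dplyr::inner_join(
    tibble::as_tibble(rates), tibble::as_tibble(deprivation),
    by = "district_id"
  )
  if (nrow(joined) < 3) {
    abort("need at least 3 districts shared between rates and deprivation")
  }
  if (!ranking %in% names(joined)) {
    abort(paste0("deprivation column not found: ", ranking))
  }
  weights <- if (weighting == "count") "n_attempted" else NULL
  # worst-off first: most deprived must sit at the bottom of the ranking
  rank_dir <- if (direction == "higher_more_deprived") "lower_better" else "higher_better"
  fit <- inequality_index(
    joined, "success_rate", ranking,
    direction = rank_dir, weights = weights, ci_level = ci_level,
    method = method, n_boot = n_boot, seed = seed
  )
  fit$weighting <- weighting
  fit
}
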