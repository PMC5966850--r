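#' Simulate a country-level availability and mortality table
#'
#' Generates the statistical structure the international analysis
#' assumes: a single latent "data richness" variable per country drives
#' every provider indicator (availability co-varies across providers, as
#' it does empirically), and age-standardised mortality declines
#' log-linearly with the latent. Each ordinal indicator is produced by
#' rank-binning a noisy copy of the latent into the indicator's level set
#' using the catalog's reference counts as bin widths, so at the default
#' 183 countries the simulated marginal distribution of coverage levels
#' reproduces the catalog's reference distribution exactly — including
#' its heavy ties, the feature that most shapes rank-based indices.
#'
#' @param n_countries Number of countries (default 183).
#' @param gradients Named log-linear mortality gradients per outcome
#'   (decline in log mortality from the data-poorest to the data-richest
#'   country). Defaults make the communicable-disease group steepest and
#'   non-communicable diseases shallowest.
#' @param baselines Named log baselines per outcome (log mortality at the
#'   data-poor end), on the per-100,000 scale.
#' @param noise_sd Lognormal noise SD on each mortality outcome.
#' @param indicator_fidelity Correlation weight in `[0, 1]` tying each
#'   indicator to the latent (1 = indicators are deterministic functions
#'   of the latent up to binning ties).
#' @param mb_missing_rate Fraction of countries (the most data-poor by
#'   the indicator's own signal) with no areal-statistics provider data;
#'   these fall back to the national population downstream.
#' @param n_gdp_missing Number of countries with missing GDP per capita.
#' @param catalog A `geo_catalog` supplying level sets and reference
#'   counts.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with one row per country: identifiers, the four
#'   mortality outcomes, `population_2015`, `gdp_per_capita`,
#'   `internet_users_pct`, every indicator column, and the true
#'   `latent_richness` used to generate them.
#' @examples
#' simulate_countries(n_countries = 10, seed = 42)
#' @export
simulate_countries <- function(n_countries = 183,
                               gradients = c(
                                 mortality_all = 1.0, mortality_cmnn = 3.0,
                                 mortality_ncd = 0.45, mortality_inj = 1.0
                               ),
                               baselines = c(
                                 mortality_all = 7.2, mortality_cmnn = 6.3,
                                 mortality_ncd = 6.6, mortality_inj = 4.6
                               ),
                               noise_sd = 0.15,
                               indicator_fidelity = 0.9,
                               mb_missing_rate = 0.2,
                               n_gdp_missing = 9,
                               catalog = default_catalog(),
                               seed = NULL) {
  if (n_countries < 2) abort("need at least 2 countries")
  if (indicator_fidelity < 0 || indicator_fidelity > 1) {
    abort("indicator_fidelity must lie in [0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (any(gradients < 0)) abort("gradients must be non-negative")
  if (mb_missing_rate < 0 || mb_missing_rate > 1) {
    abort("mb_missing_rate must lie in [0, 1]")
  }
  with_optional_seed(seed, {
    n <- n_countries
    rho <- indicator_fidelity
    latent <- runif(n)
    signal <- function() rho * latent + (1 - rho) * runif(n)

    out <- tibble::tibble(
      country_id = sprintf("C%03d", seq_len(n)),
      name = sprintf("Country %03d", seq_len(n)),
      latent_richness = latent
    )

    # ordinal indicators: rank-bin a noisy latent into the level set with
    # bin widths proportional to the catalog's reference counts
    for (ind in catalog_names(catalog, "ordinal")) {
      counts <- catalog_level_counts(catalog, ind)
      out[[ind]] <- bin_by_rank(signal(), names(counts), counts, n)
    }

    # five Google travel components, each good/approximate/none
    comp_ref <- catalog$indicators[["google_travel"]]$components
    for (cp in google_component_names()) {
      ref <- comp_ref[[cp]]
      counts <- c(none = ref$none, approximate = ref$approximate, good = ref$good)
      out[[paste0("google_", cp)]] <- bin_by_rank(signal(), names(counts), counts, n)
    }

    # geodemographic products: available in the top-k countries by signal
    geo_ref <- catalog$indicators[["geodemographic"]]$components
    for (cp in names(geo_ref)) {
      k <- round(geo_ref[[cp]] * n / catalog$countries_total)
      s <- signal()
      out[[cp]] <- rank(s, ties.method = "first") > n - k
    }

    # areal statistics: log population per unit falls with data richness;
    # provider absent in the most data-poor countries
    s_mb <- signal()
    log_pop_unit <- log(130000) - 12.2 * (s_mb - 0.5) + rnorm(n, 0, 0.5)
    mb_present <- rank(s_mb, ties.method = "first") >
      floor(mb_missing_rate * n)
    out$mb_mean_population <- ifelse(mb_present, exp(log_pop_unit), NA_real_)
    s_attr <- signal()
    out$mb_attribute_groups <- ifelse(
      mb_present, pmin(9L, pmax(0L, round(9 * s_attr))), NA_integer_
    )

    # covariates: population, GDP and internet use all rise with the latent
    out$population_2015 <- round(exp(15 + 1.2 * (latent - 0.5) + rnorm(n, 0, 1.2)))
    gdp <- exp(6.5 + 3.5 * latent + rnorm(n, 0, 0.5))
    if (n_gdp_missing > 0) {
      gdp[sample.int(n, min(n_gdp_missing, n))] <- NA_real_
    }
    out$gdp_per_capita <- gdp
    out$internet_users_pct <- 100 * plogis(-2 + 5 * latent + rnorm(n, 0, 0.6))

    # log-linear mortality decline with data richness
    for (oc in names(gradients)) {
      out[[oc]] <- exp(
        baselines[[oc]] - gradients[[oc]] * latent + rnorm(n, 0, noise_sd)
      )
    }
    out
  })
}

#' Simulate a district-level deprivation and geocoding table
#'
#' A latent deprivation variable per district drives both the census
#' indicators (a one-factor model with the given loading, orientations
#' alternating so the explicit orientation map is exercised) and the
#' geocoding outcome: successes are binomial with a success probability
#' that falls with deprivation on the log-odds scale.
#'
#' @param n_districts Number of districts (default 25).
#' @param indicators_per_domain Census indicators per domain (default 2,
#'   i.e. 12 indicators over the six domains).
#' @param loading Factor loading of each indicator on the latent
#'   deprivation (default 0.8).
#' @param facility_count_range Integer range for geocoding attempts per
#'   district.
#' @param success_intercept,success_slope Log-odds intercept and decline
#'   per unit latent deprivation of the geocoding success probability.
#' @param seed Integer seed.
#' @return A tibble with one row per district: `district_id`, the census
#'   indicator columns, `n_attempted`, `n_success`, `dlt_score` (an
#'   external development score, higher = less deprived) and the true
#'   `latent_deprivation`. The indicator-to-domain assignment with
#'   orientations is attached as attribute `"domain_map"`.
#' @examples
#' sim <- simulate_districts(n_districts = 8, seed = 1)
#' attr(sim, "domain_map")
#' @export
simulate_districts <- function(n_districts = 25,
                               indicators_per_domain = 2,
                               loading = 0.8,
                               facility_count_range = c(10, 70),
                               success_intercept = -0.5,
                               success_slope = 0.5,
                               seed = NULL) {
  if (n_districts < 2) abort("need at least 2 districts")
  if (loading < 0 || loading > 1) abort("loading must lie in [0, 1]")
  if (any(facility_count_range < 1) || length(facility_count_range) != 2) {
    abort("facility_count_range must be two counts >= 1")
  }
  with_optional_seed(seed, {
    n <- n_districts
    d_latent <- rnorm(n)
    domain_map <- tidyr::expand_grid(
      domain = DEPRIVATION_DOMAINS,
      j = seq_len(indicators_per_domain)
    ) |>
      dplyr::mutate(
        indicator = paste0(.data$domain, "_", .data$j),
        orientation = ifelse(.data$j %% 2 == 1, 1, -1)
      ) |>
      dplyr::select("indicator", "domain", "orientation")

    out <- tibble::tibble(
      district_id = sprintf("D%02d", seq_len(n)),
      name = sprintf("District %02d", seq_len(n)),
      latent_deprivation = d_latent
    )
    for (i in seq_len(nrow(domain_map))) {
      sgn <- domain_map$orientation[i]
      factor_part <- loading * d_latent + sqrt(1 - loading^2) * rnorm(n)
      out[[domain_map$indicator[i]]] <- 50 + 15 * sgn * factor_part
    }
    out$n_attempted <- sample(
      seq(facility_count_range[1], facility_count_range[2]), n,
      replace = TRUE
    )
    p_success <- plogis(success_intercept - success_slope * d_latent)
    out$n_success <- rbinom(n, out$n_attempted, p_success)
    out$dlt_score <- 60 - 12 * d_latent + rnorm(n, 0, 4)
    attr(out, "domain_map") <- domain_map
    out
  })
}

# bin values into labelled levels (worst to best) with bin widths
# proportional to reference counts, by rank: the k worst-signal countries
# get the worst level, and so on; largest-remainder rounding keeps the
# rescaled counts summing to n
bin_by_rank <- function(signal, labels, ref_counts, n) {
  counts <- scale_counts(ref_counts, n)
  assigned <- rep(labels, counts)
  assigned[order(order(signal))]
}

scale_counts <- function(ref_counts, n) {
  raw <- ref_counts * n / sum(ref_counts)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
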