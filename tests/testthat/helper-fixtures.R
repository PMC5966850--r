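# tiny in-code fixtures shared across test files

# a minimal valid country table with explicit indicator values
tiny_countries <- function() {
  tibble::tibble(
    country_id = c("AAA", "BBB", "CCC"),
    name = c("Alpha", "Beta", "Gamma"),
    mortality_all = c(1200, 800, 500),
    mortality_cmnn = c(500, 150, 40),
    mortality_ncd = c(600, 580, 420),
    mortality_inj = c(100, 70, 40),
    population_2015 = c(5e6, 2e7, 8e6),
    gdp_per_capita = c(900, 5000, 30000),
    internet_users_pct = c(10, 45, 90),
    esri_geocoding = c("Level 4", "Level 3", "Level 1"),
    pitney_bowes = c(
      "Administrative boundaries or place-names", "Post code",
      "Precise address point geocoding"
    ),
    tomtom_geocoding = c("Locality", "Street-level", "Address point"),
    mapbox_geocoding = c("No service", "Place-name", "Address geocoding"),
    loqate = c("Locality", "Thoroughfare", "Premises - point"),
    esri_here_travel = c(
      "Minimal street coverage", "Limited street coverage", "Predictive traffic"
    ),
    google_traffic = c("none", "none", "good"),
    google_speed_limits = c("approximate", "approximate", "good"),
    google_cycling = c("none", "none", "good"),
    google_walking = c("good", "good", "good"),
    google_driving = c("good", "good", "good"),
    igeolise = c(
      "Travel times unavailable", "Travel times for driving only",
      "Travel times for public transport and driving"
    ),
    tomtom_travel = c(
      "No online routing", "Online routing without traffic",
      "Online routing with traffic incidents and traffic flows"
    ),
    mapbox_travel = c(
      "Traffic layer unavailable", "Traffic layer unavailable",
      "Traffic layer available"
    ),
    mb_mean_population = c(NA, 500000, 800),
    mb_attribute_groups = c(NA, 3, 9),
    mosaic_available = c(FALSE, FALSE, TRUE),
    cameo_available = c(FALSE, TRUE, TRUE),
    maptitude_available = c(FALSE, FALSE, TRUE)
  )
}

# long scored tibble built directly from per-indicator score vectors
scores_from_matrix <- function(mat, domain = "geocoding",
                               direction = "higher_better") {
  ids <- if (is.null(rownames(mat))) {
    paste0("U", seq_len(nrow(mat)))
  } else {
    rownames(mat)
  }
  purrr::imap(as.data.frame(mat), function(col, nm) {
    tibble::tibble(
      country_id = ids,
      indicator = nm,
      domain = domain,
      score = as.numeric(col),
      direction = direction,
      provenance = "observed"
    )
  }) |> purrr::list_rbind()
}

# independent oracle: availability rank by exhaustive pairwise comparison,
# rank n = best, ties as mean of tied positions
pairwise_rank_oracle <- function(scores) {
  vapply(seq_along(scores), function(i) {
    below <- sum(scores < scores[i])
    tied <- sum(scores == scores[i]) # includes i
    below + (tied + 1) / 2
  }, numeric(1))
}

# independent oracle: concentration index by the direct summation form
# (2 / (n * mu)) * sum(y_i * r_i) - 1, valid for equal weights and no ties
rci_sum_oracle <- function(y, exposure) {
  n <- length(y)
  r <- (rank(exposure, ties.method = "first") - 0.5) / n
  2 * sum(y * r) / (n * mean(y)) - 1
}

`%||%` <- rlang::`%||%`
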