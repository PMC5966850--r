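simple_map <- function(indicators, domains = NULL, orientation = NULL) {
  tibble::tibble(
    indicator = indicators,
    domain = domains %||% rep_len(
      c(
        "information_access", "education", "energy",
        "employment", "water_sanitation", "living_conditions"
      ),
      length(indicators)
    ),
    orientation = orientation %||% rep(1, length(indicators))
  )
}

test_that("deprivation z-scores have mean zero and unit population SD", {
  sim <- simulate_districts(n_districts = 25, seed = 12)
  map <- attr(sim, "domain_map")
  dep <- deprivation_index(sim, map)
  m <- nrow(sim)
  expect_equal(mean(dep$deprivation_total), 0, tolerance = 1e-10)
  # each domain column is a mean of z-scores: mean zero across districts
  for (dom in setdiff(names(dep), c("district_id", "deprivation_total"))) {
    expect_equal(mean(dep[[dom]]), 0, tolerance = 1e-10)
  }
  # reconstruct one indicator z by hand with the population SD
  ind <- map$indicator[1]
  x <- map$orientation[1] * sim[[ind]]
  z <- (x - mean(x)) / (sd(x) * sqrt((m - 1) / m))
  expect_equal(sd(z) * sqrt((m - 1) / m), 1, tolerance = 1e-10)
})

test_that("two districts give symmetric totals about zero", {
  d <- tibble::tibble(
    district_id = c("D1", "D2"),
    a = c(10, 20), b = c(5, 1), c = c(0.2, 0.8),
    d = c(100, 50), e = c(7, 9), f = c(3, 4)
  )
  dep <- deprivation_index(d, simple_map(letters[1:6]))
  expect_equal(dep$deprivation_total[1], -dep$deprivation_total[2])
})

test_that("zero-variance indicators are rejected by name", {
  d <- tibble::tibble(
    district_id = c("D1", "D2", "D3"),
    a = c(1, 2, 3), b = c(4, 4, 4)
  )
  expect_error(
    deprivation_index(d, simple_map(c("a", "b"))), "`b`"
  )
})

test_that("the domain map is validated before any computation", {
  d <- tibble::tibble(district_id = c("D1", "D2"), a = c(1, 2))
  expect_error(deprivation_index(d, simple_map("missing_col")), "missing_col")
  expect_error(
    deprivation_index(d, simple_map("a", domains = "wealth")), "wealth"
  )
  bad_orient <- simple_map("a")
  bad_orient$orientation <- 0.5
  expect_error(deprivation_index(d, bad_orient), "orientation")
  expect_error(
    deprivation_index(d[1, ], simple_map("a")), "at least 2"
  )
})

test_that("deprivation totals are invariant to affine indicator rescaling", {
  sim <- simulate_districts(n_districts = 15, seed = 30)
  map <- attr(sim, "domain_map")
  base <- deprivation_index(sim, map)
  shifted <- sim
  shifted[[map$indicator[3]]] <- 100 + 7 * shifted[[map$indicator[3]]]
  shifted[[map$indicator[8]]] <- -2 + 0.01 * shifted[[map$indicator[8]]]
  expect_equal(
    deprivation_index(shifted, map)$deprivation_total,
    base$deprivation_total,
    tolerance = 1e-10
  )
})

test_that("success rates are exact proportions with boundary cases", {
  d <- tibble::tibble(
    district_id = c("D1", "D2", "D3"),
    n_attempted = c(10, 5, 5),
    n_success = c(7, 0, 5)
  )
  expect_equal(success_rates(d)$success_rate, c(0.7, 0, 1))
  expect_error(
    success_rates(dplyr::mutate(d, n_attempted = c(0, 5, 5))), "n_attempted"
  )
})

test_that("district inequality orients most-deprived first", {
  # success strictly increasing with affluence -> positive RCI
  d <- tibble::tibble(
    district_id = paste0("D", 1:6),
    n_attempted = rep(100, 6),
    n_success = c(20, 30, 40, 50, 60, 70)
  )
  dep <- tibble::tibble(
    district_id = paste0("D", 1:6),
    deprivation_total = c(3, 2, 1, 0, -1, -2) # D1 most deprived
  )
  fit <- subnational_inequality(success_rates(d), dep)
  expect_gt(fit$rci, 0)
  # constant rates -> no gradient
  flat <- dplyr::mutate(d, n_success = 50)
  fit0 <- subnational_inequality(success_rates(flat), dep)
  expect_equal(fit0$rci, 0, tolerance = 1e-12)
  expect_equal(fit0$sii, 0, tolerance = 1e-12)
  # a development score (higher = better-off) gives the same answer flipped in
  dlt <- dplyr::mutate(dep, dlt_score = -deprivation_total)
  fit_dlt <- subnational_inequality(
    success_rates(d), dlt,
    ranking = "dlt_score", direction = "higher_less_deprived"
  )
  expect_equal(fit_dlt$rci, fit$rci, tolerance = 1e-12)
})

test_that("district inequality is invariant to row order and to cloning", {
  sim <- simulate_districts(n_districts = 12, seed = 8)
  dep <- deprivation_index(sim, attr(sim, "domain_map"))
  rates <- success_rates(sim)
  base <- subnational_inequality(rates, dep)
  perm <- sample(12)
  shuffled <- subnational_inequality(rates[perm, ], dep)
  expect_equal(shuffled$rci, base$rci, tolerance = 1e-12)
  expect_equal(shuffled$sii, base$sii, tolerance = 1e-9)
  # k identical copies of every district reproduce the single-copy metrics
  clone_ids <- function(tbl, k) {
    out <- tbl[rep(seq_len(nrow(tbl)), k), ]
    out$district_id <- paste0(out$district_id, "_", rep(seq_len(k), each = nrow(tbl)))
    out
  }
  rates3 <- clone_ids(rates, 3)
  dep3 <- clone_ids(dep, 3)
  tripled <- subnational_inequality(rates3, dep3)
  expect_equal(tripled$rci, base$rci, tolerance = 1e-10)
  expect_equal(tripled$sii, base$sii, tolerance = 1e-8)
})

test_that("count weighting uses geocoding attempts as weights", {
  sim <- simulate_districts(n_districts = 10, seed = 44)
  dep <- deprivation_index(sim, attr(sim, "domain_map"))
  rates <- success_rates(sim)
  wfit <- subnational_inequality(rates, dep, weighting = "count")
  manual <- concentration_index(
    rates$success_rate,
    -dep$deprivation_total[match(rates$district_id, dep$district_id)],
    weights = rates$n_attempted
  )
  expect_equal(wfit$rci, manual, tolerance = 1e-12)
})
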