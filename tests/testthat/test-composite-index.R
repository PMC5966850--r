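test_that("availability ranks orient, average ties, and sum to n(n+1)/2", {
  s <- scores_from_matrix(cbind(ind = c(A = 3, B = 1, C = 2)))
  expect_equal(rank_countries(s)$rank, c(3, 1, 2))

  tied <- scores_from_matrix(cbind(ind = c(A = 5, B = 5, C = 1)))
  expect_equal(rank_countries(tied)$rank, c(2.5, 2.5, 1))

  pop <- scores_from_matrix(cbind(ind = c(A = 1000, B = 1e7)),
    direction = "lower_better"
  )
  expect_equal(rank_countries(pop)$rank, c(2, 1))

  withr::with_seed(5, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      s <- scores_from_matrix(cbind(ind = sample(1:4, n, replace = TRUE)))
      expect_equal(sum(rank_countries(s)$rank), n * (n + 1) / 2)
    }
  })
})

test_that("domain index is the rank sum over the maximum possible rank sum", {
  # K = 2, n = 3, one country with ranks (3, 1) -> 4 / 6
  s <- scores_from_matrix(cbind(i1 = c(A = 9, B = 5, C = 1), i2 = c(A = 1, B = 5, C = 9)))
  di <- domain_indices(s)
  expect_equal(di$index[di$country_id == "A"], 4 / 6)
  expect_equal(di$index[di$country_id == "B"], 4 / 6)

  # best on all K indicators with no ties -> exactly 1
  best <- scores_from_matrix(cbind(i1 = c(A = 3, B = 2, C = 1), i2 = c(A = 9, B = 8, C = 7)))
  expect_equal(domain_indices(best)$index[1], 1)

  # worst on all K of n countries -> 1/n regardless of K
  n <- 183
  mat <- cbind(i1 = c(1, seq(2, n)), i2 = c(1, seq(2, n)), i3 = c(1, seq(2, n)))
  rownames(mat) <- sprintf("C%03d", seq_len(n))
  di <- domain_indices(scores_from_matrix(mat))
  expect_equal(di$index[di$country_id == "C001"], 1 / n)
})

test_that("a completely tied domain gives (n+1)/(2n) for every country", {
  for (n in c(3, 8, 25)) {
    mat <- cbind(i1 = rep(7, n), i2 = rep(7, n))
    rownames(mat) <- paste0("U", seq_len(n))
    di <- domain_indices(scores_from_matrix(mat))
    expect_equal(di$index, rep((n + 1) / (2 * n), n))
  }
})

test_that("rank aggregation matches the exhaustive pairwise-comparison oracle", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(2:8, 1)
      k <- sample(1:4, 1)
      mat <- matrix(sample(1:5, n * k, replace = TRUE), n, k,
        dimnames = list(paste0("U", seq_len(n)), paste0("i", seq_len(k)))
      )
      got <- domain_indices(scores_from_matrix(mat))
      oracle <- rowSums(apply(mat, 2, pairwise_rank_oracle)) / (k * n)
      expect_equal(
        got$index[match(rownames(mat), got$country_id)],
        unname(oracle),
        tolerance = 1e-12
      )
    }
  })
})

test_that("indices are invariant to monotone rescaling of any indicator", {
  withr::with_seed(8, {
    mat <- matrix(sample(1:6, 30, replace = TRUE), 10, 3,
      dimnames = list(paste0("U", 1:10), c("a", "b", "c"))
    )
    base <- domain_indices(scores_from_matrix(mat))
    mat2 <- mat
    mat2[, "b"] <- 17 * mat2[, "b"] # positive scale
    mat2[, "c"] <- exp(mat2[, "c"]) # strictly monotone transform
    expect_equal(domain_indices(scores_from_matrix(mat2)), base)
  })
})

test_that("adding a uniformly worse country preserves the original ordering", {
  withr::with_seed(13, {
    mat <- matrix(sample(2:6, 24, replace = TRUE), 8, 3,
      dimnames = list(paste0("U", 1:8), c("a", "b", "c"))
    )
    before <- domain_indices(scores_from_matrix(mat))
    worse <- rbind(mat, WORST = c(1, 1, 1))
    after <- domain_indices(scores_from_matrix(worse))
    after_common <- after$index[match(before$country_id, after$country_id)]
    expect_equal(rank(before$index), rank(after_common))
  })
})

test_that("the overall index is the sum of the three domain indices", {
  co <- simulate_countries(n_countries = 20, seed = 2)
  sc <- score_indicators(co)
  idx <- resource_index(sc)
  di <- domain_indices(sc) |>
    tidyr::pivot_wider(
      id_cols = "country_id", names_from = "domain", values_from = "index"
    )
  merged <- dplyr::inner_join(idx, di, by = "country_id")
  expect_equal(
    merged$overall_index,
    merged$geocoding + merged$travel + merged$neighbourhood
  )
  expect_true(all(idx$overall_index > 0 & idx$overall_index <= 3))
})

test_that("mismatched country coverage across indicators is an error", {
  s <- scores_from_matrix(cbind(i1 = c(A = 1, B = 2, C = 3)))
  partial <- dplyr::bind_rows(
    s,
    tibble::tibble(
      country_id = c("A", "B"), indicator = "i2", domain = "geocoding",
      score = c(1, 2), direction = "higher_better", provenance = "observed"
    )
  )
  expect_error(domain_indices(partial), "i2")
  expect_error(rank_countries(s[0, ]), "empty")
})
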