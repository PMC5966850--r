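test_that("fractional ranks follow the cumulative-midpoint construction", {
  expect_equal(fractional_ranks(c(1, 2, 3, 4)), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(fractional_ranks(c(4, 1, 3, 2)), c(0.875, 0.125, 0.625, 0.375))
  expect_equal(fractional_ranks(c(7, 7)), c(0.5, 0.5))
  expect_equal(fractional_ranks(c(1, 2), weights = c(1, 3)), c(0.125, 0.625))
  expect_error(fractional_ranks(1), "at least 2")
  expect_error(fractional_ranks(c(1, 2), weights = c(1, -1)), "positive")
})

test_that("weighted mean of fractional ranks is exactly 0.5, ties included", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(2:40, 1)
      x <- sample(1:6, n, replace = TRUE) # heavy ties
      w <- runif(n, 0.1, 5)
      r <- fractional_ranks(x, w)
      expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-12)
      expect_true(all(r > 0 & r < 1))
      # tied exposures share one rank
      expect_true(all(tapply(r, x, function(v) diff(range(v))) < 1e-12))
    }
  })
})

test_that("concentration index matches its direct-evaluation examples", {
  expect_equal(concentration_index(c(10, 20, 30, 40), 1:4), 0.25)
  expect_equal(concentration_index(c(10, 20, 30, 40), 4:1), -0.25)
  expect_equal(concentration_index(rep(7, 6), 1:6), 0)
  expect_warning(out <- concentration_index(rep(0, 4), 1:4), "zero")
  expect_equal(out, 0)
})

test_that("covariance form agrees with the summation-form oracle to 1e-12", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(3:10, 1)
      y <- runif(n, 0, 50)
      x <- sample(seq_len(100), n) # distinct -> no ties
      expect_equal(
        concentration_index(y, x), rci_sum_oracle(y, x),
        tolerance = 1e-12
      )
    }
  })
})

test_that("the concentration index is scale-free and bounded", {
  withr::with_seed(32, {
    for (i in 1:20) {
      n <- sample(4:30, 1)
      y <- rexp(n, 1 / 50)
      x <- sample(1:5, n, replace = TRUE)
      rci <- concentration_index(y, x)
      expect_lte(abs(rci), 1)
      expect_equal(concentration_index(3.7 * y, x), rci, tolerance = 1e-12)
    }
  })
})

test_that("slope index recovers a noiseless linear gradient exactly", {
  r <- (seq_len(8) - 0.5) / 8
  y <- 100 - 50 * r
  got <- slope_index(y, seq_len(8))
  expect_equal(got$sii, 50, tolerance = 1e-9)
  expect_equal(got$hi - got$lo, 0, tolerance = 1e-6)
})

test_that("slope index is minus the rank-regression slope", {
  got <- slope_index(c(10, 20, 30, 40), 1:4)
  expect_equal(got$sii, -40, tolerance = 1e-9)
  flat <- slope_index(rep(5, 5), 1:5)
  expect_equal(flat$sii, 0, tolerance = 1e-12)
  expect_true(flat$lo <= 0 && flat$hi >= 0)
  expect_error(slope_index(c(1, 2, 3), c(2, 2, 2)), "tie")
  expect_error(slope_index(c(1, 2), 1:2), "at least 3")
})

test_that("reversing the exposure ranking negates both metrics", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(4:25, 1)
      y <- runif(n, 1, 100)
      x <- runif(n)
      expect_equal(
        concentration_index(y, -x), -concentration_index(y, x),
        tolerance = 1e-10
      )
      expect_equal(
        slope_index(y, -x)$sii, -slope_index(y, x)$sii,
        tolerance = 1e-8
      )
    }
  })
})

test_that("rescaling the outcome leaves RCI fixed and scales SII", {
  withr::with_seed(15, {
    y <- runif(12, 10, 90)
    x <- runif(12)
    k <- 4.2
    expect_equal(concentration_index(k * y, x), concentration_index(y, x))
    expect_equal(slope_index(k * y, x)$sii, k * slope_index(y, x)$sii)
  })
})

test_that("inequality_index handles direction, weights, and tidy output", {
  d <- tibble::tibble(
    rate = c(40, 30, 20, 10),
    availability = 1:4,
    burden = 4:1,
    w = c(1, 1, 1, 1)
  )
  fit <- inequality_index(d, "rate", "availability")
  expect_s3_class(fit, "geo_ineq")
  expect_equal(fit$rci, -0.25)
  expect_equal(fit$sii, 40, tolerance = 1e-9)
  # lower_better flips the exposure orientation
  flip <- inequality_index(d, "rate", "burden", direction = "lower_better")
  expect_equal(flip$rci, fit$rci)
  expect_equal(flip$sii, fit$sii, tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(
    names(td),
    c("outcome", "ranking", "rci", "sii", "sii_lo", "sii_hi", "n")
  )
  expect_true(td$sii_lo <= td$sii & td$sii <= td$sii_hi)
  gl <- glance(fit)
  expect_equal(gl$n, 4)
})

test_that("bootstrap intervals are seeded and bracket the point estimate", {
  withr::with_seed(3, {
    d <- tibble::tibble(y = 100 - 40 * runif(30) + rnorm(30, 0, 5), x = runif(30))
  })
  b1 <- inequality_index(d, "y", "x", method = "bootstrap", n_boot = 200, seed = 7)
  b2 <- inequality_index(d, "y", "x", method = "bootstrap", n_boot = 200, seed = 7)
  expect_equal(b1$sii_lo, b2$sii_lo)
  expect_true(b1$sii_lo <= b1$sii && b1$sii <= b1$sii_hi)
})

test_that("inequality_table yields one row per ranking x outcome pair", {
  withr::with_seed(19, {
    d <- tibble::tibble(
      u = paste0("U", 1:12),
      y1 = runif(12, 10, 50), y2 = runif(12, 1, 5),
      r1 = runif(12), r2 = sample(1:3, 12, TRUE), r3 = runif(12)
    )
  })
  tbl <- inequality_table(d, outcomes = c("y1", "y2"), rankings = c("r1", "r2", "r3"))
  expect_equal(nrow(tbl), 6)
  expect_equal(names(tbl)[1:2], c("ranking", "outcome"))
  # determinism: the same outcome passed twice gives identical rows
  tbl2 <- inequality_table(d, outcomes = c("y1", "y1"), rankings = "r1")
  expect_equal(tbl2[1, -2], tbl2[2, -2])
})

test_that("permuting input row order leaves the metrics unchanged", {
  withr::with_seed(55, {
    d <- tibble::tibble(y = runif(15, 5, 50), x = sample(1:4, 15, TRUE))
    perm <- sample(15)
    expect_equal(
      concentration_index(d$y[perm], d$x[perm]),
      concentration_index(d$y, d$x),
      tolerance = 1e-12
    )
    expect_equal(
      slope_index(d$y[perm], d$x[perm])$sii,
      slope_index(d$y, d$x)$sii,
      tolerance = 1e-9
    )
  })
})
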