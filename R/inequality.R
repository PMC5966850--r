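#' Fractional (ridit) ranks
#'
#' Positions each unit at the midpoint of its cumulative weight share
#' after sorting by the ranking variable ascending, i.e. worst-off first
#' (most data-poor, or most deprived). With equal weights and no ties the
#' ranks are (i - 0.5)/n; tied units all receive the midpoint of their
#' tied block, so the weighted mean of the ranks is exactly 0.5.
#'
#' @param exposure Numeric ranking variable; smallest = worst-off.
#' @param weights Positive weights, default equal.
#' @return Fractional ranks in (0, 1), in the input order.
#' @examples
#' fractional_ranks(c(4, 1, 3, 2))
#' @export
fractional_ranks <- function(exposure, weights = NULL) {
  n <- length(exposure)
  if (n < 2) abort("fractional ranks need at least 2 units")
  if (anyNA(exposure)) abort("exposure contains missing values")
  weights <- weights %||% rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    abort("weights must be positive and match the number of units")
  }
  w <- weights / sum(weights)
  ord <- order(exposure)
  w_sorted <- w[ord]
  x_sorted <- exposure[ord]
  cum_before <- cumsum(w_sorted) - w_sorted
  r_sorted <- cum_before + w_sorted / 2
  # tied exposures share their block's cumulative-weight midpoint
  blocks <- match(x_sorted, unique(x_sorted))
  block_w <- tapply(w_sorted, blocks, sum)
  block_before <- tapply(cum_before, blocks, min)
  r_sorted <- as.numeric(block_before[blocks] + block_w[blocks] / 2)
  r <- numeric(n)
  r[ord] <- r_sorted
  r
}

#' Relative concentration index
#'
#' The covariance form `2 * cov_w(y, r) / mu`, where `r` are fractional
#' ranks by the exposure variable (worst-off first) and `mu` the weighted
#' mean outcome. Negative values mean the outcome is concentrated among
#' the worst-off units (data-poor, or most deprived); zero means no
#' gradient. Bounded in (-1, 1) for non-negative outcomes.
#'
#' @param y Non-negative outcome values.
#' @param exposure Ranking variable, smallest = worst-off.
#' @param weights Optional positive weights.
#' @return A single numeric value.
#' @examples
#' concentration_index(c(10, 20, 30, 40), 1:4)
#' @export
concentration_index <- function(y, exposure, weights = NULL) {
  n <- length(y)
  weights <- weights %||% rep(1, n)
  r <- fractional_ranks(exposure, weights)
  w <- weights / sum(weights)
  mu <- sum(w * y)
  if (mu == 0) {
    warn("outcome is identically zero; concentration index defined as 0")
    return(0)
  }
  r_bar <- sum(w * r)
  cov_w <- sum(w * (y - mu) * (r - r_bar))
  2 * cov_w / mu
}

#' Slope index of inequality
#'
#' Fits a (weighted) least-squares regression of the outcome on the
#' fractional rank and reports the modelled outcome gap between the two
#' extremes of the ranking, oriented as worst-off end minus best-off end:
#' positive when the data-poor / most-deprived end carries the higher
#' outcome, the natural companion of a negative concentration index.
#'
#' @inheritParams concentration_index
#' @param ci_level Confidence level for the interval (default 0.95).
#' @param method `"wls"` for the analytic t-based interval on the
#'   regression slope, or `"bootstrap"` for a seeded percentile interval.
#' @param n_boot Number of bootstrap resamples (`method = "bootstrap"`).
#' @param seed Seed for the bootstrap resampling.
#' @return A list with elements `sii`, `lo`, `hi`, `se`, `n`.
#' @examples
#' slope_index(c(40, 30, 20, 10), 1:4)
#' @export
slope_index <- function(y, exposure, weights = NULL, ci_level = 0.95,
                        method = c("wls", "bootstrap"), n_boot = 1000,
                        seed = NULL) {
  method <- match.arg(method)
  n <- length(y)
  if (n < 3) abort("slope index needs at least 3 units")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must lie in (0, 1)")
  weights <- weights %||% rep(1, n)
  if (length(unique(exposure)) == 1) {
    abort("all exposures identical: slope undefined on a complete tie")
  }
  r <- fractional_ranks(exposure, weights)
  fit <- lm(y ~ r, weights = weights)
  beta <- unname(coef(fit)[["r"]])
  # an exact fit legitimately has zero slope SE; vcov.lm warns about it
  se <- sqrt(suppressWarnings(vcov(fit))["r", "r"])
  sii <- -beta # worst-off end minus best-off end
  if (method == "wls") {
    tcrit <- qt(1 - (1 - ci_level) / 2, df = n - 2)
    bounds <- sort(c(sii - tcrit * se, sii + tcrit * se))
  } else {
    draws <- withr::with_seed(seed %||% 1L, {
      purrr::map_dbl(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(exposure[idx])) == 1) {
          return(NA_real_)
        }
        rb <- fractional_ranks(exposure[idx], weights[idx])
        -unname(coef(lm(y[idx] ~ rb, weights = weights[idx]))[["rb"]])
      })
    })
    alpha <- 1 - ci_level
    bounds <- unname(quantile(draws,
      probs = c(alpha / 2, 1 - alpha / 2),
      na.rm = TRUE
    ))
  }
  list(sii = sii, lo = bounds[1], hi = bounds[2], se = se, n = n)
}

#' Fit both inequality metrics for one outcome and ranking
#'
#' Convenience wrapper producing a fitted `geo_ineq` object holding the
#' relative concentration index and the slope index of inequality with
#' its confidence interval, plus the unit-level data used. [tidy()]
#' returns the one-row result table; [glance()] the fit metadata;
#' [autoplot()] the outcome-versus-rank scatter with the fitted line.
#'
#' @param data A data frame with one row per unit.
#' @param outcome Name of the outcome column (string).
#' @param ranking Name of the ranking column (string); larger values must
#'   mean better-off (more data-rich / less deprived). Use
#'   `direction = "lower_better"` to flip.
#' @param direction `"higher_better"` (default) or `"lower_better"` for
#'   the ranking variable.
#' @param weights Optional name of a weight column.
#' @inheritParams slope_index
#' @return An object of class `geo_ineq`.
#' @examples
#' d <- tibble::tibble(rate = c(40, 30, 20, 10), availability = 1:4)
#' tidy(inequality_index(d, "rate", "availability"))
#' @export
inequality_index <- function(data, outcome, ranking,
                             direction = c("higher_better", "lower_better"),
                             weights = NULL, ci_level = 0.95,
                             method = c("wls", "bootstrap"),
                             n_boot = 1000, seed = NULL) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  for (col in c(outcome, ranking, weights)) {
    if (!col %in% names(data)) abort(paste0("column not found: ", col))
  }
  y <- data[[outcome]]
  exposure <- data[[ranking]]
  if (direction == "lower_better") exposure <- -exposure
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  rci <- concentration_index(y, exposure, w)
  sii <- slope_index(y, exposure, w,
    ci_level = ci_level, method = method,
    n_boot = n_boot, seed = seed
  )
  structure(
    list(
      rci = rci,
      sii = sii$sii, sii_lo = sii$lo, sii_hi = sii$hi, sii_se = sii$se,
      n = sii$n,
      outcome = outcome, ranking = ranking, ci_level = ci_level,
      method = method,
      units = tibble::tibble(
        outcome = y,
        fractional_rank = fractional_ranks(exposure, w),
        weight = w
      )
    ),
    class = "geo_ineq"
  )
}

#' @export
print.geo_ineq <- function(x, ...) {
  cat("<geo_ineq> ", x$outcome, " vs ", x$ranking, " (n = ", x$n, ")\n",
    sep = ""
  )
  cat(sprintf(
    "  RCI %.3f | SII %.2f (%d%% CI %.2f to %.2f)\n",
    x$rci, x$sii, round(100 * x$ci_level), x$sii_lo, x$sii_hi
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geo_ineq <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    ranking = x$ranking,
    rci = x$rci,
    sii = x$sii,
    sii_lo = x$sii_lo,
    sii_hi = x$sii_hi,
    n = x$n
  )
}

#' @exportS3Method generics::glance
glance.geo_ineq <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    ci_level = x$ci_level,
    method = x$method,
    sii_se = x$sii_se,
    mean_outcome = weighted.mean(x$units$outcome, x$units$weight)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.geo_ineq <- function(object, ...) {
  ggplot2::ggplot(
    object$units,
    ggplot2::aes(x = .data$fractional_rank, y = .data$outcome)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.7) +
    ggplot2::geom_smooth(
      formula = y ~ x, method = "lm",
      ggplot2::aes(weight = .data$weight), se = FALSE, colour = "firebrick"
    ) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(
      x = paste0("Fractional rank by ", object$ranking, " (worst-off first)"),
      y = object$outcome,
      title = sprintf(
        "RCI %.3f, SII %.2f (%.0f%% CI %.2f to %.2f)",
        object$rci, object$sii, 100 * object$ci_level,
        object$sii_lo, object$sii_hi
      )
    ) +
    ggplot2::theme_minimal()
}

#' Inequality metrics for every ranking x outcome pair
#'
#' Builds the full results grid: each ranking variable (each provider
#' indicator, each domain index, the overall index) against each outcome
#' column, one row per pair.
#'
#' @param data Data frame holding the outcome and ranking columns, one
#'   row per unit.
#' @param outcomes Character vector of outcome column names.
#' @param rankings Character vector of ranking column names.
#' @param directions Optional named character vector giving the direction
#'   of specific rankings (`"lower_better"` entries are flipped);
#'   unnamed rankings default to `"higher_better"`.
#' @inheritParams inequality_index
#' @return A tibble with columns `ranking`, `outcome`, `rci`, `sii`,
#'   `sii_lo`, `sii_hi`, `n`.
#' @export
inequality_table <- function(data, outcomes, rankings, directions = NULL,
                             weights = NULL, ci_level = 0.95,
                             method = c("wls", "bootstrap"),
                             n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(ranking = rankings, outcome = outcomes)
  purrr::pmap(grid, function(ranking, outcome) {
    dir <- directions[ranking]
    dir <- if (is.null(dir) || is.na(dir)) "higher_better" else unname(dir)
    fit <- inequality_index(
      data, outcome, ranking,
      direction = dir, weights = weights, ci_level = ci_level,
      method = method, n_boot = n_boot, seed = seed
    )
    tidy(fit)
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("ranking", "outcome")
}

#' Forest-style plot of an inequality results table
#'
#' @param table Output of [inequality_table()] or
#'   [international_inequality()].
#' @param value `"sii"` (with its confidence interval) or `"rci"`.
#' @return A ggplot object.
#' @export
plot_inequality <- function(table, value = c("sii", "rci")) {
  value <- match.arg(value)
  p <- ggplot2::ggplot(
    table,
    ggplot2::aes(y = .data$ranking, x = .data[[value]])
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL)
  if (value == "sii" && all(c("sii_lo", "sii_hi") %in% names(table))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$sii_lo, xmax = .data$sii_hi),
      height = 0.2
    )
  }
  p
}
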