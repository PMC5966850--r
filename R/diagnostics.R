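#' Outlier diagnostics for the mortality-index regression
#'
#' Regresses log mortality on the overall geospatial resource index and
#' flags countries whose studentised residual exceeds the threshold in
#' absolute value — countries with unusually rich or poor commercial data
#' given their mortality. Residuals are externally studentised by default
#' (each country's residual scaled by the leave-one-out error variance),
#' the standard choice for outlier screening; internally studentised
#' residuals are available via `type`.
#'
#' @param data Country table containing the outcome column.
#' @param index Resource index tibble from [resource_index()], or any
#'   data frame with `country_id` and the column named by `index_col`.
#' @param outcome Outcome column in `data` (must be strictly positive).
#' @param index_col Index column in `index`.
#' @param threshold Absolute studentised-residual cutoff (default 2).
#' @param type `"external"` (leave-one-out, default) or `"internal"`.
#' @return A `geo_outliers` object. [tidy()] gives the per-country table
#'   (index, outcome, fitted log outcome, studentised residual, outlier
#'   flag); [glance()] the regression summary; [autoplot()] the labelled
#'   scatter of log outcome versus index.
#' @examples
#' countries <- simulate_countries(n_countries = 30, seed = 2)
#' idx <- resource_index(score_indicators(countries))
#' rep <- log_regression_outliers(countries, idx)
#' glance(rep)
#' @export
log_regression_outliers <- function(data, index, outcome = "mortality_all",
                                    index_col = "overall_index",
                                    threshold = 2,
                                    type = c("external", "internal")) {
  type <- match.arg(type)
  if (threshold <= 0) abort("threshold must be positive")
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(data), "country_id", dplyr::all_of(outcome)),
    dplyr::select(tibble::as_tibble(index), "country_id", dplyr::all_of(index_col)),
    by = "country_id"
  )
  if (nrow(joined) < 4) abort("need at least 4 countries")
  y <- joined[[outcome]]
  if (any(y <= 0)) {
    abort(paste0(
      "log undefined: non-positive ", outcome, " for ",
      paste(joined$country_id[y <= 0], collapse = ", ")
    ))
  }
  x <- joined[[index_col]]
  fit <- lm(log(y) ~ x)
  resid_st <- if (type == "external") rstudent(fit) else rstandard(fit)
  # on an (almost) exact fit the residual variance degenerates to floating
  # noise: a vanishing residual is then no outlier, a non-vanishing one an
  # extreme whose leave-one-out variance is zero
  raw <- stats::residuals(fit)
  tol <- 1e-8 * (1 + max(abs(log(y))))
  if (stats::sigma(fit) <= tol) {
    resid_st[] <- 0
  } else {
    degenerate <- !is.finite(resid_st)
    resid_st[degenerate] <- ifelse(
      abs(raw[degenerate]) <= tol, 0, sign(raw[degenerate]) * Inf
    )
  }
  tbl <- tibble::tibble(
    country_id = joined$country_id,
    index = x,
    outcome = y,
    log_outcome = log(y),
    fitted = unname(fitted(fit)),
    studentised_residual = unname(resid_st),
    is_outlier = abs(unname(resid_st)) > threshold
  )
  structure(
    list(
      table = tbl,
      model = fit,
      slope = unname(coef(fit)[["x"]]),
      intercept = unname(coef(fit)[[1]]),
      threshold = threshold,
      type = type,
      outcome = outcome
    ),
    class = "geo_outliers"
  )
}

#' @export
print.geo_outliers <- function(x, ...) {
  out <- x$table$country_id[x$table$is_outlier]
  cat("<geo_outliers> log(", x$outcome, ") ~ index, n = ", nrow(x$table),
    "\n  slope ", format(x$slope, digits = 4),
    ", ", length(out), " outlier(s) at |t| > ", x$threshold, "\n",
    sep = ""
  )
  if (length(out) > 0) cat("  ", paste(out, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geo_outliers <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.geo_outliers <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    # summary.lm warns on an exact fit; its R^2 of 1 is still the answer
    r_squared = suppressWarnings(summary(x$model)$r.squared),
    n = nrow(x$table),
    n_outliers = sum(x$table$is_outlier),
    threshold = x$threshold,
    residual_type = x$type
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.geo_outliers <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$index, y = .data$log_outcome)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_outlier)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey40") +
    ggplot2::geom_text(
      data = dplyr::filter(tbl, .data$is_outlier),
      ggplot2::aes(label = .data$country_id),
      vjust = -0.6, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Overall geospatial resource index",
      y = paste0("log(", object$outcome, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Correlation of the resource index with national covariates
#'
#' Pearson correlation of the overall index with internet use and GDP per
#' capita, each on pairwise-complete observations (GDP is missing for
#' some countries, so its n is reported separately).
#'
#' @inheritParams log_regression_outliers
#' @param covariates Covariate columns in `data`.
#' @return A tibble `covariate`, `r`, `p_value`, `n`.
#' @export
covariate_correlations <- function(data, index,
                                   covariates = c("internet_users_pct", "gdp_per_capita"),
                                   index_col = "overall_index") {
  joined <- dplyr::inner_join(
    tibble::as_tibble(data), dplyr::select(
      tibble::as_tibble(index), "country_id", dplyr::all_of(index_col)
    ),
    by = "country_id"
  )
  purrr::map(covariates, function(cv) {
    if (!cv %in% names(joined)) abort(paste0("covariate not found: ", cv))
    ok <- stats::complete.cases(joined[[cv]], joined[[index_col]])
    if (sum(ok) < 3) {
      abort(paste0("fewer than 3 complete pairs for ", cv))
    }
    ct <- cor.test(joined[[index_col]][ok], joined[[cv]][ok], method = "pearson")
    tibble::tibble(
      covariate = cv,
      r = unname(ct$estimate),
      p_value = ct$p.value,
      n = sum(ok)
    )
  }) |>
    purrr::list_rbind()
}
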