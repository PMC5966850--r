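#' Indicator catalogs
#'
#' A catalog describes every availability indicator the international
#' analysis uses: its domain (`geocoding`, `travel` or `neighbourhood`),
#' its kind, and — for categorical indicators — the ordered set of provider
#' coverage levels from worst to best, together with a reference count of
#' countries at each level out of a reference total. The package ships a
#' catalog covering five geocoding providers, five travel-time providers
#' and three neighbourhood-statistics measures; [read_catalog()] loads an
#' edited copy from any YAML file with the same layout.
#'
#' Indicator kinds:
#' \describe{
#'   \item{`ordinal`}{a single provider coverage category per country,
#'     scored by its 1-based position in `levels` (worst = 1).}
#'   \item{`travel_composite`}{five quality components each scored
#'     good = 2 / approximate = 1 / otherwise 0 and summed (range 0-10).}
#'   \item{`numeric`}{a continuous measure with an explicit `direction`
#'     (e.g. mean population per areal unit, where lower is better).}
#'   \item{`count`}{a non-negative count, missing treated as zero.}
#'   \item{`availability_count`}{number of available products out of a
#'     fixed set of boolean flags (range 0-3).}
#' }
#'
#' @param path Path to a catalog YAML file.
#' @return A `geo_catalog` object: a list with elements `countries_total`
#'   and `indicators` (a named list of indicator specifications).
#' @examples
#' cat <- default_catalog()
#' catalog_indicators(cat)
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("catalog file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$indicators) || is.null(raw$countries_total)) {
    abort("catalog must define `countries_total` and `indicators`")
  }
  for (nm in names(raw$indicators)) {
    spec <- raw$indicators[[nm]]
    kind <- spec$kind %||% abort(paste0("indicator `", nm, "` has no kind"))
    if (kind == "ordinal" && length(spec$levels) == 0) {
      abort(paste0("ordinal indicator `", nm, "` has no levels"))
    }
  }
  structure(raw, class = "geo_catalog")
}

#' @rdname read_catalog
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "indicator_catalog.yaml",
    package = "geoequity", mustWork = TRUE
  ))
}

#' @rdname read_catalog
#' @param catalog A `geo_catalog` object.
#' @return `catalog_indicators()` returns one row per indicator with
#'   columns `indicator`, `label`, `domain`, `kind`, `direction`,
#'   `missing_policy` and a list-column `levels` (worst to best).
#' @export
catalog_indicators <- function(catalog) {
  stopifnot(inherits(catalog, "geo_catalog"))
  purrr::imap(catalog$indicators, function(spec, nm) {
    tibble::tibble(
      indicator = nm,
      label = spec$label %||% nm,
      domain = spec$domain,
      kind = spec$kind,
      direction = spec$direction %||% "higher_better",
      missing_policy = spec$missing_policy %||% "worst",
      levels = list(purrr::map_chr(spec$levels %||% list(), "label"))
    )
  }) |>
    purrr::list_rbind()
}

#' @export
print.geo_catalog <- function(x, ...) {
  tbl <- catalog_indicators(x)
  cat(
    "<geo_catalog> ", nrow(tbl), " indicators, reference total ",
    x$countries_total, " countries\n",
    sep = ""
  )
  print(dplyr::count(tbl, .data$domain, name = "indicators"))
  invisible(x)
}

# ordered worst-to-best level labels of a categorical indicator
catalog_levels <- function(catalog, indicator) {
  spec <- catalog$indicators[[indicator]]
  if (is.null(spec)) abort(paste0("unknown indicator: ", indicator))
  purrr::map_chr(spec$levels, "label")
}

# reference count of countries at each level (worst to best)
catalog_level_counts <- function(catalog, indicator) {
  spec <- catalog$indicators[[indicator]]
  counts <- purrr::map_int(spec$levels, "count")
  setNames(counts, purrr::map_chr(spec$levels, "label"))
}

# indicator names of a given kind, in catalog order
catalog_names <- function(catalog, kinds = NULL) {
  nms <- names(catalog$indicators)
  if (is.null(kinds)) {
    return(nms)
  }
  keep <- purrr::map_chr(catalog$indicators, "kind") %in% kinds
  nms[keep]
}

google_component_names <- function() {
  c("traffic", "speed_limits", "cycling", "walking", "driving")
}

geodemographic_components <- function() {
  c("mosaic_available", "cameo_available", "maptitude_available")
}
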