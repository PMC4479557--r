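#' Baseline-year ratio normalization
#'
#' Transforms every indicator into a dimensionless the-higher-the-better
#' number relative to the baseline (background) year:
#' benefit-direction indicators use \eqn{x' = x_{i,j} / x_{base,j}},
#' cost-direction indicators use \eqn{x' = x_{base,j} / x_{i,j}}. Every
#' indicator therefore equals exactly 1 in the baseline year, and values
#' below 1 mark deterioration relative to the background condition. The
#' direction flag is a property of the indicator, not of individual
#' values.
#'
#' Both ratios divide by raw values, so any zero or negative value is an
#' error (reported with indicator and year).
#'
#' @param panel An [indicator_panel()] (or data frame in panel layout with
#'   a baseline year supplied via `baseline_year`).
#' @param baseline_year Optional override of the panel's baseline year.
#' @return A `normalized_panel`: same layout as the input panel, values
#'   replaced by normalized ones.
#' @examples
#' pan <- indicator_panel(
#'   tibble::tibble(
#'     year = rep(2000:2002, 2),
#'     indicator_id = rep(c("gdp", "tp"), each = 3),
#'     category = rep(c("D", "S"), each = 3),
#'     direction = rep(c("benefit", "cost"), each = 3),
#'     value = c(2, 3, 4, 2, 4, 8)
#'   ),
#'   baseline_year = 2000
#' )
#' normalize_panel(pan)
#' @export
normalize_panel <- function(panel, baseline_year = NULL) {
  x <- as_tibble(panel)
  bad <- x[!is.finite(x$value) | x$value <= 0, ]
  if (nrow(bad) > 0) {
    abort(paste0(
      "Normalization requires strictly positive values; offending: ",
      paste(head(paste0(bad$indicator_id, "@", bad$year), 5L),
            collapse = ", ")
    ))
  }
  panel <- as_indicator_panel(panel, baseline_year)
  by <- panel_baseline(panel)
  base_vals <- dplyr::filter(as_tibble(panel), .data$year == by) |>
    dplyr::select("indicator_id", base = "value")
  out <- as_tibble(panel) |>
    dplyr::left_join(base_vals, by = "indicator_id") |>
    dplyr::mutate(
      value = dplyr::if_else(
        .data$direction == "benefit",
        .data$value / .data$base,
        .data$base / .data$value
      )
    ) |>
    dplyr::select(-"base")
  res <- indicator_panel(out, baseline_year = by)
  class(res) <- c("normalized_panel", class(res))
  res
}

#' Component weights
#'
#' Weights for the geometric-mean aggregation: within each DPSIR
#' component, non-negative per-indicator weights summing to 1; across
#' components, non-negative weights summing to 1. The default is uniform
#' weighting at both levels (1/m within a component with m indicators,
#' 1/5 across the five components), the convention used for lake
#' assessments unless expert weighting is available.
#'
#' @param panel An [indicator_panel()] used to enumerate the indicators of
#'   each component (only needed when `within` is not fully specified).
#' @param within Named list: category -> named numeric vector of
#'   per-indicator weights. Missing categories get uniform weights.
#' @param across Named numeric vector of component weights over the
#'   categories present. Defaults to uniform.
#' @return A list of class `component_weights` with elements `within` and
#'   `across`.
#' @export
component_weights <- function(panel, within = NULL, across = NULL) {
  meta <- panel_meta(panel)
  cats <- intersect(DPSIR_CATEGORIES, unique(meta$category))
  within_full <- lapply(setNames(cats, cats), function(cat) {
    ids <- sort(meta$indicator_id[meta$category == cat])
    w <- within[[cat]]
    if (is.null(w)) {
      return(setNames(rep(1 / length(ids), length(ids)), ids))
    }
    if (!setequal(names(w), ids)) {
      abort(paste0(
        "Weights for category ", cat, " must cover exactly its ",
        "indicators. Missing: ",
        paste(setdiff(ids, names(w)), collapse = ", "),
        "; extraneous: ",
        paste(setdiff(names(w), ids), collapse = ", ")
      ))
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort(paste0(
        "Within-component weights for ", cat,
        " must be non-negative and sum to 1."
      ))
    }
    w[ids]
  })
  if (is.null(across)) {
    across <- setNames(rep(1 / length(cats), length(cats)), cats)
  } else {
    if (!setequal(names(across), cats)) {
      abort(paste0(
        "Across-component weights must cover exactly: ",
        paste(cats, collapse = ", ")
      ))
    }
    if (any(across < 0) || abs(sum(across) - 1) > 1e-8) {
      abort("Across-component weights must be non-negative and sum to 1.")
    }
    across <- across[cats]
  }
  structure(
    list(within = within_full, across = across),
    class = "component_weights"
  )
}

#' DPSIR component index (weighted geometric mean)
#'
#' For component k with normalized indicator values \eqn{x'_{i,j}} and
#' weights \eqn{w_{k,j}} summing to 1, the annual index is
#' \deqn{Index_{k,i} = \prod_{j \in k} (x'_{i,j})^{w_{k,j}}.}
#'
#' @param norm_panel A `normalized_panel` (from [normalize_panel()]).
#' @param category Component to aggregate; `NULL` aggregates every
#'   category present.
#' @param weights A [component_weights()] object; `NULL` for uniform.
#' @return A tibble with columns `year`, `category`, `index`.
#' @export
component_index <- function(norm_panel, category = NULL, weights = NULL) {
  x <- as_tibble(norm_panel)
  cats <- if (is.null(category)) {
    intersect(DPSIR_CATEGORIES, unique(x$category))
  } else {
    category
  }
  if (is.null(weights)) weights <- component_weights(norm_panel)
  purrr::map_dfr(cats, function(cat) {
    sub <- dplyr::filter(x, .data$category == !!cat)
    if (nrow(sub) == 0L) {
      abort(paste0("No indicators in category ", cat, "."))
    }
    ids <- sort(unique(sub$indicator_id))
    w <- weights$within[[cat]]
    if (is.null(w) || !setequal(names(w), ids)) {
      abort(paste0(
        "Weight set mismatch for category ", cat, ". Missing weights: ",
        paste(setdiff(ids, names(w)), collapse = ", "),
        "; weights without indicator: ",
        paste(setdiff(names(w), ids), collapse = ", ")
      ))
    }
    sub |>
      dplyr::mutate(w = w[.data$indicator_id]) |>
      dplyr::group_by(year = .data$year) |>
      dplyr::summarise(
        category = cat,
        index = prod(.data$value^.data$w),
        .groups = "drop"
      )
  })
}

#' Ecological Security Index (ESI)
#'
#' Weighted geometric mean of the five DPSIR component indices:
#' \deqn{ESI_i = \prod_k (Index_{k,i})^{w_k},} with uniform default
#' weights \eqn{w_k = 1/5}. Every component must be present for every
#' year.
#'
#' @param components A tibble with columns `year`, `category`, `index`
#'   (as from [component_index()]) covering all five categories.
#' @param weights A [component_weights()] object or a named numeric vector
#'   of component weights; `NULL` for uniform.
#' @return A tibble with columns `year`, `esi`.
#' @export
esi <- function(components, weights = NULL) {
  x <- as_tibble(components)
  cats <- sort(unique(x$category))
  w <- if (is.null(weights)) {
    setNames(rep(1 / length(cats), length(cats)), cats)
  } else if (inherits(weights, "component_weights")) {
    weights$across
  } else {
    weights
  }
  if (!setequal(names(w), cats)) {
    abort(paste0(
      "Component weights must cover exactly: ",
      paste(cats, collapse = ", ")
    ))
  }
  grid <- tidyr::expand_grid(
    year = sort(unique(x$year)), category = cats
  )
  missing <- dplyr::anti_join(grid, x, by = c("year", "category"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Missing component-year combination(s): ",
      paste(head(
        paste0(missing$category, "@", missing$year), 5L
      ), collapse = ", ")
    ))
  }
  x |>
    dplyr::mutate(w = w[.data$category]) |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(esi = prod(.data$index^.data$w), .groups = "drop")
}

#' Full index table from a panel
#'
#' Convenience wrapper: normalizes a panel, computes every component
#' index and the ESI, and returns a wide year-by-component tibble.
#'
#' @param panel An [indicator_panel()] (raw values).
#' @param weights A [component_weights()] object; `NULL` for uniform.
#' @return A tibble with columns `year`, one column per category present,
#'   and `ESI`.
#' @export
compute_indices <- function(panel, weights = NULL) {
  norm <- normalize_panel(panel)
  comp <- component_index(norm, weights = weights)
  es <- esi(comp, weights = weights)
  wide <- tidyr::pivot_wider(
    comp,
    names_from = "category", values_from = "index"
  )
  dplyr::left_join(wide, es, by = "year") |>
    dplyr::rename(ESI = "esi") |>
    dplyr::arrange(.data$year)
}

#' Write index series as tidy CSV
#'
#' @param indices A wide index tibble (as from [compute_indices()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_indices_csv <- function(indices, path) {
  readr::write_csv(indices, path)
  invisible(path)
}
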