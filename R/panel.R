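#' Indicator panels
#'
#' An indicator panel is a long-format tibble of annual indicator values,
#' one row per year and indicator, with columns:
#'
#' * `year` — calendar year (integer); years must form a contiguous range
#'   and every indicator must cover every year.
#' * `indicator_id` — short unique identifier of the indicator.
#' * `category` — DPSIR component the indicator belongs to, one of
#'   `"D"` (driving force), `"P"` (pressure), `"S"` (status),
#'   `"I"` (impact), `"R"` (risk).
#' * `direction` — `"benefit"` if higher values mean improvement,
#'   `"cost"` if higher values mean deterioration. Decides which
#'   baseline-ratio normalization applies.
#' * `value` — the measured value; must be strictly positive because the
#'   downstream normalization and geometric-mean aggregation divide by and
#'   take logs of the values.
#'
#' The baseline (background) year against which all indicators are
#' ratio-normalized is carried as the `baseline_year` attribute.
#'
#' @param x A data frame with the columns above.
#' @param baseline_year Calendar year used as background condition; must be
#'   inside the panel's year range.
#' @return A tibble of class `indicator_panel` with a `baseline_year`
#'   attribute.
#' @examples
#' pan <- indicator_panel(
#'   tibble::tibble(
#'     year = rep(2000:2004, 2),
#'     indicator_id = rep(c("pop", "tp_conc"), each = 5),
#'     category = rep(c("D", "S"), each = 5),
#'     direction = rep(c("cost", "cost"), each = 5),
#'     value = c(10, 11, 12, 13, 14, 0.05, 0.06, 0.08, 0.07, 0.06)
#'   ),
#'   baseline_year = 2000
#' )
#' panel_baseline(pan)
#' @export
indicator_panel <- function(x, baseline_year) {
  x <- as_tibble(x)
  required <- c("year", "indicator_id", "category", "direction", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Panel is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- dplyr::mutate(
    x,
    year = as.integer(.data$year),
    indicator_id = as.character(.data$indicator_id),
    category = as.character(.data$category),
    direction = as.character(.data$direction),
    value = as.double(.data$value)
  )
  x <- dplyr::arrange(x, .data$indicator_id, .data$year)

  bad_cat <- setdiff(unique(x$category), DPSIR_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0(
      "Unknown DPSIR category: ", paste(bad_cat, collapse = ", "),
      " (expected one of ", paste(DPSIR_CATEGORIES, collapse = ", "), ")"
    ))
  }
  bad_dir <- setdiff(unique(x$direction), DIRECTIONS)
  if (length(bad_dir) > 0) {
    abort(paste0(
      "Unknown direction: ", paste(bad_dir, collapse = ", "),
      " (expected benefit or cost)"
    ))
  }

  years <- sort(unique(x$year))
  if (!identical(years, seq(min(years), max(years)))) {
    abort("Panel years must form a contiguous range.")
  }
  baseline_year <- as.integer(baseline_year)
  if (length(baseline_year) != 1L || !baseline_year %in% years) {
    abort(paste0(
      "baseline_year (", baseline_year, ") must be one of the panel years ",
      min(years), "-", max(years), "."
    ))
  }

  cover <- dplyr::count(x, .data$indicator_id)
  bad_cover <- cover$indicator_id[cover$n != length(years)]
  if (length(bad_cover) > 0) {
    abort(paste0(
      "Indicator(s) not covering every panel year exactly once: ",
      paste(bad_cover, collapse = ", ")
    ))
  }
  meta <- dplyr::distinct(
    x, .data$indicator_id, .data$category, .data$direction
  )
  dup_meta <- meta$indicator_id[duplicated(meta$indicator_id)]
  if (length(dup_meta) > 0) {
    abort(paste0(
      "Indicator(s) with inconsistent category/direction metadata: ",
      paste(unique(dup_meta), collapse = ", ")
    ))
  }

  bad_val <- x[!is.finite(x$value) | x$value <= 0, ]
  if (nrow(bad_val) > 0) {
    abort(paste0(
      "Indicator values must be finite and strictly positive; offending: ",
      paste(head(
        paste0(bad_val$indicator_id, "@", bad_val$year),
        5L
      ), collapse = ", ")
    ))
  }

  structure(
    x,
    baseline_year = baseline_year,
    class = c("indicator_panel", class(tibble()))
  )
}

#' Coerce to an indicator panel
#'
#' @param x A data frame (or existing `indicator_panel`).
#' @param baseline_year Baseline year; defaults to the `baseline_year`
#'   attribute of `x` if present.
#' @return An `indicator_panel`.
#' @export
as_indicator_panel <- function(x, baseline_year = NULL) {
  baseline_year <- baseline_year %||% attr(x, "baseline_year", exact = TRUE)
  if (is.null(baseline_year)) {
    abort("baseline_year must be supplied (or present as an attribute).")
  }
  indicator_panel(x, baseline_year)
}

#' @rdname indicator_panel
#' @param panel An `indicator_panel`.
#' @export
panel_baseline <- function(panel) {
  by <- attr(panel, "baseline_year", exact = TRUE)
  if (is.null(by)) abort("Not an indicator panel: no baseline_year attribute.")
  by
}

#' @rdname indicator_panel
#' @export
panel_years <- function(panel) {
  sort(unique(panel$year))
}

#' @export
print.indicator_panel <- function(x, ...) {
  yrs <- panel_years(x)
  cat(
    "# Indicator panel: ", dplyr::n_distinct(x$indicator_id),
    " indicators, years ", min(yrs), "-", max(yrs),
    ", baseline ", panel_baseline(x), "\n",
    sep = ""
  )
  NextMethod()
}

# year-by-indicator value matrix for one category (rows = years)
panel_matrix <- function(panel, category = NULL) {
  x <- panel
  if (!is.null(category)) {
    x <- dplyr::filter(x, .data$category == !!category)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(x, "year", "indicator_id", "value"),
    names_from = "indicator_id", values_from = "value"
  )
  wide <- dplyr::arrange(wide, .data$year)
  m <- as.matrix(dplyr::select(wide, -"year"))
  rownames(m) <- wide$year
  m
}

panel_meta <- function(panel) {
  dplyr::distinct(
    as_tibble(panel), .data$indicator_id, .data$category, .data$direction
  )
}

#' Read / write indicator panel CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `year,indicator_id,category,direction,value`.
#'
#' @param path File path.
#' @param baseline_year Baseline year to attach on read.
#' @return `read_panel_csv()` returns an `indicator_panel`;
#'   `write_panel_csv()` returns `path` invisibly.
#' @export
read_panel_csv <- function(path, baseline_year) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      indicator_id = readr::col_character(),
      category = readr::col_character(),
      direction = readr::col_character(),
      value = readr::col_double()
    )
  )
  indicator_panel(x, baseline_year)
}

#' @rdname read_panel_csv
#' @param panel An `indicator_panel` (or data frame in panel layout).
#' @export
write_panel_csv <- function(panel, path) {
  cols <- c("year", "indicator_id", "category", "direction", "value")
  readr::write_csv(dplyr::select(as_tibble(panel), dplyr::all_of(cols)), path)
  invisible(path)
}
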