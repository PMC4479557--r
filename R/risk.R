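#' Annual cyanobacterial bloom-risk statistic
#'
#' For each year, daily records are compared against the lowest
#' temperature and the lowest TP/TN concentrations at which blooms occur.
#' With `n` records in a year, of which `n_T`, `n_P`, `n_N` lie strictly
#' below the temperature, TP and TN thresholds respectively, the statistic
#' is
#'
#' \deqn{x_r = 1 - \frac{n - n_T}{n}\cdot\frac{n - n_P}{n}\cdot
#'   \frac{n - n_N}{n}}
#'
#' which lies in \[0, 1\]. As written it rises when more days fail a bloom
#' precondition, i.e. it behaves as a the-higher-the-better (safety-type)
#' quantity: low values flag years in which temperature and nutrients were
#' bloom-capable nearly year-round. It therefore enters the index pipeline
#' as a benefit-direction indicator by default (see
#' [risk_as_indicator()]).
#'
#' `bloom_risk_year()` computes the statistic for one set of records
#' (typically one year); `bloom_risk_series()` computes it per year.
#'
#' @param daily A data frame of daily records with columns `temperature`,
#'   `tp`, `tn` (and `year` for `bloom_risk_series()`).
#' @param thresholds A [bloom_thresholds()] object.
#' @return `bloom_risk_year()`: a one-row tibble with `n`, `n_below_temp`,
#'   `n_below_tp`, `n_below_tn`, `risk`. `bloom_risk_series()`: the same
#'   columns plus `year`, one row per year.
#' @examples
#' rec <- tibble::tibble(
#'   temperature = c(5, 12, 20), tp = c(0.02, 0.06, 0.08),
#'   tn = c(0.5, 1.5, 2)
#' )
#' bloom_risk_year(rec, bloom_thresholds(10, 0.05, 1))
#' @export
bloom_risk_year <- function(daily, thresholds = bloom_thresholds()) {
  stopifnot(inherits(thresholds, "bloom_thresholds"))
  daily <- as_tibble(daily)
  n <- nrow(daily)
  if (n == 0L) {
    abort("Cannot compute bloom risk from zero records (n = 0).")
  }
  # strictly below: a record exactly at a threshold still counts as
  # bloom-capable for that condition
  n_t <- sum(daily$temperature < thresholds$t_min)
  n_p <- sum(daily$tp < thresholds$tp_min)
  n_n <- sum(daily$tn < thresholds$tn_min)
  risk <- 1 - ((n - n_t) / n) * ((n - n_p) / n) * ((n - n_n) / n)
  tibble(
    n = n, n_below_temp = n_t, n_below_tp = n_p, n_below_tn = n_n,
    risk = risk
  )
}

#' @rdname bloom_risk_year
#' @export
bloom_risk_series <- function(daily, thresholds = bloom_thresholds()) {
  daily <- as_tibble(daily)
  if (nrow(daily) == 0L) abort("No daily records supplied.")
  if (!"year" %in% names(daily)) abort("Daily records need a `year` column.")
  years_present <- sort(unique(daily$year))
  full_range <- seq(min(years_present), max(years_present))
  gaps <- setdiff(full_range, years_present)
  if (length(gaps) > 0) {
    abort(paste0(
      "Year(s) with zero daily records inside the span: ",
      paste(gaps, collapse = ", ")
    ))
  }
  daily |>
    dplyr::group_by(year = .data$year) |>
    dplyr::group_modify(~ bloom_risk_year(.x, thresholds)) |>
    dplyr::ungroup()
}

#' Package a risk series as indicator-panel rows
#'
#' Converts the output of [bloom_risk_series()] into rows mergeable into
#' an [indicator_panel()], category `"R"`. The default direction is
#' `"benefit"`, matching the statistic as printed (higher = safer); pass
#' `direction = "cost"` to override if the statistic is reinterpreted as
#' a higher-is-worse risk.
#'
#' @param risk Output of [bloom_risk_series()].
#' @param id Indicator id to assign.
#' @param direction `"benefit"` (default) or `"cost"`.
#' @return A tibble in panel layout
#'   (`year,indicator_id,category,direction,value`).
#' @export
risk_as_indicator <- function(risk, id = "bloom_risk",
                              direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  tibble(
    year = as.integer(risk$year),
    indicator_id = id,
    category = "R",
    direction = direction,
    value = risk$risk
  )
}

#' Write a risk series as JSON (with audit counts)
#'
#' @param risk Output of [bloom_risk_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_risk_json <- function(risk, path) {
  jsonlite::write_json(
    as_tibble(risk), path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
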