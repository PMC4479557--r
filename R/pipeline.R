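#' Compare two index series by linear regression
#'
#' Ordinary least squares of `b` on `a` over their shared years, excluding
#' `exclude_years` (typically the baseline year, whose value is 1 in both
#' series by construction and would inflate the fit). Returns the
#' coefficient of determination together with slope and intercept for
#' audit; for a simple regression the R-squared is symmetric in the two
#' series, so the direction of the fit does not affect it.
#'
#' A constant predictor leaves R-squared undefined; it is reported as
#' `NA`, not as 0.
#'
#' @param a,b Index series: either data frames with columns `year` and a
#'   single value column, or plain numeric vectors of equal length
#'   (years then taken as positional).
#' @param exclude_years Years dropped before fitting.
#' @return A one-row tibble: `n_years`, `r_squared`, `slope`,
#'   `intercept`.
#' @examples
#' compare_series(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
compare_series <- function(a, b, exclude_years = integer()) {
  as_series <- function(x, label) {
    if (is.data.frame(x)) {
      x <- as_tibble(x)
      if (!"year" %in% names(x) || ncol(x) != 2L) {
        abort(paste0(
          "Series ", label,
          " must have a `year` column plus one value column."
        ))
      }
      val <- setdiff(names(x), "year")
      tibble(year = x$year, value = x[[val]])
    } else {
      tibble(year = seq_along(x), value = as.double(x))
    }
  }
  sa <- as_series(a, "a")
  sb <- as_series(b, "b")
  xy <- dplyr::inner_join(sa, sb, by = "year",
                          suffix = c("_a", "_b")) |>
    dplyr::filter(!.data$year %in% exclude_years)
  if (nrow(xy) < 3L) {
    abort("Need at least 3 shared years after exclusion.")
  }
  if (sd(xy$value_a) == 0) {
    return(tibble(
      n_years = nrow(xy), r_squared = NA_real_,
      slope = NA_real_, intercept = NA_real_
    ))
  }
  fit <- lm(value_b ~ value_a, data = xy)
  sst <- sum((xy$value_b - mean(xy$value_b))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  tibble(
    n_years = nrow(xy),
    r_squared = r2,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1])
  )
}

# OLS slope of an index series on year (baseline optionally excluded)
index_trend_slope <- function(series, exclude_years = integer()) {
  x <- dplyr::filter(as_tibble(series), !.data$year %in% exclude_years)
  unname(coef(lm(x[[setdiff(names(x), "year")]] ~ x$year))[2])
}

#' Assessment configuration
#'
#' Run-level settings of the end-to-end assessment.
#'
#' @param baseline_year Background year for normalization.
#' @param alpha,pc_variance_threshold Screening settings, see
#'   [screening_config()].
#' @param thresholds A [bloom_thresholds()] object for the risk
#'   statistic.
#' @param risk_direction Direction under which the bloom-risk statistic
#'   enters normalization; `"benefit"` (as the statistic is defined:
#'   higher = safer) or `"cost"`.
#' @param exclude_baseline Whether the baseline year is excluded from the
#'   screened-vs-unscreened regression comparisons.
#' @return A named list of class `assessment_config`.
#' @export
assessment_config <- function(baseline_year,
                              alpha = 0.05,
                              pc_variance_threshold = 0.8,
                              thresholds = bloom_thresholds(),
                              risk_direction = c("benefit", "cost"),
                              exclude_baseline = TRUE) {
  risk_direction <- match.arg(risk_direction)
  structure(
    list(
      baseline_year = as.integer(baseline_year),
      screening = screening_config(alpha, pc_variance_threshold),
      thresholds = thresholds,
      risk_direction = risk_direction,
      exclude_baseline = isTRUE(exclude_baseline)
    ),
    class = "assessment_config"
  )
}

#' Read an assessment configuration from YAML
#'
#' Recognized keys: `baseline_year` (required), `alpha`,
#' `pc_variance_threshold`, `risk_direction`, `exclude_baseline`, and a
#' `thresholds` map with `t_min`, `tp_min`, `tn_min`.
#'
#' @param path YAML file path.
#' @return An [assessment_config()].
#' @export
read_assessment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$baseline_year)) {
    abort("Config must set baseline_year.")
  }
  thr <- if (!is.null(y$thresholds)) {
    do.call(bloom_thresholds, y$thresholds)
  } else {
    bloom_thresholds()
  }
  assessment_config(
    baseline_year = y$baseline_year,
    alpha = y$alpha %||% 0.05,
    pc_variance_threshold = y$pc_variance_threshold %||% 0.8,
    thresholds = thr,
    risk_direction = y$risk_direction %||% "benefit",
    exclude_baseline = y$exclude_baseline %||% TRUE
  )
}

#' Run the full ecological security assessment
#'
#' End-to-end pipeline: screen the indicator panel for multicollinearity,
#' compute the annual bloom-risk series from the daily records and append
#' it as the risk component, normalize against the baseline year,
#' aggregate into DPSIR component indices and the ESI — twice, with and
#' without screening — and regress each unscreened series on its screened
#' counterpart. The unscreened ESI quantifies the bias that redundant
#' indicators would introduce.
#'
#' @param panel An [indicator_panel()], a data frame in panel layout, or
#'   the path of a panel CSV.
#' @param daily A daily-records tibble or the path of a daily CSV.
#' @param config An [assessment_config()] or the path of a YAML file.
#' @param out_dir Optional directory; when given, `esi.csv`,
#'   `screening.json` and `report.json` are written there.
#' @return An object of class `esi_assessment`: list with `screening`
#'   (the `screening_result`), `risk` (risk series with counts),
#'   `normalized` (screened normalized panel), `indices` (tibble
#'   `year`, `D`, `P`, `S`, `I`, `R`, `ESI`, `ESINEW`),
#'   `indices_unscreened` (full unscreened index table), `comparison`
#'   (per-series regression tibble), `config`.
#' @export
run_assessment <- function(panel, daily, config, out_dir = NULL) {
  if (is.character(config)) config <- read_assessment_config(config)
  stopifnot(inherits(config, "assessment_config"))
  if (is.character(panel)) {
    panel <- read_panel_csv(panel, baseline_year = config$baseline_year)
  } else {
    panel <- as_indicator_panel(panel, config$baseline_year)
  }
  if (is.character(daily)) daily <- read_daily_csv(daily)

  screening <- screen_panel(panel, config$screening)
  risk <- bloom_risk_series(daily, config$thresholds)
  risk_rows <- risk_as_indicator(risk, direction = config$risk_direction)

  add_risk <- function(p) {
    indicator_panel(
      dplyr::bind_rows(
        as_tibble(p),
        dplyr::filter(risk_rows, .data$year %in% panel_years(p))
      ),
      baseline_year = panel_baseline(p)
    )
  }
  risk_years <- sort(unique(risk_rows$year))
  missing_years <- setdiff(panel_years(panel), risk_years)
  if (length(missing_years) > 0) {
    abort(paste0(
      "Daily records missing for panel year(s): ",
      paste(missing_years, collapse = ", ")
    ))
  }

  screened_panel <- add_risk(screening$selected_panel)
  unscreened_panel <- add_risk(panel)

  idx_scr <- compute_indices(screened_panel)
  idx_raw <- compute_indices(unscreened_panel)

  excl <- if (config$exclude_baseline) config$baseline_year else integer()
  series_names <- setdiff(names(idx_scr), "year")
  comparison <- purrr::map_dfr(series_names, function(nm) {
    cmp <- compare_series(
      idx_scr[c("year", nm)], idx_raw[c("year", nm)], exclude_years = excl
    )
    dplyr::mutate(
      cmp,
      series = nm,
      slope_screened = index_trend_slope(idx_scr[c("year", nm)], excl),
      slope_unscreened = index_trend_slope(idx_raw[c("year", nm)], excl),
      # D, P, S and ESI are the conventionally reported comparisons;
      # impact and risk are computed additionally and flagged
      supplementary = nm %in% c("I", "R"),
      .before = 1
    )
  })

  indices <- dplyr::left_join(
    idx_scr,
    dplyr::select(idx_raw, "year", ESINEW = "ESI"),
    by = "year"
  )

  result <- structure(
    list(
      screening = screening,
      risk = risk,
      normalized = normalize_panel(screened_panel),
      indices = indices,
      indices_unscreened = idx_raw,
      comparison = comparison,
      config = config
    ),
    class = "esi_assessment"
  )
  if (!is.null(out_dir)) write_assessment(result, out_dir)
  result
}

#' Write assessment report files
#'
#' Writes `esi.csv` (year, component indices, ESI, ESINEW),
#' `screening.json` (audit trail) and `report.json` (comparisons, risk
#' series with counts, configuration) into a directory.
#'
#' @param x An `esi_assessment`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_assessment <- function(x, out_dir) {
  stopifnot(inherits(x, "esi_assessment"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    esi = file.path(out_dir, "esi.csv"),
    screening = file.path(out_dir, "screening.json"),
    report = file.path(out_dir, "report.json")
  )
  readr::write_csv(x$indices, paths[["esi"]])
  write_screening_json(x$screening, paths[["screening"]])
  report <- list(
    baseline_year = x$config$baseline_year,
    risk_direction = x$config$risk_direction,
    thresholds = unclass(x$config$thresholds),
    selected_ids = x$screening$selected_ids,
    comparison = x$comparison,
    risk = as_tibble(x$risk),
    package_version = as.character(utils::packageVersion("lakesec"))
  )
  jsonlite::write_json(report, paths[["report"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(paths)
}

#' @export
print.esi_assessment <- function(x, ...) {
  g <- glance(x)
  cat("# Ecological security assessment\n")
  cat("  years: ", min(x$indices$year), "-", max(x$indices$year),
      ", baseline ", x$config$baseline_year, "\n", sep = "")
  cat("  indicators: ", g$n_indicators, " -> ", g$n_selected,
      " after screening (+ bloom risk)\n", sep = "")
  cat("  minimum ESI: ", format(g$min_esi, digits = 4), " in ",
      g$min_esi_year, "\n", sep = "")
  cat("  screened vs unscreened ESI R^2: ",
      format(g$esi_r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy esi_assessment
tidy.esi_assessment <- function(x, ...) {
  tidyr::pivot_longer(
    x$indices, -"year",
    names_to = "series", values_to = "value"
  )
}

#' @export
#' @method glance esi_assessment
glance.esi_assessment <- function(x, ...) {
  excl <- if (x$config$exclude_baseline) {
    x$config$baseline_year
  } else {
    integer()
  }
  esi_tbl <- dplyr::filter(x$indices, !.data$year %in% excl)
  i_min <- which.min(esi_tbl$ESI)
  tibble(
    n_indicators = length(x$screening$input_ids),
    n_selected = length(x$screening$selected_ids),
    baseline_year = x$config$baseline_year,
    min_esi = esi_tbl$ESI[i_min],
    min_esi_year = esi_tbl$year[i_min],
    esi_r_squared = x$comparison$r_squared[x$comparison$series == "ESI"]
  )
}

#' Plot the assessment indices
#'
#' Line plot of the five DPSIR component indices, the ESI and the
#' unscreened ESI over time. Values below 1 mark deterioration relative
#' to the baseline year.
#'
#' @param object An `esi_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot esi_assessment
autoplot.esi_assessment <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$year, y = .data$value,
                 colour = .data$series)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Year", y = "Index (baseline = 1)", colour = NULL,
      title = "DPSIR component indices and Ecological Security Index"
    ) +
    ggplot2::theme_minimal()
}

#' Screened vs unscreened index trajectories
#'
#' Faceted comparison of each index series computed with and without
#' indicator screening, visualizing the bias that redundant collinear
#' indicators introduce.
#'
#' @param x An `esi_assessment`.
#' @return A ggplot object.
#' @export
plot_screening_effect <- function(x) {
  stopifnot(inherits(x, "esi_assessment"))
  scr <- tidyr::pivot_longer(
    dplyr::select(x$indices, -"ESINEW"), -"year",
    names_to = "series", values_to = "value"
  ) |>
    dplyr::mutate(variant = "screened")
  raw <- tidyr::pivot_longer(
    x$indices_unscreened, -"year",
    names_to = "series", values_to = "value"
  ) |>
    dplyr::mutate(variant = "unscreened")
  ggplot2::ggplot(
    dplyr::bind_rows(scr, raw),
    ggplot2::aes(x = .data$year, y = .data$value,
                 colour = .data$variant)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~series) +
    ggplot2::labs(
      x = "Year", y = "Index (baseline = 1)", colour = NULL,
      title = "Effect of indicator screening on index trajectories"
    ) +
    ggplot2::theme_minimal()
}
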