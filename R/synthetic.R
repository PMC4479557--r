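#' Bloom thresholds
#'
#' The lowest temperature and the lowest total phosphorus / total nitrogen
#' concentrations at which cyanobacterial blooms have been observed. Daily
#' records strictly below a threshold count as bloom-incapable for that
#' condition. The defaults are synthetic placeholders of realistic
#' magnitude (blooms need warm water and eutrophic nutrient levels); for a
#' real lake they must come from local monitoring.
#'
#' @param t_min Temperature threshold, degrees Celsius.
#' @param tp_min Total phosphorus threshold, mg/L.
#' @param tn_min Total nitrogen threshold, mg/L.
#' @return A named list of class `bloom_thresholds`.
#' @export
bloom_thresholds <- function(t_min = 10, tp_min = 0.05, tn_min = 1.0) {
  if (tp_min < 0 || tn_min < 0) {
    abort("Nutrient thresholds must be non-negative.")
  }
  structure(
    list(t_min = t_min, tp_min = tp_min, tn_min = tn_min),
    class = "bloom_thresholds"
  )
}

#' Synthetic watershed configuration
#'
#' Parameters of the synthetic indicator panel and daily-record generator.
#' The generator emulates the statistical structure of a two-decade lake
#' monitoring programme: a block of near-collinear socio-economic
#' driving-force series riding one monotone latent trend, and
#' pressure/status/impact series tied to a V-shaped latent ecological
#' trajectory whose extremum (the worst year) is planted and recoverable.
#'
#' @param year_start,year_end First and last calendar year of the panel.
#' @param baseline_year Background year for normalization; must satisfy
#'   `year_start <= baseline_year < worst_year <= year_end`.
#' @param worst_year Vertex of the planted V-shaped ecological trend.
#' @param driver_block_size Number of collinear driving-force series
#'   (at least 2).
#' @param driver_block_correlation Target expected pairwise Pearson
#'   correlation within the driver block, in (0, 1).
#' @param noise_sd Log-scale standard deviation of the idiosyncratic noise
#'   on the strongly trend-tied pressure/status/impact series. Weakly tied
#'   companion series use `2.5 * noise_sd`.
#' @param n_daily_per_year Number of daily condition records per year.
#' @param thresholds A [bloom_thresholds()] object.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A named list of class `synthetic_config`.
#' @export
synthetic_config <- function(year_start = 1988,
                             year_end = 2007,
                             baseline_year = 1988,
                             worst_year = 1998,
                             driver_block_size = 3,
                             driver_block_correlation = 0.98,
                             noise_sd = 0.04,
                             n_daily_per_year = 365,
                             thresholds = bloom_thresholds(),
                             seed = 1L) {
  if (!(year_start <= baseline_year &&
          baseline_year < worst_year &&
          worst_year <= year_end)) {
    abort(paste0(
      "Invalid year ordering: need year_start <= baseline_year < ",
      "worst_year <= year_end, got ", year_start, " / ", baseline_year,
      " / ", worst_year, " / ", year_end, "."
    ))
  }
  if (driver_block_size < 2) abort("driver_block_size must be >= 2.")
  if (driver_block_correlation <= 0 || driver_block_correlation >= 1) {
    abort("driver_block_correlation must lie strictly in (0, 1).")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (n_daily_per_year < 1) abort("n_daily_per_year must be >= 1.")
  stopifnot(inherits(thresholds, "bloom_thresholds"))
  structure(
    list(
      year_start = as.integer(year_start),
      year_end = as.integer(year_end),
      baseline_year = as.integer(baseline_year),
      worst_year = as.integer(worst_year),
      driver_block_size = as.integer(driver_block_size),
      driver_block_correlation = driver_block_correlation,
      noise_sd = noise_sd,
      n_daily_per_year = as.integer(n_daily_per_year),
      thresholds = thresholds,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# V-shaped "ecological badness" latent: 0 far from the worst year,
# 1 exactly at it, piecewise linear in between.
v_badness <- function(years, worst_year) {
  span <- max(worst_year - min(years), max(years) - worst_year)
  1 - abs(years - worst_year) / span
}

# Latent-correlation targets for the driver block: the representative sits
# close to the common factor so its top loading is recoverable from ~20
# annual samples, the rest sit just below sqrt(r) so every pairwise
# correlation stays near r.
driver_loadings <- function(r, m) {
  base <- sqrt(r)
  rep_c <- min(0.9995, base + 0.0095)
  others <- base - seq(0.0035, 0.006, length.out = m - 1)
  pmin(pmax(c(rep_c, others), 1e-3), 0.9995)
}

DRIVER_IDS <- c(
  "population", "gdp", "industry_output", "urban_land", "energy_use",
  "freight_volume", "retail_sales", "fixed_investment"
)

# log-scale amplitude of the strong V-tied series and the relative
# amplitude of their weakly tied companions
V_AMPLITUDE <- 1.0
WEAK_AMPLITUDE <- 0.08
WEAK_NOISE_FACTOR <- 2.5

#' Generate a synthetic indicator panel with planted ground truth
#'
#' Produces a DPSIR indicator panel over the configured year range:
#'
#' * a driving-force block of `driver_block_size` cost-direction series
#'   following a single monotone common factor plus independent noise,
#'   calibrated so pairwise correlations match
#'   `driver_block_correlation`; exactly one member (chosen at random per
#'   seed) carries the largest common-factor loading and is recorded as
#'   the planted representative;
#' * one pressure, two status and two impact series tied (strongly or
#'   weakly) to a piecewise-linear V-shaped latent whose extremum falls in
#'   `worst_year` — cost series peak there, benefit series trough there.
#'
#' All values are strictly positive (log-linear construction), as the
#' baseline normalization and geometric-mean aggregation require.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `panel` (an [indicator_panel()]) and
#'   `truth` (list: `representative_driver_id`, `worst_year`,
#'   `block_member_ids`, `driver_loadings`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$year_start:config$year_end
  ny <- length(years)
  m <- config$driver_block_size
  with_local_seed(config$seed, {
    latent <- as.vector(scale(seq_len(ny)))
    cc <- driver_loadings(config$driver_block_correlation, m)
    log_scales <- 0.06 + 0.03 * (seq_len(m) - 1)

    ids <- if (m <= length(DRIVER_IDS)) {
      DRIVER_IDS[seq_len(m)]
    } else {
      sprintf("driver_%02d", seq_len(m))
    }
    # which id receives which loading varies with the seed
    ids <- sample(ids)

    drivers <- purrr::map_dfr(seq_len(m), function(j) {
      z <- cc[j] * latent + sqrt(1 - cc[j]^2) * rnorm(ny)
      tibble(
        year = years,
        indicator_id = ids[j],
        category = "D",
        direction = "cost",
        value = 100 * j * exp(log_scales[j] * z)
      )
    })

    b <- v_badness(years, config$worst_year)
    sd_s <- config$noise_sd
    sd_w <- WEAK_NOISE_FACTOR * config$noise_sd
    v_series <- function(id, category, direction, base, amp, sd) {
      sgn <- if (direction == "cost") 1 else -1
      tibble(
        year = years,
        indicator_id = id,
        category = category,
        direction = direction,
        value = base * exp(sgn * amp * b + rnorm(ny, sd = sd))
      )
    }
    eco <- dplyr::bind_rows(
      v_series("tp_load", "P", "cost", 5000, V_AMPLITUDE, sd_s),
      v_series("tp_conc", "S", "cost", 0.08, V_AMPLITUDE, sd_s),
      v_series("do_conc", "S", "benefit", 6, WEAK_AMPLITUDE, sd_w),
      v_series("fish_production", "I", "benefit", 10, V_AMPLITUDE, sd_s),
      v_series("tourism_income", "I", "benefit", 800, WEAK_AMPLITUDE, sd_w)
    )

    panel <- indicator_panel(
      dplyr::bind_rows(drivers, eco),
      baseline_year = config$baseline_year
    )
    truth <- list(
      representative_driver_id = ids[1],
      worst_year = config$worst_year,
      block_member_ids = sort(ids),
      driver_loadings = setNames(cc, ids)
    )
    list(panel = panel, truth = truth)
  })
}

#' Generate synthetic daily condition records
#'
#' One record per day and year with water temperature (seasonal sine cycle
#' plus noise), and daily total phosphorus / total nitrogen concentrations
#' whose levels rise toward the configured worst year and fall again, so
#' the below-threshold day counts feeding the bloom-risk statistic vary
#' across years. Days are an ordinal index within the year; the risk
#' statistic only needs within-year counts.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `year`, `day_index`, `temperature`,
#'   `tp`, `tn`.
#' @export
generate_daily_conditions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$year_start:config$year_end
  nd <- config$n_daily_per_year
  b <- v_badness(years, config$worst_year)
  # daily seed decoupled from the panel seed, kept inside 32-bit range
  daily_seed <- (config$seed + 500009L) %% .Machine$integer.max
  with_local_seed(daily_seed, {
    purrr::map_dfr(seq_along(years), function(i) {
      day <- seq_len(nd)
      season <- sin(2 * pi * (day - 0.2 * nd) / nd)
      tibble(
        year = years[i],
        day_index = day,
        temperature = 16 + 8 * season + rnorm(nd, sd = 2),
        tp = exp(log(0.04) + 0.52 * b[i] + rnorm(nd, sd = 0.3)),
        tn = exp(log(0.80) + 0.52 * b[i] + rnorm(nd, sd = 0.3))
      )
    })
  })
}

#' Read / write daily condition CSV
#'
#' Plain CSV with header `year,day_index,temperature,tp,tn`.
#'
#' @param path File path.
#' @return `read_daily_csv()` returns a tibble; `write_daily_csv()`
#'   returns `path` invisibly.
#' @export
read_daily_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      day_index = readr::col_integer(),
      temperature = readr::col_double(),
      tp = readr::col_double(),
      tn = readr::col_double()
    )
  )
}

#' @rdname read_daily_csv
#' @param daily A tibble of daily condition records.
#' @export
write_daily_csv <- function(daily, path) {
  cols <- c("year", "day_index", "temperature", "tp", "tn")
  readr::write_csv(dplyr::select(as_tibble(daily), dplyr::all_of(cols)), path)
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Writes `panel.csv`, `daily.csv` and `truth.json` for a configuration.
#' Deterministic for a fixed seed: two runs produce identical files.
#'
#' @param config A [synthetic_config()], or the path of a YAML file whose
#'   keys are `synthetic_config()` arguments (`thresholds` as a nested
#'   map).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named character vector of file paths.
#' @export
generate_fixture <- function(config, out_dir) {
  if (is.character(config)) config <- read_synthetic_config(config)
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  gen <- generate_panel(config)
  daily <- generate_daily_conditions(config)
  paths <- c(
    panel = file.path(out_dir, "panel.csv"),
    daily = file.path(out_dir, "daily.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_panel_csv(gen$panel, paths[["panel"]])
  write_daily_csv(daily, paths[["daily"]])
  jsonlite::write_json(
    gen$truth, paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

# YAML -> synthetic_config
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- if (!is.null(y$thresholds)) {
    do.call(bloom_thresholds, y$thresholds)
  } else {
    bloom_thresholds()
  }
  y$thresholds <- NULL
  do.call(synthetic_config, c(y, list(thresholds = thr)))
}
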