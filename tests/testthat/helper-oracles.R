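# Independent oracles, deliberately written by a different route than the
# package implementation.

# Pearson correlation, raw sum-of-products form
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# bloom-risk statistic straight from its defining arithmetic
eq1_oracle <- function(n, n_t, n_p, n_n) {
  1 - ((n - n_t) / n) * ((n - n_p) / n) * ((n - n_n) / n)
}

# weighted geometric mean in log space
geomean_oracle <- function(x, w) exp(sum(w * log(x)))

# PC loadings via direct eigen-decomposition of the correlation matrix
pca_loadings_oracle <- function(m) {
  eigen(cor(m), symmetric = TRUE)$vectors
}

# r^2 of a simple OLS equals the squared Pearson correlation
ols_r2_oracle <- function(a, b) pearson_oracle(a, b)^2

# build a daily-record table realizing prescribed below-threshold counts
# against bloom_thresholds(10, 0.05, 1): fields are independent, so each
# count can be planted separately
records_from_counts <- function(n, n_t, n_p, n_n) {
  data.frame(
    temperature = c(rep(5, n_t), rep(20, n - n_t)),
    tp = c(rep(0.01, n_p), rep(0.2, n - n_p)),
    tn = c(rep(0.5, n_n), rep(3, n - n_n))
  )
}

# small panel builder: wide year-by-indicator values -> panel layout
make_panel <- function(.years, ..., .baseline_year, .categories, .directions) {
  cols <- list(...)
  ids <- names(cols)
  df <- purrr::map_dfr(seq_along(ids), function(j) {
    tibble::tibble(
      year = .years,
      indicator_id = ids[j],
      category = .categories[[j]],
      direction = .directions[[j]],
      value = cols[[j]]
    )
  })
  indicator_panel(df, baseline_year = .baseline_year)
}

# a panel of mutually independent series, one per category, fixed values
independent_panel <- function(years = 2000:2009, baseline_year = 2000) {
  n <- length(years)
  set.seed(42)
  vals <- replicate(5, exp(rnorm(n, sd = 0.2)), simplify = FALSE)
  make_panel(
    years, .baseline_year = baseline_year,
    d1 = vals[[1]], p1 = vals[[2]], s1 = vals[[3]], i1 = vals[[4]],
    r1 = vals[[5]],
    .categories = c("D", "P", "S", "I", "R"),
    .directions = c("cost", "cost", "cost", "benefit", "benefit")
  )
}

# duplicate the driver block of a synthetic panel: `copies` extra copies
# of every block member, fresh ids, identical values
duplicate_driver_block <- function(panel, block_ids, copies = 2) {
  extra <- purrr::map_dfr(seq_len(copies), function(k) {
    dplyr::mutate(
      dplyr::filter(tibble::as_tibble(panel), indicator_id %in% block_ids),
      indicator_id = paste0(indicator_id, "_copy", k)
    )
  })
  indicator_panel(
    dplyr::bind_rows(tibble::as_tibble(panel), extra),
    baseline_year = panel_baseline(panel)
  )
}
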