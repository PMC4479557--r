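test_that("baseline normalization follows the direction-specific ratios", {
  pan <- make_panel(
    2000:2002, .baseline_year = 2000,
    cost_tp = c(2, 4, 8), benefit_fish = c(2, 4, 1),
    .categories = c("S", "I"), .directions = c("cost", "benefit")
  )
  norm <- tibble::as_tibble(normalize_panel(pan))
  val <- function(id, yr) norm$value[norm$indicator_id == id & norm$year == yr]
  expect_equal(val("cost_tp", 2000), 1)
  expect_equal(val("benefit_fish", 2000), 1)
  expect_equal(val("cost_tp", 2001), 0.5)       # base 2 / value 4
  expect_equal(val("benefit_fish", 2001), 2)    # value 4 / base 2
  expect_equal(val("cost_tp", 2002), 0.25)
  expect_equal(val("benefit_fish", 2002), 0.5)
})

test_that("normalization rejects non-positive values, naming the culprit", {
  bad <- tibble::tibble(
    year = rep(2000:2002, 2),
    indicator_id = rep(c("ok", "broken"), each = 3),
    category = rep(c("S", "P"), each = 3),
    direction = "cost",
    value = c(1, 2, 3, 4, 0, 6)
  )
  expect_error(normalize_panel(bad, baseline_year = 2000), "broken@2001")
})

test_that("component index is the weighted geometric mean", {
  years <- 2000:2002
  norm <- make_panel(
    years, .baseline_year = 2000,
    a = c(1, 1, 0.25), b = c(1, 1, 0.5), c = c(1, 1, 1),
    .categories = rep("P", 3), .directions = rep("cost", 3)
  )
  idx <- component_index(norm, "P")
  expect_equal(idx$index[idx$year == 2000], 1)   # all ones
  # (0.25 * 0.5 * 1)^(1/3)
  expect_equal(idx$index[idx$year == 2002], (0.25 * 0.5)^(1 / 3),
               tolerance = 1e-12)

  two <- make_panel(
    years, .baseline_year = 2000,
    a = c(1, 0.5, 0.25), b = c(1, 2, 0.5),
    .categories = rep("S", 2), .directions = rep("cost", 2)
  )
  idx2 <- component_index(two, "S")
  expect_equal(idx2$index[idx2$year == 2001], 1)          # (2 * 0.5)^0.5
  expect_equal(idx2$index[idx2$year == 2002], sqrt(0.125),
               tolerance = 1e-12)
  expect_equal(idx2$index[idx2$year == 2002], 0.35355, tolerance = 1e-5)
})

test_that("weight sets must cover exactly the component's indicators", {
  pan <- independent_panel()
  expect_error(
    component_weights(pan, within = list(D = c(wrong_id = 1))),
    "exactly its indicators"
  )
  expect_error(
    component_weights(pan, within = list(D = c(d1 = 0.7))),
    "sum to 1"
  )
  expect_error(
    component_weights(pan, across = c(D = 1)),
    "cover exactly"
  )
  w <- component_weights(pan)
  expect_equal(w$within$D, c(d1 = 1))
  expect_equal(sum(w$across), 1)
})

test_that("the ESI is the weighted geometric mean of the five components", {
  comp <- tidyr::expand_grid(
    year = 2000:2002, category = c("D", "P", "S", "I", "R")
  )
  comp$index <- 1
  expect_equal(esi(comp)$esi, rep(1, 3))
  comp$index[comp$year == 2001 & comp$category == "R"] <- 1 / 32
  expect_equal(esi(comp)$esi[2], 0.5, tolerance = 1e-12)
  expect_error(esi(comp[-1, ]), "D@2000")
})

test_that("baseline identity holds to 12 decimals on synthetic panels", {
  for (seed in c(1, 5, 9)) {
    gen <- generate_panel(synthetic_config(seed = seed))
    idx <- compute_indices(gen$panel)
    base_row <- idx[idx$year == panel_baseline(gen$panel), ]
    expect_equal(
      unname(unlist(base_row[setdiff(names(base_row), "year")])),
      rep(1, ncol(base_row) - 1),
      tolerance = 1e-12
    )
  }
})

test_that("indices agree with the log-space oracle and obey mean bounds", {
  set.seed(303)
  for (i in 1:20) {
    n_ind <- sample(2:5, 1)
    years <- 2000:2006
    vals <- matrix(exp(rnorm(7 * n_ind, sd = 0.5)), nrow = 7)
    vals[1, ] <- 1  # normalized panels equal 1 at baseline
    df <- purrr::map_dfr(seq_len(n_ind), function(j) {
      tibble::tibble(
        year = years, indicator_id = paste0("x", j), category = "S",
        direction = "cost", value = vals[, j]
      )
    })
    pan <- indicator_panel(df, baseline_year = 2000)
    w <- runif(n_ind)
    w <- w / sum(w)
    names(w) <- paste0("x", seq_len(n_ind))
    cw <- component_weights(pan, within = list(S = w))
    idx <- component_index(pan, "S", weights = cw)
    oracle <- apply(vals, 1, geomean_oracle, w = w)
    expect_equal(idx$index, unname(oracle), tolerance = 1e-10)
    expect_true(all(idx$index >= apply(vals, 1, min) - 1e-12))
    expect_true(all(idx$index <= apply(vals, 1, max) + 1e-12))
  }
})

test_that("indices are invariant to rescaling any raw series", {
  gen <- generate_panel(synthetic_config(seed = 6))
  idx0 <- compute_indices(gen$panel)
  pan <- tibble::as_tibble(gen$panel)
  for (const in c(0.001, 1000)) {
    scaled <- pan
    target <- unique(pan$indicator_id)[3]
    scaled$value[scaled$indicator_id == target] <-
      scaled$value[scaled$indicator_id == target] * const
    idx1 <- compute_indices(
      indicator_panel(scaled, panel_baseline(gen$panel))
    )
    expect_equal(idx1, idx0, tolerance = 1e-10)
  }
})

test_that("worsening one indicator-year strictly lowers its component and ESI", {
  gen <- generate_panel(synthetic_config(seed = 10))
  pan <- tibble::as_tibble(gen$panel)
  idx0 <- compute_indices(gen$panel)
  # raise a cost indicator in one non-baseline year
  hit <- pan$indicator_id == "tp_load" & pan$year == 1995
  pan_bad <- pan
  pan_bad$value[hit] <- pan_bad$value[hit] * 2
  idx1 <- compute_indices(indicator_panel(pan_bad, 1988))
  expect_lt(idx1$P[idx1$year == 1995], idx0$P[idx0$year == 1995])
  expect_lt(idx1$ESI[idx1$year == 1995], idx0$ESI[idx0$year == 1995])
  expect_equal(idx1$ESI[idx1$year != 1995], idx0$ESI[idx0$year != 1995])
  # lower a benefit indicator
  hit2 <- pan$indicator_id == "fish_production" & pan$year == 2003
  pan_bad2 <- pan
  pan_bad2$value[hit2] <- pan_bad2$value[hit2] / 2
  idx2 <- compute_indices(indicator_panel(pan_bad2, 1988))
  expect_lt(idx2$I[idx2$year == 2003], idx0$I[idx0$year == 2003])
  expect_lt(idx2$ESI[idx2$year == 2003], idx0$ESI[idx0$year == 2003])
})
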