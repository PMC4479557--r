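test_that("correlation matrix matches a brute-force Pearson oracle", {
  pan <- make_panel(
    2001:2004, .baseline_year = 2001,
    a = c(1, 2, 4, 8), b = c(1, 3, 2, 7),
    .categories = c("D", "D"), .directions = c("cost", "cost")
  )
  cm <- correlation_matrix(pan, "D")
  expect_equal(diag(cm$r), c(a = 1, b = 1))
  expect_equal(cm$r["a", "b"], pearson_oracle(c(1, 2, 4, 8), c(1, 3, 2, 7)),
               tolerance = 1e-12)
  expect_equal(cm$r["a", "b"], cm$r["b", "a"])
  # p-value agrees with the standard t-test route
  ct <- cor.test(c(1, 2, 4, 8), c(1, 3, 2, 7))
  expect_equal(cm$p["a", "b"], ct$p.value, tolerance = 1e-10)

  neg <- make_panel(
    2001:2003, .baseline_year = 2001,
    x = c(1, 2, 3), y = c(3, 2, 1),
    .categories = c("S", "S"), .directions = c("cost", "cost")
  )
  expect_equal(correlation_matrix(neg, "S")$r["x", "y"], -1)
})

test_that("a constant series is flagged and treated as non-significant", {
  pan <- make_panel(
    2001:2005, .baseline_year = 2001,
    flat = rep(2, 5), rise = 1:5 + 0.0,
    .categories = c("P", "P"), .directions = c("cost", "cost")
  )
  cm <- correlation_matrix(pan, "P")
  expect_equal(cm$constant, "flat")
  expect_true(is.na(cm$r["flat", "rise"]))
  cl <- cluster_correlated(cm$r, cm$p, screening_config())
  expect_equal(cl, list("flat", "rise"))
})

test_that("clusters are connected components of the significance graph", {
  ids <- c("A", "B", "C")
  p_none <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  diag(p_none) <- 0
  expect_equal(
    cluster_correlated(NULL, p_none, screening_config()),
    list("A", "B", "C")
  )
  p_all <- matrix(0.001, 3, 3, dimnames = list(ids, ids))
  diag(p_all) <- 0
  expect_equal(
    cluster_correlated(NULL, p_all, screening_config()),
    list(c("A", "B", "C"))
  )
  # path graph: edges A-B and B-C only -> one component
  p_path <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  p_path["A", "B"] <- p_path["B", "A"] <- 0.01
  p_path["B", "C"] <- p_path["C", "B"] <- 0.01
  diag(p_path) <- 0
  expect_equal(
    cluster_correlated(NULL, p_path, screening_config()),
    list(c("A", "B", "C"))
  )
})

test_that("representative selection matches an eigen-decomposition oracle", {
  set.seed(101)
  n <- 20
  latent <- as.vector(scale(cumsum(rnorm(n))))
  vals <- sapply(c(1, 0.9, 0.8), function(l) {
    exp(0.3 * (l * latent + rnorm(n, sd = 0.15)))
  })
  pan <- make_panel(
    2001:2020, .baseline_year = 2001,
    m1 = vals[, 1], m2 = vals[, 2], m3 = vals[, 3],
    .categories = rep("D", 3), .directions = rep("cost", 3)
  )
  sel <- select_representative(pan, c("m1", "m2", "m3"))
  ids <- c("m1", "m2", "m3")
  ev <- pca_loadings_oracle(vals)
  oracle_top <- ids[which.max(abs(ev[, 1]))]
  expect_equal(sel$selected, oracle_top)
  expect_equal(
    abs(unname(sel$loadings[ids, 1])), abs(ev[, 1]),
    tolerance = 1e-6
  )
})

test_that("singleton clusters pass through and ties break lexicographically", {
  pan <- independent_panel()
  expect_equal(select_representative(pan, "d1")$selected, "d1")
  twin <- make_panel(
    2001:2006, .baseline_year = 2001,
    bbb = c(1, 2, 3, 4, 5, 6), aaa = c(1, 2, 3, 4, 5, 6),
    .categories = c("D", "D"), .directions = c("cost", "cost")
  )
  expect_message(
    sel <- select_representative(twin, c("aaa", "bbb")),
    "tie"
  )
  expect_equal(sel$selected, "aaa")
})

test_that("screening a panel of independent series selects everything", {
  pan <- independent_panel()
  res <- screen_panel(pan)
  expect_setequal(res$selected_ids, unique(tibble::as_tibble(pan)$indicator_id))
  expect_equal(
    tibble::as_tibble(res$selected_panel),
    tibble::as_tibble(pan)
  )
})

test_that("screening recovers the planted driver representative", {
  gen <- generate_panel(synthetic_config(seed = 1))
  res <- screen_panel(gen$panel)
  block <- gen$truth$block_member_ids
  selected_d <- intersect(res$selected_ids, block)
  expect_length(selected_d, 1)
  expect_equal(selected_d, gen$truth$representative_driver_id)
  # the D cluster collapsed to its representative; everything else kept
  expect_setequal(
    res$selected_ids,
    c(gen$truth$representative_driver_id,
      setdiff(unique(tibble::as_tibble(gen$panel)$indicator_id), block))
  )
})

test_that("screening is idempotent on its own output", {
  for (seed in c(1, 2, 3)) {
    gen <- generate_panel(synthetic_config(seed = seed))
    res <- screen_panel(gen$panel)
    again <- screen_panel(res$selected_panel)
    expect_equal(again$selected_ids, res$selected_ids)
    expect_equal(
      tibble::as_tibble(again$selected_panel),
      tibble::as_tibble(res$selected_panel)
    )
  }
})

test_that("screening result accessors expose a usable audit trail", {
  gen <- generate_panel(synthetic_config(seed = 2))
  res <- screen_panel(gen$panel)
  td <- tidy(res)
  expect_true(all(
    c("category", "cluster", "indicator_id", "selected") %in% names(td)
  ))
  # every input indicator appears in exactly one cluster of its category
  expect_setequal(td$indicator_id, res$input_ids)
  expect_equal(anyDuplicated(td$indicator_id), 0L)
  g <- glance(res)
  expect_equal(g$n_selected, length(res$selected_ids))
  expect_s3_class(autoplot(res), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_screening_json(res, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(parsed$selected_ids, res$selected_ids)
})

test_that("requesting an absent category warns and skips it", {
  pan <- make_panel(
    2001:2005, .baseline_year = 2001,
    a = 1:5 + 0.0,
    .categories = "D", .directions = "cost"
  )
  expect_warning(
    res <- screen_panel(pan, categories = c("D", "S")),
    "zero indicators"
  )
  expect_equal(res$selected_ids, "a")
})
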