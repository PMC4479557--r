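#' Screening configuration
#'
#' @param alpha Two-sided significance level for the pairwise Pearson
#'   correlation test that declares two indicators redundant. 0.05 by
#'   default; 0.01 is the common stricter alternative.
#' @param pc_variance_threshold Fraction of variance the first principal
#'   component must explain for a correlated cluster to be represented by
#'   a single indicator; otherwise one indicator is taken per leading
#'   component until this cumulative fraction is reached.
#' @return A named list of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.05, pc_variance_threshold = 0.8) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1).")
  if (pc_variance_threshold <= 0 || pc_variance_threshold > 1) {
    abort("pc_variance_threshold must lie in (0, 1].")
  }
  structure(
    list(alpha = alpha, pc_variance_threshold = pc_variance_threshold),
    class = "screening_config"
  )
}

#' Pairwise correlation and significance within one DPSIR category
#'
#' Pearson correlations between all indicator series of one category, with
#' two-sided p-values from the t-distribution on `n - 2` degrees of
#' freedom. A constant (zero-variance) series yields undefined
#' correlations; these are reported as `NA`, treated as non-significant
#' downstream, and the series is flagged.
#'
#' @param panel An [indicator_panel()] (or data frame in panel layout).
#' @param category One of `"D"`, `"P"`, `"S"`, `"I"`, `"R"`.
#' @return A list with `r` (correlation matrix), `p` (p-value matrix),
#'   `n` (years used), `constant` (ids of zero-variance series).
#' @export
correlation_matrix <- function(panel, category) {
  panel <- as_tibble(panel)
  m <- panel_matrix(panel, category)
  if (ncol(m) == 0L) {
    abort(paste0("No indicators in category ", category, "."))
  }
  n <- nrow(m)
  if (n < 3L) {
    abort("Need at least 3 years for the correlation t-test (df = n - 2).")
  }
  sds <- apply(m, 2, sd)
  constant <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  r[!is.finite(r)] <- NA_real_
  diag(r) <- 1
  # two-sided t-test: t = r * sqrt((n-2) / (1 - r^2))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- NA_real_
  diag(p) <- 0
  list(r = r, p = p, n = n, constant = constant)
}

#' Cluster indicators by correlation significance
#'
#' Builds a graph with an edge for every indicator pair whose correlation
#' p-value is `<= alpha` (undefined p-values count as non-significant) and
#' returns its connected components. Indicators with no significant
#' partner pass through as singleton clusters.
#'
#' @param r,p Square correlation and p-value matrices with matching
#'   dimnames (as from [correlation_matrix()]).
#' @param config A [screening_config()].
#' @return A list of character vectors of indicator ids, each sorted;
#'   clusters ordered by their first member.
#' @export
cluster_correlated <- function(r, p, config = screening_config()) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  ids <- colnames(p)
  adj <- !is.na(p) & p <= config$alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(
    adj, mode = "max", diag = FALSE
  )
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp[ids])
  clusters <- lapply(unname(clusters), sort)
  clusters[order(vapply(clusters, `[`, "", 1L))]
}

#' Select representative indicators from a correlated cluster
#'
#' A singleton cluster passes through unchanged. For a multi-member
#' cluster, the member series are standardized (zero mean, unit variance)
#' and a PCA is run on the year-by-member matrix (equivalently, on the
#' member correlation matrix, since the indicators have incommensurable
#' units). If the first principal component explains at least
#' `pc_variance_threshold` of the variance, the single member with the
#' largest absolute PC1 loading is selected; otherwise the smallest set of
#' leading components reaching that cumulative fraction each contribute
#' the not-yet-chosen member with the largest absolute loading. Loading
#' ties are broken lexicographically by id (reported via a message).
#'
#' @param panel An [indicator_panel()] (or data frame in panel layout).
#' @param cluster Character vector of indicator ids forming one cluster.
#' @param config A [screening_config()].
#' @return A list with `selected` (character vector), `loadings` (member
#'   by component matrix, `NULL` for singletons), `explained_variance`
#'   (fractions per component, `NULL` for singletons).
#' @export
select_representative <- function(panel, cluster,
                                  config = screening_config()) {
  stopifnot(length(cluster) >= 1)
  if (length(cluster) == 1L) {
    return(list(selected = cluster, loadings = NULL,
                explained_variance = NULL))
  }
  panel <- as_tibble(panel)
  m <- panel_matrix(
    dplyr::filter(panel, .data$indicator_id %in% cluster)
  )
  m <- m[, sort(cluster), drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    # constant members carry no information; they cannot be standardized
    keep <- colnames(m)[sds > 0]
    if (length(keep) == 0L) {
      inform(paste0(
        "Cluster of constant series {", paste(cluster, collapse = ", "),
        "}: selecting lexicographically first id."
      ))
      return(list(selected = sort(cluster)[1], loadings = NULL,
                  explained_variance = NULL))
    }
    m <- m[, keep, drop = FALSE]
  }
  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  load <- pca$rotation

  pick <- function(pc, exclude) {
    cand <- setdiff(rownames(load), exclude)
    al <- abs(load[cand, pc])
    top <- max(al)
    winners <- sort(cand[abs(al - top) < 1e-12])
    if (length(winners) > 1L) {
      inform(paste0(
        "Loading tie on component ", pc, " among {",
        paste(winners, collapse = ", "),
        "}; keeping ", winners[1], " (lexicographic)."
      ))
    }
    winners[1]
  }

  if (ev[1] >= config$pc_variance_threshold) {
    selected <- pick(1L, character())
  } else {
    k <- which(cumsum(ev) >= config$pc_variance_threshold)[1]
    if (is.na(k)) k <- length(ev)
    selected <- character()
    for (pc in seq_len(k)) {
      if (length(selected) >= nrow(load)) break
      selected <- c(selected, pick(pc, selected))
    }
    selected <- sort(selected)
  }
  list(selected = selected, loadings = load, explained_variance = ev)
}

#' Screen an indicator panel for independence and representativeness
#'
#' Applies, per DPSIR category: pairwise Pearson correlation with
#' significance testing ([correlation_matrix()]), clustering of
#' significantly correlated indicators into connected components
#' ([cluster_correlated()]), and PCA-based selection of representatives
#' within each multi-member cluster ([select_representative()]). The
#' surviving indicators are mutually non-redundant within their category;
#' the full audit trail (matrices, clusters, loadings) is retained.
#'
#' @param panel An [indicator_panel()].
#' @param config A [screening_config()].
#' @param categories Categories to screen; defaults to those present.
#'   Requesting an absent category raises a warning and skips it.
#' @return An object of class `screening_result`: list with
#'   `per_category` (named list holding `correlation`, `p_value`,
#'   `clusters`, `selection` per category), `selected_ids`,
#'   `selected_panel` (an [indicator_panel()]), `config`.
#' @export
screen_panel <- function(panel, config = screening_config(),
                         categories = NULL) {
  panel <- as_indicator_panel(panel)
  present <- intersect(DPSIR_CATEGORIES, unique(panel$category))
  if (is.null(categories)) {
    categories <- present
  } else {
    absent <- setdiff(categories, present)
    if (length(absent) > 0) {
      warn(paste0(
        "Skipping category with zero indicators: ",
        paste(absent, collapse = ", ")
      ))
      categories <- intersect(categories, present)
    }
  }
  per_category <- lapply(setNames(categories, categories), function(cat) {
    cm <- correlation_matrix(panel, cat)
    clusters <- cluster_correlated(cm$r, cm$p, config)
    selection <- lapply(clusters, function(cl) {
      select_representative(panel, cl, config)
    })
    list(
      correlation = cm$r, p_value = cm$p, n = cm$n,
      constant = cm$constant, clusters = clusters, selection = selection
    )
  })
  selected_ids <- sort(unlist(lapply(per_category, function(x) {
    unlist(lapply(x$selection, `[[`, "selected"))
  }), use.names = FALSE))
  selected_panel <- indicator_panel(
    dplyr::filter(as_tibble(panel), .data$indicator_id %in% selected_ids),
    baseline_year = panel_baseline(panel)
  )
  structure(
    list(
      per_category = per_category,
      selected_ids = selected_ids,
      selected_panel = selected_panel,
      input_ids = sort(unique(panel$indicator_id)),
      config = config
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("# Indicator screening:", length(x$input_ids), "->",
      length(x$selected_ids), "indicators\n")
  for (cat_id in names(x$per_category)) {
    pc <- x$per_category[[cat_id]]
    for (i in seq_along(pc$clusters)) {
      cl <- pc$clusters[[i]]
      sel <- pc$selection[[i]]$selected
      if (length(cl) == 1L) {
        cat("  ", cat_id, ": ", cl, " (independent)\n", sep = "")
      } else {
        cat("  ", cat_id, ": {", paste(cl, collapse = ", "), "} -> ",
            paste(sel, collapse = ", "), "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' @export
#' @method tidy screening_result
tidy.screening_result <- function(x, ...) {
  purrr::map_dfr(names(x$per_category), function(cat_id) {
    pc <- x$per_category[[cat_id]]
    purrr::map_dfr(seq_along(pc$clusters), function(i) {
      cl <- pc$clusters[[i]]
      sel <- pc$selection[[i]]
      pc1 <- if (is.null(sel$loadings)) {
        rep(NA_real_, length(cl))
      } else {
        unname(sel$loadings[, 1][cl])
      }
      tibble(
        category = cat_id,
        cluster = i,
        cluster_size = length(cl),
        indicator_id = cl,
        pc1_loading = pc1,
        selected = cl %in% sel$selected
      )
    })
  })
}

#' @export
#' @method glance screening_result
glance.screening_result <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_indicators = length(x$input_ids),
    n_selected = length(x$selected_ids),
    n_clusters = nrow(dplyr::distinct(td, .data$category, .data$cluster)),
    n_multimember_clusters = nrow(
      dplyr::distinct(
        dplyr::filter(td, .data$cluster_size > 1),
        .data$category, .data$cluster
      )
    ),
    alpha = x$config$alpha,
    pc_variance_threshold = x$config$pc_variance_threshold
  )
}

#' Write a screening result as JSON
#'
#' Matrices are written as nested arrays with an `ids` vector giving the
#' row/column order; suitable for audit.
#'
#' @param x A `screening_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_screening_json <- function(x, path) {
  out <- list(
    selected_ids = x$selected_ids,
    input_ids = x$input_ids,
    alpha = x$config$alpha,
    pc_variance_threshold = x$config$pc_variance_threshold,
    categories = lapply(x$per_category, function(pc) {
      list(
        ids = colnames(pc$correlation),
        correlation = unname(apply(pc$correlation, 1, as.list)),
        p_value = unname(apply(pc$p_value, 1, as.list)),
        clusters = pc$clusters,
        selected = lapply(pc$selection, `[[`, "selected")
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Plot the correlation structure found by screening
#'
#' Heatmap of pairwise correlations per category with selected indicators
#' marked.
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot screening_result
autoplot.screening_result <- function(object, ...) {
  cor_long <- purrr::map_dfr(names(object$per_category), function(cat_id) {
    r <- object$per_category[[cat_id]]$correlation
    as_tibble(r, rownames = "row") |>
      tidyr::pivot_longer(-"row", names_to = "col", values_to = "r") |>
      dplyr::mutate(category = cat_id)
  })
  sel <- object$selected_ids
  cor_long <- dplyr::mutate(
    cor_long,
    row = ifelse(.data$row %in% sel, paste0(.data$row, "*"), .data$row),
    col = ifelse(.data$col %in% sel, paste0(.data$col, "*"), .data$col)
  )
  ggplot2::ggplot(
    cor_long,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "Pearson r",
      title = "Indicator correlation by DPSIR category",
      subtitle = "* = selected by screening"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
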