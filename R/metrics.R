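## Per-cluster and dataset-level statistics.

#' Per-cluster statistics: size, median degree, taxonomic purity
#'
#' For every cluster of the network, computes its size, the median over
#' members of the within-cluster degree ("median edge count" — a median
#' close to size − 1 signals near-complete interconnectivity), the
#' dominant origin kingdom and its purity. Purity is the fraction of
#' members *with known kingdom* that belong to the dominant kingdom;
#' members with `kingdom == "unknown"` are excluded from the denominator,
#' and a cluster whose members are all unknown has `purity = NA`.
#'
#' @param network An `np_network` object.
#' @param purity_threshold Purity level defining a taxonomically pure
#'   cluster (inclusive, default 0.95). A cluster of size >= 2 counts as
#'   pure when `purity >= purity_threshold` and the dominant kingdom is
#'   `bacterium` or `fungus`.
#' @return A tibble with one row per cluster: `cluster_id`, `size`,
#'   `median_edge_count`, `dominant_kingdom`, `purity`,
#'   `n_unknown_kingdom`, `is_pure`; sorted by `cluster_id`.
#' @export
cluster_stats <- function(network, purity_threshold = 0.95) {
  stopifnot(inherits(network, "np_network"))
  deg <- .within_degree(network)
  df <- dplyr::left_join(
    network$clusters,
    network$compounds[, c("compound_id", "kingdom")],
    by = "compound_id")
  df$degree <- unname(deg[df$compound_id])
  stats <- df |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      size = dplyr::n(),
      median_edge_count = stats::median(.data$degree),
      dominant_kingdom = {
        known <- .data$kingdom[.data$kingdom != "unknown"]
        if (length(known) == 0) "unknown" else {
          tab <- sort(table(known), decreasing = TRUE)
          # tie-break: alphabetical among equally common kingdoms
          names(tab)[tab == max(tab)][order(names(tab)[tab == max(tab)])][1]
        }
      },
      purity = {
        known <- .data$kingdom[.data$kingdom != "unknown"]
        if (length(known) == 0) NA_real_ else max(table(known)) / length(known)
      },
      n_unknown_kingdom = sum(.data$kingdom == "unknown"),
      .groups = "drop") |>
    dplyr::arrange(.data$cluster_id)
  stats$is_pure <- !is.na(stats$purity) &
    stats$purity >= purity_threshold &
    stats$dominant_kingdom %in% c("bacterium", "fungus")
  stats
}

#' Dataset-level summary of a similarity network
#'
#' Headline counts of the clustering: how many clusters of two or more
#' compounds exist, how many compounds they contain (and the percentage),
#' the median cluster size, the number of clusters with at least five
#' members, the singleton count and percentage, and how many clusters of
#' size >= 2 are taxonomically pure at the threshold.
#'
#' The primary `median_cluster_size` is computed over clusters of size
#' >= 2 (clusters in the "two or more compounds" sense); the variant
#' including singletons is reported as `median_cluster_size_all`.
#' Percentages are rounded to one decimal place.
#'
#' @param x An `np_network` object, or a per-cluster statistics tibble
#'   from [cluster_stats()].
#' @param purity_threshold See [cluster_stats()].
#' @return A one-row tibble with columns `n_compounds`, `n_clusters_ge2`,
#'   `n_compounds_in_clusters_ge2`, `pct_in_clusters`,
#'   `median_cluster_size`, `median_cluster_size_all`, `n_clusters_ge5`,
#'   `n_singletons`, `pct_singletons`, `n_pure_clusters`.
#' @export
dataset_summary <- function(x, purity_threshold = 0.95) {
  stats <- if (inherits(x, "np_network")) {
    cluster_stats(x, purity_threshold = purity_threshold)
  } else {
    stopifnot(is.data.frame(x), all(c("size", "median_edge_count") %in% names(x)))
    x
  }
  if (nrow(stats) == 0) rlang::abort("empty cluster statistics")
  n_compounds <- sum(stats$size)
  ge2 <- stats$size >= 2
  n_in <- sum(stats$size[ge2])
  n_single <- sum(!ge2)
  tibble::tibble(
    n_compounds = n_compounds,
    n_clusters_ge2 = sum(ge2),
    n_compounds_in_clusters_ge2 = n_in,
    pct_in_clusters = round(100 * n_in / n_compounds, 1),
    median_cluster_size = if (any(ge2)) stats::median(stats$size[ge2]) else NA_real_,
    median_cluster_size_all = stats::median(stats$size),
    n_clusters_ge5 = sum(stats$size >= 5),
    n_singletons = n_single,
    pct_singletons = round(100 * n_single / n_compounds, 1),
    n_pure_clusters = sum(stats$is_pure & ge2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity network into per-cluster statistics
#'
#' @param x An `np_network` object.
#' @param purity_threshold See [cluster_stats()].
#' @param ... Unused.
#' @return The [cluster_stats()] tibble.
#' @method tidy np_network
#' @export
tidy.np_network <- function(x, purity_threshold = 0.95, ...) {
  cluster_stats(x, purity_threshold = purity_threshold)
}

#' One-row summary of a similarity network
#'
#' @param x An `np_network` object.
#' @param purity_threshold See [cluster_stats()].
#' @param ... Unused.
#' @return The [dataset_summary()] tibble.
#' @method glance np_network
#' @export
glance.np_network <- function(x, purity_threshold = 0.95, ...) {
  dataset_summary(x, purity_threshold = purity_threshold)
}
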