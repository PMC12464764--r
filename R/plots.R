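## ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cluster-size vs median-degree landscape of a similarity network
#'
#' One point per cluster of two or more members: size against the median
#' within-cluster degree, coloured by dominant kingdom. Points on the
#' diagonal are fully interconnected families (every member similar to
#' every other); points far below it are sparser, chain-like clusters.
#'
#' @param object An `np_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_network
#' @export
autoplot.np_network <- function(object, ...) {
  stats <- cluster_stats(object)
  stats <- stats[stats$size >= 2, , drop = FALSE]
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$size,
                                      y = .data$median_edge_count,
                                      colour = .data$dominant_kingdom)) +
    ggplot2::geom_abline(slope = 1, intercept = -1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size",
                  y = "median within-cluster degree",
                  colour = "kingdom") +
    ggplot2::theme_minimal()
}

#' Rank-similarity profile plot
#'
#' Scores against rank for one query compound, coloured by cluster
#' membership; the cluster boundary shows as the drop between the two
#' colours.
#'
#' @param object An `np_profile` tibble from [rank_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_profile
#' @export
autoplot.np_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$score,
                                       colour = .data$in_same_cluster)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                            `FALSE` = "#bdbdbd")) +
    ggplot2::labs(x = "rank", y = "Dice similarity",
                  colour = "same cluster",
                  title = attr(object, "query_id")) +
    ggplot2::theme_minimal()
}

#' Novelty-timeline plot
#'
#' Contemporary and current singleton percentages per year of first
#' report.
#'
#' @param object An `np_timeline` tibble from [novelty_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot np_timeline
#' @export
autoplot.np_timeline <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("year", "pct_contemporary", "pct_current")],
    cols = c("pct_contemporary", "pct_current"),
    names_to = "measure", values_to = "pct")
  long$measure <- ifelse(long$measure == "pct_contemporary",
                         "contemporary singletons", "current singletons")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$pct,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year of first report", y = "% of compounds",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
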