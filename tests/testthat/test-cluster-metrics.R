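clique_edges <- function(ids, score = 1) {
  pairs <- t(utils::combn(ids, 2))
  tibble::tibble(id_a = pairs[, 1], id_b = pairs[, 2], score = score)
}

test_that("complete clusters have median degree size - 1", {
  ids <- paste0("m", 1:5)
  net <- fake_network(ids, clique_edges(ids))
  stats <- cluster_stats(net)
  expect_equal(stats$size, 5)
  expect_equal(stats$median_edge_count, 4)
})

test_that("median degree of a path cluster uses per-member degrees", {
  # a-b-c: degrees 1, 2, 1 -> median 1
  net <- fake_network(c("a", "b", "c"),
                      tibble::tibble(id_a = c("a", "b"), id_b = c("b", "c"),
                                     score = 0.8))
  expect_equal(cluster_stats(net)$median_edge_count, 1)
})

test_that("singletons have median degree 0 and degree bound holds", {
  ids <- c(paste0("f", 1:4), "solo")
  net <- fake_network(ids, clique_edges(paste0("f", 1:4)))
  stats <- cluster_stats(net)
  expect_equal(stats$median_edge_count[stats$size == 1], 0)
  expect_true(all(stats$median_edge_count <= stats$size - 1))
})

test_that("purity is computed over known kingdoms, inclusively thresholded", {
  ids <- paste0("m", 1:20)
  net <- fake_network(ids, clique_edges(ids),
                      kingdom = c(rep("bacterium", 19), "fungus"))
  stats <- cluster_stats(net, purity_threshold = 0.95)
  expect_equal(stats$purity, 19 / 20)
  expect_equal(stats$dominant_kingdom, "bacterium")
  expect_true(stats$is_pure)                 # 0.95 passes at threshold 0.95
})

test_that("unknown kingdoms are excluded from purity denominators", {
  ids <- paste0("m", 1:4)
  net <- fake_network(ids, clique_edges(ids),
                      kingdom = c("bacterium", "bacterium", "unknown",
                                  "unknown"))
  stats <- cluster_stats(net)
  expect_equal(stats$purity, 1)
  expect_equal(stats$n_unknown_kingdom, 2)
  all_unknown <- fake_network(c("a", "b"),
                              clique_edges(c("a", "b")),
                              kingdom = c("unknown", "unknown"))
  s2 <- cluster_stats(all_unknown)
  expect_true(is.na(s2$purity))
  expect_false(s2$is_pure)
})

test_that("purity is invariant under compound relabeling", {
  ids <- paste0("m", 1:6)
  king <- c("fungus", "fungus", "fungus", "fungus", "bacterium", "other")
  net1 <- fake_network(ids, clique_edges(ids), kingdom = king)
  perm <- c(3, 1, 6, 2, 5, 4)
  net2 <- fake_network(paste0("r", 1:6),
                       clique_edges(paste0("r", 1:6)),
                       kingdom = king[perm])
  expect_equal(cluster_stats(net1)$purity, cluster_stats(net2)$purity)
})

test_that("dataset summary counts clusters, singletons and percentages", {
  # sizes {4, 2, 1}: 2 clusters >= 2, 1 singleton of 7 compounds -> 14.3%
  ids4 <- paste0("a", 1:4); ids2 <- paste0("b", 1:2)
  net <- fake_network(c(ids4, ids2, "solo"),
                      dplyr::bind_rows(clique_edges(ids4),
                                       clique_edges(ids2)))
  summ <- dataset_summary(net)
  expect_equal(summ$n_compounds, 7)
  expect_equal(summ$n_clusters_ge2, 2)
  expect_equal(summ$n_compounds_in_clusters_ge2, 6)
  expect_equal(summ$n_singletons, 1)
  expect_equal(summ$pct_singletons, 14.3)
  expect_equal(summ$pct_in_clusters, 85.7)
})

test_that("all-singleton datasets summarize to 100% singletons", {
  net <- fake_network(paste0("s", 1:5),
                      tibble::tibble(id_a = character(0),
                                     id_b = character(0), score = numeric(0)))
  summ <- dataset_summary(net)
  expect_equal(summ$n_clusters_ge2, 0)
  expect_equal(summ$pct_singletons, 100)
  expect_true(is.na(summ$median_cluster_size))
})

test_that("median cluster size is over clusters of two or more", {
  # sizes {2, 3, 5} -> median 3, one cluster >= 5
  ids2 <- paste0("a", 1:2); ids3 <- paste0("b", 1:3); ids5 <- paste0("c", 1:5)
  net <- fake_network(c(ids2, ids3, ids5, "solo"),
                      dplyr::bind_rows(clique_edges(ids2),
                                       clique_edges(ids3),
                                       clique_edges(ids5)))
  summ <- dataset_summary(net)
  expect_equal(summ$median_cluster_size, 3)
  expect_equal(summ$n_clusters_ge5, 1)
  # secondary variant includes the singleton
  expect_equal(summ$median_cluster_size_all, 2.5)
})

test_that("cluster sizes always sum to the compound count", {
  ds <- generate_compound_dataset(n_families = 3, n_singletons = 4, seed = 21)
  net <- similarity_network(ds)
  stats <- cluster_stats(net)
  expect_equal(sum(stats$size), nrow(ds))
  expect_equal(dataset_summary(net)$n_compounds, nrow(ds))
})

test_that("tidy and glance methods mirror the stats functions", {
  ds <- generate_compound_dataset(n_families = 2, n_singletons = 1, seed = 13)
  net <- similarity_network(ds)
  expect_equal(tidy(net), cluster_stats(net))
  expect_equal(glance(net), dataset_summary(net))
})
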