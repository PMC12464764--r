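no_edges <- tibble::tibble(id_a = character(0), id_b = character(0),
                           score = numeric(0))

test_that("earliest-year compounds are contemporary singletons vacuously", {
  net <- fake_network(c("a", "b"),
                      tibble::tibble(id_a = "a", id_b = "b", score = 0.9),
                      year = c(1980L, 1980L))
  cs <- contemporary_singletons(net)
  expect_setequal(cs$compound_id, c("a", "b"))
})

test_that("a similar earlier compound removes contemporary novelty", {
  net <- fake_network(c("old", "new"),
                      tibble::tibble(id_a = "new", id_b = "old", score = 1),
                      year = c(1980L, 2000L))
  cs <- contemporary_singletons(net)
  expect_equal(cs$compound_id, "old")
  # the strict prior-year rule is directional: old stays novel
  expect_false("new" %in% cs$compound_id)
})

test_that("same-year neighbours do not spoil contemporary novelty by default", {
  net <- fake_network(
    c("p1", "p2", "earlier"),
    tibble::tibble(id_a = "p1", id_b = "p2", score = 0.95),
    year = c(1995L, 1995L, 1970L))
  cs <- contemporary_singletons(net)
  expect_setequal(cs$compound_id, c("p1", "p2", "earlier"))
  # with the flag on, the same-year pair is no longer novel
  cs2 <- contemporary_singletons(net, include_same_year = TRUE)
  expect_setequal(cs2$compound_id, "earlier")
  # but neither is a current singleton either way
  cur <- current_singletons(net)
  expect_equal(cur$compound_id, "earlier")
})

test_that("current singletons are exactly the size-1 clusters", {
  ds <- generate_compound_dataset(n_families = 3, n_singletons = 3, seed = 31)
  net <- similarity_network(ds)
  cur <- current_singletons(net)
  expect_setequal(cur$compound_id,
                  net$clusters$compound_id[net$clusters$cluster_size == 1])
})

test_that("current singletons are a subset of contemporary singletons", {
  for (seed in c(7, 41)) {
    ds <- generate_compound_dataset(n_families = 4, n_singletons = 2,
                                    seed = seed)
    net <- similarity_network(ds)
    cur <- current_singletons(net)
    con <- contemporary_singletons(net)
    expect_true(all(cur$compound_id %in% con$compound_id))
  }
})

test_that("timeline percentages are consistent and ordered", {
  ds <- generate_compound_dataset(n_families = 4, n_singletons = 3, seed = 37)
  net <- similarity_network(ds)
  tl <- novelty_timeline(net)
  expect_true(all(tl$pct_contemporary >= tl$pct_current))
  expect_true(all(tl$pct_contemporary >= 0 & tl$pct_contemporary <= 100))
  expect_equal(sum(tl$n_discovered), sum(!is.na(ds$year)))
  expect_true(all(tl$n_current_singletons <= tl$n_contemporary_singletons))
  # only years with discoveries appear
  expect_true(all(tl$n_discovered >= 1))
})

test_that("single-year datasets are 100% contemporary singletons", {
  net <- fake_network(c("a", "b", "c"),
                      tibble::tibble(id_a = "a", id_b = "b", score = 0.8),
                      year = c(1999L, 1999L, 1999L))
  tl <- novelty_timeline(net)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$pct_contemporary, 100)
})

test_that("compounds without a year are excluded and reported", {
  net <- fake_network(c("a", "b", "noyear"), no_edges,
                      year = c(1990L, 2000L, NA))
  cs <- contemporary_singletons(net)
  expect_false("noyear" %in% cs$compound_id)
  expect_equal(attr(cs, "excluded"), "noyear")
  all_na <- fake_network(c("a", "b"), no_edges)
  expect_error(contemporary_singletons(all_na), "year")
})

test_that("a planned 3-year dataset reproduces its constructed counts", {
  # y1990: x1, x2 similar pair; y2000: x3 similar to x1; y2010: x4 isolated
  net <- fake_network(
    c("x1", "x2", "x3", "x4"),
    tibble::tibble(id_a = c("x1", "x1"), id_b = c("x2", "x3"),
                   score = c(0.9, 0.85)),
    year = c(1990L, 1990L, 2000L, 2010L))
  tl <- novelty_timeline(net)
  expect_equal(tl$year, c(1990L, 2000L, 2010L))
  expect_equal(tl$n_discovered, c(2L, 1L, 1L))
  expect_equal(tl$n_contemporary_singletons, c(2L, 0L, 1L))
  expect_equal(tl$n_current_singletons, c(0L, 0L, 1L))
  expect_equal(tl$pct_contemporary, c(100, 0, 100))
  expect_equal(tl$pct_current, c(0, 0, 100))
})
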