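test_that("valid compound tables are read completely", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    compound_id = c("a", "b", "c"),
    smiles = unname(fx_smiles$valid3),
    kingdom = c("bacterium", "Fungal", "cyanobacteria"),
    year = c(1980, 2001, NA)), path)
  cpds <- read_compound_table(path, format = "csv",
                              column_map = c(compound_id = "compound_id",
                                             smiles = "smiles",
                                             kingdom = "kingdom",
                                             year = "year"))
  expect_equal(nrow(cpds), 3)
  expect_equal(nrow(rejected_compounds(cpds)), 0)
  # kingdom vocabulary is normalized; cyanobacteria count as bacteria
  expect_equal(cpds$kingdom, c("bacterium", "fungus", "bacterium"))
  expect_equal(cpds$year, c(1980L, 2001L, NA))
  expect_true(all(nzchar(cpds$structure_key)))
})

test_that("unparseable SMILES are rejected per-record, not fatally", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    compound_id = c("a", "bad", "c"),
    smiles = c("c1ccccc1", fx_smiles$bad_ring, "CCO")), path)
  cpds <- suppressMessages(read_compound_table(path, format = "csv"))
  expect_equal(nrow(cpds), 2)
  rej <- rejected_compounds(cpds)
  expect_equal(rej$compound_id, "bad")
  expect_match(rej$reason, "SMILES")
  # accepted + rejected always add up to the input rows
  expect_equal(nrow(cpds) + nrow(rej), 3)
})

test_that("duplicate identifiers are a fatal error naming the id", {
  df <- data.frame(compound_id = c("x1", "x1"), smiles = c("CCO", "CCC"))
  expect_error(compound_table(df), "x1")
})

test_that("missing files and missing mandatory columns are fatal", {
  expect_error(read_compound_table(file.path(tempdir(), "nope.csv")),
               "not found")
  df <- data.frame(id = "a", structure = "CCO")
  expect_error(compound_table(df), "compound_id")
})

test_that("deduplication collapses notational variants, keeps distinct ones", {
  same <- compound_table(data.frame(compound_id = c("a", "b"),
                                    smiles = c("OCC", "CCO")))
  expect_equal(nrow(suppressMessages(deduplicate_compounds(same))), 1)
  expect_equal(suppressMessages(deduplicate_compounds(same))$compound_id, "a")
  diff <- compound_table(data.frame(compound_id = c("a", "b"),
                                    smiles = c("CCO", "CCC")))
  expect_equal(nrow(deduplicate_compounds(diff)), 2)
  empty <- compound_table(data.frame(compound_id = character(0),
                                     smiles = character(0)))
  expect_equal(nrow(deduplicate_compounds(empty)), 0)
})

test_that("stereoisomers survive deduplication", {
  iso <- compound_table(data.frame(
    compound_id = c("r", "s"),
    smiles = c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O")))
  expect_equal(nrow(deduplicate_compounds(iso)), 2)
})

test_that("SDF input yields the same records as CSV input", {
  sdf_path <- withr::local_tempfile(fileext = ".sdf")
  sdfset <- ChemmineR::smiles2sdf(c(cpd1 = "CC(=O)Nc1ccc(O)cc1",
                                    cpd2 = "c1ccncc1"))
  ChemmineR::datablock(sdfset) <- list(
    cpd1 = c(kingdom = "bacterium", year = "1999"),
    cpd2 = c(kingdom = "fungus", year = "2005"))
  ChemmineR::write.SDF(sdfset, sdf_path)
  cpds <- read_compound_table(sdf_path, format = "sdf",
                              column_map = c(kingdom = "kingdom",
                                             year = "year"))
  expect_equal(nrow(cpds), 2)
  expect_setequal(cpds$kingdom, c("bacterium", "fungus"))
  expect_setequal(cpds$year, c(1999L, 2005L))
  ref <- compound_table(data.frame(compound_id = c("x", "y"),
                                   smiles = c("CC(=O)Nc1ccc(O)cc1",
                                              "c1ccncc1")))
  expect_setequal(cpds$structure_key, ref$structure_key)
})

test_that("edge-list export writes scores to exactly four decimals", {
  net <- fake_network(c("a", "b"),
                      tibble::tibble(id_a = "a", id_b = "b", score = 0.8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, format = "edge_list_tsv")
  lines <- readLines(path)
  expect_equal(lines, c("source\ttarget\tscore", "a\tb\t0.8000"))
})

test_that("graphml export round-trips nodes, edges and attributes", {
  net <- fake_network(
    c("a", "b", "c"),
    tibble::tibble(id_a = "a", id_b = "b", score = 0.87654),
    kingdom = c("bacterium", "fungus", "unknown"),
    year = c(1990L, 2000L, NA))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  back <- read_network_graphml(path)
  expect_setequal(back$nodes$compound_id, c("a", "b", "c"))
  expect_equal(back$nodes$kingdom[match(c("a", "b"), back$nodes$compound_id)],
               c("bacterium", "fungus"))
  expect_equal(back$nodes$year[match("a", back$nodes$compound_id)], 1990L)
  expect_equal(back$nodes$cluster_id,
               net$clusters$cluster_id[match(back$nodes$compound_id,
                                             net$clusters$compound_id)])
  expect_equal(nrow(back$edges), 1)
  expect_equal(back$edges$score, round(0.87654, 4))
})

test_that("singleton-only networks export as nodes without edges", {
  net <- fake_network(c("a", "b", "c"),
                      tibble::tibble(id_a = character(0),
                                     id_b = character(0),
                                     score = numeric(0)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  back <- read_network_graphml(path)
  expect_equal(nrow(back$nodes), 3)
  expect_equal(nrow(back$edges), 0)
})

test_that("unknown export formats are fatal", {
  net <- fake_network(c("a"), tibble::tibble(id_a = character(0),
                                             id_b = character(0),
                                             score = numeric(0)))
  expect_error(write_network(net, tempfile(), format = "gexf"), "format")
})
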