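# Molecules with known ring systems for the macrolactone census.
ring_fixtures <- function() {
  compound_table(data.frame(
    compound_id = c("hexadecanolide", "pentadecanolide", "benzene",
                    "lactam16", "diolide16", "fused", "ketone16"),
    smiles = c(
      fx_smiles$hexadecanolide,            # 16-membered lactone
      fx_smiles$pentadecanolide,           # 15-membered lactone
      "c1ccccc1",                          # no macrocycle, no ester
      "O=C1CCCCCCCCCCCCCCN1",              # 16-ring but amide, not ester
      "O=C1CCCCCCOC(=O)CCCCCCO1",           # 16-ring with two ester units
      "O=C1CCCCCC2CCC(CC2)CCCCCO1",          # macrolactone bridged by a ring
      "O=C1CCCCCCCCCCCCCCC1"               # 16-ring ketone, no ring O
    )))
}

test_that("the 16-membered lactone matches and the 15-membered does not", {
  cpds <- ring_fixtures()
  m16 <- find_macrolactones(cpds, ring_size = 16)
  expect_true("hexadecanolide" %in% m16$compound_id)
  expect_false("pentadecanolide" %in% m16$compound_id)
  expect_false("benzene" %in% m16$compound_id)
  m15 <- find_macrolactones(cpds, ring_size = 15)
  expect_true("pentadecanolide" %in% m15$compound_id)
  expect_false("hexadecanolide" %in% m15$compound_id)
})

test_that("amides and ring ketones are not macrolactones", {
  m16 <- find_macrolactones(ring_fixtures(), ring_size = 16)
  expect_false("lactam16" %in% m16$compound_id)
  expect_false("ketone16" %in% m16$compound_id)
})

test_that("multiple qualifying cycles are counted once per cycle", {
  m16 <- find_macrolactones(ring_fixtures(), ring_size = 16)
  row <- m16[m16$compound_id == "diolide16", ]
  expect_equal(nrow(row), 1)
  # the single 16-cycle contains two ester units but is one ring
  expect_equal(row$n_matching_rings, 1L)
})

test_that("macrocycles bridged by smaller rings are still found", {
  m16 <- find_macrolactones(ring_fixtures(), ring_size = 16)
  expect_true("fused" %in% m16$compound_id)
})

test_that("cycle enumeration agrees with the exhaustive oracle", {
  cpds <- ring_fixtures()
  for (size in c(14L, 15L, 16L, 17L)) {
    got <- find_macrolactones(cpds, ring_size = size)
    for (i in seq_len(nrow(cpds))) {
      expected <- exhaustive_macrolactone_count(cpds$smiles[i], size)
      row <- got[got$compound_id == cpds$compound_id[i], ]
      if (expected == 0) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(row$n_matching_rings, expected,
                     label = paste(cpds$compound_id[i], "size", size))
      }
    }
  }
})

test_that("ring size bounds are enforced", {
  expect_error(find_macrolactones(ring_fixtures(), ring_size = 2), "ring_size")
  expect_error(find_macrolactones(ring_fixtures(), ring_size = 100),
               "ring_size")
})

test_that("substructure annotation flags presence per compound", {
  cpds <- compound_table(data.frame(
    compound_id = c("toluene", "cyclohexane"),
    smiles = c("Cc1ccccc1", "C1CCCCC1")))
  ann <- annotate_substructure(cpds, "c1ccccc1", "benzene_core")
  expect_equal(ann$query_name, rep("benzene_core", 2))
  expect_equal(ann$present[ann$compound_id == "toluene"], TRUE)
  expect_equal(ann$present[ann$compound_id == "cyclohexane"], FALSE)
})

test_that("invalid SMARTS patterns are fatal and name the pattern", {
  cpds <- compound_table(data.frame(compound_id = "a", smiles = "CCO"))
  expect_error(annotate_substructure(cpds, "c1ccccc"), "c1ccccc")
})

test_that("annotation flags match generator ground truth on decorated families", {
  lib <- scaffold_library()
  # a chlorine-free scaffold decorated only with chloro or methyl
  fam <- generate_compound_family(
    lib$template[lib$scaffold_id == "s01"], "fam", n_members = 8,
    decorations = c(chloro = "Cl", methyl = "C"), seed = 5)
  ann <- annotate_substructure(fam, "[Cl]", "chloro")
  truth <- grepl("Cl", fam$decorations)
  expect_equal(ann$present, truth)
})

test_that("ring matches group into classes by matched-subgraph components", {
  # 7 matches; edges give components of sizes {4, 2, 1}
  ids <- paste0("m", 1:7)
  edges <- tibble::tibble(
    id_a = c("m1", "m2", "m3", "m5"),
    id_b = c("m2", "m3", "m4", "m6"),
    score = 0.9)
  net <- fake_network(c(ids, "other"), edges)
  matches <- tibble::tibble(compound_id = ids, ring_size = 16L,
                            n_matching_rings = 1L, is_macrolactone = TRUE)
  classes <- group_ring_matches(matches, net, min_class_size = 3)
  by_class <- split(classes$compound_id, classes$class_id)
  expect_equal(unname(sort(lengths(by_class), decreasing = TRUE)),
               c(4L, 2L, 1L))
  expect_equal(sum(!classes$minor), 4)       # only the size-4 class is major
  expect_equal(sum(classes$minor), 3)
})

test_that("degenerate grouping inputs behave", {
  net <- fake_network(c("a", "b"),
                      tibble::tibble(id_a = "a", id_b = "b", score = 1))
  empty <- tibble::tibble(compound_id = character(0), ring_size = integer(0),
                          n_matching_rings = integer(0),
                          is_macrolactone = logical(0))
  expect_equal(nrow(group_ring_matches(empty, net)), 0)
  all_conn <- tibble::tibble(compound_id = c("a", "b"), ring_size = 16L,
                             n_matching_rings = 1L, is_macrolactone = TRUE)
  cls <- group_ring_matches(all_conn, net, min_class_size = 2)
  expect_equal(unique(cls$class_id), 1L)
  expect_false(any(cls$minor))
})
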