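## Compound-table ingestion, validation, deduplication and network export.

.kingdoms <- c("bacterium", "fungus", "other", "unknown")

.normalize_kingdom <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  x[x %in% c("bacteria", "bacterial", "cyanobacterium", "cyanobacteria")] <- "bacterium"
  x[x %in% c("fungi", "fungal")] <- "fungus"
  x[!x %in% .kingdoms] <- "other"
  x
}

#' Build a validated compound table from a data frame
#'
#' Entry point for in-memory data: validates identifiers and SMILES,
#' canonicalizes structures, normalizes origin-kingdom labels and years,
#' and attaches a rejection report for rows whose SMILES do not parse.
#'
#' The origin kingdom is coerced to one of `bacterium`, `fungus`, `other`,
#' `unknown` (cyanobacteria count as bacteria); years outside
#' `[1800, current year]` are treated as missing. The `structure_key`
#' column holds the canonical SMILES (stereochemistry retained —
#' stereoisomers are distinct compounds) and is the deduplication key.
#'
#' @param df A data frame with at least an identifier and a SMILES column.
#' @param id_col,smiles_col,name_col,kingdom_col,year_col Column names in
#'   `df` for each semantic field; `name_col`, `kingdom_col` and
#'   `year_col` may be `NULL` when absent.
#' @return A tibble with columns `compound_id`, `smiles`, `name`,
#'   `kingdom`, `year`, `structure_key`, containing only rows whose
#'   SMILES parse. The rejection report (columns `compound_id`, `reason`)
#'   is attached as the `"rejections"` attribute; see
#'   [rejected_compounds()].
#' @export
compound_table <- function(df, id_col = "compound_id", smiles_col = "smiles",
                           name_col = NULL, kingdom_col = NULL,
                           year_col = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c(id_col, smiles_col)) {
    if (!col %in% names(df))
      rlang::abort(paste0("mandatory column '", col, "' not found in input"))
  }
  ids <- as.character(df[[id_col]])
  if (anyNA(ids) || any(!nzchar(ids)))
    rlang::abort("missing compound identifiers in input")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    rlang::abort(paste0("duplicate compound identifier(s): ",
                        paste(utils::head(dup, 5), collapse = ", ")))
  smiles <- as.character(df[[smiles_col]])
  key <- ob_canonical_smiles(smiles)
  name <- if (!is.null(name_col) && name_col %in% names(df)) {
    as.character(df[[name_col]])
  } else rep(NA_character_, nrow(df))
  kingdom <- if (!is.null(kingdom_col) && kingdom_col %in% names(df)) {
    .normalize_kingdom(df[[kingdom_col]])
  } else rep("unknown", nrow(df))
  year <- if (!is.null(year_col) && year_col %in% names(df)) {
    suppressWarnings(as.integer(df[[year_col]]))
  } else rep(NA_integer_, nrow(df))
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  year[!is.na(year) & (year < 1800L | year > this_year)] <- NA_integer_
  ok <- !is.na(key)
  rejections <- tibble::tibble(
    compound_id = ids[!ok],
    reason = rep("SMILES failed to parse", sum(!ok)))
  out <- tibble::tibble(
    compound_id = ids[ok], smiles = smiles[ok], name = name[ok],
    kingdom = kingdom[ok], year = year[ok], structure_key = key[ok])
  attr(out, "rejections") <- rejections
  attr(out, "provenance") <- "in-memory data frame"
  if (nrow(rejections) > 0)
    rlang::inform(paste0(nrow(rejections), " record(s) rejected (unparseable SMILES)"))
  out
}

#' Read a compound table from CSV, TSV or SDF
#'
#' Reads a compound collection from disk, then validates it with
#' [compound_table()]: rows with unparseable structures are rejected (not
#' fatal) and reported via [rejected_compounds()]; missing files, missing
#' mandatory columns and duplicate identifiers are fatal.
#'
#' For `format = "sdf"` the structures come from the V2000 connection
#' tables (converted to SMILES) and metadata from named SD tags; the
#' `column_map` entries then name SD tags instead of columns, and the
#' identifier defaults to the molecule title when no tag is mapped.
#'
#' @param path Path to the input file.
#' @param format One of `"csv"`, `"tsv"`, `"sdf"`; defaults to the file
#'   extension.
#' @param column_map Named character vector mapping the semantic fields
#'   `compound_id`, `smiles`, `name`, `kingdom`, `year` to source columns
#'   or SD tags. Only `compound_id` and `smiles` are mandatory (the
#'   `smiles` entry is ignored for SDF input).
#' @return A validated compound tibble; see [compound_table()].
#' @export
read_compound_table <- function(path, format = c("csv", "tsv", "sdf"),
                                column_map = c(compound_id = "compound_id",
                                               smiles = "smiles",
                                               name = "name",
                                               kingdom = "kingdom",
                                               year = "year")) {
  if (!file.exists(path))
    rlang::abort(paste0("input file not found: ", path))
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "sdf")) ext else "csv"
  }
  format <- match.arg(format)
  cm <- function(field, default = NULL) {
    if (field %in% names(column_map)) unname(column_map[[field]]) else default
  }
  if (format %in% c("csv", "tsv")) {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    df <- reader(path, show_col_types = FALSE, progress = FALSE)
    out <- compound_table(
      df,
      id_col = cm("compound_id", "compound_id"),
      smiles_col = cm("smiles", "smiles"),
      name_col = cm("name"), kingdom_col = cm("kingdom"),
      year_col = cm("year"))
  } else {
    out <- .read_sdf_table(path, cm)
  }
  attr(out, "provenance") <- path
  out
}

.read_sdf_table <- function(path, cm) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  titles <- vapply(seq_along(sdfset), function(i) {
    h <- ChemmineR::header(sdfset[[i]])
    if (length(h) >= 1) trimws(h[[1]]) else ""
  }, character(1))
  n <- length(sdfset)
  smiles <- rep(NA_character_, n)
  if (any(valid)) {
    smi <- ChemmineR::sdf2smiles(sdfset[valid])
    smiles[valid] <- as.character(smi)
  }
  get_tag <- function(i, tag) {
    db <- ChemmineR::datablock(sdfset[[i]])
    if (!is.null(tag) && tag %in% names(db)) db[[tag]] else NA_character_
  }
  id_tag <- cm("compound_id")
  ids <- vapply(seq_len(n), function(i) {
    v <- get_tag(i, id_tag)
    if (!is.na(v)) v else titles[i]
  }, character(1))
  ids[!nzchar(ids)] <- paste0("sdf_", which(!nzchar(ids)))
  df <- tibble::tibble(
    compound_id = ids,
    smiles = smiles,
    name = vapply(seq_len(n), get_tag, character(1), tag = cm("name")),
    kingdom = vapply(seq_len(n), get_tag, character(1), tag = cm("kingdom")),
    year = vapply(seq_len(n), get_tag, character(1), tag = cm("year")))
  df$smiles[is.na(df$smiles)] <- "*invalid*"
  compound_table(df, kingdom_col = "kingdom", name_col = "name",
                 year_col = "year")
}

#' Rejection report of a compound table
#'
#' @param compounds A compound tibble from [compound_table()] or
#'   [read_compound_table()].
#' @return A tibble with columns `compound_id` and `reason`, one row per
#'   rejected input record.
#' @export
rejected_compounds <- function(compounds) {
  rej <- attr(compounds, "rejections")
  if (is.null(rej)) {
    rej <- tibble::tibble(compound_id = character(0), reason = character(0))
  }
  rej
}

#' Remove duplicate structures from a compound table
#'
#' Collapses records sharing a `structure_key` (canonical SMILES,
#' stereochemistry included) to the first occurrence, preserving input
#' order. Notational variants of the same molecule therefore count once;
#' stereoisomers remain distinct.
#'
#' @param compounds A compound tibble.
#' @return The deduplicated tibble; the number of removed records is
#'   reported as a message.
#' @export
deduplicate_compounds <- function(compounds) {
  stopifnot(is.data.frame(compounds), "structure_key" %in% names(compounds))
  keep <- !duplicated(compounds$structure_key)
  removed <- sum(!keep)
  if (removed > 0)
    rlang::inform(paste0(removed, " duplicate structure(s) removed"))
  out <- compounds[keep, , drop = FALSE]
  attr(out, "rejections") <- attr(compounds, "rejections")
  attr(out, "provenance") <- attr(compounds, "provenance")
  out
}

#' Write a compound table as CSV
#'
#' Writes the dialect [read_compound_table()] reads back: UTF-8,
#' comma-separated, header row.
#'
#' @param compounds A compound tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  readr::write_csv(compounds, path, progress = FALSE)
  invisible(path)
}

#' Export a similarity network for external viewers
#'
#' Writes the thresholded similarity network in a Cytoscape-importable
#' format: GraphML (nodes carry `kingdom`, `year` and `cluster_id`
#' attributes, edges the numeric `score`) or a plain TSV edge list with
#' columns `source`, `target`, `score` (4 decimal places).
#'
#' @param network An `np_network` object from [similarity_network()].
#' @param path Output path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_list_tsv")) {
  stopifnot(inherits(network, "np_network"))
  if (is.character(format) && length(format) == 1 &&
      !format %in% c("graphml", "edge_list_tsv"))
    rlang::abort(paste0("unknown network format: ", format))
  format <- match.arg(format)
  edges <- network$edges
  if (format == "edge_list_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("source\ttarget\tscore", con)
    if (nrow(edges) > 0) {
      writeLines(sprintf("%s\t%s\t%.4f", edges$id_a, edges$id_b, edges$score), con)
    }
    return(invisible(path))
  }
  nodes <- dplyr::left_join(network$clusters,
                            network$compounds[, c("compound_id", "kingdom", "year")],
                            by = "compound_id")
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (k in list(c("d_kingdom", "node", "kingdom", "string"),
                 c("d_year", "node", "year", "int"),
                 c("d_cluster", "node", "cluster_id", "int"),
                 c("d_score", "edge", "score", "double"))) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        `attr.name` = k[3], `attr.type` = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "similarity_network",
                               edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$compound_id[i])
    xml2::xml_add_child(nd, "data", key = "d_kingdom",
                        nodes$kingdom[i] %||% "unknown")
    if (!is.na(nodes$year[i]))
      xml2::xml_add_child(nd, "data", key = "d_year", as.character(nodes$year[i]))
    xml2::xml_add_child(nd, "data", key = "d_cluster",
                        as.character(nodes$cluster_id[i]))
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = edges$id_a[i], target = edges$id_b[i])
    xml2::xml_add_child(ed, "data", key = "d_score",
                        sprintf("%.4f", edges$score[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a GraphML similarity network
#'
#' Counterpart of [write_network()]'s GraphML output, mainly for
#' round-trip checking and for re-importing externally edited networks.
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return A list with `nodes` (tibble: `compound_id`, `kingdom`, `year`,
#'   `cluster_id`) and `edges` (tibble: `id_a`, `id_b`, `score`).
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, paste0("./data[@key='", key, "']"))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  node_els <- xml2::xml_find_all(doc, ".//node")
  nodes <- tibble::tibble(
    compound_id = xml2::xml_attr(node_els, "id"),
    kingdom = vapply(node_els, get_data, character(1), key = "d_kingdom"),
    year = suppressWarnings(as.integer(
      vapply(node_els, get_data, character(1), key = "d_year"))),
    cluster_id = as.integer(
      vapply(node_els, get_data, character(1), key = "d_cluster")))
  edge_els <- xml2::xml_find_all(doc, ".//edge")
  edges <- tibble::tibble(
    id_a = xml2::xml_attr(edge_els, "source"),
    id_b = xml2::xml_attr(edge_els, "target"),
    score = as.numeric(vapply(edge_els, get_data, character(1), key = "d_score")))
  list(nodes = nodes, edges = edges)
}
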