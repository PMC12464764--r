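## End-to-end orchestration of the analysis stages.

#' Default pipeline configuration
#'
#' Collects the tunable parameters of the pipeline with the standard
#' defaults of the analysis: fingerprint radius 2 over 2048 bits, Dice
#' cutoff 0.75, purity threshold 0.95, macrolactone ring size 16, minimum
#' class size 3, profile depth 500.
#'
#' @param radius,n_bits Fingerprint parameters.
#' @param cutoff Dice similarity cutoff (inclusive).
#' @param purity_threshold Taxonomic purity threshold.
#' @param ring_size Macrolactone ring size for the census.
#' @param min_class_size Minimum members for a macrolactone class.
#' @param top_n Profile depth for rank profiles.
#' @return A named list of class `np_config`.
#' @export
np_config <- function(radius = 2L, n_bits = 2048L, cutoff = 0.75,
                      purity_threshold = 0.95, ring_size = 16L,
                      min_class_size = 3L, top_n = 500L) {
  stopifnot(radius >= 0, n_bits >= 2, cutoff > 0, cutoff <= 1,
            purity_threshold > 0, purity_threshold <= 1,
            ring_size >= 3, min_class_size >= 1, top_n >= 1)
  structure(
    list(radius = as.integer(radius), n_bits = as.integer(n_bits),
         cutoff = cutoff, purity_threshold = purity_threshold,
         ring_size = as.integer(ring_size),
         min_class_size = as.integer(min_class_size),
         top_n = as.integer(top_n)),
    class = "np_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage over a compound table and writes the results as
#' plain-text tables under one output directory: accepted compounds and
#' rejections, the fingerprint cache, the thresholded edge list, the
#' cluster assignment, per-cluster statistics, the dataset summary, the
#' novelty timeline (when years are present), the macrolactone census and
#' a JSON run manifest echoing the configuration and input hash. Reruns
#' with identical inputs are byte-identical (the manifest's timestamp
#' aside).
#'
#' @param input A compound tibble, or a path to a CSV/TSV/SDF file read
#'   via [read_compound_table()].
#' @param output_dir Directory for outputs (created if needed).
#' @param config An [np_config()] list.
#' @param ... Passed to [read_compound_table()] when `input` is a path.
#' @return The `np_network` object, invisibly; outputs on disk.
#' @export
run_pipeline <- function(input, output_dir, config = np_config(), ...) {
  stopifnot(inherits(config, "np_config"))
  compounds <- if (is.character(input)) {
    read_compound_table(input, ...)
  } else {
    input
  }
  if (!is.data.frame(compounds) || nrow(compounds) == 0)
    rlang::abort("no valid compounds in input")
  compounds <- deduplicate_compounds(compounds)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)

  readr::write_tsv(compounds, p("compounds.tsv"), progress = FALSE)
  readr::write_tsv(rejected_compounds(compounds), p("rejections.tsv"),
                   progress = FALSE)
  fps <- morgan_fingerprints(compounds, radius = config$radius,
                             n_bits = config$n_bits)
  write_fingerprints(fps, p("fingerprints.tsv"))
  network <- similarity_network(compounds, cutoff = config$cutoff, fps = fps)
  write_network(network, p("edges.tsv"), format = "edge_list_tsv")
  write_network(network, p("network.graphml"), format = "graphml")
  readr::write_tsv(network$clusters, p("clusters.tsv"), progress = FALSE)
  stats <- cluster_stats(network, purity_threshold = config$purity_threshold)
  readr::write_tsv(stats, p("cluster_stats.tsv"), progress = FALSE)
  summ <- dataset_summary(stats, purity_threshold = config$purity_threshold)
  readr::write_tsv(
    tibble::tibble(key = names(summ),
                   value = vapply(summ, as.character, character(1))),
    p("summary.tsv"), progress = FALSE)
  if (any(!is.na(compounds$year))) {
    readr::write_tsv(novelty_timeline(network), p("timeline.tsv"),
                     progress = FALSE)
  }
  rings <- find_macrolactones(compounds, ring_size = config$ring_size)
  readr::write_tsv(rings, p("macrolactones.tsv"), progress = FALSE)
  if (nrow(rings) > 0) {
    readr::write_tsv(
      group_ring_matches(rings, network,
                         min_class_size = config$min_class_size),
      p("macrolactone_classes.tsv"), progress = FALSE)
  }
  manifest <- list(
    config = unclass(config),
    n_compounds = nrow(compounds),
    n_rejections = nrow(rejected_compounds(compounds)),
    input = attr(compounds, "provenance") %||% "unknown",
    input_hash = .table_hash(compounds),
    package_version = as.character(utils::packageVersion("npdiversity")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(network)
}

# Cheap deterministic content hash (FNV-style over the serialized table).
.table_hash <- function(df) {
  txt <- paste(utils::capture.output(utils::write.csv(df, row.names = FALSE)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
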