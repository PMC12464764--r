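## Thresholded similarity graph and its partition into clusters.

#' Partition compounds into clusters by connected components
#'
#' Clusters are the connected components of the thresholded similarity
#' graph (single-linkage at the cutoff): two compounds share a cluster iff
#' they are joined by a chain of edges at or above the cutoff. Compounds
#' with no incident edge form size-1 clusters (singletons). Cluster ids
#' are assigned by decreasing cluster size, ties broken by the
#' lexicographically smallest member id, so numbering is deterministic.
#'
#' @param edges Edge tibble (`id_a`, `id_b`, `score`) from
#'   [similarity_edges()].
#' @param all_ids Character vector of every compound id in the set,
#'   including compounds without edges.
#' @return A tibble with columns `compound_id`, `cluster_id`,
#'   `cluster_size`, one row per compound, in `all_ids` order.
#' @export
connected_components <- function(edges, all_ids) {
  stopifnot(is.data.frame(edges), is.character(all_ids))
  unknown <- setdiff(unique(c(edges$id_a, edges$id_b)), all_ids)
  if (length(unknown) > 0)
    rlang::abort(paste0("edge references unknown compound id(s): ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  n <- length(all_ids)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("id_a", "id_b")], directed = FALSE,
      vertices = data.frame(name = all_ids))
    comp <- igraph::components(g)$membership[all_ids]
  } else {
    comp <- stats::setNames(seq_len(n), all_ids)
  }
  sizes <- table(comp)
  # deterministic numbering: decreasing size, then smallest member id
  min_member <- tapply(all_ids, comp, min)
  comp_keys <- names(sizes)
  ord <- order(-as.integer(sizes), min_member[comp_keys])
  new_id <- stats::setNames(seq_along(comp_keys), comp_keys[ord])
  cluster_id <- unname(new_id[as.character(comp)])
  cluster_size <- unname(as.integer(sizes[as.character(comp)]))
  tibble::tibble(compound_id = all_ids, cluster_id = cluster_id,
                 cluster_size = cluster_size)
}

#' Build a compound similarity network
#'
#' The main entry point of the analysis: fingerprints every compound
#' (hashed circular substructures, radius 2 by default), scores all pairs
#' with the Dice coefficient, keeps edges at or above the cutoff
#' (default 0.75), and partitions the graph into clusters by connected
#' components.
#'
#' @param compounds A compound tibble from [compound_table()] /
#'   [read_compound_table()] or the synthetic generator.
#' @param cutoff Dice similarity threshold, inclusive (default 0.75).
#' @param radius,n_bits Fingerprint parameters, see
#'   [morgan_fingerprints()].
#' @param fps Optionally, precomputed fingerprints (`np_fps`); must cover
#'   exactly the compounds in `compounds`.
#' @return An object of class `np_network`: a list with elements
#'   `compounds`, `fps`, `edges`, `clusters` (per-compound cluster
#'   assignment) and `params`. Supports [tidy()][generics::tidy] (per-
#'   cluster statistics), [glance()][generics::glance] (dataset summary)
#'   and [autoplot()][ggplot2::autoplot] (cluster-size vs median-degree
#'   landscape).
#' @examples
#' \donttest{
#' cpds <- compound_table(data.frame(
#'   compound_id = c("a", "b", "c"),
#'   smiles = c("CC(=O)Nc1ccc(O)cc1", "CC(=O)Nc1ccc(OC)cc1", "C1CCCCC1")))
#' net <- similarity_network(cpds)
#' glance(net)
#' }
#' @export
similarity_network <- function(compounds, cutoff = 0.75, radius = 2L,
                               n_bits = 2048L, fps = NULL) {
  stopifnot(is.data.frame(compounds))
  if (nrow(compounds) == 0) rlang::abort("no valid compounds in input")
  if (is.null(fps)) {
    fps <- morgan_fingerprints(compounds, radius = radius, n_bits = n_bits)
  } else {
    stopifnot(inherits(fps, "np_fps"))
    if (!setequal(fps$compound_id, compounds$compound_id))
      rlang::abort("`fps` does not cover the same compound ids as `compounds`")
  }
  edges <- similarity_edges(fps, cutoff = cutoff)
  clusters <- connected_components(edges, compounds$compound_id)
  structure(
    list(compounds = compounds, fps = fps, edges = edges, clusters = clusters,
         params = list(cutoff = cutoff, radius = attr(fps, "radius"),
                       n_bits = attr(fps, "n_bits"))),
    class = "np_network")
}

#' @export
print.np_network <- function(x, ...) {
  n <- nrow(x$compounds)
  sizes <- x$clusters$cluster_size[!duplicated(x$clusters$cluster_id)]
  cat("<np_network> ", n, " compounds, ", nrow(x$edges),
      " edges (Dice >= ", x$params$cutoff, ", radius ",
      x$params$radius, ", ", x$params$n_bits, " bits)\n", sep = "")
  cat("  clusters: ", sum(sizes >= 2), " with >= 2 members, ",
      sum(sizes == 1), " singletons\n", sep = "")
  invisible(x)
}

# Within-cluster degree of every compound (number of incident edges whose
# other end lies in the same cluster; at the construction cutoff every
# edge is within-cluster by definition of connected components).
.within_degree <- function(network) {
  deg <- stats::setNames(rep(0L, nrow(network$clusters)),
                         network$clusters$compound_id)
  if (nrow(network$edges) > 0) {
    t1 <- table(network$edges$id_a)
    t2 <- table(network$edges$id_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}
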