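## Rank-similarity profiles and the score drop at a cluster boundary.

#' Rank the whole collection by similarity to one query compound
#'
#' For a query compound, scores every other compound in the network with
#' the Dice coefficient and returns the top matches ranked by descending
#' score (ties broken by ascending compound id), excluding the query
#' itself. This is the per-compound view of how sharply a compound family
#' is separated from the rest of chemical space.
#'
#' @param network An `np_network` object.
#' @param query_id Compound id of the query; must exist in the network.
#' @param top_n Maximum number of matches returned (default 500). When
#'   larger than the collection, all `n - 1` comparisons are returned.
#' @return A tibble of class `np_profile` with columns `rank`,
#'   `compound_id`, `score`, `in_same_cluster`; the query id is attached
#'   as the `"query_id"` attribute.
#' @export
rank_profile <- function(network, query_id, top_n = 500L) {
  stopifnot(inherits(network, "np_network"))
  fps <- network$fps
  pos <- match(query_id, fps$compound_id)
  if (is.na(pos))
    rlang::abort(paste0("unknown query compound id: ", query_id))
  qbits <- fps$bits[[pos]]
  scores <- vapply(fps$bits, dice_similarity, numeric(1), b = qbits)
  keep <- seq_along(scores) != pos
  ids <- fps$compound_id[keep]
  scores <- scores[keep]
  ord <- order(-scores, ids)
  n_out <- min(as.integer(top_n), length(ids))
  ord <- ord[seq_len(n_out)]
  q_cluster <- network$clusters$cluster_id[
    match(query_id, network$clusters$compound_id)]
  member <- network$clusters$cluster_id[
    match(ids[ord], network$clusters$compound_id)] == q_cluster
  out <- tibble::tibble(
    rank = seq_len(n_out),
    compound_id = ids[ord],
    score = scores[ord],
    in_same_cluster = member)
  attr(out, "query_id") <- query_id
  class(out) <- c("np_profile", class(out))
  out
}

#' Similarity drop at the cluster boundary of a ranked profile
#'
#' Quantifies how steeply similarity falls off where a compound's cluster
#' ends: the difference between the lowest score among same-cluster
#' entries and the highest score among non-members. A negative drop
#' (flagged) means some non-member outranks a cluster member.
#'
#' @param profile An `np_profile` tibble from [rank_profile()].
#' @return A one-row tibble with `query_id`, `last_in_cluster_score`,
#'   `first_out_cluster_score`, `drop`, `inverted` (TRUE when drop < 0).
#' @export
boundary_drop <- function(profile) {
  stopifnot(inherits(profile, "np_profile"))
  if (!any(profile$in_same_cluster))
    rlang::abort("no boundary: query is a singleton (no cluster members in profile)")
  if (all(profile$in_same_cluster))
    rlang::abort("no boundary: no non-member present in profile")
  last_in <- min(profile$score[profile$in_same_cluster])
  first_out <- max(profile$score[!profile$in_same_cluster])
  tibble::tibble(
    query_id = attr(profile, "query_id"),
    last_in_cluster_score = last_in,
    first_out_cluster_score = first_out,
    drop = last_in - first_out,
    inverted = last_in - first_out < 0)
}

#' Ranked profiles for every member of one cluster
#'
#' Batch version of [rank_profile()] over all members of a cluster,
#' stacked into one tibble (plot-ready for rank-vs-score panels).
#'
#' @param network An `np_network` object.
#' @param cluster_id Cluster id to profile.
#' @param top_n See [rank_profile()].
#' @return A tibble with the [rank_profile()] columns plus `query_id`.
#' @export
cluster_profiles <- function(network, cluster_id, top_n = 500L) {
  stopifnot(inherits(network, "np_network"))
  members <- network$clusters$compound_id[network$clusters$cluster_id == cluster_id]
  if (length(members) == 0)
    rlang::abort(paste0("unknown cluster id: ", cluster_id))
  purrr::map_dfr(members, function(m) {
    p <- rank_profile(network, m, top_n = top_n)
    dplyr::mutate(tibble::as_tibble(p), query_id = m, .before = 1)
  })
}
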