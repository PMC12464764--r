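## Macrocyclic-lactone detection and substructure presence annotation.

# All distinct simple cycles of exactly `size` atoms that contain the
# bond (from, to), found by depth-first search for paths from `to` back
# to `from` of size-1 edges. BFS distances from `from` prune branches
# that cannot close in the remaining depth. Returns a list of atom-index
# vectors (cycles, starting at `to`, ending at `from`).
.cycles_through_bond <- function(adj, from, to, size) {
  n <- length(adj)
  # BFS distances from `from`
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier) > 0 && d < size) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  cycles <- list()
  visited <- rep(FALSE, n)
  visited[to] <- TRUE
  path <- integer(size)
  path[1] <- to
  recurse <- function(v, depth) {
    # depth = number of atoms placed so far; need `size` atoms total,
    # the last being `from`
    remaining <- size - depth
    for (w in adj[[v]]) {
      if (w == from) {
        if (remaining == 1L) {
          cycles[[length(cycles) + 1L]] <<- c(path[seq_len(depth)], from)
        }
        next
      }
      if (visited[w] || remaining <= 1L) next
      if (is.na(dist[w]) || dist[w] > remaining - 1L) next
      visited[w] <<- TRUE
      path[depth + 1L] <<- w
      recurse(w, depth + 1L)
      visited[w] <<- FALSE
    }
  }
  if (size >= 3) recurse(to, 1L)
  cycles
}

# Canonical key of a cycle (invariant under rotation and direction).
.cycle_key <- function(cycle) {
  k <- length(cycle)
  i <- which.min(cycle)
  fwd <- cycle[((i - 1 + seq_len(k) - 1) %% k) + 1]
  rev_ <- cycle[((i - 1 - (seq_len(k) - 1)) %% k) + 1]
  best <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
    fwd else rev_
  paste(best, collapse = ",")
}

# Ester bonds of a molecular graph: single bonds O-C where the carbon
# carries an exocyclic double-bonded oxygen (degree-1 O). Returns a
# two-column matrix (o_atom, c_atom).
.ester_bonds <- function(graph) {
  atoms <- graph$atoms; bonds <- graph$bonds
  if (nrow(bonds) == 0) return(matrix(integer(0), ncol = 2))
  carbonyl_c <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$order[b] == 2L) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (atoms$element[a1] == "C" && atoms$element[a2] == "O" &&
          atoms$degree[a2] == 1L) carbonyl_c <- c(carbonyl_c, a1)
      if (atoms$element[a2] == "C" && atoms$element[a1] == "O" &&
          atoms$degree[a1] == 1L) carbonyl_c <- c(carbonyl_c, a2)
    }
  }
  if (length(carbonyl_c) == 0) return(matrix(integer(0), ncol = 2))
  out <- matrix(integer(0), ncol = 2)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$order[b] != 1L) next
    a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
    if (atoms$element[a1] == "O" && atoms$element[a2] == "C" &&
        a2 %in% carbonyl_c && atoms$degree[a1] >= 2L)
      out <- rbind(out, c(a1, a2))
    if (atoms$element[a2] == "O" && atoms$element[a1] == "C" &&
        a1 %in% carbonyl_c && atoms$degree[a2] >= 2L)
      out <- rbind(out, c(a2, a1))
  }
  out
}

#' Census of N-membered macrolactones in a compound table
#'
#' Finds compounds containing a macrocyclic lactone of exactly
#' `ring_size` atoms: a simple cycle of `ring_size` atoms that includes an
#' ester unit, with both the ester oxygen and the carbonyl carbon in the
#' cycle and the carbonyl oxygen exocyclic. Ring sizes count both ester
#' atoms (the usual macrolide convention, e.g. 16 for the
#' 16-hexadecanolide core).
#'
#' Cycle search is an exhaustive bounded enumeration of simple cycles
#' through each ester bond, not a smallest-set-of-smallest-rings
#' treatment, so macrocycles bridged by smaller fused rings are still
#' found.
#'
#' @param compounds A compound tibble.
#' @param ring_size Exact macrocycle size in atoms (default 16).
#' @param max_ring_size Upper bound accepted for `ring_size` (default
#'   72); guards against runaway cycle enumeration.
#' @return A tibble with one row per matching compound: `compound_id`,
#'   `ring_size`, `n_matching_rings` (number of distinct qualifying
#'   cycles), `is_macrolactone` (always `TRUE` for returned rows).
#' @examples
#' \donttest{
#' cpds <- compound_table(data.frame(
#'   compound_id = c("hexadecanolide", "pentadecanolide"),
#'   smiles = c("O=C1CCCCCCCCCCCCCCO1", "O=C1CCCCCCCCCCCCCO1")))
#' find_macrolactones(cpds, ring_size = 16)
#' }
#' @export
find_macrolactones <- function(compounds, ring_size = 16L,
                               max_ring_size = 72L) {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "structure_key") %in% names(compounds)))
  ring_size <- as.integer(ring_size)
  if (ring_size < 3 || ring_size > max_ring_size)
    rlang::abort(paste0("`ring_size` must be in [3, ", max_ring_size, "]"))
  graphs <- parse_molecules(compounds$structure_key)
  rows <- purrr::map(seq_len(nrow(compounds)), function(i) {
    g <- graphs[[i]]
    esters <- .ester_bonds(g)
    if (nrow(esters) == 0) return(NULL)
    adj <- .adjacency(nrow(g$atoms), g$bonds)
    keys <- character(0)
    for (e in seq_len(nrow(esters))) {
      cycles <- .cycles_through_bond(adj, esters[e, 1], esters[e, 2], ring_size)
      keys <- c(keys, vapply(cycles, .cycle_key, character(1)))
    }
    keys <- unique(keys)
    if (length(keys) == 0) return(NULL)
    tibble::tibble(compound_id = compounds$compound_id[i],
                   ring_size = ring_size,
                   n_matching_rings = length(keys),
                   is_macrolactone = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(compound_id = character(0), ring_size = integer(0),
                          n_matching_rings = integer(0),
                          is_macrolactone = logical(0))
  }
  out
}

#' Annotate compounds with presence/absence of a substructure
#'
#' Flags every compound of a table by whether a SMARTS pattern has at
#' least one embedding in its structure — the per-cluster
#' pharmacophore-presence view used to colour cluster networks.
#'
#' @param compounds A compound tibble (e.g. the members of one cluster).
#' @param pattern A SMARTS substructure pattern.
#' @param query_name Short label for the pattern (defaults to the pattern
#'   string).
#' @return A tibble with columns `compound_id`, `query_name`, `present`,
#'   one row per compound.
#' @export
annotate_substructure <- function(compounds, pattern, query_name = pattern) {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "structure_key") %in% names(compounds)))
  n <- nrow(compounds)
  present <- rep(FALSE, n)
  single <- grepl("^(\\[[^]]+\\]|Br|Cl|[BCNOFPSI])$", compounds$structure_key)
  multi <- which(!single)
  if (length(multi) > 0) {
    sdf <- ChemmineR::smiles2sdf(
      stats::setNames(compounds$structure_key[multi],
                      paste0("m", seq_along(multi))))
    counts <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = FALSE),
      error = function(e)
        rlang::abort(paste0("invalid SMARTS pattern: ", pattern)))
    present[multi] <- counts > 0
  }
  if (any(single)) {
    # single heavy atoms: match only the trivial single-atom patterns
    present[single] <- compounds$structure_key[single] == pattern
  }
  tibble::tibble(compound_id = compounds$compound_id,
                 query_name = query_name,
                 present = present)
}

#' Group ring matches into compound classes
#'
#' Partitions the macrolactone matches by connectivity *within the
#' matched subset*: connected components are re-run over the matched
#' compounds only, using the network's similarity edges restricted to
#' them. Components with at least `min_class_size` members are the
#' compound classes; smaller ones are flagged as minor groups.
#'
#' @param matches A tibble from [find_macrolactones()].
#' @param network The `np_network` the matches came from.
#' @param min_class_size Minimum members for a full class (default 3).
#' @return A tibble with columns `compound_id`, `class_id`, `class_size`,
#'   `minor` (TRUE when `class_size < min_class_size`).
#' @export
group_ring_matches <- function(matches, network, min_class_size = 3L) {
  stopifnot(is.data.frame(matches), inherits(network, "np_network"))
  ids <- matches$compound_id
  if (length(ids) == 0) {
    return(tibble::tibble(compound_id = character(0), class_id = integer(0),
                          class_size = integer(0), minor = logical(0)))
  }
  unknown <- setdiff(ids, network$clusters$compound_id)
  if (length(unknown) > 0)
    rlang::abort(paste0("matched compound(s) absent from network: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  sub_edges <- dplyr::filter(network$edges,
                             .data$id_a %in% ids & .data$id_b %in% ids)
  comp <- connected_components(sub_edges, sort(ids))
  tibble::tibble(compound_id = comp$compound_id,
                 class_id = comp$cluster_id,
                 class_size = comp$cluster_size,
                 minor = comp$cluster_size < min_class_size)
}
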