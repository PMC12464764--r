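# Independent oracles and shared fixtures for the test suite.

# Naive O(n^2) edge list: double loop over dice_similarity, no matrix
# engine involved.
naive_edges <- function(fps, cutoff = 0.75) {
  n <- nrow(fps)
  out <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- dice_similarity(fps$bits[[i]], fps$bits[[j]])
        if (s >= cutoff) {
          ia <- fps$compound_id[i]; ib <- fps$compound_id[j]
          out[[length(out) + 1L]] <- data.frame(
            id_a = min(ia, ib), id_b = max(ia, ib), score = s)
        }
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(id_a = character(0), id_b = character(0),
                     score = numeric(0))
  }
  df[order(df$id_a, df$id_b), , drop = FALSE]
}

# Brute-force union-find over an edge list; returns membership groups as
# a list of sorted id vectors.
union_find_components <- function(edges, all_ids) {
  parent <- stats::setNames(all_ids, all_ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(all_ids, find, character(1))
  unname(lapply(split(all_ids, roots), sort))
}

# Partition-as-set-of-sets comparison (ignores labels).
same_partition <- function(groups_a, groups_b) {
  a <- sort(vapply(groups_a, function(g) paste(sort(g), collapse = "|"),
                   character(1)))
  b <- sort(vapply(groups_b, function(g) paste(sort(g), collapse = "|"),
                   character(1)))
  identical(a, b)
}

# Clusters of an np_network as a list of member-id vectors.
network_partition <- function(network) {
  unname(split(network$clusters$compound_id, network$clusters$cluster_id))
}

# Ground-truth partition of a synthetic dataset (singletons = own group).
truth_partition <- function(compounds) {
  key <- ifelse(is.na(compounds$family_id), compounds$compound_id,
                compounds$family_id)
  unname(split(compounds$compound_id, key))
}

# Hand-built np_network (no fingerprints) for metric tests with a known
# edge topology.
fake_network <- function(ids, edges, kingdom = NULL, year = NULL,
                         cutoff = 0.75) {
  compounds <- tibble::tibble(
    compound_id = ids,
    smiles = NA_character_, name = NA_character_,
    kingdom = kingdom %||% rep("unknown", length(ids)),
    year = year %||% rep(NA_integer_, length(ids)),
    structure_key = ids)
  edges <- tibble::tibble(
    id_a = pmin(edges$id_a, edges$id_b),
    id_b = pmax(edges$id_a, edges$id_b),
    score = edges$score)
  structure(
    list(compounds = compounds, fps = NULL, edges = edges,
         clusters = connected_components(edges, ids),
         params = list(cutoff = cutoff, radius = 2L, n_bits = 2048L)),
    class = "np_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of every simple cycle of exactly `size` atoms:
# vertex-anchored backtracking (each cycle found once from its smallest
# vertex, closing back to the anchor, second vertex < last vertex to fix
# direction). Independent of the package's bond-anchored search.
enumerate_cycles <- function(n_atoms, bonds, size) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) adj[[i]] <- integer(0)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
  }
  cycles <- list()
  path <- integer(size)
  visited <- rep(FALSE, n_atoms)
  dfs <- function(anchor, v, depth) {
    for (w in adj[[v]]) {
      if (w == anchor && depth == size) {
        if (path[2] < path[size]) {
          cycles[[length(cycles) + 1L]] <<- path[seq_len(size)]
        }
      } else if (!visited[w] && w > anchor && depth < size) {
        visited[w] <<- TRUE
        path[depth + 1L] <<- w
        dfs(anchor, w, depth + 1L)
        visited[w] <<- FALSE
      }
    }
  }
  for (a in seq_len(n_atoms)) {
    visited[a] <- TRUE
    path[1] <- a
    dfs(a, a, 1L)
    visited[a] <- FALSE
  }
  cycles
}

# Exhaustive oracle for the macrolactone search: enumerate every simple
# cycle of exactly `ring_size` atoms, keep those containing an ester O-C
# bond (carbonyl C with an exocyclic double-bonded O), count distinct
# cycles.
exhaustive_macrolactone_count <- function(smiles, ring_size) {
  can <- npdiversity:::ob_canonical_smiles(smiles)
  g <- npdiversity:::parse_molecules(can)[[1]]
  bonds <- g$bonds
  if (nrow(bonds) == 0) return(0L)
  cycles <- enumerate_cycles(nrow(g$atoms), bonds, ring_size)
  esters <- npdiversity:::.ester_bonds(g)
  if (nrow(esters) == 0 || length(cycles) == 0) return(0L)
  has_ester <- vapply(cycles, function(cyc) {
    cyc <- as.integer(cyc)
    k <- length(cyc)
    for (e in seq_len(nrow(esters))) {
      o <- esters[e, 1]; cc <- esters[e, 2]
      for (i in seq_len(k)) {
        j <- if (i == k) 1L else i + 1L
        if ((cyc[i] == o && cyc[j] == cc) || (cyc[i] == cc && cyc[j] == o))
          return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  keys <- vapply(cycles[has_ester], function(cyc)
    npdiversity:::.cycle_key(as.integer(cyc)), character(1))
  length(unique(keys))
}

# Small valid/invalid molecule fixtures.
fx_smiles <- list(
  valid3 = c(benzene = "c1ccccc1", ethanol = "CCO", pyridine = "c1ccncc1"),
  hexadecanolide = "O=C1CCCCCCCCCCCCCCO1",
  pentadecanolide = "O=C1CCCCCCCCCCCCCO1",
  bad_ring = "C1CC"
)
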