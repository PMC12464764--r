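## Hashed circular (Morgan / ECFP-style) fingerprints and Dice similarity.

# Deterministic integer hash of an integer vector, folded into [0, 2^31 - 2].
# Plain polynomial rolling hash: every intermediate stays below 2^53 so the
# arithmetic is exact in doubles, hence reproducible across platforms.
.hash_ints <- function(x) {
  m <- 2147483647
  h <- 17
  for (v in x) h <- (h * 31 + (v %% m)) %% m
  h
}

# Circular-substructure bit positions for one molecular graph.
#
# Radius-0 identifiers hash each atom's local invariant (atomic number,
# heavy-atom degree, attached hydrogens, formal charge, ring membership).
# Each subsequent iteration rehashes the atom's previous identifier with
# the sorted (bond order, neighbour identifier) pairs, so the identifier
# at radius r captures the full environment within r bonds. All
# identifiers from radius 0 through `radius` are folded modulo n_bits
# into one presence/absence bit set.
.morgan_bits <- function(graph, radius = 2L, n_bits = 2048L) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  if (n == 0) return(integer(0))
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(atoms$atomic_number[i], atoms$degree[i], atoms$n_h[i],
                 atoms$charge[i] + 8L, as.integer(atoms$in_ring[i])))
  }, numeric(1))
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- list(idx = integer(0), ord = integer(0))
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]; o <- bonds$order[b]
      nbrs[[a1]]$idx <- c(nbrs[[a1]]$idx, a2); nbrs[[a1]]$ord <- c(nbrs[[a1]]$ord, o)
      nbrs[[a2]]$idx <- c(nbrs[[a2]]$idx, a1); nbrs[[a2]]$ord <- c(nbrs[[a2]]$ord, o)
    }
  }
  ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (length(nb$idx) == 0) {
        new_inv[i] <- .hash_ints(c(r, inv[i]))
      } else {
        pairs <- cbind(nb$ord, inv[nb$idx])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_inv[i] <- .hash_ints(c(r, inv[i], as.numeric(t(pairs))))
      }
    }
    inv <- new_inv
    ids <- c(ids, inv)
  }
  sort(unique(as.integer(ids %% n_bits)))
}

#' Compute hashed circular (Morgan) fingerprints for a compound table
#'
#' Encodes every structure as the set of hashed circular atom environments
#' up to `radius` bonds, the standard extended-connectivity (ECFP-style)
#' representation used for natural-product similarity networks. Bits are
#' presence/absence, not counts.
#'
#' Fingerprints are computed from the canonical structure (the
#' `structure_key` column when present, otherwise the SMILES is
#' canonicalized first), so notational variants of the same molecule
#' always yield identical bit sets.
#'
#' @param compounds A compound tibble as returned by
#'   [read_compound_table()] or [compound_table()]; needs at least
#'   `compound_id` and `smiles` columns.
#' @param radius Maximum environment radius in bonds (default 2, i.e.
#'   ECFP4-equivalent diameter).
#' @param n_bits Fingerprint length; power of two (default 2048).
#' @return A tibble of class `np_fps` with columns `compound_id` and
#'   `bits` (list-column of sorted integer bit positions), carrying
#'   `radius` and `n_bits` attributes.
#' @examples
#' \donttest{
#' cpds <- compound_table(data.frame(compound_id = c("a", "b"),
#'                                   smiles = c("CCO", "c1ccccc1")))
#' fps <- morgan_fingerprints(cpds)
#' lengths(fps$bits)
#' }
#' @export
morgan_fingerprints <- function(compounds, radius = 2L, n_bits = 2048L) {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "smiles") %in% names(compounds)))
  radius <- as.integer(radius); n_bits <- as.integer(n_bits)
  if (radius < 0) rlang::abort("`radius` must be >= 0")
  if (n_bits < 2 || bitwAnd(n_bits, n_bits - 1L) != 0)
    rlang::abort("`n_bits` must be a power of two >= 2")
  smi <- if ("structure_key" %in% names(compounds)) {
    compounds$structure_key
  } else {
    ob_canonical_smiles(compounds$smiles)
  }
  if (anyNA(smi)) {
    bad <- compounds$compound_id[is.na(smi)]
    rlang::abort(paste0("unparseable SMILES for compound(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  graphs <- parse_molecules(smi)
  bits <- lapply(graphs, .morgan_bits, radius = radius, n_bits = n_bits)
  out <- tibble::tibble(compound_id = compounds$compound_id, bits = bits)
  attr(out, "radius") <- radius
  attr(out, "n_bits") <- n_bits
  class(out) <- c("np_fps", class(out))
  out
}

#' Dice similarity between two fingerprints
#'
#' The Dice coefficient on bit sets, `2|A n B| / (|A| + |B|)`, the score
#' used throughout the similarity-network analysis. Defined as 0 when both
#' bit sets are empty (which cannot arise for a valid molecule).
#'
#' @param a,b Integer vectors of bit positions, or single fingerprint rows
#'   extracted from an `np_fps` tibble (`fps$bits[[i]]`).
#' @return A single numeric score in `[0, 1]`.
#' @examples
#' dice_similarity(c(1L, 2L, 5L, 9L), c(1L, 2L, 5L, 7L, 8L, 11L))  # 0.6
#' @export
dice_similarity <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  na <- length(a); nb <- length(b)
  if (na + nb == 0) return(0)
  2 * length(intersect(a, b)) / (na + nb)
}

# Dense 0/1 bit matrix (n_compounds x n_bits) for the blocked pairwise
# engine; rows follow the fps tibble order.
.bit_matrix <- function(fps) {
  n_bits <- attr(fps, "n_bits")
  n <- nrow(fps)
  x <- matrix(0, nrow = n, ncol = n_bits)
  for (i in seq_len(n)) x[i, fps$bits[[i]] + 1L] <- 1
  x
}

#' Build the thresholded Dice-similarity edge list
#'
#' Scores every unordered pair of compounds with the Dice coefficient and
#' keeps pairs at or above `cutoff` (inclusive). Pairs are scored with a
#' blocked bit-matrix cross-product engine that is exactly equivalent to
#' the naive double loop over [dice_similarity()] but handles tens of
#' thousands of compounds in manageable memory.
#'
#' @param fps An `np_fps` tibble from [morgan_fingerprints()].
#' @param cutoff Similarity threshold in `(0, 1]`; edges require
#'   `score >= cutoff` (default 0.75).
#' @param block Row-block size of the pairwise engine (performance knob
#'   only; results are identical for any value).
#' @return A tibble with columns `id_a`, `id_b`, `score`, one row per
#'   retained pair, with `id_a < id_b` lexicographically and rows sorted
#'   by (`id_a`, `id_b`).
#' @export
similarity_edges <- function(fps, cutoff = 0.75, block = 1024L) {
  stopifnot(inherits(fps, "np_fps"))
  if (!(cutoff > 0 && cutoff <= 1)) rlang::abort("`cutoff` must be in (0, 1]")
  n <- nrow(fps)
  if (n < 2) {
    return(tibble::tibble(id_a = character(0), id_b = character(0),
                          score = numeric(0)))
  }
  x <- .bit_matrix(fps)
  sizes <- rowSums(x)
  ids <- fps$compound_id
  res <- vector("list", 0)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    inter <- x[s:e, , drop = FALSE] %*% t(x)   # intersection counts
    denom <- outer(sizes[s:e], sizes, "+")
    dice <- ifelse(denom == 0, 0, 2 * inter / denom)
    hit <- which(dice >= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      gi <- s + hit[, 1] - 1L
      gj <- hit[, 2]
      keep <- gi < gj
      if (any(keep)) {
        res[[length(res) + 1L]] <- tibble::tibble(
          i = gi[keep], j = gj[keep],
          score = dice[hit[keep, , drop = FALSE]])
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(id_a = character(0), id_b = character(0),
                          score = numeric(0)))
  }
  pairs <- dplyr::bind_rows(res)
  ia <- ids[pairs$i]; ib <- ids[pairs$j]
  swap <- ia > ib
  edges <- tibble::tibble(
    id_a = ifelse(swap, ib, ia),
    id_b = ifelse(swap, ia, ib),
    score = pairs$score)
  dplyr::arrange(edges, .data$id_a, .data$id_b)
}

#' Write or read a fingerprint cache
#'
#' Fingerprints are cached as a TSV of `compound_id` and a hex-encoded bit
#' vector, preceded by a header line recording `n_bits` and `radius`; the
#' loader validates that header before decoding.
#'
#' @param fps An `np_fps` tibble.
#' @param path File path for the cache.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns an `np_fps` tibble.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "np_fps"))
  n_bits <- attr(fps, "n_bits")
  hex <- vapply(fps$bits, function(b) {
    bytes <- integer(n_bits / 8)
    if (length(b) > 0) {
      byte_idx <- b %/% 8L + 1L
      bit_in_byte <- b %% 8L
      for (k in seq_along(b)) {
        bytes[byte_idx[k]] <- bitwOr(bytes[byte_idx[k]],
                                     bitwShiftL(1L, bit_in_byte[k]))
      }
    }
    paste(sprintf("%02x", bytes), collapse = "")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_bits=%d radius=%d", n_bits, attr(fps, "radius")), con)
  writeLines("compound_id\tfingerprint_hex", con)
  writeLines(paste(fps$compound_id, hex, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^# n_bits=\\d+ radius=\\d+$", lines[1]))
    rlang::abort("not a fingerprint cache: missing '# n_bits=... radius=...' header")
  n_bits <- as.integer(sub("^# n_bits=(\\d+).*$", "\\1", lines[1]))
  radius <- as.integer(sub("^.*radius=(\\d+)$", "\\1", lines[1]))
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  bits <- lapply(parts, function(p) {
    bytes <- strtoi(substring(p[2], seq(1, nchar(p[2]), 2),
                              seq(2, nchar(p[2]), 2)), 16L)
    out <- integer(0)
    nz <- which(bytes != 0)
    for (i in nz) {
      set <- which(bitwAnd(bytes[i], bitwShiftL(1L, 0:7)) != 0) - 1L
      out <- c(out, (i - 1L) * 8L + set)
    }
    sort(out)
  })
  out <- tibble::tibble(compound_id = ids, bits = bits)
  attr(out, "radius") <- radius
  attr(out, "n_bits") <- n_bits
  class(out) <- c("np_fps", class(out))
  out
}
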