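## Internal molecular-graph layer.
##
## All structure handling funnels through OpenBabel (via ChemmineOB /
## ChemmineR): SMILES validation, canonicalization and conversion to an
## atom/bond table. Everything downstream (fingerprints, ring search)
## operates on the plain graph returned by parse_molecules(), so it is
## independent of input SMILES notation: notational variants of the same
## structure share a canonical SMILES and therefore an identical graph.

# Canonicalize a vector of SMILES. Returns a character vector aligned with
# the input; unparseable entries come back NA. Vectorized through a single
# OpenBabel call: each molecule is tagged with its index as the title and
# invalid molecules are simply dropped from the output stream.
ob_canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  payload <- paste0(smiles[idx], " ", seq_along(idx), collapse = "\n")
  # "e": continue with the next molecule after a parse error, so one bad
  # SMILES does not abort the rest of the batch
  res <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(payload, "\n"),
    options = data.frame(names = "e", args = "", stringsAsFactors = FALSE))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    can <- vapply(parts, `[`, character(1), 1L)
    tag <- suppressWarnings(as.integer(vapply(parts, function(p) {
      if (length(p) >= 2) trimws(p[2]) else NA_character_
    }, character(1))))
    keep <- !is.na(tag) & tag >= 1 & tag <= length(idx) & nzchar(can)
    out[idx[tag[keep]]] <- can[keep]
  }
  out
}

# MDL ctab charge codes (field 5 of the atom block) to formal charges.
.mdl_charge <- function(code) {
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  ifelse(code >= 0 & code <= 7, map[code + 1L], 0L)
}

.element_numbers <- local({
  syms <- c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
    "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
    "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
    "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
    "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")
  stats::setNames(seq_along(syms), syms)
})

# Usual valences used to infer implicit hydrogen counts from a kekulized
# connection table. Multi-valent elements list their allowed states; the
# smallest state accommodating the bond-order sum is chosen.
.valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = c(1L, 3L, 5L, 7L),
  Se = c(2L, 4L, 6L), As = c(3L, 5L), Te = c(2L, 4L, 6L)
)

.implicit_h <- function(element, bond_sum, charge) {
  v <- .valences[[element]]
  if (is.null(v)) return(0L)                      # metals etc: no implicit H
  # charge shifts the effective valence: N+ carries 4 bonds, O- only 1,
  # carbo-cations and -anions both drop to 3.
  adj <- if (element %in% c("N", "O", "P", "S", "Se", "Te")) charge else -abs(charge)
  v <- v + adj
  v <- v[v >= bond_sum]
  if (length(v) == 0) return(0L)
  as.integer(min(v) - bond_sum)
}

# Parse SMILES into plain molecular graphs. Input SMILES are assumed valid
# (run ob_canonical_smiles() first); each element of the returned list is
# a list(atoms = data.frame, bonds = data.frame) where atoms has columns
# element, atomic_number, charge, degree, n_h, in_ring and bonds has
# columns a1, a2, order (kekulized orders 1/2/3).
parse_molecules <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(list())
  out <- vector("list", n)
  # ChemmineR's SDF reader drops the atom of a bond-less (single heavy
  # atom) molecule, so those are built directly from the SMILES token
  single <- grepl("^(\\[[^]]+\\]|Br|Cl|[BCNOFPSI])$", smiles)
  for (i in which(single)) out[[i]] <- .single_atom_graph(smiles[i])
  rest <- which(!single)
  if (length(rest) > 0) {
    ids <- paste0("m", rest)
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[rest], ids))
    for (k in seq_along(rest)) out[[rest[k]]] <- .graph_from_sdf(sdf[[k]])
  }
  out
}

.single_atom_graph <- function(smiles) {
  token <- gsub("^\\[|\\]$", "", smiles)
  element <- sub("^([A-Z][a-z]?).*$", "\\1", token)
  charge <- 0L
  if (grepl("\\+\\d", token)) charge <- as.integer(sub(".*\\+(\\d).*", "\\1", token))
  else if (grepl("-\\d", token)) charge <- -as.integer(sub(".*-(\\d).*", "\\1", token))
  else charge <- sum(strsplit(token, "")[[1]] == "+") - sum(strsplit(token, "")[[1]] == "-")
  n_h <- if (grepl("H\\d", token)) {
    as.integer(sub(".*H(\\d).*", "\\1", token))
  } else if (startsWith(smiles, "[") && grepl("H", substring(token, 2))) {
    1L
  } else if (startsWith(smiles, "[")) {
    0L
  } else {
    .implicit_h(element, 0L, charge)
  }
  atomic_number <- unname(.element_numbers[element])
  if (is.na(atomic_number)) atomic_number <- 0L
  list(
    atoms = data.frame(
      element = element, atomic_number = atomic_number, charge = charge,
      degree = 0L, n_h = n_h, in_ring = FALSE),
    bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  )
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_atoms <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  # ctab atom-line fields come through as C1=x, C2=y, C3=z, C5=mass diff,
  # C6=charge code
  charge_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n_atoms)
  charge <- .mdl_charge(as.integer(charge_col))
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(
      a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
      order = as.integer(bb[, 3]))
  }
  # drop explicit hydrogens (OpenBabel occasionally emits them, e.g. for
  # stereo centres); fold them into the heavy-atom H counts
  explicit_h <- which(element == "H")
  extra_h <- integer(n_atoms)
  if (length(explicit_h) > 0) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (a1 %in% explicit_h) extra_h[a2] <- extra_h[a2] + 1L
      if (a2 %in% explicit_h) extra_h[a1] <- extra_h[a1] + 1L
    }
    keep <- setdiff(seq_len(n_atoms), explicit_h)
    remap <- integer(n_atoms); remap[keep] <- seq_along(keep)
    bonds <- bonds[!(bonds$a1 %in% explicit_h) & !(bonds$a2 %in% explicit_h), , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    element <- element[keep]; charge <- charge[keep]; extra_h <- extra_h[keep]
    n_atoms <- length(keep)
  }
  degree <- integer(n_atoms)
  bond_sum <- integer(n_atoms)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      degree[bonds$a1[b]] <- degree[bonds$a1[b]] + 1L
      degree[bonds$a2[b]] <- degree[bonds$a2[b]] + 1L
      bond_sum[bonds$a1[b]] <- bond_sum[bonds$a1[b]] + bonds$order[b]
      bond_sum[bonds$a2[b]] <- bond_sum[bonds$a2[b]] + bonds$order[b]
    }
  }
  n_h <- vapply(seq_len(n_atoms), function(i) {
    .implicit_h(element[i], bond_sum[i], charge[i])
  }, integer(1)) + extra_h
  in_ring <- .ring_atoms(n_atoms, bonds)
  atomic_number <- unname(.element_numbers[element])
  atomic_number[is.na(atomic_number)] <- 0L
  list(
    atoms = data.frame(
      element = element, atomic_number = atomic_number, charge = charge,
      degree = degree, n_h = n_h, in_ring = in_ring),
    bonds = bonds
  )
}

# Ring membership: an atom is in a ring iff it is an endpoint of some
# non-bridge edge of the molecular graph.
.ring_atoms <- function(n_atoms, bonds) {
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds) == 0 || n_atoms < 3) return(in_ring)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  for (b in ring_edges) {
    in_ring[bonds$a1[b]] <- TRUE
    in_ring[bonds$a2[b]] <- TRUE
  }
  in_ring
}

# Adjacency list representation used by the ring-search code.
.adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) adj[[i]] <- integer(0)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
      adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  adj
}
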