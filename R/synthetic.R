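## Synthetic compound-family generator with known ground truth.
##
## Families are built by decorating a shared scaffold with small
## substituents, which mirrors how natural-product families arise as
## variations on a biosynthetic theme: members of a family stay similar
## (Dice at or above the clustering cutoff along a decoration chain)
## while distinct scaffolds stay dissimilar, so the generated family
## partition is exactly recoverable by the similarity network. The
## scaffold library is a hand-curated set of 38 drug-like and
## macrocyclic templates (24-36 heavy atoms), each with three
## substitutable positions, packaged as a versioned TSV fixture.

.default_decorations <- c(methyl = "C", hydroxyl = "O", amino = "N",
                          fluoro = "F", chloro = "Cl", acetyl = "OC(C)=O")

#' Packaged scaffold template library
#'
#' @return A tibble with columns `scaffold_id` and `template`; templates
#'   are SMILES with three substitutable positions written `{1}`, `{2}`,
#'   `{3}`.
#' @export
scaffold_library <- function() {
  path <- system.file("extdata", "scaffold_templates.tsv",
                      package = "npdiversity", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Instantiate a template: decorations is a named character vector mapping
# slot ("1","2","3") to a substituent SMILES fragment; empty slots vanish.
.fill_template <- function(template, decorations = character(0)) {
  for (slot in c("1", "2", "3")) {
    sub <- if (slot %in% names(decorations)) {
      paste0("(", decorations[[slot]], ")")
    } else ""
    template <- gsub(paste0("\\{", slot, "\\}"), sub, template)
  }
  template
}

.decoration_string <- function(decorations) {
  if (length(decorations) == 0) return("")
  ord <- order(names(decorations))
  paste(paste0(names(decorations)[ord], ":", unname(decorations)[ord]),
        collapse = ";")
}

#' Generate one family of structurally related compounds
#'
#' Produces `n_members` distinct valid structures sharing one scaffold.
#' The first member is the bare scaffold; each further member adds one
#' substituent to a previously generated member (up to three occupied
#' positions), so every member is one decoration step away from another —
#' the chain of steps keeps the family connected at the similarity
#' cutoff. With `single_site = TRUE` all members differ only at the first
#' position, which empirically yields a fully interconnected (complete)
#' family.
#'
#' @param template A scaffold template string (see [scaffold_library()]).
#' @param family_id Identifier used as the compound-id prefix.
#' @param n_members Number of members (>= 1).
#' @param decorations Named character vector of substituent fragments
#'   (default: methyl, hydroxyl, amino, fluoro, chloro, acetyl).
#' @param kingdom Origin kingdom label for the family.
#' @param year_range Integer vector `c(min, max)`; member years are drawn
#'   uniformly from this range.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param single_site Restrict decorations to position 1 (see above).
#' @param cutoff Dice cutoff every decoration step must stay above:
#'   candidate members whose fingerprint falls below `cutoff` similarity
#'   to their parent are rejected and redrawn, so the family is connected
#'   at the cutoff by construction (default 0.75).
#' @return A compound tibble with the usual columns plus ground-truth
#'   columns `family_id`, `decorations` (e.g. `"1:C;3:Cl"`) and
#'   `n_decorations`.
#' @export
generate_compound_family <- function(template, family_id, n_members,
                                     decorations = .default_decorations,
                                     kingdom = "bacterium",
                                     year_range = c(1965L, 2024L),
                                     seed = 1L,
                                     single_site = FALSE,
                                     cutoff = 0.75) {
  stopifnot(n_members >= 1, length(decorations) >= 1)
  withr::with_seed(seed, {
    bare <- .fill_template(template)
    bare_can <- ob_canonical_smiles(bare)
    if (is.na(bare_can))
      rlang::abort("scaffold template does not parse")
    specs <- list(character(0))             # member 1: bare scaffold
    bits <- list(.morgan_bits(parse_molecules(bare_can)[[1]]))
    seen <- bare
    attempts <- 0L
    max_attempts <- 200L * n_members
    while (length(specs) < n_members) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        rlang::abort(paste0(
          "decoration set too small to produce ", n_members,
          " distinct members for family ", family_id))
      parent_idx <- sample.int(length(specs), 1)
      parent <- specs[[parent_idx]]
      open <- if (single_site) "1" else c("1", "2", "3")
      open <- setdiff(open, names(parent))
      if (length(open) == 0) next
      slot <- if (length(open) == 1) open else sample(open, 1)
      dec <- decorations[[sample.int(length(decorations), 1)]]
      child <- c(parent, stats::setNames(dec, slot))
      smi <- .fill_template(template, child)
      if (smi %in% seen) next
      can <- ob_canonical_smiles(smi)
      if (is.na(can)) next
      # the decoration step must preserve similarity to the parent, so
      # the family stays connected at the clustering cutoff
      child_bits <- .morgan_bits(parse_molecules(can)[[1]])
      if (dice_similarity(child_bits, bits[[parent_idx]]) < cutoff) next
      seen <- c(seen, smi)
      specs[[length(specs) + 1L]] <- child
      bits[[length(bits) + 1L]] <- child_bits
    }
    smiles <- vapply(specs, function(s) .fill_template(template, s), character(1))
    years <- sample(seq(year_range[1], year_range[2]), n_members, replace = TRUE)
    out <- compound_table(
      data.frame(
        compound_id = paste0(family_id, "_", seq_len(n_members)),
        smiles = smiles),
      id_col = "compound_id", smiles_col = "smiles")
    if (nrow(out) < n_members)
      rlang::abort(paste0("family ", family_id,
                          " produced unparseable structures"))
    out$kingdom <- kingdom
    out$year <- as.integer(years)
    out$family_id <- family_id
    out$decorations <- vapply(specs, .decoration_string, character(1))
    out$n_decorations <- lengths(specs)
    out
  })
}

#' Generate a full synthetic dataset with known ground truth
#'
#' Builds a compound set of structurally separated families plus isolated
#' singletons, with kingdoms and years attached — the desk-scale stand-in
#' for a real natural-product collection. Families use structurally
#' distant scaffolds from [scaffold_library()]; singletons are bare
#' leftover scaffolds. After generation the separation certificate is
#' verified on the actual fingerprints: every family must form a single
#' connected component at `cutoff` and no edge may join different
#' families (or touch a singleton); a violation is an error, never a
#' silent defect. The generated partition is therefore exactly the
#' clustering ground truth.
#'
#' @param n_families Number of families.
#' @param family_sizes Integer vector of family sizes, recycled to
#'   `n_families`; by default sizes are drawn uniformly from 3:8.
#' @param n_singletons Number of planted singleton compounds.
#' @param kingdom_mix Named probabilities over kingdoms for family (and
#'   singleton) origin labels.
#' @param family_purity Probability that a member inherits its family's
#'   kingdom; otherwise a different kingdom is drawn (families are nearly
#'   pure by origin, default 0.95).
#' @param year_range Years of first report are drawn uniformly from this
#'   range (default 1965-2024, spanning six decades).
#' @param cutoff Dice cutoff the certificate is checked at (default 0.75).
#' @param seed Integer seed; the dataset is deterministic per seed.
#' @param single_site Passed to [generate_compound_family()].
#' @return A compound tibble with ground-truth columns `family_id` (`NA`
#'   for singletons), `decorations` and `n_decorations`; generator
#'   parameters are attached as the `"provenance"` attribute.
#' @export
generate_compound_dataset <- function(n_families = 5L,
                                      family_sizes = NULL,
                                      n_singletons = 3L,
                                      kingdom_mix = c(bacterium = 0.55,
                                                      fungus = 0.35,
                                                      other = 0.10),
                                      family_purity = 0.95,
                                      year_range = c(1965L, 2024L),
                                      cutoff = 0.75,
                                      seed = 1L,
                                      single_site = FALSE) {
  lib <- scaffold_library()
  if (n_families + n_singletons > nrow(lib))
    rlang::abort(paste0("scaffold library has ", nrow(lib),
                        " templates; cannot source ", n_families,
                        " families + ", n_singletons, " singletons"))
  pieces <- withr::with_seed(seed, {
    scaffolds <- lib[sample.int(nrow(lib)), ]
    sizes <- if (is.null(family_sizes)) {
      sample(3:8, n_families, replace = TRUE)
    } else rep_len(as.integer(family_sizes), n_families)
    fam_kingdom <- if (n_families > 0)
      sample(names(kingdom_mix), n_families, replace = TRUE,
             prob = kingdom_mix) else character(0)
    fam_seeds <- sample.int(2^20, max(n_families, 1))
    fams <- purrr::map(seq_len(n_families), function(i) {
      fam <- generate_compound_family(
        scaffolds$template[i], family_id = paste0("fam", i),
        n_members = sizes[i], kingdom = fam_kingdom[i],
        year_range = year_range, seed = fam_seeds[i],
        single_site = single_site, cutoff = cutoff)
      impure <- stats::runif(nrow(fam)) > family_purity
      if (any(impure)) {
        others <- setdiff(names(kingdom_mix), fam_kingdom[i])
        if (length(others) > 0)
          fam$kingdom[impure] <- sample(others, sum(impure), replace = TRUE)
      }
      fam
    })
    singles <- if (n_singletons > 0) {
      idx <- n_families + seq_len(n_singletons)
      smi <- vapply(scaffolds$template[idx], .fill_template, character(1))
      s <- compound_table(
        data.frame(compound_id = paste0("single", seq_len(n_singletons)),
                   smiles = unname(smi)))
      s$kingdom <- sample(names(kingdom_mix), n_singletons, replace = TRUE,
                          prob = kingdom_mix)
      s$year <- as.integer(sample(seq(year_range[1], year_range[2]),
                                  n_singletons, replace = TRUE))
      s$family_id <- NA_character_
      s$decorations <- ""
      s$n_decorations <- 0L
      s
    } else NULL
    c(fams, list(singles))
  })
  out <- dplyr::bind_rows(pieces)
  .check_separation(out, cutoff)
  attr(out, "provenance") <- paste0(
    "synthetic: n_families=", n_families, " n_singletons=", n_singletons,
    " seed=", seed, " cutoff=", cutoff)
  attr(out, "rejections") <- tibble::tibble(compound_id = character(0),
                                            reason = character(0))
  out
}

# Separation certificate: families connected at the cutoff, no edge
# across families or touching singletons.
.check_separation <- function(compounds, cutoff) {
  fps <- morgan_fingerprints(compounds)
  edges <- similarity_edges(fps, cutoff = cutoff)
  fam <- stats::setNames(compounds$family_id, compounds$compound_id)
  if (nrow(edges) > 0) {
    fa <- fam[edges$id_a]; fb <- fam[edges$id_b]
    cross <- is.na(fa) | is.na(fb) | fa != fb
    if (any(cross))
      rlang::abort(paste0(
        "separation violated: similarity edge across families (e.g. ",
        edges$id_a[which(cross)[1]], " - ", edges$id_b[which(cross)[1]], ")"))
  }
  for (f in unique(stats::na.omit(compounds$family_id))) {
    ids <- compounds$compound_id[!is.na(compounds$family_id) &
                                   compounds$family_id == f]
    if (length(ids) < 2) next
    sub <- edges[edges$id_a %in% ids & edges$id_b %in% ids, ]
    comp <- connected_components(sub, ids)
    if (max(comp$cluster_id) > 1)
      rlang::abort(paste0("separation violated: family ", f,
                          " is not connected at cutoff ", cutoff))
  }
  invisible(TRUE)
}
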