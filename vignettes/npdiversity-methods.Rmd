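---
title: "Methods: similarity networks for natural-product chemical diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks for natural-product chemical diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npdiversity)
```

## The model

`npdiversity` treats a compound collection as a graph. Each structure is
reduced to a set of hashed circular substructures: for every atom, the
environment within 0, 1 and 2 bonds is summarised into an integer
identifier, and all identifiers are folded modulo the fingerprint length
into a presence/absence bit set (the Morgan/ECFP construction; radius 2
corresponds to ECFP4's diameter of 4). Two compounds are compared with
the Dice coefficient on their bit sets,

$$D(A, B) = \frac{2\,|A \cap B|}{|A| + |B|} \in [0, 1],$$

and an edge is drawn whenever $D \ge 0.75$ (inclusive). Compound
*clusters* are the connected components of this graph — single-linkage
clustering at the cutoff — and compounds with no incident edge are
*singletons*. Everything else the package computes is a statistic of
this object: cluster sizes; the median over a cluster's members of their
within-cluster degree (the "median edge count", which equals size − 1
exactly when the cluster is a complete graph, the signature of a tightly
conserved family); taxonomic purity; rank-similarity profiles; novelty
timelines; and substructure censuses on top of the same parsed
structures.

### Why connected components

The clustering algorithm is deliberately the weakest one consistent with
a thresholded similarity graph: any chain of above-cutoff links merges
two compounds into one cluster. This matches how such networks are
drawn and read in Cytoscape-style figures, keeps the partition uniquely
determined by the edge set (no initialisation, no tie-breaking
heuristics), and makes the dual statement exact: a singleton is
precisely a compound with no neighbour at the cutoff. Community
detection inside large components is out of scope.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 2 | circular-environment radius in bonds |
| `n_bits` | 2048 | hashed fingerprint length (power of two) |
| `cutoff` | 0.75 | Dice threshold for an edge, inclusive |
| `purity_threshold` | 0.95 | fraction of known-kingdom members in the dominant kingdom for a "pure" cluster, inclusive |
| `ring_size` | 16 | macrolactone cycle size, counting both ester atoms |
| `min_class_size` | 3 | members needed for a macrolactone class |
| `top_n` | 500 | depth of rank-similarity profiles |

The fingerprint length is not dictated by the analysis itself; 2048 bits
is the de-facto standard for hashed Morgan fingerprints and is
configurable. Bits are binary, not counts: similarity measures presence
or absence of structural attributes. Atom environments use achiral
invariants (element, heavy-atom degree, attached hydrogens, formal
charge, ring membership); stereochemistry does not enter the bits but
*is* retained in the canonical `structure_key`, so stereoisomers count
as distinct compounds during deduplication — natural-product collections
distinguish stereoisomeric metabolites.

## Interpretation choices

Several quantities admit more than one reasonable reading; the package
fixes one and, where useful, reports the alternative:

* **Median cluster size** is computed over clusters of two or more
  members (clusters in the "two or more compounds" sense); the variant
  including singletons is also emitted (`median_cluster_size_all`).
* **Taxonomic purity** excludes members with unknown kingdom from the
  denominator; clusters that are entirely unknown have `NA` purity and
  never count as pure. Cyanobacteria are mapped to `bacterium`. A
  cluster counts as pure when purity ≥ threshold (inclusive) *and* the
  dominant kingdom is bacterial or fungal.
* **Contemporary singletons** compare a compound only against compounds
  from strictly earlier years: two similar compounds first reported in
  the same year are both contemporary singletons. The inclusive variant
  (`include_same_year = TRUE`) is available but off by default.
* **Cluster numbering** is by decreasing size, ties broken by the
  lexicographically smallest member id. Published cluster indices from
  other tools follow unstated schemes, so clusters should be matched by
  member compounds, never by index.
* **Boundary drop** is the absolute difference between the worst
  in-cluster score and the best out-of-cluster score in a profile; a
  negative value (flagged `inverted`) means a non-member outranks a
  member. No numeric definition of a "steep" drop is imposed.

## Numerical and algorithmic notes

* **Canonicalization.** All structure handling funnels through
  OpenBabel. Input SMILES are canonicalized once; fingerprints and ring
  searches operate on the graph parsed from the canonical form, so
  notational variants of one molecule are bitwise identical everywhere
  downstream. Unparseable SMILES are rejected per record with a logged
  reason, never fatally.
* **Hashing.** Environment identifiers use a polynomial rolling hash
  modulo $2^{31}-1$ computed in doubles (every intermediate < $2^{53}$),
  so bit sets are exactly reproducible across platforms. Hash collisions
  are accepted as inherent to hashed fingerprints.
* **Pairwise engine.** Edges are found with a blocked 0/1-matrix
  cross-product (intersection counts via BLAS), mathematically identical
  to the naive double loop — the test suite and the acceptance script
  assert exact agreement at n = 200 — while scaling to tens of
  thousands of compounds in bounded memory.
* **Dice edge cases.** `dice(∅, ∅)` is defined as 0; it cannot arise for
  a valid molecule (any heavy atom yields at least one bit).
* **Macrolactone search.** A compound matches when some simple cycle of
  exactly `ring_size` atoms contains an ester unit with both the ester
  oxygen and carbonyl carbon in the cycle and the carbonyl oxygen
  exocyclic (ring-internal C=O alone is a ketone, not a lactone; the
  nitrogen analogue is a lactam and does not match). The search
  enumerates cycles through each ester bond by depth-first search with
  breadth-first distance pruning, so macrocycles bridged by smaller
  fused rings — invisible to smallest-set-of-smallest-rings treatments —
  are found, without enumerating the full cycle space. Distinct cycles
  are deduplicated up to rotation and direction; a compound with several
  qualifying cycles counts once, with the multiplicity recorded.
* **PKS counts.** Product counts are exact arbitrary-precision integers
  (base-10⁷ digit vectors; every partial product < $2^{53}$), not
  doubles: $5^{50}$-scale counts overflow doubles long before the chain
  lengths of interest.

## The synthetic generator

The generator emulates the one feature of real collections the analysis
depends on: similarity topology. A *family* is a scaffold plus members
that each add 0–3 small substituents (methyl, hydroxyl, amino, fluoro,
chloro, acetyl) at up to three fixed positions. Members are built
incrementally — each new member adds one substituent to an existing
member, and a candidate is accepted only if its fingerprint stays at or
above the cutoff relative to its parent — so every family is connected
at the cutoff by construction. The 38 packaged scaffold templates
(24–36 heavy atoms: anilides, indoles, quinolones, flavanones,
macrolactones, steroids, glycosides, peptides, anthraquinones, and so
on) were curated so that all pairwise scaffold similarities sit far
below the cutoff (maximum 0.47), giving inter-family separation with a
wide margin. A dataset is families plus bare leftover scaffolds as
planted singletons; after generation a *separation certificate* is
verified on the actual fingerprints (families connected, no cross-family
or singleton edge) and any violation is an error. Cluster recovery on
generated data is therefore an exact test, not a statistical one.

Kingdoms are assigned per family from a configurable mix and inherited
by members with probability `family_purity` (default 0.95 — families are
nearly pure by origin); years are uniform over 1965–2024, spanning six
decades of discovery. With `single_site = TRUE` all members vary at one
position only, which empirically yields fully interconnected (complete)
families — these exercise the median-degree-equals-size-minus-one
signature.

The spec of small substituent operations deliberately excludes
ring-size changes: altering a ring would break the scaffold-sharing
guarantee that keeps intra-family similarity above the cutoff, and the
generator's purpose is exact ground truth, not maximal chemical realism.
The generator likewise makes no attempt to mimic molecular-weight or
logP distributions of real natural products. Consequently, passing
tests demonstrate correctness of the pipeline's graph construction and
statistics — they do not show that any particular real collection is as
cleanly separated as the synthetic one; on real data, families overlap
and cluster boundaries are genuinely fuzzy.

## Problem sizes

The packaged tests and the acceptance script run entirely on generated
data: the standard study dataset is 5 families (sizes 3–8) plus 3
singletons (29 compounds), oracle-equivalence checks use 200 compounds
(19,900 pairs), the novelty-ordering property is checked over 20
independently seeded datasets, and ring enumeration is verified against
an exhaustive cycle oracle on fixtures of ≤ 30 atoms. These sizes keep a
full run in tens of seconds while exercising every code path; the same
functions scale to full collections through the blocked engine.

## Known limitations

* Aromatic systems are compared on their canonical kekulized forms;
  identical molecules always agree, but the bit sets differ from
  toolkits that perceive aromaticity symbolically, so absolute Dice
  values are toolkit-specific (as they always are for hashed
  fingerprints). Conclusions should rest on the cutoff-thresholded
  topology, not on third-decimal score comparisons across toolkits.
* Tautomers and salt forms are taken as drawn; no normalisation is
  attempted beyond canonicalization.
* The macrolactone census is purely structural; it cannot distinguish
  polyketide-derived lactones from other biosynthetic origins.
* Contemporary-singleton rates depend on the year metadata supplied;
  missing years exclude a compound from the timeline (reported, never
  imputed).
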