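---
title: "Quantifying the DNA barcoding gap with K2P distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the DNA barcoding gap with K2P distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

DNA barcoding identifies animal species from a short fragment of the
mitochondrial COI gene (the ~658 bp "barcode" region). The method works
when sequences from conspecific individuals are much more similar to one
another than to sequences from any other species — when there is a
*barcoding gap* between the distributions of intraspecific and
interspecific divergence. `barcodegap` implements the survey-style
analysis used to test this for a taxonomically annotated barcode
alignment (specimens assigned to species, genus and subfamily, as in a
regional inventory of a diverse insect family such as the plant bugs):
pairwise K2P distances, divergence summaries per taxonomic level, a
strict gap statistic, per-species discrimination verdicts, and a
neighbor-joining tree with monophyly queries.

## The distance model

Distances are computed under Kimura's two-parameter (K2P) model, the
de facto standard in barcoding studies. For a pair of aligned
sequences, every site where either sequence carries a gap, an `N`, or an
IUPAC ambiguity code is excluded (*pairwise deletion*: each pair uses
its own set of `L` clean sites). Remaining mismatches are classified as
transitions (A↔G, C↔T) or transversions (all others), giving proportions
`P` and `Q`, and the distance in substitutions per site is

d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)].

Two situations yield no number, and are flagged `NA` rather than
clamped: `L = 0` (nothing to compare) and saturation (either logarithm
argument non-positive). Downstream statistics skip flagged entries and
report how many were skipped. Ambiguity codes are excluded rather than
probabilistically resolved so that a dataset always yields the same
matrix. Complete deletion (dropping dirty columns once, for all pairs)
is available as an option; on indel-free data the two policies
coincide.

Distances are stored as substitutions/site throughout and converted to
percent only at the reporting surface, so rounding never propagates.

## The gap statistic

The package follows the strict "minimal" convention:

* per species, the **maximum** intraspecific distance (defined only for
  species with ≥ 2 specimens — singletons are excluded, not counted as
  zero, since a maximum over no pairs is undefined and zeros would
  deflate the average);
* per species, the **minimum** distance to a congeneric heterospecific
  specimen (defined only when the genus holds ≥ 2 sampled species);
* the **gap ratio** = average of the minima / average of the maxima,
  computed from unrounded means. A ratio of at least 10× is the
  conventional evidence for a usable gap.

This is deliberately conservative: it compares the *worst* intraspecific
spread against the *closest* congeneric neighbour. `levelSummaries()`
complements it with plain mean/min/max over all pairs in each class —
intraspecific, congeneric-interspecific, and interspecific within
subfamily. The within-subfamily class *includes* congeneric pairs (it
is a superset): that is what allows a subfamily's range to reach down
to 0 when two congeners share haplotypes, which a genus-excluded
definition could not reproduce.

Because the gap statistic averages extremes, it is not an unbiased
estimate of the underlying mean divergences: with a handful of
specimens per species the maximum of several noisy ~0.2% estimates sits
above 0.2%, and the minimum over many ~11% congeneric comparisons sits
below 11%. The ratio of averaged extremes therefore runs below the
ratio of the true means. This is a property of the statistic itself —
visible in real surveys, where the average *maximum* intraspecific
distance exceeds the overall intraspecific mean — and it is why
parameter-recovery checks on simulated data compare like against like
(see below).

## Discrimination criteria

"Can the barcode tell this species apart?" has two common readings, and
`assessDiscrimination()` implements both rather than conflating them:

* **nearest-neighbor**: a species fails if any of its specimens has a
  heterospecific specimen at a distance ≤ its nearest conspecific; a
  singleton fails only on a zero-distance heterospecific.
* **local-gap**: a species fails if its maximum intraspecific distance
  reaches its minimum distance to *any* heterospecific specimen.

The default (`"both"`) passes a species only if both hold.
Heterospecifics at distance 0 — shared haplotypes, the classic failure
mode of closely related congeners — fail a species under every
criterion. `failure_partners` names the offending species, so a flagged
trio lists its two partners.

## Neighbor joining

`njTree()` implements neighbor joining in the Studier–Keppler
formulation: repeatedly join the pair minimising
`Q(i,j) = (n−2)·d(i,j) − R(i) − R(j)` (`R` = row sums), with the
standard split formula for branch lengths and
`d(u,k) = (d(i,k)+d(j,k)−d(i,j))/2` for the new node. Choices that the
generic algorithm leaves open are pinned down for reproducibility:

* **Ties** in `Q` go to the smallest index pair in current matrix
  order, so a given matrix always yields the same tree, bit for bit.
* **Negative branch estimates** are clamped to 0 with the deficit moved
  to the sister branch of the same join, preserving the path length
  through the joined pair.
* **Undefined entries** are handled before agglomeration by policy:
  `"drop-specimen"` greedily removes the specimens carrying the most
  undefined pairs (logged), `"strict"` refuses and names the pairs.
* A 2-leaf matrix yields the single edge split at its midpoint; for
  n ≥ 3 the unrooted tree is represented with a trifurcating root node.

On additive (tree-realisable) matrices this recovers the generating
topology and path distances exactly, which the test suite asserts on
random trees of 5–12 leaves. Monophyly queries treat the tree as
unrooted: a label set is monophyletic iff some edge bipartitions the
leaves into exactly that set versus the rest, so answers do not depend
on where the tree happens to be rooted. No bootstrap is computed.

## The synthetic-data generator

`simulateBarcodes()` exists so that every stage of the pipeline can be
exercised, and its statistical behaviour measured, without any external
data. It evolves sequences along a four-level taxonomy tree (root →
subfamily ancestors → genus ancestors → species ancestors → specimens)
under the exact K2P transition-probability matrix, site-independent and
rate-homogeneous, from a uniform-base root — precisely the regime in
which the K2P estimator is consistent, so estimates of simulated pairs
recover their generating path lengths. Every configured divergence is
an expected K2P distance between two nodes of the same level, split
equally across the two connecting branches; intraspecific variation is
a star per species (each specimen on its own branch of half the
intraspecific divergence), the simplest structure for "individuals of a
species" that avoids modelling coalescence.

Defaults describe a realistic regional survey of a diverse family:

| parameter | default | meaning |
|---|---|---|
| `n_subfamilies` | 7 | subfamilies sampled |
| `genera_per_subfamily` | 2–6 | uniform range |
| `species_per_genus` | 2–7 | uniform range (~120–130 species total) |
| `specimens_per_species` | 1–4, probs (.25,.45,.15,.15) | mean 2.2 specimens/species |
| `seq_length` | 658 | COI barcode fragment, sites |
| `kappa` | 2 | transition/transversion rate ratio |
| `intra_divergence` | 0.002 | conspecific specimens (0.2%) |
| `congener_divergence` | 0.11 | congeneric species ancestors (11%) |
| `subfamily_divergence` | 0.19 | genus ancestors within a subfamily |
| `cross_subfamily_divergence` | 0.25 | subfamily ancestors |
| `lumped_trio` | off | plant three haplotype-sharing congeners |
| `lumped_spread` | 0.016 | spread of the lumped trio's specimens |

The specimen-count probabilities are chosen to hit a mean sampling
depth of 2.2 with a realistic share of singletons; a uniform integer
range cannot produce that mean. `cross_subfamily_divergence` and
`lumped_spread` are the two knobs the four-level tree needs beyond the
three within-level divergences: the former places subfamilies a little
above the within-subfamily level, the latter gives the lumped trio the
elevated, overlapping intra/interspecific spread characteristic of a
species complex that barcodes cannot separate (its three species also
share one exact haplotype, so they fail discrimination under every
criterion, deterministically). With `lumped_trio` off, defaults are
ordered well apart, so essentially all simulated species are
discriminated and monophyletic.

What the generator does **not** emulate: codon structure and
third-position rate heterogeneity, base-composition bias, NUMTs,
sequencing error, geographic population structure, and unequal species
ages. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *pipeline*, not that any particular
real fauna has a barcoding gap.

Reproducibility: the dataset is a pure function of the configuration
including its `seed`; the same seed gives a byte-identical FASTA.

## Numerical and interface choices

* Reports carry full-precision values alongside percent strings rounded
  the way barcoding papers print them (one decimal, two where
  conventional), so rounded displays never feed later computation.
* The headline ratio is reported rounded to the nearest integer
  ("about N times") but computed from unrounded means.
* Undefined distances are `NA` everywhere, with counts in logs; no
  sentinel values.
* Taxonomy lives in a TSV separate from the FASTA (the shape of survey
  supplementary tables); a `Genus_species_voucher` header parser is a
  fallback, and the TSV wins on conflict.
* Validation is strict at the boundary: characters outside IUPAC+gap,
  unequal lengths, duplicated IDs, taxonomy joins and hierarchy
  violations all error with the offending IDs named, because silent
  coercion hides data corruption.

## Problem sizes used in the tests

The shipped suite exercises the full default-scale simulation (~300
specimens, 658 sites) once for parameter recovery and once for the
lumped-trio construction, and uses reduced configurations (two
subfamilies, 400 sites) for properties asserted across many seeds;
estimator checks use 200 replicate pairs of 10,000 sites at true
divergence 0.1 and a single 100,000-site branch for the closed-form
transition/transversion expectations. The reproduction of the original
survey's headline numbers additionally requires that survey's alignment
and taxonomy files, which are not shipped; the corresponding test names
the expected drop-in location under `inst/extdata/miridae/`.

## Known limitations

* Only the K2P model is provided (no JC69/TN93/GTR, no Γ rates): the
  goal is the barcoding-survey convention, not model selection.
* The gap ratio compares averaged extremes (see above); treat it as the
  survey statistic it is, not as an estimate of mean-divergence ratio.
* NJ is the only tree method, without bootstrap; the tree supports
  monophyly bookkeeping, not phylogenetic inference claims.
* Discrimination criteria are distance-based; formal species
  delimitation (GMYC, ABGD, PTP) is out of scope.
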