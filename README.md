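# barcodegap

DNA barcoding gap analysis for COI alignments.

`barcodegap` is for taxonomists and molecular ecologists who have a
species-level barcode survey — an aligned set of COI sequences, each
specimen assigned to a species, genus and subfamily — and want to know
whether the barcode actually separates the species sampled. It
implements the standard survey workflow: Kimura 2-parameter (K2P)
pairwise distances, divergence summaries per taxonomic level, the
barcoding-gap statistic, per-species discrimination verdicts, and a
neighbor-joining (NJ) tree with monophyly bookkeeping. A built-in K2P
substitution-process simulator generates taxonomy-structured synthetic
datasets, so the whole pipeline is testable and calibratable without
any external data.

## The statistics

For sequences compared over the `L` sites where both carry an
unambiguous base, with transition proportion `P` (A↔G, C↔T) and
transversion proportion `Q`, the K2P distance is

    d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]

Saturated or empty comparisons are flagged `NA`, never clamped.

The barcoding gap is quantified strictly: per species the **maximum**
intraspecific distance, per species the **minimum** distance to a
congeneric heterospecific specimen, and the gap ratio

    gap_ratio = mean(min interspecific of congeners) / mean(max intraspecific)

with ≥ 10× as the conventional criterion for a usable gap. Species
discrimination is assessed per species by a nearest-neighbor criterion,
a local-gap criterion, or (default) both; heterospecific specimens at
distance 0 — shared haplotypes — always fail.

## Worked example

Simulate a survey-scale dataset — about 120–140 species in 7
subfamilies at a mean of 2.2 specimens per species, 0.2% intraspecific
and 11% congeneric divergence — including a "lumped trio" of congeneric
species sharing a haplotype, then run the analysis:

```r
library(barcodegap)

sim <- simulateBarcodes(simulationConfig(lumped_trio = TRUE, seed = 42))
sim$alignment
#> BarcodeAlignment: 304 specimens x 658 sites
#>   136 species, 30 genera, 7 subfamilies
#>   specimens: Genus001_sp001_01, Genus001_sp001_02, Genus001_sp001_03, ...

d <- k2pDistanceMatrix(sim$alignment)
barcodingGapReport(speciesGapTable(d, sim$alignment, criterion = NULL))
#> Barcoding gap report
#>   avg max intraspecific distance:        0.2%  (108 species)
#>   avg min congeneric interspecific dist: 10.1%  (136 species)
#>   gap ratio: 44.3 (about 44 times)  [>= 10: yes]

disc <- assessDiscrimination(d, sim$alignment)
subset(disc, !discriminated)
#>           species n_specimens discriminated              failure_partners
#> 65 Genus016 sp065           2         FALSE Genus016 sp066,Genus016 sp067
#> 66 Genus016 sp066           1         FALSE Genus016 sp065,Genus016 sp067
#> 67 Genus016 sp067           2         FALSE Genus016 sp065,Genus016 sp066
```

The report reads: across the 108 species with ≥ 2 specimens, the worst
intraspecific divergence averages 0.2%; across all 136 species the
closest congeneric neighbour averages 10.1%; the interspecific average
is about 44 times the intraspecific one, a clear barcoding gap. The
discrimination table flags exactly the three planted haplotype-sharing
species, each naming the other two as its failure partners — the
pattern a real species complex leaves in a survey. The NJ tree
(`njTree(d)`) and `taxonMonophylyTable()` show the same three species
as the only non-monophyletic ones.

Real data enter through `readBarcodeAlignment("alignment.fasta",
"taxonomy.tsv")` (taxonomy TSV columns: `specimen_id`, `species`,
`genus`, `subfamily`), and `runBarcodePipeline()` writes the full
artifact set (distance matrix, per-species gap table, gap report JSON,
level summaries, discrimination table, Newick tree, monophyly table,
run log) in one call. A thin CLI wrapper is installed at
`exec/barcode-gap` (`barcode-gap run --fasta F --taxonomy T --out DIR`;
`barcode-gap simulate --seed N --out DIR`).

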