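# barcodelim

Species delimitation and barcoding-gap analytics for COI DNA-barcode
reference libraries.

Reference libraries couple a ~651-bp fragment of mitochondrial COI per
specimen with a morphological species label. Taxonomists and molecular
ecologists use them to ask whether molecular lineages match described
species — or reveal cryptic, lumped or misidentified taxa — and whether a
*barcoding gap* separates the largest within-species distances from the
smallest between-species distances, the condition for reliable molecular
identification. `barcodelim` implements that analysis chain end to end,
with a coalescent simulator providing ground-truth benchmarks so every
stage is testable offline.

## What it computes

* **QC**: ungapped-length filtering, a vertebrate-mitochondrial
  stop-codon screen over all three forward frames (TAA/TAG/AGA/AGG), and
  exact-match haplotype collapsing.
* **K2P distances** with pairwise deletion:
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` for transition and
  transversion proportions P and Q over jointly unambiguous sites; plus
  per-group maximum-intraspecific and nearest-neighbor distances.
* **Trees**: Saitou–Nei neighbor joining, UPGMA chronograms, outgroup
  rooting, strict-clock time scaling (default 1.2% divergence/My).
* **Species delimitation**, four families:
  single-linkage threshold clustering at 2.2% (RESL-like), recursive
  barcode-gap discovery over a geometric prior ladder (ABGD-style),
  Poisson tree processes on substitution trees (PTP single- and
  multi-rate), and the generalized mixed Yule-coalescent on chronograms
  (GMYC single- and multiple-threshold), with likelihood-ratio testing.
* **Consensus**: pairwise co-assignment frequencies across methods,
  merged at a 50% quorum, with transitive merges reported.
* **Gap analytics**: per-group overlap flags, both definitions of the
  "nearest-neighbor is X-fold higher than max-intraspecific" summary, 1%
  histograms, and the table of species split into multiple OTUs.
* **Simulation**: Yule species tree + within-species Kingman coalescent +
  K80 sequence evolution (optionally ORF-preserving), returning a library
  with its true partition.

## Worked example

```r
library(barcodelim)

bm  <- make_benchmark(seed = 7)          # 10 species x 10 specimens, 651 bp
bm$library
#> barcode_library: 100 records, 651 aligned sites, 10 species labels

res <- run_pipeline(library = bm$library, seed = 7)
res
#> pipeline_result: 100 records, 42 haplotypes
#>   OTU counts:
#>     resl_like  10
#>     abgd       10
#>     ptp        15
#>     mptp       15
#>     gmyc       10
#>     mgmyc      10
#>     consensus  10

res$gap_otu
#> gap_stats [otu]: 10 groups; nn/max-intra ratio of means 10.2 (mean of ratios 18.5); overlap: FALSE
```

The 100 simulated records collapse to 42 unique haplotypes. Four of the
six methods recover the 10 true species exactly; PTP and its multi-rate
variant oversplit the noisy NJ tree into 15 lineages, and the 50%
consensus across all six restores the true 10 — the usual argument for
combining delimitation methods. At the OTU level the nearest-neighbor
distances average 10.2-fold higher than the maximum intraspecific
distances with no per-group overlap: a clean barcoding gap, as built into
the simulation.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate → QC → distances/trees → delimit → consensus/gap),
writing tables and newick files under `results/`.

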