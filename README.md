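# bindmode

Classifying and characterising the two binding modes of a transcription
factor that shares its DNA recognition motif with a paralogue.

## The problem

ETS-family transcription factors all recognise GGA(A/T)-core motifs, so a
ChIP peak for one family member (here the ternary complex factor **ELK1**)
may sit on a site that a divergent family member (here **GABPA**) can also
occupy. Partitioning a focal factor's high-confidence peaks into
**"unique"** regions (no comparator overlap) and **"redundant"** regions
(overlapped by a comparator peak) turns out to split the binding landscape
into two mechanistically distinct regimes. `bindmode` implements that
analysis end to end:

- **Confidence calling** — replicate-2 peaks overlapped by replicate-1
  peaks, both filtered at FDR < 10%, define the high-confidence set.
- **Binding-mode classification** — a region is *redundant* iff it shares
  ≥ 1 bp with any comparator region, else *unique*.
- **TSS geometry** — summit-anchored nearest-TSS assignment; proximal
  fraction within ±2 kb; promoter / gene-body / downstream / intergenic
  distribution against a random baseline.
- **Motif content** — degenerate IUPAC word scanning on both strands;
  non-overlapping counts of the three hexamer derivatives of the strong
  (`CCGGAAGT`) and variant (`CAGGATGT`) ETS octamers (greedy left-to-right
  selection, which is optimal for equal-length footprints); SRF CArG
  (`CCWWWWWWGG`) and AP1 (`TGANTCA`) word rates; and composite
  **ETS–SRF modules**: an ETS and an SRF site whose centres both lie
  within 100 bp of the peak summit and less than 50 bp apart.
- **Expression response** — probeset collapsing (background filter,
  opposite-direction exclusion, largest-change selection), batch-paired
  t-tests with BH adjustment over the 2×2 knockdown × EGF-stimulus
  design, p < 0.05 & q < 0.1 regulated lists, z-transformed 4-condition
  profiles, and k-means clustering with k = 8.
- **Association statistics** — uncorrected 2×2 chi-square (Fisher's exact
  for sparse tables), Monte-Carlo gene-list overlap z-scores against
  10,000 random background lists, per-chromosome region-overlap
  permutation tests, and hypergeometric gene-set enrichment from GMT
  files.

A first-class **synthetic-data generator** (`simulateBundle`) emulates the
statistical structure of such a study — two peak classes with distinct
motif content and TSS geometry, comparator overlap confined to one class,
and 8 archetype expression responses with class-specific membership — so
the whole pipeline is testable without any external data.

## Worked example

```r
library(bindmode)

cfg    <- simConfig(seed = 1)        # 303 unique + 226 redundant regions
bundle <- simulateBundle(cfg)
report <- reportResults(runAll(bundle))

report$modes$counts
#> modes
#>    unique redundant
#>       243       183
report$modes$truthAccuracy
#> [1] 1
round(c(unique    = report$tss$unique$fractionWithin,
        redundant = report$tss$redundant$fractionWithin), 2)
#>    unique redundant
#>      0.24      0.94
round(report$motifRates$srf, 2)
#>    unique redundant
#>      0.52      0.31
report$overlapZ$any$z
#> [1] 19.24905
```

The 426 high-confidence regions (of 529 planted; the rest fall to the FDR
filter or replicate dropout) all recover their planted binding-mode
label; the
redundant class is promoter-proximal (94% within 2 kb vs 24% for unique),
carries SRF words at roughly half the unique-class rate, and the overlap
between bound genes and knockdown-regulated genes is ~19 background SDs
above chance. `report$clusters` holds the k-means assignment and its
per-cluster mode association; `report$directionMode` shows that uniquely
bound targets are predominantly down-regulated by knockdown while
redundantly bound targets go up. (Counts printed here are for seed 1;
other seeds differ slightly through replicate dropout and the FDR filter.)

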