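---
title: "Unique vs redundant transcription factor binding: models and methods"
author: "bindmode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unique vs redundant transcription factor binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
```

## The scientific question

Members of multi-gene transcription factor families share closely related
DNA-binding domains. For the ETS family (28 human members recognising a
GGA(A/T) core) a ChIP peak for one member does not imply that the site is
functionally specific to it: a divergent paralogue may occupy the same
region. `bindmode` operationalises the distinction by overlap with a
second factor's peak set: a high-confidence focal peak is **redundant**
when any comparator peak shares at least one base pair with it, and
**unique** otherwise. The package then asks whether the two classes
differ in promoter geometry, motif grammar, partner-factor co-occurrence,
and in the expression response of their target genes to knockdown of the
focal factor.

## Peak-level model

**Confidence calling.** Both replicate peak lists are filtered to
FDR < 10% (MACS-style FDR stored as a percent). The high-confidence set
is the replicate-2 regions overlapped by at least one replicate-1 region;
replicate-2 regions without a partner are low-confidence. Replicate-2
coordinates are retained (not the intersection interval), because the
replicate with the more stringent peak statistics defines the region
boundaries. The FDR filter precedes intersection — each list is filtered
on its own — which is the reading that treats the two replicates
symmetrically.

**Coordinates.** Internally everything is 1-based closed (`GRanges`);
narrowPeak I/O converts from the 0-based half-open BED convention, with
the summit as a 0-based offset in field 10. All distance rules are
anchored at the summit, the single-base position of maximal read pile-up.

**Nearest-TSS assignment.** Each summit is assigned to the gene whose TSS
minimises the absolute distance on the same chromosome; the signed
distance is negative when the summit lies 5' of the TSS in gene
orientation. Equidistant ties go to the smaller TSS coordinate, then to
the lexicographically smaller symbol, so assignment is deterministic.
Peaks on gene-free chromosomes are flagged, not dropped.

**Genomic distribution.** Summits are categorised with the precedence
promoter (≤ 10 kb upstream of any TSS) > gene body ([TSS, TTS]) >
downstream (≤ 10 kb past the TTS) > intergenic, and compared with a
seeded uniform-random baseline of the same size. Finer categories (UTRs,
individual exons) are deliberately out of scope.

**Region-overlap permutation test.** With set A fixed, every set B region
is re-placed uniformly at random within its own chromosome (lengths and
per-chromosome counts preserved — each chromosome is its own bin). The
statistic is the number of A regions overlapped; the one-sided empirical
p-value is `(1 + #{perm >= obs}) / (nPerm + 1)`, so it is never zero.

## Motif grammar

**Word scanning.** Motifs are degenerate IUPAC words, not weight
matrices: scanning is exact-set matching, reported on both strands with
minus-strand hits given forward-strand footprints. A hit of a palindromic
word at the same footprint on both strands is a single genomic event and
is collapsed to one `+` hit. Matching is delegated to Biostrings; the
test suite holds an independent position-by-position matcher that the
implementation must reproduce exactly.

**Hexamer-derivative counting.** An octamer consensus contributes its
three hexamer substrings; all (possibly overlapping) hits of the three
derivatives are collected on both strands and a maximum set of mutually
non-overlapping footprints is selected greedily left-to-right (ties: `+`
strand first). For equal-length intervals greedy-by-start is provably
optimal, and the suite cross-checks it against exhaustive
maximum-independent-set enumeration. Cross-strand overlap blocks
selection: a site is a genomic footprint, not a strand-specific event.
The background score uses the *reversed* motif string (`TGAAGGCC` for
`CCGGAAGT`) — the reverse complement would be redundant with both-strand
scanning, so the reversed word is the only distinct background of the
same composition.

**ETS–SRF modules.** A module is an (ETS, SRF) site pair with both motif
centres within 100 bp of the peak summit and centre-to-centre distance
strictly below 50 bp. Distances are measured centre-to-centre (footprint
midpoints); the boundaries are ≤ 100 and < 50 exactly. The ETS site
defaults to the union of the derivative hexamers of the strong and
variant octamers; the SRF site is the CArG word `CCWWWWWWGG`. No
published matrix for the SRF partner is assumed — the IUPAC CArG box is
the configurable stand-in.

## Expression model

The design is 2×2 (control vs knockdown × 0 vs 30 min EGF) with at least
two batch-paired replicates per cell, signals on the log10 scale.

**Probeset collapsing**, in order: (1) probesets at or below the
background level in the EGF-treated control samples are discarded; the
background level defaults to the 2.5th percentile of all signals, since
no absolute chip background is available, and is overridable; (2) genes
with two significant probesets (paired knockdown-contrast t-test,
p < 0.05) changing in opposite directions are excluded; (3) of the
remaining probesets per gene, the one with the largest absolute knockdown
effect is kept.

**Differential response.** Per gene and contrast (knockdown effect at
0 min, at 30 min, and the stimulus effect in control cells) a paired
t-test across batches, BH-adjusted across genes. This is a transparent
stand-in for a moderated linear model: with thousands of genes and few
replicates, empirical-Bayes shrinkage would gain power, but the paired
t-test is exact, dependency-free and easy to verify against the
noncentral-t closed form, which the test suite does. The substitution is
recorded in the result's `method` attribute. Regulated genes satisfy
p < 0.05 *and* q < 0.1.

**Profiles and clustering.** Per gene the four condition means are
z-scored (mean 0, unit sample (n−1) SD; all-equal profiles excluded), so
clustering sees response *shape*, not magnitude. Condition means — not
replicate-level values — enter the transform; the replicate dimension is
noise here, not signal. K-means with k = 8 runs with 20 seeded random
restarts keeping the lowest within-cluster sum of squares
(`stats::kmeans`, Hartigan–Wong). A k-means++ initialisation would be an
alternative; with 20 restarts on 4-dimensional z-profiles the choice of
initialiser is immaterial and the standard R implementation is preferred.
Cluster display order comes from average-linkage hierarchical clustering
of the cluster means.

**Association.** Cluster-vs-mode and direction-vs-mode 2×2 tables use the
uncorrected Pearson chi-square, switching to Fisher's exact test when any
expected cell is below 5. The gene-list overlap z-score compares the
observed overlap with the mean and SD of overlaps of 10,000 random lists
of the same size drawn uniformly without replacement from the gene
universe; its background moments converge to the hypergeometric closed
form, which the suite verifies. Gene-set enrichment is a plain upper-tail
hypergeometric test over user-supplied GMT categories (no GO-DAG
propagation), with raw and BH-adjusted p-values both reported.

## The synthetic-data generator

`simulateBundle` produces the full input bundle — genome, TSS table, two
focal replicates, comparator and co-factor peaks, probeset matrix, gene
sets, and the generating truth. Its defaults *are* the study conditions:

| parameter | default | meaning |
|---|---|---|
| `nUnique` / `nRedundant` | 303 / 226 | regions per binding class |
| `regionLength` | 400 bp | peak width |
| `fracUniqueProximal` / `fracRedundantProximal` | 0.26 / 0.93 | summits within 2 kb of the TSS |
| `uniqueSiteCountDist` | mode 1 | planted strong-ETS sites per unique region |
| `redundantSiteCountDist` | mode 3 | per redundant region |
| `srfRateUnique` / `srfRateRedundant` | 0.54 / 0.27 | CArG word rates |
| `moduleRateUnique` / `moduleRateRedundant` | 0.30 / 0.05 | ETS–SRF module rates |
| `nReps` | 3 | batch-paired replicates per condition |
| `noiseSd` | 0.10 | per-measurement noise, log10 units |
| `archetypeAmplitude` | 0.4 | response amplitude (~2.5-fold) |

Genome and sizing defaults (4 × 2 Mb, 1200 genes) are chosen so genes are
tiled densely enough for a realistic promoter landscape yet far enough
apart (≥ ~5 kb) that each region's nearest gene is unambiguous and
regions attached to different genes can never collide — which is what
makes the planted binding-mode labels exactly recoverable and the
module/SRF rates interpretable. Rates not printed anywhere (module, AP1
and co-factor overlap rates, replicate jitter and dropout, the
below-background and opposite-pair probeset fractions) are fixed once at
values a ChIP-seq/array practitioner would consider realistic and are
documented in `?simConfig`.

**Expression archetypes.** The 8 archetypes are the sign combinations of
three orthogonal contrasts over the four conditions — knockdown main
effect, stimulus main effect, interaction — scaled by the amplitude.
After the z-transform they sit exactly on 8 points at pairwise Euclidean
distance 2, so cluster recovery is identifiable and its failure would
indicate a pipeline defect rather than an unlucky geometry. Archetypes
1–4 (knockdown-down: the factor activates) are preferentially assigned to
unique-bound genes via archetypes 2/4; archetypes 7/8 (knockdown-up) to
redundant-bound genes, with enrichment probability 0.8. This plants the
cluster↔mode and direction↔mode couplings the association stages must
detect.

**What the generator does not emulate.** Background sequence is i.i.d.
uniform: chance motif hits occur at their combinatorial rate and are
*not* suppressed, so measured rates sit slightly above planted rates;
tests needing exact counts rebuild sequence from the planted-site ledger.
There is no read-level noise, mappability structure, GC bias, copy-number
variation, probe-sequence effect or array normalisation artefact.
Passing tests therefore demonstrate the correctness of the analysis
logic under the planted statistical structure — not robustness to the
full failure modes of real ChIP-seq and microarray data.

## Numerical and design choices

- **Chi-square without continuity correction** is the default: on the
  region-scale tables this is the conventional choice, and the corrected
  statistic is available via `correct = TRUE`.
- **Overlap criterion** is ≥ 1 shared bp, configurable
  (`minOverlapBp`), since interval-overlap tools differ in their minimum
  overlap conventions.
- **Nearest-gene ties** break to the smaller coordinate; **greedy ties**
  at equal footprint start to the `+` strand — both documented,
  deterministic rules.
- **Empty k-means clusters** cannot be returned: a failing start is
  re-drawn (up to 5 re-seeds) within the seeded stream.
- **Seeding.** A single global seed fans out to per-stage seeds by stable
  hashing of stage names (`stageSeed`), so each stage is independently
  reproducible and inserting a stage does not shift the others' streams.
  All derived seeds stay below 2^31.
- **Degenerate inputs.** Zero-margin tables raise errors (chi-square) or
  return p = 1 (Fisher); a zero-variance gene is flagged and excluded
  from ranking; a zero-SD background in the overlap z is flagged
  `degenerate` with `z = NA`.
- **Problem sizes.** The packaged tests run the full pipeline at the
  default study scale (529 regions, 1200 genes, 8 Mb genome), 25-seed
  cluster-recovery simulations, 50-seed null calibrations, and exhaustive
  small-table enumeration for Fisher's test — sizes chosen so the whole
  suite completes in minutes on a laptop while keeping every Monte-Carlo
  interval tight enough to be informative.

## Known limitations

- The unique/redundant split is a binary overlap call; partial or
  condition-dependent co-occupancy is not modelled.
- IUPAC words cannot express position-specific affinities; weight-matrix
  scoring is intentionally out of scope.
- The paired t-test underpowers short designs relative to moderated
  models (the 3-pair knockdown contrast detects a 0.3 log10 effect with
  probability ≈ 0.5, per the noncentral-t closed form; the power of the
  planted 2×amplitude contrast effects is ≈ 0.95).
- The gene universe is the annotation's gene set; selection effects from
  array coverage are not represented.
- `runAll` analyses one comparator and one co-factor at a time;
  multi-factor joint models are not attempted.
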