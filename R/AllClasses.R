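#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo
#'   seqinfo<- Seqinfo
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic binding-mode study
#'
#' Holds every parameter of the synthetic-data generator: genome and
#' annotation sizing, the two peak classes and their TSS geometry, the
#' planted motif content, replicate behaviour, and the knockdown-by-stimulus
#' expression design. Defaults encode the statistical structure of the kind
#' of ChIP-seq / microarray study the pipeline analyses: 303 "unique" and
#' 226 "redundant" regions; 26\% vs 93\% of summits within 2 kb of a TSS;
#' strong (\code{CCGGAAGT}) and variant (\code{CAGGATGT}) ETS octamers with
#' per-region site-count distributions peaking at 1 (unique) and 3
#' (redundant); SRF CArG-box rates of 54\% vs 27\%; an 8-archetype
#' expression response over the 2x2 (knockdown x EGF-stimulus) design with
#' 3 batch-paired replicates per condition.
#'
#' Slots are documented by \code{\link{simConfig}}, the user-facing
#' constructor, which validates every field.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateBundle}}
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChrom = "integer", chromLength = "integer", nGenes = "integer",
  nUnique = "integer", nRedundant = "integer", regionLength = "integer",
  fracUniqueProximal = "numeric", fracRedundantProximal = "numeric",
  proximalWindow = "integer",
  etsStrongOctamer = "character", etsVariantOctamer = "character",
  srfPattern = "character", ap1Pattern = "character",
  uniqueSiteCountDist = "numeric", redundantSiteCountDist = "numeric",
  variantOnlyFracUnique = "numeric",
  srfRateUnique = "numeric", srfRateRedundant = "numeric",
  moduleRateUnique = "numeric", moduleRateRedundant = "numeric",
  ap1RateUnique = "numeric", ap1RateRedundant = "numeric",
  cofactor = "logical",
  fosRateUnique = "numeric", fosRateRedundant = "numeric",
  replicateJitterSd = "numeric", replicateDropout = "numeric",
  fdrExceedFrac = "numeric",
  nReps = "integer", noiseSd = "numeric", batchSd = "numeric",
  archetypeAmplitude = "numeric", clusterEnrichment = "numeric",
  fracResponsiveUnbound = "numeric",
  multiProbesetFrac = "numeric", oppositePairFrac = "numeric",
  belowBackgroundFrac = "numeric",
  baselineMean = "numeric", baselineSd = "numeric",
  backgroundSignal = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  props <- c("fracUniqueProximal", "fracRedundantProximal",
             "variantOnlyFracUnique", "srfRateUnique", "srfRateRedundant",
             "moduleRateUnique", "moduleRateRedundant", "ap1RateUnique",
             "ap1RateRedundant", "fosRateUnique", "fosRateRedundant",
             "replicateDropout", "fdrExceedFrac", "clusterEnrichment",
             "fracResponsiveUnbound", "multiProbesetFrac",
             "oppositePairFrac", "belowBackgroundFrac")
  for (p in props) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, paste0(p, " must lie in [0, 1]"))
  }
  if (object@regionLength >= object@chromLength)
    msg <- c(msg, "regionLength must be smaller than chromLength")
  for (d in c("uniqueSiteCountDist", "redundantSiteCountDist")) {
    v <- slot(object, d)
    if (is.null(names(v)) || any(is.na(suppressWarnings(as.integer(names(v))))))
      msg <- c(msg, paste0(d, " must be named by integer site counts"))
    else if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
      msg <- c(msg, paste0(d, " probabilities must be >= 0 and sum to 1"))
  }
  if (object@moduleRateUnique > object@srfRateUnique ||
      object@moduleRateRedundant > object@srfRateRedundant)
    msg <- c(msg, "module rate cannot exceed the SRF rate of its class")
  if (object@nReps < 2L)
    msg <- c(msg, "nReps must be >= 2 (paired design)")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-study configuration
#'
#' @param seed Integer seed controlling every random draw of the generator.
#' @param nChrom,chromLength Number and length (bp) of synthetic chromosomes.
#' @param nGenes Number of genes tiled across the genome (the gene universe).
#' @param nUnique,nRedundant Number of focal-factor regions of each binding
#'   class. Defaults 303 / 226.
#' @param regionLength Peak region length in bp (default 400).
#' @param fracUniqueProximal,fracRedundantProximal Probability that a region
#'   summit of each class is placed within \code{proximalWindow} of its
#'   gene's TSS (defaults 0.26 / 0.93).
#' @param proximalWindow Promoter-proximal window in bp (default 2000).
#' @param etsStrongOctamer,etsVariantOctamer Strong and variant ETS octamer
#'   consensus planted in regions.
#' @param srfPattern IUPAC CArG-box word planted for SRF (default
#'   \code{CCWWWWWWGG}).
#' @param ap1Pattern IUPAC AP1 word (default \code{TGANTCA}).
#' @param uniqueSiteCountDist,redundantSiteCountDist Named probability
#'   vectors over per-region planted ETS site counts; names are counts.
#'   Defaults peak at 1 (unique) and 3 (redundant).
#' @param variantOnlyFracUnique Fraction of unique regions whose ETS sites
#'   are drawn from the variant octamer only.
#' @param srfRateUnique,srfRateRedundant Per-class probability that a region
#'   carries a CArG box (defaults 0.54 / 0.27).
#' @param moduleRateUnique,moduleRateRedundant Per-class probability that a
#'   region carries an ETS--SRF module satisfying the 100 bp summit /
#'   50 bp pair constraints. Must not exceed the class SRF rate.
#' @param ap1RateUnique,ap1RateRedundant Per-class AP1 word rates.
#' @param cofactor Generate a co-factor (FOS-like) peak set?
#' @param fosRateUnique,fosRateRedundant Per-class probability that a region
#'   is overlapped by a co-factor peak.
#' @param replicateJitterSd SD (bp) of the coordinate jitter applied to
#'   replicate-1 regions.
#' @param replicateDropout Fraction of regions present in only one replicate.
#' @param fdrExceedFrac Fraction of regions given an FDR above the 10\%
#'   retention cut-off.
#' @param nReps Replicates (batches) per condition of the 2x2 design.
#' @param noiseSd Per-measurement noise SD (log10 signal units).
#' @param batchSd SD of the batch offset shared by all samples of one batch.
#' @param archetypeAmplitude Amplitude (log10 units) of the archetype
#'   response profiles (default 0.4, about 2.5-fold).
#' @param clusterEnrichment Probability that a bound gene is assigned to one
#'   of its class's preferred archetypes (unique: 2/4; redundant: 7/8).
#' @param fracResponsiveUnbound Fraction of unbound genes given a (random)
#'   archetype response.
#' @param multiProbesetFrac Fraction of responsive genes carrying a second,
#'   weaker probeset (exercises the largest-change collapsing rule).
#' @param oppositePairFrac Fraction of responsive unbound genes given an
#'   opposite-direction probeset pair (exercises the exclusion rule).
#' @param belowBackgroundFrac Fraction of genes given an extra probeset
#'   below the background signal level.
#' @param baselineMean,baselineSd Mean and SD of per-gene baseline log10
#'   signal.
#' @param backgroundSignal Signal level of below-background probesets.
#' @return A validated \code{\link{SimConfig}} object.
#' @examples
#' cfg <- simConfig(seed = 1, nUnique = 50, nRedundant = 40)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 4L, chromLength = 2000000L, nGenes = 1200L,
                      nUnique = 303L, nRedundant = 226L, regionLength = 400L,
                      fracUniqueProximal = 0.26, fracRedundantProximal = 0.93,
                      proximalWindow = 2000L,
                      etsStrongOctamer = "CCGGAAGT",
                      etsVariantOctamer = "CAGGATGT",
                      srfPattern = "CCWWWWWWGG", ap1Pattern = "TGANTCA",
                      uniqueSiteCountDist =
                        c("1" = 0.80, "2" = 0.15, "3" = 0.05),
                      redundantSiteCountDist =
                        c("2" = 0.15, "3" = 0.65, "4" = 0.15, "5" = 0.05),
                      variantOnlyFracUnique = 0.25,
                      srfRateUnique = 0.54, srfRateRedundant = 0.27,
                      moduleRateUnique = 0.30, moduleRateRedundant = 0.05,
                      ap1RateUnique = 0.45, ap1RateRedundant = 0.20,
                      cofactor = TRUE,
                      fosRateUnique = 0.25, fosRateRedundant = 0.08,
                      replicateJitterSd = 30, replicateDropout = 0.10,
                      fdrExceedFrac = 0.10,
                      nReps = 3L, noiseSd = 0.10, batchSd = 0.05,
                      archetypeAmplitude = 0.4, clusterEnrichment = 0.8,
                      fracResponsiveUnbound = 0.3,
                      multiProbesetFrac = 0.10, oppositePairFrac = 0.02,
                      belowBackgroundFrac = 0.05,
                      baselineMean = 3, baselineSd = 0.3,
                      backgroundSignal = 0.8) {
  assertDna(etsStrongOctamer, "etsStrongOctamer")
  assertDna(etsVariantOctamer, "etsVariantOctamer")
  assertDna(srfPattern, "srfPattern")
  assertDna(ap1Pattern, "ap1Pattern")
  new("SimConfig",
      seed = assertCount(seed, "seed"),
      nChrom = assertCount(nChrom, "nChrom", 1L),
      chromLength = assertCount(chromLength, "chromLength", 1000L),
      nGenes = assertCount(nGenes, "nGenes", 1L),
      nUnique = assertCount(nUnique, "nUnique"),
      nRedundant = assertCount(nRedundant, "nRedundant"),
      regionLength = assertCount(regionLength, "regionLength", 50L),
      fracUniqueProximal = fracUniqueProximal,
      fracRedundantProximal = fracRedundantProximal,
      proximalWindow = assertCount(proximalWindow, "proximalWindow", 1L),
      etsStrongOctamer = etsStrongOctamer,
      etsVariantOctamer = etsVariantOctamer,
      srfPattern = srfPattern, ap1Pattern = ap1Pattern,
      uniqueSiteCountDist = uniqueSiteCountDist,
      redundantSiteCountDist = redundantSiteCountDist,
      variantOnlyFracUnique = variantOnlyFracUnique,
      srfRateUnique = srfRateUnique, srfRateRedundant = srfRateRedundant,
      moduleRateUnique = moduleRateUnique,
      moduleRateRedundant = moduleRateRedundant,
      ap1RateUnique = ap1RateUnique, ap1RateRedundant = ap1RateRedundant,
      cofactor = isTRUE(cofactor),
      fosRateUnique = fosRateUnique, fosRateRedundant = fosRateRedundant,
      replicateJitterSd = replicateJitterSd,
      replicateDropout = replicateDropout,
      fdrExceedFrac = fdrExceedFrac,
      nReps = assertCount(nReps, "nReps", 2L),
      noiseSd = noiseSd, batchSd = batchSd,
      archetypeAmplitude = archetypeAmplitude,
      clusterEnrichment = clusterEnrichment,
      fracResponsiveUnbound = fracResponsiveUnbound,
      multiProbesetFrac = multiProbesetFrac,
      oppositePairFrac = oppositePairFrac,
      belowBackgroundFrac = belowBackgroundFrac,
      baselineMean = baselineMean, baselineSd = baselineSd,
      backgroundSignal = backgroundSignal)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@nChrom, " x ", object@chromLength, " bp, ",
      object@nGenes, " genes\n", sep = "")
  cat("  regions: ", object@nUnique, " unique + ", object@nRedundant,
      " redundant, ", object@regionLength, " bp\n", sep = "")
  cat("  proximal (", object@proximalWindow, " bp): ",
      object@fracUniqueProximal, " / ", object@fracRedundantProximal,
      "  SRF: ", object@srfRateUnique, " / ", object@srfRateRedundant,
      "\n", sep = "")
  cat("  expression: ", object@nReps, " reps/condition, noise sd ",
      object@noiseSd, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PeakSet
## ---------------------------------------------------------------------------

#' A set of ChIP-seq peak regions
#'
#' Wraps a \code{\link[GenomicRanges]{GRanges}} whose metadata columns carry
#' the MACS-style per-peak annotations used throughout the pipeline:
#' \code{summit} (absolute 1-based position of the read pile-up maximum),
#' \code{score} (integer pseudo tag-count) and \code{fdrPct} (false
#' discovery rate as a percent in [0, 100]). Regions are kept sorted by
#' (chromosome, start) and are named by a stable region identifier.
#'
#' Coordinates are 1-based closed internally (the GRanges convention);
#' \code{\link{readNarrowPeak}} and \code{\link{writeNarrowPeak}} convert
#' from/to the 0-based half-open BED convention.
#'
#' @slot name Single character label for the set.
#' @slot regions \code{GRanges} with mcols \code{summit}, \code{score},
#'   \code{fdrPct}.
#' @seealso \code{\link{readNarrowPeak}}, \code{\link{intersectConfidence}},
#'   \code{\link{classifyByOverlap}}
#' @export
setClass("PeakSet", representation(name = "character", regions = "GRanges"))

setValidity("PeakSet", function(object) {
  gr <- object@regions
  msg <- character()
  need <- c("summit", "score", "fdrPct")
  if (!all(need %in% names(mcols(gr))))
    return(paste("regions must carry mcols:", paste(need, collapse = ", ")))
  if (length(gr)) {
    s <- mcols(gr)$summit
    if (any(s < start(gr) | s > end(gr)))
      msg <- c(msg, "every summit must lie within its region")
    f <- mcols(gr)$fdrPct
    if (any(f < 0 | f > 100))
      msg <- c(msg, "fdrPct must lie in [0, 100]")
    o <- order(as.integer(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "regions must be sorted by (chrom, start)")
    if (is.null(names(gr)) || anyDuplicated(names(gr)))
      msg <- c(msg, "regions must have unique names (region ids)")
    sl <- seqlengths(gr)
    if (!all(is.na(sl))) {
      lim <- sl[as.character(seqnames(gr))]
      if (any(!is.na(lim) & end(gr) > lim))
        msg <- c(msg, "regions exceed their chromosome length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param regions A \code{GRanges} with mcols \code{summit}, \code{score},
#'   \code{fdrPct} and unique names, or a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end} (1-based closed), \code{summit},
#'   \code{score}, \code{fdrPct}, \code{id}.
#' @param name Label for the set.
#' @param chromSizes Optional named vector of chromosome lengths.
#' @return A \code{\link{PeakSet}}.
#' @export
PeakSet <- function(regions, name = "peaks", chromSizes = NULL) {
  if (is.data.frame(regions)) {
    gr <- GRanges(regions$chrom, IRanges(regions$start, regions$end))
    mcols(gr)$summit <- as.integer(regions$summit)
    mcols(gr)$score <- as.integer(regions$score)
    mcols(gr)$fdrPct <- as.numeric(regions$fdrPct)
    names(gr) <- as.character(regions$id)
  } else gr <- regions
  if (!is.null(chromSizes))
    seqlengths(gr) <- chromSizes[seqlevels(gr)]
  gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
  new("PeakSet", name = name, regions = gr)
}

#' @describeIn PeakSet the underlying \code{GRanges}
#' @param x A \code{PeakSet}.
#' @export
peakRegions <- function(x) x@regions

#' @describeIn PeakSet absolute summit positions, named by region id
#' @export
summits <- function(x) setNames(mcols(x@regions)$summit, names(x@regions))

#' @describeIn PeakSet per-region FDR (percent), named by region id
#' @export
fdrPct <- function(x) setNames(mcols(x@regions)$fdrPct, names(x@regions))

#' @describeIn PeakSet the set label
#' @export
peakName <- function(x) x@name

setMethod("length", "PeakSet", function(x) length(x@regions))

setMethod("names", "PeakSet", function(x) names(x@regions))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet \"", object@name, "\": ", length(object), " regions on ",
      length(unique(as.character(seqnames(object@regions)))),
      " chromosome(s)\n", sep = "")
  if (length(object)) {
    f <- fdrPct(object)
    cat("  fdrPct range: ", round(min(f), 2), "-", round(max(f), 2),
        "; median width: ", stats::median(width(object@regions)),
        " bp\n", sep = "")
  }
})

## Subset helper used internally (keeps validity: order preserved).
subsetPeaks <- function(x, keep) {
  new("PeakSet", name = x@name, regions = x@regions[keep])
}

## ---------------------------------------------------------------------------
## SynthBundle
## ---------------------------------------------------------------------------

#' A self-contained synthetic study bundle
#'
#' The full output of \code{\link{simulateBundle}}: genome sequences with
#' planted motifs, the focal factor's two replicate peak sets, the
#' comparator (and optional co-factor) peaks, the TSS annotation, the
#' probeset-level expression experiment, gene sets, and the generating
#' truth (class labels, planted-site ledger, archetype assignments).
#'
#' @slot config The generating \code{\link{SimConfig}}.
#' @slot genome \code{DNAStringSet} of chromosome sequences.
#' @slot tss data.frame: \code{gene}, \code{chrom}, \code{tss}, \code{tts},
#'   \code{strand}.
#' @slot rep1,rep2 Focal-factor replicate \code{\link{PeakSet}}s (the
#'   high-confidence call keeps replicate-2 coordinates).
#' @slot comparator Comparator-factor \code{\link{PeakSet}}.
#' @slot cofactor Optional co-factor \code{\link{PeakSet}} (may be empty).
#' @slot expression \code{SummarizedExperiment}: probeset x sample log10
#'   signals; colData \code{treatment}, \code{stimulus}, \code{batch};
#'   rowData \code{gene}.
#' @slot geneSets Named list of character vectors (GMT-style categories).
#' @slot truth List of planted labels: \code{regionMode}, \code{regionGene},
#'   \code{siteCounts}, \code{hasSrf}, \code{hasModule}, \code{hasAp1},
#'   \code{hasFos}, \code{isProximal}, \code{geneArchetype},
#'   \code{geneDirection}, \code{ledger} (planted-site data.frame).
#' @export
setClass("SynthBundle", representation(
  config = "SimConfig", genome = "ANY", tss = "data.frame",
  rep1 = "PeakSet", rep2 = "PeakSet", comparator = "PeakSet",
  cofactor = "PeakSet", expression = "ANY", geneSets = "list",
  truth = "list"))

setMethod("show", "SynthBundle", function(object) {
  cat("SynthBundle (seed ", object@config@seed, ")\n", sep = "")
  cat("  genome: ", length(object@genome), " chromosomes, ",
      sum(Biostrings::width(object@genome)), " bp total\n", sep = "")
  cat("  peaks: rep1 ", length(object@rep1), ", rep2 ", length(object@rep2),
      ", comparator ", length(object@comparator),
      ", cofactor ", length(object@cofactor), "\n", sep = "")
  cat("  expression: ", nrow(object@expression), " probesets x ",
      ncol(object@expression), " samples; ", nrow(object@tss),
      " genes; ", length(object@geneSets), " gene sets\n", sep = "")
  cat("  ledger: ", nrow(object@truth$ledger), " planted sites\n", sep = "")
})

## ---------------------------------------------------------------------------
## AnalysisReport
## ---------------------------------------------------------------------------

#' End-to-end analysis report
#'
#' Returned by \code{\link{runAll}}. The \code{results} slot is a named list
#' of per-stage tables (confidence counts, binding-mode table, TSS-distance
#' summaries, hexamer histograms, module rates, cluster assignments, and
#' every contingency / overlap statistic); \code{provenance} records the
#' seed, configuration digest and package version so any number in the
#' report can be recomputed.
#'
#' @slot results Named list of stage outputs.
#' @slot provenance Named list: \code{seed}, \code{configDigest},
#'   \code{packageVersion}, \code{timestamp}.
#' @seealso \code{\link{runAll}}, \code{\link{writeReport}}
#' @export
setClass("AnalysisReport",
         representation(results = "list", provenance = "list"))

#' @describeIn AnalysisReport the named list of stage results
#' @param x An \code{AnalysisReport}.
#' @export
reportResults <- function(x) x@results

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport (seed ", object@provenance$seed, ")\n  sections: ",
      paste(names(object@results), collapse = ", "), "\n", sep = "")
})
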