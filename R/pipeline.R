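resultList <- function(x) {
  if (inherits(x, "ContingencyResult"))
    return(list(table = as.vector(x$table), statistic = x$statistic,
                p = x$p, testUsed = x$testUsed, oddsRatio = x$oddsRatio))
  x
}

#' Run the complete binding-mode analysis
#'
#' Executes every stage in dependency order on a synthetic bundle (or a
#' \code{\link{SimConfig}}, which is simulated first): replicate
#' confidence calling with the FDR filter; unique/redundant classification
#' against the comparator; nearest-TSS assignment, proximal fractions and
#' genomic distribution; hexamer-derivative counting (strong, variant and
#' reversed-background octamers), SRF/AP1 word rates and ETS-SRF module
#' calling with the class comparisons; the co-factor overlap analyses
#' (rates by class, overlap permutation test, overlap split by regulatory
#' direction and by proximal/distal location); probeset collapsing,
#' differential response, regulated-list overlap z-scores, z-transformed
#' profile clustering (k = 8), cluster-mode association, direction-mode
#' split, and gene-set enrichment. Identical config and seed give an
#' identical report; optional inputs (co-factor peaks, gene sets) merely
#' skip their sections with a notice.
#'
#' @param x A \code{\link{SimConfig}}, \code{\link{SynthBundle}} or input
#'   list from \code{\link{readBundleDir}}.
#' @param seed Global seed for the analysis stages (default: the config
#'   seed when available, else 1).
#' @param fdrMaxPct,proximalWindow,promoterBp Stage parameters (defaults
#'   10, 2000, 10000).
#' @param summitWindow,pairMax Module-calling constraints (100 bp, 50 bp).
#' @param pMax,qMax Regulated-gene thresholds (0.05, 0.1).
#' @param k Number of expression clusters (8).
#' @param nBackground Background lists for overlap z-scores (10000).
#' @param nPerm Permutations for the region-overlap test (1000).
#' @param etsStrongOctamer,etsVariantOctamer,srfPattern,ap1Pattern Motif
#'   words used by the scanning stages.
#' @return An \code{\link{AnalysisReport}}.
#' @examples
#' cfg <- simConfig(seed = 2, nUnique = 40, nRedundant = 30, nChrom = 2,
#'                  chromLength = 500000L, nGenes = 150L)
#' rep <- runAll(cfg, nBackground = 500L, nPerm = 100L)
#' reportResults(rep)$modes$counts
#' @export
runAll <- function(x, seed = NULL, fdrMaxPct = 10, proximalWindow = 2000L,
                   promoterBp = 10000L, summitWindow = 100L, pairMax = 50L,
                   pMax = 0.05, qMax = 0.1, k = 8L, nBackground = 10000L,
                   nPerm = 1000L,
                   etsStrongOctamer = "CCGGAAGT",
                   etsVariantOctamer = "CAGGATGT",
                   srfPattern = "CCWWWWWWGG", ap1Pattern = "TGANTCA") {
  if (is(x, "SimConfig")) {
    if (is.null(seed)) seed <- x@seed
    bundle <- simulateBundle(x)
    inputs <- list(genome = bundle@genome, tss = bundle@tss,
                   rep1 = bundle@rep1, rep2 = bundle@rep2,
                   comparator = bundle@comparator,
                   cofactor = if (length(bundle@cofactor)) bundle@cofactor
                              else NULL,
                   expression = bundle@expression,
                   geneSets = bundle@geneSets,
                   chromSizes = seqlengths(peakRegions(bundle@rep2)))
    truth <- bundle@truth
    etsStrongOctamer <- x@etsStrongOctamer
    etsVariantOctamer <- x@etsVariantOctamer
    srfPattern <- x@srfPattern
    ap1Pattern <- x@ap1Pattern
  } else if (is(x, "SynthBundle")) {
    if (is.null(seed)) seed <- x@config@seed
    inputs <- list(genome = x@genome, tss = x@tss, rep1 = x@rep1,
                   rep2 = x@rep2, comparator = x@comparator,
                   cofactor = if (length(x@cofactor)) x@cofactor else NULL,
                   expression = x@expression, geneSets = x@geneSets,
                   chromSizes = seqlengths(peakRegions(x@rep2)))
    truth <- x@truth
  } else if (is.list(x)) {
    inputs <- x
    truth <- x$truth
    if (is.null(seed)) seed <- 1L
  } else stop("x must be a SimConfig, SynthBundle or input list",
              call. = FALSE)
  need <- c("genome", "tss", "rep1", "rep2", "comparator", "expression")
  miss <- need[vapply(inputs[need], is.null, logical(1))]
  if (length(miss))
    stop("missing required inputs: ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- list()

  ## stage: confidence --------------------------------------------------
  conf <- intersectConfidence(inputs$rep1, inputs$rep2, fdrMaxPct)
  high <- conf$high
  res$confidence <- list(nHigh = length(conf$high), nLow = length(conf$low),
                         fdrDropped = conf$fdrDropped)

  ## stage: classification ----------------------------------------------
  modes <- classifyByOverlap(high, inputs$comparator)
  res$modes <- list(counts = table(modes))
  if (!is.null(truth)) {
    tr <- factor(truth$regionMode[names(modes)],
                 levels = c("unique", "redundant"))
    res$modes$truthAccuracy <- mean(as.character(modes) ==
                                      as.character(tr))
  }

  ## stage: TSS geometry --------------------------------------------------
  assign <- assignNearestTss(high, inputs$tss)
  byMode <- split(assign, as.character(modes[assign$region]))
  res$tss <- lapply(byMode, tssDistanceHistogram,
                    windowBp = proximalWindow)
  res$tss$all <- tssDistanceHistogram(assign, windowBp = proximalWindow)
  res$genomicDistribution <-
    genomicDistribution(high, inputs$tss, promoterBp = promoterBp,
                        downstreamBp = promoterBp,
                        seed = stageSeed(seed, "genomic_baseline"))

  ## stage: motifs --------------------------------------------------------
  seqs <- regionSequences(high, inputs$genome)
  mU <- names(modes)[modes == "unique"]
  mR <- names(modes)[modes == "redundant"]
  hex <- function(ids, octamer)
    perRegionCountDistribution(seqs[ids], octamer)
  res$hexamers <- list(
    strong = list(unique = hex(mU, etsStrongOctamer),
                  redundant = hex(mR, etsStrongOctamer)),
    variant = list(unique = hex(mU, etsVariantOctamer),
                   redundant = hex(mR, etsVariantOctamer)),
    background = list(unique = hex(mU, invertMotif(etsStrongOctamer)),
                      redundant = hex(mR, invertMotif(etsStrongOctamer))))
  srfHits <- vapply(seq_along(seqs), function(i)
    nrow(countIupac(seqs[[i]], srfPattern)) > 0, logical(1))
  ap1Hits <- vapply(seq_along(seqs), function(i)
    nrow(countIupac(seqs[[i]], ap1Pattern)) > 0, logical(1))
  names(srfHits) <- names(ap1Hits) <- names(seqs)
  sm <- summits(high)
  gr <- peakRegions(high)
  summitOffset <- setNames(sm - start(gr) + 1L, names(gr))
  nModules <- vapply(seq_along(seqs), function(i)
    nrow(callEtsSrfModules(seqs[[i]], summitOffset[i],
                           c(etsStrongOctamer, etsVariantOctamer),
                           srfPattern, summitWindow, pairMax)),
    integer(1))
  names(nModules) <- names(seqs)
  res$motifRates <- list(
    srf = c(unique = mean(srfHits[mU]), redundant = mean(srfHits[mR])),
    ap1 = c(unique = mean(ap1Hits[mU]), redundant = mean(ap1Hits[mR])),
    module = c(unique = mean(nModules[mU] > 0),
               redundant = mean(nModules[mR] > 0)),
    srfTest = resultList(motifClassCompare(srfHits[mU], srfHits[mR])),
    ap1Test = resultList(motifClassCompare(ap1Hits[mU], ap1Hits[mR])),
    moduleTest = resultList(motifClassCompare(nModules[mU] > 0,
                                              nModules[mR] > 0)))

  ## stage: expression ----------------------------------------------------
  coll <- collapseProbesets(inputs$expression)
  de <- differentialResponse(coll$se)
  regulated <- filterRegulated(de, pMax = pMax, qMax = qMax)
  res$expression <- list(
    nGenes = nrow(coll$se),
    exclusions = table(coll$exclusions$rule),
    backgroundLevel = coll$backgroundLevel,
    nRegulated = lapply(regulated, function(r)
      c(up = length(r$up), down = length(r$down))))

  ## bound genes and overlap z -------------------------------------------
  boundGenes <- unique(assign$gene[!is.na(assign$gene)])
  universe <- unique(inputs$tss$gene)
  res$overlapZ <- lapply(seq_along(regulated), function(i) {
    r <- regulated[[i]]
    listOverlapZ(boundGenes, unique(c(r$up, r$down)), universe,
                 nBackground = nBackground,
                 seed = stageSeed(seed, paste0("overlapz_",
                                               names(regulated)[i])))
  })
  names(res$overlapZ) <- names(regulated)
  res$overlapZ$any <- listOverlapZ(
    boundGenes, unique(unlist(lapply(regulated, unlist))), universe,
    nBackground = nBackground, seed = stageSeed(seed, "overlapz_any"))

  ## clustering: regulated genes associated with bound regions -----------
  geneMode <- geneModeTable(assign, modes)
  regGenes <- unique(unlist(lapply(regulated, unlist)))
  clusterGenes <- intersect(intersect(boundGenes, regGenes),
                            rownames(coll$se))
  z <- zTransformProfiles(coll$se[clusterGenes, ])
  km <- kmeansCluster(z$profiles, k = k,
                      seed = stageSeed(seed, "kmeans"))
  cma <- clusterModeAssociation(km$cluster, geneMode)
  dms <- directionModeSplit(regulated, geneMode)
  res$clusters <- list(sizes = table(km$cluster),
                       displayOrder = km$displayOrder,
                       totWithinss = km$totWithinss,
                       assignment = km$cluster,
                       modeAssociation = cma$perCluster,
                       zExcluded = z$excluded)
  res$directionMode <- lapply(dms, function(d)
    list(table = as.vector(d$table),
         result = if (is.null(d$result)) NULL else resultList(d$result)))

  ## co-factor section ----------------------------------------------------
  if (!is.null(inputs$cofactor) && length(inputs$cofactor)) {
    fosHit <- countOverlaps(peakRegions(high),
                            peakRegions(inputs$cofactor)) > 0L
    names(fosHit) <- names(high)
    geneFos <- tapply(fosHit[assign$region], assign$gene, any)
    upAll <- unique(unlist(lapply(regulated[c("knockdown_0",
                                              "knockdown_30")],
                                  function(r) r$up)))
    downAll <- unique(unlist(lapply(regulated[c("knockdown_0",
                                                "knockdown_30")],
                                    function(r) r$down)))
    ## knockdown-up = factor represses; knockdown-down = factor activates
    actGenes <- intersect(names(geneFos), setdiff(downAll, upAll))
    repGenes <- intersect(names(geneFos), setdiff(upAll, downAll))
    fosRegTab <- matrix(c(sum(geneFos[actGenes]),
                          sum(!geneFos[actGenes]),
                          sum(geneFos[repGenes]),
                          sum(!geneFos[repGenes])),
                        nrow = 2L, byrow = TRUE,
                        dimnames = list(c("activated", "repressed"),
                                        c("fos", "no_fos")))
    prox <- abs(assign$signedDist) <= proximalWindow
    proxHit <- fosHit[assign$region]
    fosProxTab <- matrix(c(sum(proxHit & !prox, na.rm = TRUE),
                           sum(!proxHit & !prox, na.rm = TRUE),
                           sum(proxHit & prox, na.rm = TRUE),
                           sum(!proxHit & prox, na.rm = TRUE)),
                         nrow = 2L, byrow = TRUE,
                         dimnames = list(c("distal", "proximal"),
                                         c("fos", "no_fos")))
    res$cofactor <- list(
      rates = c(unique = mean(fosHit[mU]), redundant = mean(fosHit[mR])),
      modeTest = resultList(motifClassCompare(fosHit[mU], fosHit[mR])),
      regulationTable = fosRegTab,
      regulationTest = if (all(rowSums(fosRegTab) > 0))
        resultList(chisqOrFisher2x2(fosRegTab)) else NULL,
      proximalTable = fosProxTab,
      proximalTest = if (all(rowSums(fosProxTab) > 0))
        resultList(chisqOrFisher2x2(fosProxTab)) else NULL,
      overlapPermutation = regionOverlapPermutationTest(
        high, inputs$cofactor, inputs$chromSizes, nPerm = nPerm,
        seed = stageSeed(seed, "cofactor_perm")))
  } else {
    message("no co-factor peaks supplied: co-factor section skipped")
  }

  ## gene-set section -----------------------------------------------------
  if (!is.null(inputs$geneSets) && length(inputs$geneSets)) {
    uniqueGenes <- intersect(names(geneMode)[geneMode == "unique"],
                             regGenes)
    redundantGenes <- intersect(names(geneMode)[geneMode == "redundant"],
                                regGenes)
    res$enrichment <- list(
      unique = hypergeomEnrichment(uniqueGenes, inputs$geneSets, universe),
      redundant = hypergeomEnrichment(redundantGenes, inputs$geneSets,
                                      universe),
      byCluster = lapply(
        clusterCategoryEnrichment(km$cluster, inputs$geneSets),
        function(e) list(ratios = e$ratios,
                         enrichedClusters = e$enrichedClusters,
                         p = e$result$p, testUsed = e$result$testUsed)))
  } else {
    message("no gene sets supplied: enrichment section skipped")
  }

  new("AnalysisReport", results = res,
      provenance = list(seed = seed,
                        configDigest = if (is(x, "SimConfig"))
                          configDigest(x)
                        else if (is(x, "SynthBundle"))
                          configDigest(x@config)
                        else NA_character_,
                        packageVersion =
                          as.character(packageVersion("bindmode")),
                        nHigh = length(high)))
}

#' Per-gene binding mode from region assignments
#'
#' Genes hit by regions of both classes keep the unique label (unique
#' binding is the rarer, more specific mode); reported for completeness.
#'
#' @param assign Output of \code{\link{assignNearestTss}}.
#' @param modes Region-level mode factor from
#'   \code{\link{classifyByOverlap}}.
#' @return Named character vector: gene -> mode.
#' @export
geneModeTable <- function(assign, modes) {
  md <- as.character(modes[assign$region])
  ok <- !is.na(assign$gene)
  tab <- tapply(md[ok], assign$gene[ok], function(v)
    if (any(v == "unique")) "unique" else "redundant")
  setNames(as.character(tab), names(tab))
}

## Short stable digest of a config (no external digest dependency).
configDigest <- function(config) {
  s <- paste(vapply(slotNames(config), function(sn)
    paste(format(slot(config, sn), digits = 15), collapse = ","),
    character(1)), collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write an analysis report to disk
#'
#' Emits the full report as JSON plus per-table TSV files (cluster
#' assignment, per-cluster mode association, enrichment tables), all
#' plain text.
#'
#' @param report An \code{\link{AnalysisReport}}.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "AnalysisReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(provenance = report@provenance,
         results = rapply(report@results, function(v)
           if (is.table(v)) as.list(setNames(as.vector(v), names(v)))
           else v,
           how = "replace")),
    path, auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  cl <- report@results$clusters
  if (!is.null(cl)) {
    write.table(data.frame(gene = names(cl$assignment),
                           cluster = cl$assignment),
                file.path(dir, "cluster_assignment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cl$modeAssociation,
                file.path(dir, "cluster_mode_association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  en <- report@results$enrichment
  if (!is.null(en)) {
    write.table(en$unique, file.path(dir, "enrichment_unique.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(en$redundant, file.path(dir, "enrichment_redundant.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
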