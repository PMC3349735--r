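#' Simulate the complete synthetic study bundle
#'
#' Runs \code{\link{simulateGenome}}, \code{\link{simulatePeaks}},
#' \code{\link{plantMotifs}} and \code{\link{simulateExpression}} under
#' stage-derived seeds, and builds GMT-style gene sets: a
#' cytoskeleton/migration-flavoured category biased towards unique-class
#' target genes, a transcription-flavoured category biased towards
#' redundant-class targets, and unbiased control sets. The same
#' \code{\link{SimConfig}} (including its seed) always yields an identical
#' bundle.
#'
#' @param config A \code{\link{SimConfig}}.
#' @return A \code{\link{SynthBundle}}.
#' @examples
#' bundle <- simulateBundle(simConfig(seed = 1, nUnique = 30,
#'   nRedundant = 25, nChrom = 2, chromLength = 500000L, nGenes = 120L))
#' bundle
#' @export
simulateBundle <- function(config) {
  stopifnot(is(config, "SimConfig"))
  g <- simulateGenome(config)
  pk <- simulatePeaks(g, config)
  pm <- plantMotifs(g$genome, pk$rep2, pk$truth, config)
  ex <- simulateExpression(pk$truth, g$tss, config)
  truth <- c(pk$truth, pm$truth, ex$truth, list(ledger = pm$ledger))

  geneSets <- withSeed(stageSeed(config@seed, "genesets"), {
    uniqGenes <- unname(truth$regionGene[truth$regionMode == "unique"])
    redGenes <- unname(truth$regionGene[truth$regionMode == "redundant"])
    universe <- g$tss$gene
    biased <- function(pool, size, frac) {
      nIn <- min(round(size * frac), length(pool))
      unique(c(sample(pool, nIn),
               sample(setdiff(universe, pool), size - nIn)))
    }
    sets <- list(
      ACTIN_CYTOSKELETON_MIGRATION = biased(uniqGenes, 60, 0.7),
      TRANSCRIPTION_REGULATION = biased(redGenes, 60, 0.7),
      RANDOM_SET_1 = sample(universe, 50),
      RANDOM_SET_2 = sample(universe, 50),
      RANDOM_SET_3 = sample(universe, 50))
    sets
  })

  new("SynthBundle", config = config, genome = pm$genome, tss = g$tss,
      rep1 = pk$rep1, rep2 = pk$rep2, comparator = pk$comparator,
      cofactor = pk$cofactor, expression = ex$se, geneSets = geneSets,
      truth = truth)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits the bundle in the standard formats every stage of the pipeline can
#' read back: genome FASTA, peaks as narrowPeak, TSS table / expression
#' matrix / design / probeset map as TSV, gene sets as GMT and truth labels
#' as JSON.
#'
#' @param bundle A \code{\link{SynthBundle}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @seealso \code{\link{readBundleDir}}
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "SynthBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    rep1 = file.path(dir, "focal_rep1.narrowPeak"),
    rep2 = file.path(dir, "focal_rep2.narrowPeak"),
    comparator = file.path(dir, "comparator.narrowPeak"),
    cofactor = file.path(dir, "cofactor.narrowPeak"),
    tss = file.path(dir, "tss.tsv"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    probemap = file.path(dir, "probeset_map.tsv"),
    genesets = file.path(dir, "gene_sets.gmt"),
    chromsizes = file.path(dir, "chrom.sizes"),
    truth = file.path(dir, "truth.json"))
  writeXStringSet(bundle@genome, paths["genome"], width = 80L)
  writeNarrowPeak(bundle@rep1, paths["rep1"])
  writeNarrowPeak(bundle@rep2, paths["rep2"])
  writeNarrowPeak(bundle@comparator, paths["comparator"])
  writeNarrowPeak(bundle@cofactor, paths["cofactor"])
  write.table(bundle@tss, paths["tss"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  se <- bundle@expression
  sig <- SummarizedExperiment::assay(se, "signal")
  write.table(data.frame(probeset = rownames(sig), sig,
                         check.names = FALSE),
              paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  write.table(data.frame(sample = rownames(cd), cd),
              paths["design"], sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  write.table(data.frame(probeset = rownames(rd), rd),
              paths["probemap"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeGmt(bundle@geneSets, paths["genesets"])
  sl <- seqlengths(peakRegions(bundle@rep2))
  write.table(data.frame(names(sl), unname(sl)), paths["chromsizes"],
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  truth <- bundle@truth
  truth$ledger <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE,
                       digits = NA)
  write.table(bundle@truth$ledger, file.path(dir, "ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a written bundle directory back into analysis inputs
#'
#' Reads the files produced by \code{\link{writeBundle}} (truth is not
#' required: real data laid out the same way load identically).
#'
#' @param dir Directory written by \code{\link{writeBundle}} or containing
#'   equivalently formatted files.
#' @return A list with \code{genome}, \code{tss}, \code{rep1}, \code{rep2},
#'   \code{comparator}, \code{cofactor} (\code{NULL} if absent),
#'   \code{expression} (\code{SummarizedExperiment}), \code{geneSets},
#'   \code{chromSizes}.
#' @export
readBundleDir <- function(dir) {
  chromSizes <- readChromSizes(file.path(dir, "chrom.sizes"))
  genome <- readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  tss <- read.table(file.path(dir, "tss.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  sig <- read.table(file.path(dir, "expression.tsv"), header = TRUE,
                    sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(sig[, -1, drop = FALSE])
  rownames(m) <- sig$probeset
  cd <- read.table(file.path(dir, "design.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  rownames(cd) <- cd$sample
  rd <- read.table(file.path(dir, "probeset_map.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  rownames(rd) <- rd$probeset
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m[, rownames(cd), drop = FALSE]),
    colData = DataFrame(cd[, setdiff(names(cd), "sample"), drop = FALSE]),
    rowData = DataFrame(rd[rownames(m),
                           setdiff(names(rd), "probeset"), drop = FALSE]))
  cofPath <- file.path(dir, "cofactor.narrowPeak")
  cof <- if (file.exists(cofPath))
    readNarrowPeak(cofPath, chromSizes, name = "cofactor") else NULL
  list(genome = genome, tss = tss,
       rep1 = readNarrowPeak(file.path(dir, "focal_rep1.narrowPeak"),
                             chromSizes, name = "focal_rep1"),
       rep2 = readNarrowPeak(file.path(dir, "focal_rep2.narrowPeak"),
                             chromSizes, name = "focal_rep2"),
       comparator = readNarrowPeak(file.path(dir, "comparator.narrowPeak"),
                                   chromSizes, name = "comparator"),
       cofactor = cof,
       expression = se,
       geneSets = readGmt(file.path(dir, "gene_sets.gmt")),
       chromSizes = chromSizes)
}

#' Read a UCSC-style two-column chrom.sizes file
#'
#' @param path File with chromosome name and length per line.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}
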