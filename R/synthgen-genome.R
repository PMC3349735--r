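#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet subseq replaceAt matchPattern
#'   vmatchPattern
NULL

#' Simulate a genome and TSS annotation
#'
#' Generates \code{nChrom} i.i.d. uniform A/C/G/T chromosome sequences and a
#' refGene-like TSS table with genes tiled at regular (jittered) spacing, so
#' that both promoter-proximal and distal peak placement is always possible
#' next to every gene. Gene strands alternate; gene bodies occupy roughly a
#' third of the inter-gene spacing. Deterministic for a given
#' \code{config@seed}.
#'
#' @param config A \code{\link{SimConfig}}.
#' @return A list with \code{genome} (\code{DNAStringSet}, names
#'   \code{chr1...}), \code{tss} (data.frame \code{gene}, \code{chrom},
#'   \code{tss}, \code{tts}, \code{strand}; 1-based positions) and
#'   \code{chromSizes} (named integer vector).
#' @examples
#' g <- simulateGenome(simConfig(seed = 1, nChrom = 1,
#'                               chromLength = 100000L, nGenes = 20L))
#' head(g$tss)
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  perChrom <- ceiling(config@nGenes / config@nChrom)
  spacing <- floor(config@chromLength / (perChrom + 1))
  minSpacing <- 2L * (config@proximalWindow + config@regionLength) + 200L
  if (spacing < minSpacing)
    stop("chromLength too small to host ", config@nGenes, " genes with ",
         "proximalWindow ", config@proximalWindow, ": gene spacing ",
         spacing, " bp < required ", minSpacing, " bp", call. = FALSE)
  withSeed(stageSeed(config@seed, "genome"), {
    chromNames <- paste0("chr", seq_len(config@nChrom))
    genome <- DNAStringSet(vapply(chromNames, function(ch) {
      paste(sample(c("A", "C", "G", "T"), config@chromLength,
                   replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- chromNames

    recs <- vector("list", config@nChrom)
    idx <- 0L
    for (ci in seq_len(config@nChrom)) {
      n <- min(perChrom, config@nGenes - (ci - 1L) * perChrom)
      if (n <= 0L) break
      anchor <- spacing * seq_len(n)
      tssPos <- as.integer(anchor + sample(-50:50, n, replace = TRUE))
      strand <- rep_len(c("+", "-"), n)
      glen <- as.integer(round(runif(n, 0.2, 0.35) * spacing))
      tts <- ifelse(strand == "+", tssPos + glen, tssPos - glen)
      recs[[ci]] <- data.frame(
        gene = sprintf("GENE%04d", idx + seq_len(n)),
        chrom = chromNames[ci], tss = tssPos, tts = as.integer(tts),
        strand = strand, stringsAsFactors = FALSE)
      idx <- idx + n
    }
    tss <- do.call(rbind, recs)
    rownames(tss) <- NULL
    list(genome = genome, tss = tss,
         chromSizes = setNames(rep(config@chromLength, config@nChrom),
                               chromNames))
  })
}
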