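## Instantiate an IUPAC word: each degenerate code is resolved to a random
## concrete base. Used when planting motifs.
iupacInstance <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)],
               character(1)), collapse = "")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## Sample a non-overlapping footprint for a site of length `len` whose
## centre offset from the summit lies in [lo, hi] (either side unless
## side is fixed), at least `gap` bp from already-occupied footprints and
## inside [regionStart + margin, regionEnd - margin]. Absolute coords.
placeSite <- function(len, summit, lo, hi, occupied, regionStart, regionEnd,
                      side = 0L, gap = 8L, maxTry = 300L) {
  half <- (len - 1) / 2
  for (i in seq_len(maxTry)) {
    s <- if (side == 0L) sample(c(-1L, 1L), 1L) else side
    centre <- summit + s * sample(seq.int(lo, hi), 1L)
    st <- as.integer(round(centre - half))
    en <- st + len - 1L
    if (st < regionStart + 2L || en > regionEnd - 2L) next
    ok <- TRUE
    for (iv in occupied)
      if (st <= iv[2] + gap - 1L && en >= iv[1] - gap + 1L) { ok <- FALSE; break }
    if (ok) return(c(st, en))
  }
  NULL
}

#' Plant motif instances into the genome at peak regions
#'
#' Mutates the genome sequence so that each region carries the motif
#' content of its binding class: redundant regions receive \code{k} strong
#' ETS octamers (\code{k} from \code{redundantSiteCountDist}, footprints
#' spaced >= 8 bp so they are countable as distinct non-overlapping sites);
#' unique regions receive sites per \code{uniqueSiteCountDist}, a fraction
#' \code{variantOnlyFracUnique} of them from the variant octamer only. SRF
#' CArG words and AP1 words are planted at their class rates. Module-flagged
#' regions get an ETS site and a CArG site both within 100 bp of the summit
#' and with motif centres less than 50 bp apart; non-module CArG words are
#' placed more than 110 bp from the summit so the module rate stays
#' interpretable. Planted strand is uniform and every planted site is
#' recorded in a ledger.
#'
#' Background sequence is untouched, so chance motif occurrences remain;
#' tests that need exact counts should score ledger-derived sequence.
#'
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param peaks The canonical (replicate 2) \code{\link{PeakSet}}.
#' @param truth Truth list from \code{\link{simulatePeaks}}.
#' @param config A \code{\link{SimConfig}}.
#' @return A list with \code{genome} (mutated \code{DNAStringSet}),
#'   \code{ledger} (data.frame: \code{region}, \code{family}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{word}) and \code{truth}
#'   additions (\code{siteCounts}, \code{hasSrf}, \code{hasModule},
#'   \code{hasAp1}, \code{variantOnly}, all named by region id).
#' @export
plantMotifs <- function(genome, peaks, truth, config) {
  stopifnot(is(peaks, "PeakSet"))
  gr <- peakRegions(peaks)
  ids <- names(gr)
  mode <- truth$regionMode[ids]
  n <- length(gr)
  withSeed(stageSeed(config@seed, "motifs"), {
    uniq <- mode == "unique"
    kDist <- function(d, m) as.integer(names(d))[
      sample.int(length(d), m, replace = TRUE, prob = d)]
    k <- integer(n)
    k[uniq] <- kDist(config@uniqueSiteCountDist, sum(uniq))
    k[!uniq] <- kDist(config@redundantSiteCountDist, sum(!uniq))
    variantOnly <- uniq & runif(n) < config@variantOnlyFracUnique
    srfRate <- ifelse(uniq, config@srfRateUnique, config@srfRateRedundant)
    modRate <- ifelse(uniq, config@moduleRateUnique,
                      config@moduleRateRedundant)
    hasModule <- runif(n) < modRate
    ## conditional rate so the marginal SRF rate equals srfRate
    hasSrf <- hasModule |
      runif(n) < (srfRate - modRate) / pmax(1 - modRate, 1e-12)
    hasAp1 <- runif(n) <
      ifelse(uniq, config@ap1RateUnique, config@ap1RateRedundant)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rs <- start(gr)[i]; re <- end(gr)[i]
      sm <- mcols(gr)$summit[i]
      chrom <- as.character(seqnames(gr))[i]
      occupied <- list()
      out <- list()
      add <- function(fp, family, pattern) {
        word <- iupacInstance(pattern)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-")
          word <- as.character(reverseComplement(DNAString(word)))
        occupied[[length(occupied) + 1L]] <<- fp
        out[[length(out) + 1L]] <<- data.frame(
          region = ids[i], family = family, chrom = chrom,
          start = fp[1], end = fp[2], strand = strand, word = word,
          stringsAsFactors = FALSE)
      }
      etsPat <- if (variantOnly[i]) config@etsVariantOctamer
                else config@etsStrongOctamer
      etsLen <- nchar(etsPat)
      etsFam <- if (variantOnly[i]) "ets_variant" else "ets_strong"
      nEts <- k[i]
      if (hasModule[i]) {
        o <- sample(c(-1L, 1L), 1L)
        eC <- sm + o * sample(25:34, 1L)
        sC <- sm - o * sample(5:15, 1L)
        eFp <- c(as.integer(round(eC - (etsLen - 1) / 2)), 0L)
        eFp[2] <- eFp[1] + etsLen - 1L
        sLen <- nchar(config@srfPattern)
        sFp <- c(as.integer(round(sC - (sLen - 1) / 2)), 0L)
        sFp[2] <- sFp[1] + sLen - 1L
        add(eFp, etsFam, etsPat)
        add(sFp, "srf", config@srfPattern)
        nEts <- nEts - 1L
      } else if (hasSrf[i]) {
        roomL <- sm - rs - 8L; roomR <- re - sm - 8L
        hi <- min(max(roomL, roomR), 190L)
        fp <- placeSite(nchar(config@srfPattern), sm, 111L, max(hi, 112L),
                        occupied, rs, re)
        if (is.null(fp))
          stop("region ", ids[i], " too short to place a distal CArG word",
               call. = FALSE)
        add(fp, "srf", config@srfPattern)
      }
      for (j in seq_len(max(nEts, 0L))) {
        fp <- placeSite(etsLen, sm, 0L, 150L, occupied, rs, re)
        if (is.null(fp))
          stop("region ", ids[i], " too short for ", k[i], " ETS sites",
               call. = FALSE)
        add(fp, etsFam, etsPat)
      }
      if (hasAp1[i]) {
        fp <- placeSite(nchar(config@ap1Pattern), sm, 0L,
                        max(sm - rs, re - sm) - 6L, occupied, rs, re)
        if (is.null(fp))
          stop("region ", ids[i], " too short for an AP1 word",
               call. = FALSE)
        add(fp, "ap1", config@ap1Pattern)
      }
      rows[[i]] <- do.call(rbind, out)
    }
    ledger <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(ledger) <- NULL

    ## write planted words into the chromosome sequences
    for (chrom in unique(ledger$chrom)) {
      sel <- ledger$chrom == chrom
      genome[[chrom]] <- replaceAt(
        genome[[chrom]],
        IRanges(ledger$start[sel], ledger$end[sel]),
        ledger$word[sel])
    }
    ## return flags in the same id order as truth$regionMode so that
    ## positional indexing across truth vectors stays consistent
    ord <- if (!is.null(truth$regionMode)) names(truth$regionMode) else ids
    list(genome = genome, ledger = ledger,
         truth = list(siteCounts = setNames(k, ids)[ord],
                      hasSrf = setNames(hasSrf, ids)[ord],
                      hasModule = setNames(hasModule, ids)[ord],
                      hasAp1 = setNames(hasAp1, ids)[ord],
                      variantOnly = setNames(variantOnly, ids)[ord]))
  })
}
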