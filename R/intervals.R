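#' Read peaks from a narrowPeak (BED6+4) file
#'
#' Parses the ENCODE narrowPeak format: BED6 plus signalValue, pValue,
#' qValue and the summit offset (field 10, 0-based offset from the BED
#' start; \code{-1} means no summit and is rejected here since every
#' downstream distance rule is summit-anchored). The qValue column (field
#' 9) is interpreted as the MACS-style FDR in percent. Coordinates are
#' converted to the 1-based closed convention of \code{GRanges}.
#'
#' Malformed lines (wrong field count, summit offset outside the region,
#' non-numeric coordinates) raise an error naming the line numbers; peaks
#' on chromosomes absent from \code{chromSizes} are skipped with a warning.
#'
#' @param path narrowPeak file; may be empty (returns an empty set).
#' @param chromSizes Optional named vector of chromosome lengths.
#' @param name Label for the returned set (default: file base name).
#' @return A \code{\link{PeakSet}}.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t500\tp1\t80\t.\t12.0\t8.0\t5.0\t200", f)
#' readNarrowPeak(f)  # region [101,500], summit 301, fdr 5
#' @export
readNarrowPeak <- function(path, chromSizes = NULL, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyPeakSet(name, chromSizes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    stop("malformed narrowPeak lines (expected 10 tab-separated fields): ",
         paste(head(which(nf != 10L), 5L), collapse = ", "), call. = FALSE)
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  offset <- suppressWarnings(as.integer(m[, 10]))
  badNum <- which(is.na(start0) | is.na(end0) | is.na(offset) |
                    start0 >= end0)
  if (length(badNum))
    stop("malformed narrowPeak coordinates at lines: ",
         paste(head(badNum, 5L), collapse = ", "), call. = FALSE)
  badSummit <- which(offset < 0L | offset >= end0 - start0)
  if (length(badSummit))
    stop("summit offset outside region at lines: ",
         paste(head(badSummit, 5L), collapse = ", "), call. = FALSE)
  chrom <- m[, 1]
  keep <- rep(TRUE, length(chrom))
  if (!is.null(chromSizes)) {
    keep <- chrom %in% names(chromSizes)
    if (any(!keep))
      warning(sum(!keep), " peak(s) on unknown chromosome(s) skipped: ",
              paste(unique(chrom[!keep]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start0 + 1L, end = end0,
                   summit = start0 + offset + 1L,
                   score = suppressWarnings(as.integer(m[, 5])),
                   fdrPct = suppressWarnings(as.numeric(m[, 9])),
                   id = m[, 4], stringsAsFactors = FALSE)[keep, ]
  PeakSet(df, name = name, chromSizes = chromSizes)
}

#' Write a PeakSet as narrowPeak
#'
#' Inverse of \code{\link{readNarrowPeak}}: 0-based half-open BED
#' coordinates, FDR percent in the qValue column, summit as a 0-based
#' offset in field 10.
#'
#' @param x A \code{\link{PeakSet}}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeNarrowPeak <- function(x, path) {
  stopifnot(is(x, "PeakSet"))
  gr <- peakRegions(x)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   names(gr), mcols(gr)$score, ".", 0,
                   -1, mcols(gr)$fdrPct,
                   mcols(gr)$summit - start(gr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Replicate-based confidence calling with an FDR filter
#'
#' Both replicates are first filtered to regions with FDR below
#' \code{fdrMaxPct} percent. The high-confidence set is then the
#' replicate-2 regions (their own coordinates retained) that overlap at
#' least one replicate-1 region by \code{minOverlapBp}; replicate-2 regions
#' with no replicate-1 partner form the low-confidence set.
#'
#' @param rep1,rep2 \code{\link{PeakSet}}s of the two replicates.
#' @param fdrMaxPct FDR retention threshold in percent (default 10;
#'   regions are kept when strictly below it).
#' @param minOverlapBp Minimum shared bp to count as overlap (default 1).
#' @return A list with \code{high} and \code{low} \code{\link{PeakSet}}s
#'   and the counts of FDR-dropped regions per replicate.
#' @export
intersectConfidence <- function(rep1, rep2, fdrMaxPct = 10,
                                minOverlapBp = 1L) {
  stopifnot(is(rep1, "PeakSet"), is(rep2, "PeakSet"))
  k1 <- fdrPct(rep1) < fdrMaxPct
  k2 <- fdrPct(rep2) < fdrMaxPct
  f1 <- subsetPeaks(rep1, k1)
  f2 <- subsetPeaks(rep2, k2)
  hit <- countOverlaps(peakRegions(f2), peakRegions(f1),
                       minoverlap = minOverlapBp) > 0L
  high <- subsetPeaks(f2, hit)
  high@name <- "high_confidence"
  low <- subsetPeaks(f2, !hit)
  low@name <- "low_confidence"
  list(high = high, low = low,
       fdrDropped = c(rep1 = sum(!k1), rep2 = sum(!k2)))
}

#' Classify focal regions as uniquely or redundantly bound
#'
#' A focal region is labelled \code{redundant} when it shares at least
#' \code{minOverlapBp} bp with any comparator-factor region, else
#' \code{unique} -- the central binding-mode classification.
#'
#' @param focal High-confidence focal-factor \code{\link{PeakSet}}.
#' @param comparator Comparator-factor \code{\link{PeakSet}}.
#' @param minOverlapBp Minimum shared bp (default 1).
#' @return A factor with levels \code{unique}, \code{redundant}, named by
#'   focal region id.
#' @examples
#' # a comparator peak sharing 10 bp makes the region redundant
#' @export
classifyByOverlap <- function(focal, comparator, minOverlapBp = 1L) {
  stopifnot(is(focal, "PeakSet"), is(comparator, "PeakSet"))
  hit <- countOverlaps(peakRegions(focal), peakRegions(comparator),
                       minoverlap = minOverlapBp) > 0L
  setNames(factor(ifelse(hit, "redundant", "unique"),
                  levels = c("unique", "redundant")),
           names(focal))
}

#' Assign each region summit to its nearest TSS
#'
#' Per region, the gene minimising the absolute summit-to-TSS distance on
#' the same chromosome. The signed distance is reported in gene
#' orientation: negative when the summit lies 5' (upstream) of the TSS.
#' Ties are broken towards the gene with the smaller TSS coordinate (then
#' lexicographically), deterministically. Regions on chromosomes without
#' genes are flagged unassigned (NA gene), not dropped.
#'
#' @param peaks A \code{\link{PeakSet}}.
#' @param tss data.frame with \code{gene}, \code{chrom}, \code{tss},
#'   \code{tts}, \code{strand}.
#' @return data.frame: \code{region}, \code{gene}, \code{signedDist}.
#' @export
assignNearestTss <- function(peaks, tss) {
  stopifnot(is(peaks, "PeakSet"),
            all(c("gene", "chrom", "tss", "strand") %in% names(tss)))
  gr <- peakRegions(peaks)
  out <- data.frame(region = names(gr),
                    gene = NA_character_,
                    signedDist = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!length(gr)) return(out)
  sm <- mcols(gr)$summit
  chrom <- as.character(seqnames(gr))
  for (ch in unique(chrom)) {
    t <- tss[tss$chrom == ch, ]
    ri <- which(chrom == ch)
    if (!nrow(t)) next
    t <- t[order(t$tss, t$gene), ]
    pos <- t$tss
    iv <- findInterval(sm[ri], pos)
    for (k in seq_along(ri)) {
      i <- iv[k]
      cand <- unique(pmin(pmax(c(i, i + 1L), 1L), nrow(t)))
      dd <- abs(sm[ri[k]] - pos[cand])
      best <- cand[order(dd, pos[cand], t$gene[cand])][1L]
      out$gene[ri[k]] <- t$gene[best]
      out$signedDist[ri[k]] <- if (t$strand[best] == "+")
        sm[ri[k]] - pos[best] else pos[best] - sm[ri[k]]
    }
  }
  out
}

#' Histogram of summit-to-TSS distances around the promoter window
#'
#' Bins signed TSS distances inside \code{[-windowBp, windowBp]} and
#' reports the fraction of all assigned regions falling inside the window
#' (the "within 2 kb" proximal fraction).
#'
#' @param assignments Output of \code{\link{assignNearestTss}}.
#' @param windowBp Window half-width in bp (default 2000).
#' @param binBp Bin width in bp (default 100).
#' @return A list: \code{breaks}, \code{counts}, \code{fractionWithin},
#'   \code{nWithin}, \code{nTotal} (unassigned regions are excluded from
#'   both numerator and denominator and counted in \code{nUnassigned}).
#' @export
tssDistanceHistogram <- function(assignments, windowBp = 2000L,
                                 binBp = 100L) {
  d <- assignments$signedDist
  unassigned <- sum(is.na(d))
  d <- d[!is.na(d)]
  if (!length(d)) stop("no assigned regions", call. = FALSE)
  breaks <- seq(-windowBp, windowBp, by = binBp)
  inside <- d >= -windowBp & d <= windowBp
  counts <- table(cut(d[inside], breaks, include.lowest = TRUE,
                      right = TRUE))
  list(breaks = breaks, counts = as.integer(counts),
       fractionWithin = mean(abs(d) <= windowBp),
       nWithin = sum(inside), nTotal = length(d),
       nUnassigned = unassigned)
}

#' Genomic distribution of peak summits
#'
#' Assigns each summit exactly one category with precedence
#' promoter (up to \code{promoterBp} upstream of a TSS, gene orientation)
#' > gene body (between TSS and TTS) > downstream (up to
#' \code{downstreamBp} past the TTS) > intergenic, and compares against a
#' seeded uniform-random summit baseline of the same size.
#'
#' @param peaks A \code{\link{PeakSet}} (needs chromosome lengths for the
#'   baseline).
#' @param tss Annotation data.frame with \code{tts} present.
#' @param promoterBp,downstreamBp Window sizes in bp (default 10000).
#' @param seed Seed for the random baseline.
#' @return A list with \code{counts} and \code{baseline} (named integer
#'   vectors over the four categories).
#' @export
genomicDistribution <- function(peaks, tss, promoterBp = 10000L,
                                downstreamBp = 10000L, seed = 1L) {
  stopifnot(is(peaks, "PeakSet"), "tts" %in% names(tss))
  gr <- peakRegions(peaks)
  sm <- mcols(gr)$summit
  chrom <- as.character(seqnames(gr))
  cats <- c("promoter", "gene_body", "downstream", "intergenic")
  categorize <- function(sm, chrom) {
    out <- rep("intergenic", length(sm))
    for (ch in unique(chrom)) {
      t <- tss[tss$chrom == ch, ]
      ri <- which(chrom == ch)
      if (!nrow(t)) next
      plus <- t$strand == "+"
      pLo <- ifelse(plus, t$tss - promoterBp, t$tss)
      pHi <- ifelse(plus, t$tss, t$tss + promoterBp)
      bLo <- pmin(t$tss, t$tts); bHi <- pmax(t$tss, t$tts)
      dLo <- ifelse(plus, t$tts, t$tts - downstreamBp)
      dHi <- ifelse(plus, t$tts + downstreamBp, t$tts)
      for (k in ri) {
        x <- sm[k]
        if (any(x >= pLo & x <= pHi)) out[k] <- "promoter"
        else if (any(x >= bLo & x <= bHi)) out[k] <- "gene_body"
        else if (any(x >= dLo & x <= dHi)) out[k] <- "downstream"
      }
    }
    out
  }
  obs <- categorize(sm, chrom)
  sl <- seqlengths(gr)
  if (all(is.na(sl)))
    sl <- setNames(rep(max(c(sm, tss$tss, tss$tts)), length(unique(chrom))),
                   unique(chrom))
  base <- withSeed(seed, {
    bChrom <- sample(names(sl), length(sm), replace = TRUE,
                     prob = sl / sum(sl))
    bPos <- vapply(sl[bChrom], function(L) sample.int(L, 1L), integer(1))
    categorize(bPos, bChrom)
  })
  list(counts = setNames(as.integer(table(factor(obs, cats))), cats),
       baseline = setNames(as.integer(table(factor(base, cats))), cats))
}

#' Permutation test for overlap between two region sets
#'
#' Keeps set A fixed and re-places every set B region uniformly at random
#' within its own chromosome (per-chromosome counts and region lengths
#' preserved -- each chromosome is its own bin). The statistic is the
#' number of set A regions overlapped by at least one B region; the
#' one-sided empirical p-value is \code{(1 + #permuted >= observed) /
#' (nPerm + 1)}.
#'
#' @param setA,setB \code{\link{PeakSet}}s.
#' @param chromSizes Named chromosome lengths (bp).
#' @param nPerm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A list: \code{observed}, \code{permMean}, \code{permSd},
#'   \code{z}, \code{empiricalP}, \code{nPerm}.
#' @export
regionOverlapPermutationTest <- function(setA, setB, chromSizes,
                                         nPerm = 1000L, seed = 1L) {
  stopifnot(is(setA, "PeakSet"), is(setB, "PeakSet"))
  if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
  grA <- peakRegions(setA)
  grB <- peakRegions(setB)
  wB <- width(grB)
  chB <- as.character(seqnames(grB))
  if (any(wB > chromSizes[chB]))
    stop("set B contains a region longer than its chromosome",
         call. = FALSE)
  observed <- sum(countOverlaps(grA, grB) > 0L)
  maxStart <- chromSizes[chB] - wB + 1L
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    st <- floor(runif(length(grB), 1, maxStart + 1))
    pg <- GRanges(chB, IRanges(as.integer(st), width = wB))
    sum(countOverlaps(grA, pg) > 0L)
  }, numeric(1)))
  m <- mean(perm); s <- sd(perm)
  list(observed = observed, permMean = m, permSd = s,
       z = if (s > 0) (observed - m) / s else NA_real_,
       empiricalP = (1 + sum(perm >= observed)) / (nPerm + 1),
       nPerm = nPerm)
}
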