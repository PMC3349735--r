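normalizeSeq <- function(seq, what = "sequence") {
  if (is(seq, "DNAString")) return(seq)
  if (is.character(seq) && length(seq) == 1L) {
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq))
      stop(what, " may contain only A, C, G, T, N", call. = FALSE)
    return(DNAString(seq))
  }
  stop(what, " must be a single character string or DNAString",
       call. = FALSE)
}

#' Find all occurrences of a degenerate IUPAC word
#'
#' Scans a sequence for every (possibly overlapping) match of an IUPAC
#' pattern. With \code{strands = "both"}, matches of the reverse complement
#' are reported on strand \code{-} with their footprint in forward-strand
#' coordinates; hits of a palindromic pattern whose footprints coincide on
#' both strands are collapsed to a single \code{+} hit. A sequence position
#' matches a pattern code when the subject base is covered by the code
#' (subject \code{N} is matched only by pattern \code{N}).
#'
#' @param seq Sequence (character over ACGTN, or \code{DNAString}).
#' @param pattern IUPAC word (codes ACGTRYSWKMBDHVN).
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return data.frame of hits: \code{start}, \code{end} (1-based closed,
#'   forward strand), \code{strand}, sorted by (start, strand \code{+}
#'   first).
#' @examples
#' countIupac("TGACTCA", "TGANTCA")   # palindrome: one collapsed + hit
#' countIupac("AAAA", "CCGGAA")       # no hits
#' @export
countIupac <- function(seq, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  assertDna(pattern, "pattern")
  subject <- normalizeSeq(seq)
  fwd <- matchPattern(pattern, subject, fixed = "subject")
  hits <- data.frame(start = start(fwd),
                     end = end(fwd),
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rcPat <- as.character(reverseComplement(DNAString(pattern)))
    rev <- matchPattern(rcPat, subject, fixed = "subject")
    rhits <- data.frame(start = start(rev),
                        end = end(rev),
                        strand = rep("-", length(rev)),
                        stringsAsFactors = FALSE)
    hits <- rbind(hits, rhits)
    ## palindromic collapse: identical forward footprints on both strands
    dup <- hits$strand == "-" &
      paste(hits$start, hits$end) %in%
        paste(hits$start[hits$strand == "+"], hits$end[hits$strand == "+"])
    hits <- hits[!dup, ]
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' The three hexamer derivatives of an octamer consensus
#'
#' The length-6 substrings of an 8-mer (positions 1-6, 2-7, 3-8),
#' deduplicated. Exact matches to these derivatives are what the
#' non-overlapping site counting scores.
#'
#' @param octamer A DNA string of length 8.
#' @return Character vector of 1-3 hexamers.
#' @examples
#' hexamerDerivatives("CCGGAAGT")  # CCGGAA, CGGAAG, GGAAGT
#' hexamerDerivatives("CAGGATGT")  # CAGGAT, AGGATG, GGATGT
#' @export
hexamerDerivatives <- function(octamer) {
  assertDna(octamer, "octamer")
  if (nchar(octamer) != 8L)
    stop("octamer must have length 8", call. = FALSE)
  unique(substring(octamer, 1:3, 6:8))
}

#' Reverse a motif string (inverted-motif background)
#'
#' The background used for hexamer counting: the motif string reversed
#' (not reverse-complemented, which both-strand scanning already covers).
#'
#' @param motif DNA string.
#' @return The reversed string.
#' @examples
#' invertMotif("CCGGAAGT")  # TGAAGGCC
#' @export
invertMotif <- function(motif) {
  assertDna(motif, "motif")
  paste(rev(strsplit(motif, "")[[1]]), collapse = "")
}

#' Count non-overlapping hexamer-derivative sites in a sequence
#'
#' Collects every hit of every derivative hexamer of \code{octamer} on the
#' requested strands, collapses duplicate footprints, then greedily selects
#' hits left-to-right by footprint start (at equal start, \code{+} strand
#' first), skipping any hit whose footprint overlaps an already selected
#' one on either strand. A site is a genomic footprint, so cross-strand
#' overlap also blocks selection. Greedy-by-start selection is optimal for
#' equal-length intervals, so the count is the maximum number of
#' non-overlapping sites.
#'
#' @param seq Sequence (character over ACGTN or \code{DNAString}).
#' @param octamer Length-8 consensus whose derivatives are scored.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return A list: \code{count} and \code{sites} (the selected hits).
#' @examples
#' countHexamerSites("AACCGGAAGTAA", "CCGGAAGT")$count       # 1
#' countHexamerSites("CCGGAATTTTGGAAGT", "CCGGAAGT")$count   # 2
#' @export
countHexamerSites <- function(seq, octamer, strands = "both") {
  hx <- hexamerDerivatives(octamer)
  subject <- normalizeSeq(seq)
  hits <- do.call(rbind, lapply(hx, countIupac, seq = subject,
                                strands = strands))
  hits <- hits[!duplicated(hits[, c("start", "end", "strand")]), ,
               drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  sel <- logical(nrow(hits))
  lastEnd <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > lastEnd) {
      sel[i] <- TRUE
      lastEnd <- hits$end[i]
    }
  }
  list(count = sum(sel), sites = hits[sel, , drop = FALSE])
}

#' Per-region distribution of non-overlapping ETS site counts
#'
#' Applies \code{\link{countHexamerSites}} to every region sequence and
#' summarises the per-region counts: the histogram whose per-class modes
#' (commonly three sites in redundant regions, one in unique regions)
#' characterise the two binding modes. Scoring the reversed octamer (see
#' \code{\link{invertMotif}}) gives the background distribution.
#'
#' @param seqs Named character vector or \code{DNAStringSet} of region
#'   sequences (names = region ids).
#' @param octamer Length-8 consensus.
#' @param strands \code{"both"} (default) or \code{"forward"}.
#' @return A list: \code{counts} (named integer per region),
#'   \code{histogram} (table over counts 0..max), \code{totalSites},
#'   \code{totalRegions}, \code{octamer}.
#' @export
perRegionCountDistribution <- function(seqs, octamer, strands = "both") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must be uniquely named by region id", call. = FALSE)
  counts <- vapply(seq_along(seqs), function(i) {
    countHexamerSites(if (is(seqs, "DNAStringSet")) seqs[[i]] else seqs[i],
                      octamer, strands)$count
  }, integer(1))
  names(counts) <- names(seqs)
  histogram <- table(factor(counts, levels = 0:max(c(counts, 0L))))
  list(counts = counts, histogram = histogram,
       totalSites = sum(counts), totalRegions = length(counts),
       octamer = octamer)
}

#' Extract region sequences from a genome
#'
#' @param peaks A \code{\link{PeakSet}}.
#' @param genome Named \code{DNAStringSet} of chromosome sequences.
#' @return \code{DNAStringSet} named by region id.
#' @export
regionSequences <- function(peaks, genome) {
  gr <- peakRegions(peaks)
  missing <- setdiff(unique(as.character(seqnames(gr))), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(subseq(genome[[as.character(seqnames(gr))[i]]],
                        start(gr)[i], end(gr)[i]))
  }, character(1)))
  names(out) <- names(gr)
  out
}

#' Call composite ETS-SRF modules in a region
#'
#' A module is an (ETS hit, SRF hit) pair with both motif centres within
#' \code{summitWindow} bp of the peak summit and the two centres less than
#' \code{pairMax} bp apart (boundaries: <= for the summit window, strict <
#' for the pair distance). ETS sites default to the union of the derivative
#' hexamers of the strong and variant octamers; the SRF site is the CArG
#' word. Motif centres are footprint midpoints; distances are in bp on
#' region coordinates.
#'
#' @param seq Region sequence.
#' @param summitPos Summit position within the region (1-based).
#' @param etsOctamers Character vector of octamers whose derivative
#'   hexamers define an ETS site.
#' @param srfPattern IUPAC CArG word (default \code{CCWWWWWWGG}).
#' @param summitWindow Max centre-to-summit distance in bp (default 100).
#' @param pairMax Exclusive max centre-to-centre distance (default 50).
#' @param strands Strands to scan (default \code{"both"}).
#' @return data.frame of modules: ETS and SRF footprints and the three
#'   distances (\code{summitDistEts}, \code{summitDistSrf},
#'   \code{pairDist}); zero rows when no pair qualifies.
#' @export
callEtsSrfModules <- function(seq, summitPos,
                              etsOctamers = c("CCGGAAGT", "CAGGATGT"),
                              srfPattern = "CCWWWWWWGG",
                              summitWindow = 100L, pairMax = 50L,
                              strands = "both") {
  subject <- normalizeSeq(seq)
  if (summitPos < 1L || summitPos > length(subject))
    stop("summit must lie within the region", call. = FALSE)
  ets <- do.call(rbind, lapply(unique(unlist(
    lapply(etsOctamers, hexamerDerivatives))), countIupac,
    seq = subject, strands = strands))
  ets <- ets[!duplicated(ets[, c("start", "end", "strand")]), ,
             drop = FALSE]
  srf <- countIupac(subject, srfPattern, strands = strands)
  empty <- data.frame(etsStart = integer(), etsEnd = integer(),
                      etsStrand = character(), srfStart = integer(),
                      srfEnd = integer(), srfStrand = character(),
                      summitDistEts = numeric(), summitDistSrf = numeric(),
                      pairDist = numeric())
  if (!nrow(ets) || !nrow(srf)) return(empty)
  eC <- (ets$start + ets$end) / 2
  sC <- (srf$start + srf$end) / 2
  pairs <- expand.grid(e = seq_len(nrow(ets)), s = seq_len(nrow(srf)))
  dE <- abs(eC[pairs$e] - summitPos)
  dS <- abs(sC[pairs$s] - summitPos)
  dP <- abs(eC[pairs$e] - sC[pairs$s])
  keep <- dE <= summitWindow & dS <= summitWindow & dP < pairMax
  if (!any(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(etsStart = ets$start[pairs$e], etsEnd = ets$end[pairs$e],
             etsStrand = ets$strand[pairs$e],
             srfStart = srf$start[pairs$s], srfEnd = srf$end[pairs$s],
             srfStrand = srf$strand[pairs$s],
             summitDistEts = dE[keep], summitDistSrf = dS[keep],
             pairDist = dP[keep])
}

#' Compare a binary motif feature between the two binding classes
#'
#' Builds the 2x2 table (class x feature) from per-region logical vectors
#' and tests it with the Pearson chi-square (Fisher's exact test when any
#' expected cell is below 5).
#'
#' @param featUnique,featRedundant Logical vectors: does each region of the
#'   class carry the feature (e.g. >= 1 CArG word, >= 1 module)?
#' @return A \code{ContingencyResult} (see \code{\link{chisq2x2}}) whose
#'   table rows are the classes and columns feature presence/absence.
#' @export
motifClassCompare <- function(featUnique, featRedundant) {
  if (!length(featUnique) || !length(featRedundant))
    stop("both classes must contain regions", call. = FALSE)
  tab <- matrix(c(sum(featUnique), sum(!featUnique),
                  sum(featRedundant), sum(!featRedundant)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("unique", "redundant"),
                                c("present", "absent")))
  chisqOrFisher2x2(tab)
}
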