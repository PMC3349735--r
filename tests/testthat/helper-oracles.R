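## Independent brute-force oracles used to cross-check the implementation.
## These deliberately share no code with the package internals.

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

## position-by-position matcher: subject letter must be covered by the
## pattern code (subject N only matched by pattern N)
bruteMatch <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  L <- length(p); n <- length(s)
  if (n < L) return(integer())
  hits <- integer()
  for (i in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(s[i + j - 1L] %in% IUPAC_TABLE[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
             S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
             H = "D", V = "B", N = "N")

bruteRevComp <- function(x)
  paste(rev(unname(REVCOMP[strsplit(x, "")[[1]]])), collapse = "")

## all hits of a pattern on both strands, palindromic footprints collapsed
bruteBothStrands <- function(seq, pattern) {
  fwd <- bruteMatch(seq, pattern)
  rev <- bruteMatch(seq, bruteRevComp(pattern))
  data.frame(start = c(fwd, setdiff(rev, fwd)),
             strand = c(rep("+", length(fwd)),
                        rep("-", length(setdiff(rev, fwd)))))
}

## exhaustive maximum independent set of equal-length interval footprints
bruteMaxNonOverlapping <- function(starts, len) {
  starts <- sort(unique(starts))
  n <- length(starts)
  if (n == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    sel <- starts[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L]
    if (length(sel) <= best) next
    if (all(diff(sel) >= len)) best <- length(sel)
  }
  best
}

## the same position-by-position rule, vectorised over positions so it
## scales to genome-wide checks (still independent of the implementation)
fastIupacMatch <- function(sv, pattern) {
  p <- strsplit(pattern, "")[[1]]
  L <- length(p); n <- length(sv)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) ok <- ok & (sv[j:(n - L + j)] %in% IUPAC_TABLE[[p[j]]])
  which(ok)
}

## all-pairs nearest TSS (minimum |summit - tss| on the same chromosome)
bruteNearest <- function(summit, chrom, tss) {
  t <- tss[tss$chrom == chrom, ]
  if (!nrow(t)) return(NA_character_)
  d <- abs(summit - t$tss)
  t$gene[order(d, t$tss, t$gene)][1L]
}

## random DNA string
randomDna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## adjusted Rand index (closed form over the pair-count contingency table)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  expd <- si * sj / sn
  (sij - expd) / ((si + sj) / 2 - expd)
}
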