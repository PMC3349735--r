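test_that("narrowPeak parsing applies the field arithmetic", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t500\tp1\t80\t.\t12.0\t8.0\t5.0\t200", f)
  ps <- readNarrowPeak(f)
  gr <- peakRegions(ps)
  expect_equal(GenomicRanges::start(gr), 101L)   # 0-based 100 -> 1-based 101
  expect_equal(GenomicRanges::end(gr), 500L)
  expect_equal(unname(summits(ps)), 301L)        # start0 + offset, 1-based
  expect_equal(unname(fdrPct(ps)), 5.0)
  expect_identical(names(ps), "p1")
})

test_that("narrowPeak parsing handles empty, malformed and unknown input", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(character(), f)
  expect_length(readNarrowPeak(f), 0)
  writeLines("chr1\t100\t500\tp1\t80\t.", f)
  expect_error(readNarrowPeak(f), "10 tab-separated fields")
  writeLines("chr1\t100\t500\tp1\t80\t.\t1\t1\t5\t400", f)
  expect_error(readNarrowPeak(f), "summit offset")
  writeLines(c("chr1\t100\t500\tp1\t80\t.\t1\t1\t5\t200",
               "chrUn\t100\t500\tp2\t80\t.\t1\t1\t5\t200"), f)
  expect_warning(ps <- readNarrowPeak(f, chromSizes = c(chr1 = 1000L)),
                 "unknown chromosome")
  expect_identical(names(ps), "p1")
})

test_that("narrowPeak write/read round-trips the synthetic bundle", {
  b <- smallBundle()
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(b@rep2, f)
  back <- readNarrowPeak(f, seqlengths(peakRegions(b@rep2)),
                         name = peakName(b@rep2))
  expect_identical(names(back), names(b@rep2))
  expect_equal(GenomicRanges::start(peakRegions(back)),
               GenomicRanges::start(peakRegions(b@rep2)))
  expect_equal(unname(summits(back)), unname(summits(b@rep2)))
  expect_equal(unname(fdrPct(back)), unname(fdrPct(b@rep2)),
               tolerance = 1e-6)
})

test_that("confidence calling keeps replicate-2 coordinates and filters FDR", {
  rep1 <- makePeaks("chr1", 100, 300, name = "r1")
  rep2 <- makePeaks("chr1", 250, 450, fdr = 5, name = "r2")
  conf <- intersectConfidence(rep1, rep2)
  expect_equal(GenomicRanges::start(peakRegions(conf$high)), 250)
  expect_length(conf$low, 0)
  ## FDR 12 excluded from both outputs
  conf2 <- intersectConfidence(rep1, makePeaks("chr1", 250, 450, fdr = 12))
  expect_length(conf2$high, 0)
  expect_length(conf2$low, 0)
  expect_equal(unname(conf2$fdrDropped["rep2"]), 1L)
  ## disjoint replicate-2 region is low confidence
  conf3 <- intersectConfidence(rep1, makePeaks("chr1", 400, 500, fdr = 5))
  expect_length(conf3$high, 0)
  expect_length(conf3$low, 1)
})

test_that("confidence calling is idempotent on identical replicates", {
  b <- smallBundle()
  conf <- intersectConfidence(b@rep2, b@rep2)
  expect_identical(names(conf$high),
                   names(b@rep2)[fdrPct(b@rep2) < 10])
  expect_length(conf$low, 0)
})

test_that("overlap classification follows the >= 1 bp rule and is monotone", {
  focal <- makePeaks("chr1", 100, 300, name = "f")
  expect_equal(as.character(
    classifyByOverlap(focal, makePeaks("chr1", 290, 400))), "redundant")
  expect_equal(as.character(
    classifyByOverlap(focal, makePeaks("chr1", 301, 400))), "unique")
  ## empty comparator: everything unique
  b <- smallBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  empty <- makePeaks(character(), integer(), integer())
  expect_true(all(classifyByOverlap(conf$high, empty) == "unique"))
  ## monotone: growing the comparator never converts redundant -> unique
  m1 <- classifyByOverlap(conf$high, b@comparator)
  grown <- PeakSet(c(peakRegions(b@comparator),
                     peakRegions(b@cofactor)), name = "grown")
  m2 <- classifyByOverlap(conf$high, grown)
  expect_true(all(m2[m1 == "redundant"] == "redundant"))
})

test_that("synthetic-bundle classification equals the planted labels", {
  b <- smallBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  modes <- classifyByOverlap(conf$high, b@comparator)
  expect_identical(as.character(modes),
                   unname(b@truth$regionMode[names(modes)]))
})

test_that("nearest-TSS assignment gets the sign convention and ties right", {
  tss <- data.frame(gene = c("A", "B"), chrom = "chr1",
                    tss = c(6000L, 8000L), tts = c(7000L, 9000L),
                    strand = "+", stringsAsFactors = FALSE)
  pk <- makePeaks("chr1", 4900, 5300, summit = 5000)
  a <- assignNearestTss(pk, tss)
  expect_equal(a$gene, "A")
  expect_equal(a$signedDist, -1000L)  # summit upstream of the TSS
  ## minus-strand gene: summit beyond the TSS is upstream (negative)
  tssM <- data.frame(gene = "C", chrom = "chr1", tss = 4000L, tts = 3000L,
                     strand = "-", stringsAsFactors = FALSE)
  am <- assignNearestTss(pk, tssM)
  expect_equal(am$signedDist, -1000L)
  ## equidistant: smaller coordinate wins
  tie <- makePeaks("chr1", 6900, 7100, summit = 7000)
  expect_equal(assignNearestTss(tie, tss)$gene, "A")
  ## peak on a gene-free chromosome is flagged, not dropped
  lost <- makePeaks("chr9", 100, 500)
  expect_true(is.na(assignNearestTss(lost, tss)$gene))
})

test_that("nearest-TSS assignment agrees with the all-pairs oracle", {
  set.seed(42)
  tss <- data.frame(gene = sprintf("G%03d", 1:80),
                    chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                    tss = sample.int(500000L, 80),
                    stringsAsFactors = FALSE)
  tss$tts <- tss$tss + 1000L
  tss$strand <- sample(c("+", "-"), 80, replace = TRUE)
  n <- 300
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  st <- sample.int(499000L, n)
  pk <- makePeaks(chrom, st, st + 400L)
  a <- assignNearestTss(pk, tss)
  gr <- peakRegions(pk)
  for (i in seq_len(n)) {
    expect_identical(a$gene[i],
                     bruteNearest(mcols(gr)$summit[i],
                                  as.character(seqnames(gr))[i], tss))
  }
})

test_that("TSS-distance histogram conserves counts and fractions", {
  b <- smallBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  a <- assignNearestTss(conf$high, b@tss)
  h <- tssDistanceHistogram(a)
  expect_equal(sum(h$counts), h$nWithin)
  expect_equal(h$fractionWithin, h$nWithin / h$nTotal)
  ## all summits exactly at a TSS: one occupied bin, fraction 1
  tss0 <- data.frame(gene = "A", chrom = "chr1", tss = 5000L, tts = 6000L,
                     strand = "+", stringsAsFactors = FALSE)
  pk0 <- makePeaks("chr1", rep(4900, 3), rep(5300, 3), summit = rep(5000, 3))
  h0 <- tssDistanceHistogram(assignNearestTss(pk0, tss0))
  expect_equal(h0$fractionWithin, 1)
  expect_equal(sum(h0$counts > 0), 1)
})

test_that("planted proximal fractions are recovered through the pipeline", {
  b <- defaultBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  modes <- classifyByOverlap(conf$high, b@comparator)
  a <- assignNearestTss(conf$high, b@tss)
  byMode <- split(a, as.character(modes[a$region]))
  fr <- tssDistanceHistogram(byMode$redundant)$fractionWithin
  fu <- tssDistanceHistogram(byMode$unique)$fractionWithin
  expect_lt(abs(fr - 0.93), 3.3 * sqrt(0.93 * 0.07 / nrow(byMode$redundant)))
  expect_lt(abs(fu - 0.26), 3.3 * sqrt(0.26 * 0.74 / nrow(byMode$unique)))
})

test_that("genomic distribution categorises with the stated precedence", {
  tss <- data.frame(gene = "A", chrom = "chr1", tss = 50000L,
                    tts = 70000L, strand = "+", stringsAsFactors = FALSE)
  mk <- function(summit) makePeaks("chr1", summit - 200, summit + 199,
                                   summit = summit,
                                   chromSizes = c(chr1 = 200000L))
  gd <- function(summit) {
    g <- genomicDistribution(mk(summit), tss)
    names(which(g$counts == 1))
  }
  expect_equal(gd(46000L), "promoter")     # 4 kb upstream
  expect_equal(gd(60000L), "gene_body")    # inside [tss, tts]
  expect_equal(gd(75000L), "downstream")   # 5 kb past the TTS
  expect_equal(gd(150000L), "intergenic")
  ## counts always partition the peak set
  b <- smallBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  g <- genomicDistribution(conf$high, b@tss)
  expect_equal(sum(g$counts), length(conf$high))
  expect_equal(sum(g$baseline), length(conf$high))
})

test_that("region overlap permutation test behaves at its limits", {
  b <- smallBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  sizes <- seqlengths(peakRegions(b@rep2))
  ## self-overlap: observed = |A|, p small (A covers << genome)
  r <- regionOverlapPermutationTest(conf$high, conf$high, sizes,
                                    nPerm = 200, seed = 1)
  expect_equal(r$observed, length(conf$high))
  expect_lt(r$empiricalP, 0.01)
  ## B on chromosomes disjoint from A: observed 0, p near 1
  grA <- peakRegions(conf$high)
  a1 <- subsetPeaks <- PeakSet(grA[seqnames(grA) == "chr1"], "a1")
  b2 <- PeakSet(grA[seqnames(grA) == "chr2"], "b2")
  r2 <- regionOverlapPermutationTest(a1, b2, sizes, nPerm = 200, seed = 1)
  expect_equal(r2$observed, 0)
  expect_gt(r2$empiricalP, 0.95)
  expect_error(regionOverlapPermutationTest(a1, b2, sizes, nPerm = 50),
               ">= 100")
})

test_that("permutation z is near-null for independent uniform sets", {
  sizes <- c(chr1 = 300000L)
  zs <- vapply(1:20, function(s) {
    set.seed(s)
    stA <- sample.int(299000L, 60)
    stB <- sample.int(299000L, 60)
    A <- makePeaks("chr1", stA, stA + 400L, name = "A", chromSizes = sizes)
    B <- makePeaks("chr1", stB, stB + 400L, name = "B", chromSizes = sizes)
    regionOverlapPermutationTest(A, B, sizes, nPerm = 150,
                                 seed = s + 1000)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)
  expect_lt(max(abs(zs)), 4)
})
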