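test_that("IUPAC scanning handles palindromes, misses and validation", {
  ## degenerate palindrome TGANTCA: one collapsed + hit
  h <- countIupac("TGACTCA", "TGANTCA")
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 1)
  expect_equal(nrow(countIupac("AAAA", "CCGGAA")), 0)
  expect_error(countIupac("ACGT", "CCXGAA"), "IUPAC")
  expect_error(countIupac("ACXT", "CCGGAA"), "A, C, G, T, N")
  ## minus-strand hit reported with forward footprint
  h3 <- countIupac("TTTTTTCCGG", "CCGGAA")   # revcomp TTCCGG at 5..10
  expect_equal(h3$strand, "-")
  expect_equal(h3$start, 5)
})

test_that("IUPAC scanning equals the position-by-position oracle", {
  set.seed(7)
  patterns <- c("CCGGAA", "TGANTCA", "CCWWWWWWGG", "RYGGAWN")
  for (i in 1:40) {
    seq <- randomDna(300)
    for (p in patterns) {
      got <- countIupac(seq, p)
      want <- bruteBothStrands(seq, p)
      expect_identical(sort(got$start[got$strand == "+"]),
                       sort(want$start[want$strand == "+"]))
      expect_identical(sort(got$start[got$strand == "-"]),
                       sort(want$start[want$strand == "-"]))
    }
  }
})

test_that("strand symmetry: scanning the reverse complement swaps labels", {
  set.seed(8)
  for (i in 1:10) {
    seq <- randomDna(200)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    a <- countIupac(seq, "CCGGAA")
    b <- countIupac(rc, "CCGGAA")
    ## a + hit at s maps to a - hit at rc position n - e + 1
    expect_setequal(201 - a$end[a$strand == "+"] - 5 + 5,
                    b$start[b$strand == "-"])
    expect_equal(nrow(a), nrow(b))
  }
})

test_that("hexamer derivatives are the three octamer substrings", {
  expect_setequal(hexamerDerivatives("CCGGAAGT"),
                  c("CCGGAA", "CGGAAG", "GGAAGT"))
  expect_setequal(hexamerDerivatives("CAGGATGT"),
                  c("CAGGAT", "AGGATG", "GGATGT"))
  expect_identical(hexamerDerivatives("AAAAAAAA"), "AAAAAA")
  expect_error(hexamerDerivatives("CCGGAA"), "length 8")
  expect_identical(invertMotif("CCGGAAGT"), "TGAAGGCC")
})

test_that("greedy non-overlapping counting matches its examples", {
  ## three overlapping derivative hits collapse to one site
  expect_equal(countHexamerSites("AACCGGAAGTAA", "CCGGAAGT")$count, 1L)
  ## two disjoint derivatives count separately
  expect_equal(countHexamerSites("CCGGAATTTTGGAAGT", "CCGGAAGT")$count, 2L)
  expect_equal(countHexamerSites("", "CCGGAAGT")$count, 0L)
  ## derivative hexamers subsume the octamer itself
  set.seed(9)
  for (i in 1:20) {
    seq <- paste0(randomDna(50), "CCGGAAGT", randomDna(50))
    nOct <- nrow(countIupac(seq, "CCGGAAGT"))
    expect_gte(countHexamerSites(seq, "CCGGAAGT")$count, nOct)
  }
})

test_that("greedy selection achieves the exhaustive maximum", {
  set.seed(10)
  ## biased alphabet provokes dense overlapping hits
  for (i in 1:60) {
    seq <- paste(sample(c("C", "G", "A", "A"), 120, replace = TRUE),
                 collapse = "")
    got <- countHexamerSites(seq, "CCGGAAGT")
    allHits <- do.call(rbind, lapply(hexamerDerivatives("CCGGAAGT"),
                                     function(p) countIupac(seq, p)))
    allHits <- allHits[!duplicated(allHits[c("start", "end", "strand")]), ]
    expect_lte(got$count, nrow(allHits))
    if (nrow(allHits) <= 14) {
      expect_equal(got$count,
                   bruteMaxNonOverlapping(allHits$start, 6L))
    }
    ## selected sites are pairwise non-overlapping
    s <- got$sites[order(got$sites$start), ]
    if (nrow(s) > 1) expect_true(all(diff(s$start) >= 6))
  }
})

test_that("per-region count distributions recover the planted modes", {
  b <- defaultBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  modes <- classifyByOverlap(conf$high, b@comparator)
  seqs <- regionSequences(conf$high, b@genome)
  u <- names(modes)[modes == "unique"]
  r <- names(modes)[modes == "redundant"]
  du <- perRegionCountDistribution(seqs[u], "CCGGAAGT")
  dr <- perRegionCountDistribution(seqs[r], "CCGGAAGT")
  expect_equal(names(which.max(du$histogram)), "1")
  expect_equal(names(which.max(dr$histogram)), "3")
  expect_equal(sum(du$histogram), du$totalRegions)
  expect_equal(du$totalSites, sum(du$counts))
  ## redundant regions carry many more strong sites in total
  expect_gt(dr$totalSites, du$totalSites)
  ## inverted-motif background is flat near zero
  bg <- perRegionCountDistribution(seqs[r], invertMotif("CCGGAAGT"))
  expect_equal(names(which.max(bg$histogram)), "0")
})

test_that("counting on ledger-only sequence equals the planted count", {
  b <- smallBundle()
  led <- b@truth$ledger
  mode <- b@truth$regionMode
  strong <- names(mode)[mode == "redundant" &
                          names(mode) %in% led$region]
  for (id in head(strong, 25)) {
    rows <- led[led$region == id & led$family == "ets_strong", ]
    if (!nrow(rows)) next
    ## rebuild the region on a neutral background from the ledger alone
    offs <- rows$start - min(rows$start)
    seqc <- rep("T", max(offs) + 8L)
    for (j in seq_len(nrow(rows)))
      seqc[offs[j] + 1:8] <- strsplit(rows$word[j], "")[[1]]
    got <- countHexamerSites(paste(seqc, collapse = ""), "CCGGAAGT")$count
    expect_equal(got, unname(b@truth$siteCounts[id]),
                 label = paste("region", id))
  }
})

test_that("module calling enforces both distance constraints exactly", {
  ## ETS centre 50 from summit, SRF centre 20 on the other side: module
  pad <- function(n) strrep("T", n)
  summit <- 1000L
  mkSeq <- function(etsCentre, srfCentre) {
    s <- rep("T", 1400)
    s[(etsCentre - 3):(etsCentre + 4)] <- strsplit("CCGGAAGT", "")[[1]]
    s[(srfCentre - 4):(srfCentre + 5)] <- strsplit("CCAAATTTGG", "")[[1]]
    paste(s, collapse = "")
  }
  m1 <- callEtsSrfModules(mkSeq(950, 980), summit)
  expect_gte(nrow(m1), 1)
  expect_true(all(m1$pairDist < 50))
  ## pair distance 55: no module
  expect_equal(nrow(callEtsSrfModules(mkSeq(940, 995), summit)), 0)
  ## ETS beyond the 100 bp summit window: no module
  expect_equal(nrow(callEtsSrfModules(mkSeq(880, 930), summit)), 0)
  expect_error(callEtsSrfModules(mkSeq(950, 980), 5000), "summit")
})

test_that("module rate on unique regions recovers the configured rate", {
  b <- defaultBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  modes <- classifyByOverlap(conf$high, b@comparator)
  seqs <- regionSequences(conf$high, b@genome)
  gr <- peakRegions(conf$high)
  offs <- summits(conf$high) - GenomicRanges::start(gr) + 1L
  u <- names(modes)[modes == "unique"]
  hasMod <- vapply(u, function(id)
    nrow(callEtsSrfModules(seqs[[id]], offs[[id]])) > 0, logical(1))
  ## 99.9% binomial envelope plus a little room for chance modules
  expect_lt(abs(mean(hasMod) - 0.30),
            3.3 * sqrt(0.3 * 0.7 / length(u)) + 0.03)
})

test_that("class comparison builds conserving tables and flags the rates", {
  set.seed(3)
  ## identical rates: p near 1 territory (no signal)
  a <- runif(300) < 0.4; b <- runif(300) < 0.4
  r0 <- motifClassCompare(a, b)
  expect_gt(r0$p, 0.01)
  expect_equal(sum(r0$table[1, ]), 300)
  expect_equal(sum(r0$table[2, ]), 300)
  ## planted 54% vs 27% at the study sizes: overwhelming evidence
  r1 <- motifClassCompare(rep(c(TRUE, FALSE), c(162, 138)),
                          rep(c(TRUE, FALSE), c(61, 165)))
  expect_lt(r1$p, 1e-6)
  expect_error(motifClassCompare(logical(), a), "both classes")
})
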