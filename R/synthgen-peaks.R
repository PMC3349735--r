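#' Simulate replicate, comparator and co-factor peak sets
#'
#' Places one focal-factor region per selected gene, with the summit's
#' signed TSS distance drawn proximal (within \code{proximalWindow}) or
#' distal according to the class proportions. Replicate 2 carries the
#' canonical coordinates; replicate 1 is the same set jittered by
#' N(0, \code{replicateJitterSd}) with a fraction \code{replicateDropout}
#' of regions missing, so that confidence calling (regions in repeat 2
#' overlapped by repeat 1) is exercised. Comparator peaks are generated to
#' overlap every redundant-class region and no unique-class region, which
#' makes the planted labels exactly recoverable by
#' \code{\link{classifyByOverlap}}. Per-region FDR values are drawn so that
#' a fraction \code{fdrExceedFrac} exceed the 10\% retention cut-off.
#'
#' Gene spacing guarantees non-overlap between regions (and comparator /
#' co-factor peaks) attached to different genes; a placement that cannot
#' satisfy the constraints raises an error naming the constraint.
#'
#' @param genome Output of \code{\link{simulateGenome}} (list with
#'   \code{tss} and \code{chromSizes}).
#' @param config A \code{\link{SimConfig}}.
#' @return A list with \code{rep1}, \code{rep2}, \code{comparator},
#'   \code{cofactor} (\code{\link{PeakSet}}s; \code{cofactor} empty unless
#'   \code{config@cofactor}) and \code{truth} (list: \code{regionMode},
#'   \code{regionGene}, \code{isProximal}, \code{signedDist},
#'   \code{hasFos}, all named by region id).
#' @export
simulatePeaks <- function(genome, config) {
  stopifnot(is(config, "SimConfig"))
  tss <- genome$tss
  chromSizes <- genome$chromSizes
  n <- config@nUnique + config@nRedundant
  if (n > nrow(tss))
    stop("cannot place ", n, " regions on ", nrow(tss),
         " genes: one region per gene", call. = FALSE)
  if (n == 0L)
    stop("no regions requested", call. = FALSE)
  W <- config@proximalWindow
  L <- config@regionLength
  spacing <- min(vapply(split(tss$tss, tss$chrom),
                        function(p) if (length(p) > 1L) min(diff(sort(p)))
                        else Inf, numeric(1)))
  distalMin <- W + 100L
  distalMax <- floor(spacing / 2) - L - 300L
  if (distalMax <= distalMin)
    stop("gene spacing (", spacing, " bp) too tight for distal placement ",
         "beyond the ", W, " bp proximal window", call. = FALSE)

  withSeed(stageSeed(config@seed, "peaks"), {
    geneIdx <- sample.int(nrow(tss), n)
    mode <- rep(c("unique", "redundant"),
                c(config@nUnique, config@nRedundant))
    ids <- sprintf("peak_%04d", seq_len(n))
    pProx <- ifelse(mode == "unique", config@fracUniqueProximal,
                    config@fracRedundantProximal)
    isProx <- runif(n) < pProx
    ## signed distance in gene orientation (negative = upstream of TSS)
    d <- integer(n)
    prox <- which(isProx)
    d[prox] <- pmax(pmin(as.integer(round(rnorm(length(prox), 0, 600))),
                         W - 100L), -(W - 100L))
    dist <- which(!isProx)
    d[dist] <- as.integer(round(runif(length(dist), distalMin, distalMax))) *
      sample(c(-1L, 1L), length(dist), replace = TRUE)
    g <- tss[geneIdx, ]
    summit <- ifelse(g$strand == "+", g$tss + d, g$tss - d)
    off <- sample(150:250, n, replace = TRUE)
    start <- summit - off
    end <- start + L - 1L
    bad <- start < 1L | end > chromSizes[g$chrom]
    if (any(bad))
      stop("placement failure: ", sum(bad), " region(s) fall outside ",
           "their chromosome; increase chromLength", call. = FALSE)
    score <- as.integer(round(runif(n, 20, 200)))
    fdr <- ifelse(runif(n) < config@fdrExceedFrac,
                  runif(n, 10.5, 40), runif(n, 0, 9.5))

    rep2 <- PeakSet(data.frame(chrom = g$chrom, start = start, end = end,
                               summit = summit, score = score, fdrPct = fdr,
                               id = ids),
                    name = "focal_rep2", chromSizes = chromSizes)

    ## replicate 1: jittered copy, minus the dropout fraction
    keep1 <- runif(n) >= config@replicateDropout
    shift <- as.integer(round(rnorm(n, 0, config@replicateJitterSd)))
    shift <- pmax(pmin(shift, off - 10L), -(L - off - 10L))
    st1 <- pmax(start + shift, 1L)
    rep1 <- PeakSet(data.frame(chrom = g$chrom, start = st1,
                               end = st1 + L - 1L,
                               summit = pmin(pmax(summit, st1), st1 + L - 1L),
                               score = score, fdrPct = fdr,
                               id = sprintf("r1_%04d", seq_len(n)))[keep1, ],
                    name = "focal_rep1", chromSizes = chromSizes)

    ## comparator overlaps every redundant region (peak contains the summit)
    red <- which(mode == "redundant")
    cj <- as.integer(round(runif(length(red), -80, 80)))
    cst <- summit[red] - 150L + cj
    comparator <- PeakSet(data.frame(
      chrom = g$chrom[red], start = pmax(cst, 1L), end = cst + 299L,
      summit = summit[red] + cj,
      score = as.integer(round(runif(length(red), 20, 200))),
      fdrPct = runif(length(red), 0, 9.5),
      id = sprintf("cmp_%04d", seq_along(red))),
      name = "comparator", chromSizes = chromSizes)

    hasFos <- runif(n) < ifelse(mode == "unique", config@fosRateUnique,
                                config@fosRateRedundant)
    if (config@cofactor && any(hasFos)) {
      fi <- which(hasFos)
      fj <- as.integer(round(runif(length(fi), -70, 70)))
      fst <- summit[fi] - 140L + fj
      cofactor <- PeakSet(data.frame(
        chrom = g$chrom[fi], start = pmax(fst, 1L), end = fst + 279L,
        summit = summit[fi] + fj,
        score = as.integer(round(runif(length(fi), 20, 200))),
        fdrPct = runif(length(fi), 0, 9.5),
        id = sprintf("fos_%04d", seq_along(fi))),
        name = "cofactor", chromSizes = chromSizes)
    } else {
      cofactor <- emptyPeakSet("cofactor", chromSizes)
    }

    truth <- list(regionMode = setNames(mode, ids),
                  regionGene = setNames(g$gene, ids),
                  isProximal = setNames(isProx, ids),
                  signedDist = setNames(d, ids),
                  hasFos = setNames(hasFos, ids),
                  inRep1 = setNames(keep1, ids))
    list(rep1 = rep1, rep2 = rep2, comparator = comparator,
         cofactor = cofactor, truth = truth)
  })
}

emptyPeakSet <- function(name, chromSizes = NULL) {
  gr <- GRanges()
  if (!is.null(chromSizes))
    seqinfo(gr) <- Seqinfo(names(chromSizes),
                           as.integer(unname(chromSizes)))
  mcols(gr)$summit <- integer()
  mcols(gr)$score <- integer()
  mcols(gr)$fdrPct <- numeric()
  names(gr) <- character()
  new("PeakSet", name = name, regions = gr)
}
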