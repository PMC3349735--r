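as2x2 <- function(table) {
  if (is.matrix(table) && all(dim(table) == 2L)) m <- table
  else if (is.numeric(table) && length(table) == 4L)
    m <- matrix(table, nrow = 2L, byrow = TRUE)
  else stop("table must be a 2x2 matrix or a length-4 vector (a,b,c,d)",
            call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(m) == 0)
    stop("at least one nonzero count required", call. = FALSE)
  m
}

contingencyResult <- function(table, statistic, p, testUsed) {
  or <- unname(table[1, 1] * table[2, 2])
  bc <- unname(table[1, 2] * table[2, 1])
  structure(list(table = table, statistic = statistic,
                 df = if (testUsed == "chisq") 1L else NA_integer_,
                 p = p, testUsed = testUsed,
                 oddsRatio = if (bc == 0) Inf else or / bc),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat("2x2 ", x$testUsed, " test: p = ", format.pval(x$p, digits = 3),
      ", odds ratio = ", signif(x$oddsRatio, 3), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default: continuity correction is off because
#' word-count and overlap tables here are large enough that the
#' uncorrected statistic is the conventional choice.
#'
#' @param table 2x2 matrix (rows = group, columns = feature) or length-4
#'   vector \code{(a, b, c, d)} filling the table by row.
#' @param correct Apply the Yates continuity correction? Default
#'   \code{FALSE}.
#' @return A \code{ContingencyResult}: \code{table}, \code{statistic}
#'   (df = 1), \code{p}, \code{testUsed}, \code{oddsRatio} (\code{ad/bc};
#'   \code{Inf} when \code{bc = 0}).
#' @examples
#' chisq2x2(c(27, 114, 13, 124))$p   # ~0.022
#' @export
chisq2x2 <- function(table, correct = FALSE) {
  m <- as2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: zero row or column margin", call. = FALSE)
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  contingencyResult(m, unname(ht$statistic), unname(ht$p.value), "chisq")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric outcome probabilities not
#' exceeding that of the observed table. Zero cells are allowed (unlike
#' \code{\link{chisq2x2}}); a table with an empty row or column has p = 1.
#'
#' @inheritParams chisq2x2
#' @return A \code{ContingencyResult} with \code{testUsed = "fisher"} and
#'   the sample odds ratio \code{ad/bc}.
#' @export
fisherExact2x2 <- function(table) {
  m <- as2x2(table)
  ht <- fisher.test(m)
  contingencyResult(m, NA_real_, unname(ht$p.value), "fisher")
}

#' Chi-square with Fisher fallback
#'
#' Uses the Pearson chi-square unless any expected cell is below 5 (or a
#' margin is zero), in which case Fisher's exact test is used -- the
#' standard switch for sparse tables.
#'
#' @inheritParams chisq2x2
#' @param minExpected Expected-cell threshold for the switch (default 5).
#' @return A \code{ContingencyResult}; \code{testUsed} records the choice.
#' @export
chisqOrFisher2x2 <- function(table, minExpected = 5) {
  m <- as2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(fisherExact2x2(m))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < minExpected)) fisherExact2x2(m) else chisq2x2(m)
}

#' Monte-Carlo z-score for the overlap of two gene lists
#'
#' Compares the observed overlap of lists A and B against the overlaps of
#' \code{nBackground} random lists of size |B| sampled uniformly without
#' replacement from the gene universe: z = (observed - background mean) /
#' background SD. With 10,000 background lists the background moments match
#' the hypergeometric closed form (mean |A||B|/N).
#'
#' @param listA,listB Character vectors of gene symbols (subsets of
#'   \code{universe}).
#' @param universe Character vector: the gene universe.
#' @param nBackground Number of background lists (default 10000).
#' @param seed Integer seed.
#' @return A list: \code{observed}, \code{bgMean}, \code{bgSd}, \code{z}
#'   (\code{NA} with \code{degenerate = TRUE} when the background SD is 0),
#'   \code{nBackground}, \code{universeSize}, \code{sizeA}, \code{sizeB}.
#' @export
listOverlapZ <- function(listA, listB, universe, nBackground = 10000L,
                         seed = 1L) {
  listA <- unique(listA); listB <- unique(listB)
  universe <- unique(universe)
  if (!all(listA %in% universe) || !all(listB %in% universe))
    stop("both lists must be subsets of the universe", call. = FALSE)
  N <- length(universe)
  nB <- length(listB)
  inA <- universe %in% listA
  observed <- sum(listB %in% listA)
  bg <- withSeed(seed, vapply(seq_len(nBackground), function(i) {
    sum(inA[sample.int(N, nB)])
  }, numeric(1)))
  m <- mean(bg); s <- sd(bg)
  list(observed = observed, bgMean = m, bgSd = s,
       z = if (s > 0) (observed - m) / s else NA_real_,
       degenerate = s == 0,
       nBackground = nBackground, universeSize = N,
       sizeA = length(listA), sizeB = nB)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value for the overlap of a gene list with
#' each gene set (P[overlap >= observed]), BH-adjusted across terms. Terms
#' entirely outside the universe are skipped with a message. A generic
#' stand-in for database-backed GO/pathway tools: supply any GMT.
#'
#' @param geneList Character vector (subset of \code{universe}).
#' @param geneSets Named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param universe Character vector: the gene universe.
#' @return data.frame sorted by p: \code{term}, \code{overlap},
#'   \code{termSize}, \code{listSize}, \code{universeSize}, \code{p},
#'   \code{negLog10P}, \code{qBH}.
#' @export
hypergeomEnrichment <- function(geneList, geneSets, universe) {
  if (!length(geneSets)) stop("geneSets is empty", call. = FALSE)
  geneList <- unique(geneList); universe <- unique(universe)
  if (!all(geneList %in% universe))
    stop("geneList must be a subset of the universe", call. = FALSE)
  n <- length(geneList); N <- length(universe)
  rows <- lapply(names(geneSets), function(term) {
    inU <- unique(intersect(geneSets[[term]], universe))
    if (!length(inU)) {
      message("term skipped (no genes in universe): ", term)
      return(NULL)
    }
    k <- length(inU)
    x <- length(intersect(geneList, inU))
    p <- phyper(x - 1, k, N - k, n, lower.tail = FALSE)
    data.frame(term = term, overlap = x, termSize = k, listSize = n,
               universeSize = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no term overlaps the universe", call. = FALSE)
  out$negLog10P <- -log10(out$p)
  out$qBH <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Category enrichment across expression clusters
#'
#' For each category, computes per-cluster enrichment ratios
#' (observed / expected membership) and tests whether the category
#' concentrates in the clusters with ratio > 1: a 2x2 table of category
#' membership against membership of the enriched-cluster set, chi-square
#' tested (Fisher for categories with fewer than 5 genes in the universe).
#'
#' @param assignment Named integer/factor vector: gene -> cluster.
#' @param categorySets Named list of character vectors.
#' @return A list per category: \code{ratios} (per cluster),
#'   \code{enrichedClusters}, \code{result} (a \code{ContingencyResult}).
#' @export
clusterCategoryEnrichment <- function(assignment, categorySets) {
  genes <- names(assignment)
  if (is.null(genes)) stop("assignment must be named by gene", call. = FALSE)
  cl <- as.integer(as.character(assignment))
  ks <- sort(unique(cl))
  out <- lapply(names(categorySets), function(cat) {
    inCat <- genes %in% categorySets[[cat]]
    nCat <- sum(inCat)
    ratios <- vapply(ks, function(k) {
      obs <- sum(inCat & cl == k)
      expd <- nCat * sum(cl == k) / length(genes)
      if (expd > 0) obs / expd else NA_real_
    }, numeric(1))
    names(ratios) <- ks
    enriched <- ks[!is.na(ratios) & ratios > 1]
    inEnriched <- cl %in% enriched
    tab <- matrix(c(sum(inCat & inEnriched), sum(inCat & !inEnriched),
                    sum(!inCat & inEnriched), sum(!inCat & !inEnriched)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("category", "rest"),
                                  c("enriched_clusters", "other_clusters")))
    res <- if (nCat < 5) fisherExact2x2(tab) else chisqOrFisher2x2(tab)
    list(ratios = ratios, enrichedClusters = enriched, result = res)
  })
  names(out) <- names(categorySets)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab format: term, description, then member genes.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT lines (need term, description, >=1 gene): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2L)
  sets
}

#' Write gene sets as GMT
#'
#' @param geneSets Named list of character vectors.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(term) {
    paste(c(term, "synthetic", geneSets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
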