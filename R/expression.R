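## Paired differences for a contrast, computed per row of the signal
## matrix. Conditions are matched within batch; each batch contributes one
## difference (mean over that batch's samples of each arm, normally one).
pairedDiffs <- function(sig, cd, selHi, selLo) {
  batches <- sort(unique(cd$batch))
  d <- vapply(batches, function(b) {
    hi <- selHi & cd$batch == b
    lo <- selLo & cd$batch == b
    if (!any(hi) || !any(lo))
      stop("batch ", b, " lacks samples for the contrast", call. = FALSE)
    rowMeans(sig[, hi, drop = FALSE]) - rowMeans(sig[, lo, drop = FALSE])
  }, numeric(nrow(sig)))
  matrix(d, nrow = nrow(sig), dimnames = list(rownames(sig), batches))
}

rowPairedT <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  data.frame(effect = m, t = t, p = p, sd = s)
}

#' Collapse probesets to gene level
#'
#' Applies the three probeset-handling rules in order: (1) probesets whose
#' mean signal in the EGF-treated control samples is at or below the
#' background level are discarded; (2) genes with two significant
#' probesets (paired knockdown-contrast t-test, p < 0.05) changing in
#' opposite directions are excluded entirely; (3) for the remaining
#' multi-probeset genes only the probeset with the largest absolute
#' knockdown effect is retained (ties towards the first probeset id).
#'
#' @param se \code{SummarizedExperiment}: assay \code{signal} (log10),
#'   colData \code{treatment} (\code{control}/\code{knockdown}),
#'   \code{stimulus} (\code{0}/\code{30}), \code{batch}; rowData
#'   \code{gene}.
#' @param backgroundLevel Signal threshold; default: the 2.5th percentile
#'   of all signals (no absolute chip background is available on
#'   arbitrary input, so a low overall quantile is used and exposed).
#' @return A list: \code{se} (gene-level, rownames = gene),
#'   \code{exclusions} (data.frame: \code{probeset}, \code{gene},
#'   \code{rule}), \code{backgroundLevel}.
#' @export
collapseProbesets <- function(se, backgroundLevel = NULL) {
  sig <- SummarizedExperiment::assay(se, "signal")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  gene <- as.character(SummarizedExperiment::rowData(se)$gene)
  if (is.null(backgroundLevel))
    backgroundLevel <- unname(quantile(sig, 0.025))
  log <- list()
  ## rule 1: background in EGF-treated control samples
  egfCtrl <- cd$treatment == "control" & as.character(cd$stimulus) == "30"
  if (!any(egfCtrl))
    stop("no EGF-treated control samples in the design", call. = FALSE)
  low <- rowMeans(sig[, egfCtrl, drop = FALSE]) <= backgroundLevel
  if (any(low))
    log$background <- data.frame(probeset = rownames(sig)[low],
                                 gene = gene[low],
                                 rule = "below_background")
  sig <- sig[!low, , drop = FALSE]
  gene <- gene[!low]

  ## knockdown contrast per probeset: knockdown vs control over both stimuli
  d <- pairedDiffs(sig, cd, cd$treatment == "knockdown",
                   cd$treatment == "control")
  tt <- rowPairedT(d)

  ## rule 2: significant opposite-direction probesets exclude the gene
  sigUp <- tt$p < 0.05 & tt$effect > 0
  sigDn <- tt$p < 0.05 & tt$effect < 0
  badGenes <- intersect(unique(gene[sigUp]), unique(gene[sigDn]))
  if (length(badGenes)) {
    sel <- gene %in% badGenes
    log$opposite <- data.frame(probeset = rownames(sig)[sel],
                               gene = gene[sel],
                               rule = "opposite_directions")
    sig <- sig[!sel, , drop = FALSE]
    tt <- tt[!sel, , drop = FALSE]
    gene <- gene[!sel]
  }

  ## rule 3: keep the probeset with the largest absolute knockdown change
  ord <- order(gene, -abs(tt$effect), rownames(sig))
  keep <- !duplicated(gene[ord])
  keepIdx <- sort(ord[keep])
  dropIdx <- setdiff(seq_along(gene), keepIdx)
  if (length(dropIdx))
    log$multi <- data.frame(probeset = rownames(sig)[dropIdx],
                            gene = gene[dropIdx],
                            rule = "smaller_change")
  sig <- sig[keepIdx, , drop = FALSE]
  geneNames <- gene[keepIdx]
  rownames(sig) <- geneNames
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig),
    colData = SummarizedExperiment::colData(se))
  exclusions <- do.call(rbind, unname(log))
  if (is.null(exclusions))
    exclusions <- data.frame(probeset = character(), gene = character(),
                             rule = character())
  rownames(exclusions) <- NULL
  list(se = out, exclusions = exclusions,
       backgroundLevel = backgroundLevel)
}

#' Differential response by batch-paired t-tests
#'
#' Per gene and contrast, a paired t-test across batches with
#' Benjamini-Hochberg adjustment across genes within each contrast -- a
#' transparent stand-in for the moderated linear-model stage of array
#' pipelines (no empirical-Bayes shrinkage; the substitution is recorded
#' in the output's \code{method} attribute). Contrasts: knockdown effect
#' at 0 min, knockdown effect at 30 min (knockdown minus control), and the
#' stimulus effect in control cells (30 min minus 0 min).
#'
#' @param geneSe Gene-level \code{SummarizedExperiment} from
#'   \code{\link{collapseProbesets}}.
#' @param contrasts Which contrasts to compute (default all three).
#' @return data.frame: \code{gene}, \code{contrast}, \code{effect} (log10
#'   fold change), \code{p}, \code{q} (BH), \code{direction}
#'   (\code{up}/\code{down}); genes with zero paired variance get NA p and
#'   are flagged \code{degenerate}.
#' @export
differentialResponse <- function(geneSe,
                                 contrasts = c("knockdown_0",
                                               "knockdown_30", "egf")) {
  sig <- SummarizedExperiment::assay(geneSe, "signal")
  cd <- as.data.frame(SummarizedExperiment::colData(geneSe))
  stim <- as.character(cd$stimulus)
  sel <- list(
    knockdown_0 = list(hi = cd$treatment == "knockdown" & stim == "0",
                       lo = cd$treatment == "control" & stim == "0"),
    knockdown_30 = list(hi = cd$treatment == "knockdown" & stim == "30",
                        lo = cd$treatment == "control" & stim == "30"),
    egf = list(hi = cd$treatment == "control" & stim == "30",
               lo = cd$treatment == "control" & stim == "0"))
  out <- lapply(contrasts, function(ct) {
    s <- sel[[ct]]
    if (is.null(s)) stop("unknown contrast: ", ct, call. = FALSE)
    d <- pairedDiffs(sig, cd, s$hi, s$lo)
    tt <- rowPairedT(d)
    degenerate <- tt$sd == 0
    tt$p[degenerate] <- NA_real_
    q <- rep(NA_real_, nrow(tt))
    ok <- !is.na(tt$p)
    q[ok] <- p.adjust(tt$p[ok], method = "BH")
    data.frame(gene = rownames(sig), contrast = ct, effect = tt$effect,
               p = tt$p, q = q,
               direction = ifelse(tt$effect > 0, "up",
                                  ifelse(tt$effect < 0, "down", NA)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "method") <- "batch-paired t-test + BH (moderated-model stand-in)"
  res
}

#' Filter to regulated gene lists
#'
#' Retains genes with p below \code{pMax} and BH-adjusted q below
#' \code{qMax} (both thresholds required), partitioned by direction within
#' each contrast.
#'
#' @param results Output of \code{\link{differentialResponse}}.
#' @param pMax,qMax Thresholds (defaults 0.05 and 0.1).
#' @return Named list per contrast, each with \code{up} and \code{down}
#'   character vectors of genes.
#' @export
filterRegulated <- function(results, pMax = 0.05, qMax = 0.1) {
  keep <- !is.na(results$p) & results$p < pMax &
    !is.na(results$q) & results$q < qMax
  r <- results[keep, , drop = FALSE]
  out <- lapply(split(r, r$contrast), function(x) {
    list(up = x$gene[x$direction == "up"],
         down = x$gene[x$direction == "down"])
  })
  out[unique(results$contrast)]
}

#' Z-transform gene response profiles over the four conditions
#'
#' Per gene: the four condition means (control 0', control 30',
#' knockdown 0', knockdown 30', averaged over replicates) centred to mean
#' zero and scaled to unit sample (n-1) standard deviation. Genes with an
#' all-equal profile (zero sd) are excluded and reported.
#'
#' @param geneSe Gene-level \code{SummarizedExperiment}.
#' @return A list: \code{profiles} (genes x 4 matrix of z-scores) and
#'   \code{excluded} (character vector).
#' @examples
#' # (1,2,3,4) -> (-1.1619, -0.3873, 0.3873, 1.1619)
#' @export
zTransformProfiles <- function(geneSe) {
  sig <- SummarizedExperiment::assay(geneSe, "signal")
  cd <- as.data.frame(SummarizedExperiment::colData(geneSe))
  cond <- paste(cd$treatment, as.character(cd$stimulus), sep = "_")
  lev <- c("control_0", "control_30", "knockdown_0", "knockdown_30")
  if (!all(lev %in% cond))
    stop("design must contain all four conditions", call. = FALSE)
  means <- vapply(lev, function(cc)
    rowMeans(sig[, cond == cc, drop = FALSE]), numeric(nrow(sig)))
  m <- rowMeans(means)
  s <- apply(means, 1L, sd)
  excluded <- rownames(sig)[s == 0]
  keep <- s > 0
  z <- (means[keep, , drop = FALSE] - m[keep]) / s[keep]
  list(profiles = z, excluded = excluded)
}

#' K-means clustering of z-transformed profiles
#'
#' Euclidean k-means with \code{nRestarts} seeded random restarts, keeping
#' the solution with the lowest within-cluster sum of squares. Cluster
#' display order is obtained by average-linkage hierarchical clustering of
#' the cluster means, the standard way such panels are organised.
#' Deterministic for a given seed; a degenerate start that would leave an
#' empty cluster is re-drawn internally.
#'
#' @param profiles Genes x conditions matrix (from
#'   \code{\link{zTransformProfiles}}).
#' @param k Number of clusters (default 8).
#' @param seed Integer seed.
#' @param nRestarts Random restarts (default 20).
#' @return A list: \code{cluster} (named integer), \code{centers},
#'   \code{totWithinss}, \code{displayOrder}, \code{k}.
#' @export
kmeansCluster <- function(profiles, k = 8L, seed = 1L, nRestarts = 20L) {
  if (nrow(profiles) < k)
    stop("fewer profiles (", nrow(profiles), ") than clusters (", k, ")",
         call. = FALSE)
  fit <- withSeed(seed, {
    for (attempt in 1:5) {
      f <- tryCatch(kmeans(profiles, centers = k, nstart = nRestarts,
                           iter.max = 100L),
                    error = function(e) NULL)
      if (!is.null(f)) break
    }
    if (is.null(f))
      stop("k-means failed to find ", k, " non-empty clusters",
           call. = FALSE)
    f
  })
  ord <- hclust(dist(fit$centers), method = "average")$order
  list(cluster = setNames(as.integer(fit$cluster), rownames(profiles)),
       centers = fit$centers, totWithinss = fit$tot.withinss,
       displayOrder = ord, k = k)
}

#' Association between expression clusters and binding mode
#'
#' For each cluster, a 2x2 table of (gene in cluster vs not) against
#' (unique vs redundant binding mode), chi-square tested with the Fisher
#' fallback for sparse tables. Genes without a binding-mode label are
#' excluded and counted.
#'
#' @param cluster Named integer vector: gene -> cluster.
#' @param modes Named factor/character: gene -> \code{unique}/
#'   \code{redundant}.
#' @return A list: \code{perCluster} (data.frame: cluster, counts per
#'   mode, p, testUsed, oddsRatio), \code{table} (cluster x mode),
#'   \code{nUnlabelled}.
#' @export
clusterModeAssociation <- function(cluster, modes) {
  genes <- intersect(names(cluster), names(modes))
  nUnlabelled <- length(cluster) - length(genes)
  if (!length(genes)) stop("no clustered gene has a mode label",
                           call. = FALSE)
  cl <- cluster[genes]
  md <- as.character(modes[genes])
  ks <- sort(unique(cl))
  tab <- table(factor(cl, ks), factor(md, c("unique", "redundant")))
  per <- do.call(rbind, lapply(ks, function(kk) {
    m <- matrix(c(sum(cl == kk & md == "unique"),
                  sum(cl == kk & md == "redundant"),
                  sum(cl != kk & md == "unique"),
                  sum(cl != kk & md == "redundant")),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_cluster", "other_clusters"),
                                c("unique", "redundant")))
    r <- chisqOrFisher2x2(m)
    data.frame(cluster = kk, nUnique = m[1, 1], nRedundant = m[1, 2],
               p = r$p, testUsed = r$testUsed, oddsRatio = r$oddsRatio)
  }))
  rownames(per) <- NULL
  list(perCluster = per, table = tab, nUnlabelled = nUnlabelled)
}

#' Regulatory direction by binding mode
#'
#' Per contrast, the 2x2 split of up/down-regulated genes across the
#' unique/redundant modes, chi-square tested (Fisher for sparse tables).
#' In this system uniquely bound targets are predominantly down-regulated
#' by knockdown (the factor activates them) and redundantly bound targets
#' up-regulated.
#'
#' @param regulated Output of \code{\link{filterRegulated}}.
#' @param modes Named factor/character: gene -> mode.
#' @return Named list per contrast: \code{table} (direction x mode) and
#'   \code{result} (a \code{ContingencyResult}, or NULL when a margin is
#'   empty).
#' @export
directionModeSplit <- function(regulated, modes) {
  lapply(regulated, function(r) {
    up <- intersect(r$up, names(modes))
    down <- intersect(r$down, names(modes))
    tab <- matrix(c(sum(modes[up] == "unique"),
                    sum(modes[up] == "redundant"),
                    sum(modes[down] == "unique"),
                    sum(modes[down] == "redundant")),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("up", "down"),
                                  c("unique", "redundant")))
    res <- if (sum(tab) > 0 && all(rowSums(tab) + colSums(tab) >= 0))
      tryCatch(chisqOrFisher2x2(tab), error = function(e) NULL)
    else NULL
    list(table = tab, result = res)
  })
}
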