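#' Archetype response profiles over the 2x2 design
#'
#' The 8 archetypes are the sign combinations of three orthogonal contrast
#' vectors over the condition order (control 0', control 30', knockdown 0',
#' knockdown 30'): the knockdown main effect, the stimulus main effect and
#' their interaction, scaled by \code{amplitude}. After the per-gene
#' z-transform the archetypes map exactly onto 8 points at pairwise
#' Euclidean distance 2, which makes cluster recovery identifiable.
#' Archetypes 1-4 carry a positive knockdown contrast (expression drops on
#' knockdown: the factor activates); 5-8 the opposite.
#'
#' @param amplitude Contrast amplitude in log10 signal units.
#' @return An 8 x 4 numeric matrix (rows archetype, columns condition).
#' @export
archetypeProfiles <- function(amplitude = 0.4) {
  u1 <- c(1, 1, -1, -1) / 2   # + => higher in control => down on knockdown
  u2 <- c(1, -1, 1, -1) / 2   # + => higher at 0 min => down on stimulus
  u3 <- c(1, -1, -1, 1) / 2   # interaction
  signs <- as.matrix(expand.grid(s3 = c(1, -1), s2 = c(1, -1),
                                 s1 = c(1, -1)))[, 3:1]
  prof <- amplitude * (signs[, 1] %o% u1 + signs[, 2] %o% u2 +
                         signs[, 3] %o% u3)
  dimnames(prof) <- list(paste0("archetype", 1:8),
                         c("control_0", "control_30",
                           "knockdown_0", "knockdown_30"))
  prof
}

#' Simulate the probeset-level expression experiment
#'
#' Assigns every gene an archetype (or a flat, non-responsive profile):
#' genes bound by unique-class regions go preferentially to archetypes 2/4
#' (knockdown-down), redundant-class genes to 7/8 (knockdown-up), with
#' enrichment probability \code{clusterEnrichment}; a fraction of unbound
#' genes respond with a random archetype. Per-probeset log10 signals are
#' archetype condition mean + gene baseline + per-gene batch offset +
#' N(0, \code{noiseSd}) per measurement. The probeset layer deliberately
#' contains everything the collapsing rules must handle: multi-probeset
#' genes with a weaker secondary probeset, opposite-direction probeset
#' pairs, and probesets below the background signal level.
#'
#' @param truth Truth list carrying \code{regionMode} and \code{regionGene}
#'   (from \code{\link{simulatePeaks}}).
#' @param tss TSS annotation data.frame (defines the gene universe).
#' @param config A \code{\link{SimConfig}}.
#' @return A list with \code{se} (a \code{SummarizedExperiment}: assay
#'   \code{signal}, colData \code{treatment}, \code{stimulus}, \code{batch};
#'   rowData \code{gene}, \code{role}) and \code{truth} additions
#'   (\code{geneArchetype} 0--8 and \code{geneDirection} up/down/none,
#'   named by gene).
#' @export
simulateExpression <- function(truth, tss, config) {
  genes <- tss$gene
  nG <- length(genes)
  prof <- archetypeProfiles(config@archetypeAmplitude)
  withSeed(stageSeed(config@seed, "expression"), {
    arch <- setNames(integer(nG), genes)
    boundGene <- truth$regionGene
    boundMode <- truth$regionMode
    for (j in seq_along(boundGene)) {
      gn <- boundGene[j]
      pref <- if (boundMode[j] == "unique") c(2L, 4L) else c(7L, 8L)
      arch[gn] <- if (runif(1) < config@clusterEnrichment)
        sample(pref, 1L) else sample.int(8L, 1L)
    }
    unbound <- setdiff(genes, boundGene)
    resp <- unbound[runif(length(unbound)) < config@fracResponsiveUnbound]
    arch[resp] <- sample.int(8L, length(resp), replace = TRUE)

    direction <- rep("none", nG)
    direction[arch[genes] %in% 1:4] <- "down"
    direction[arch[genes] %in% 5:8] <- "up"
    direction <- setNames(direction, genes)

    ## probeset layout
    responsive <- genes[arch[genes] > 0L]
    multi <- responsive[runif(length(responsive)) < config@multiProbesetFrac]
    respUnbound <- intersect(responsive, unbound)
    oppo <- respUnbound[runif(length(respUnbound)) < config@oppositePairFrac]
    lowbg <- genes[runif(nG) < config@belowBackgroundFrac]
    probes <- data.frame(
      gene = c(genes, multi, oppo, lowbg),
      role = c(rep("main", nG), rep("secondary", length(multi)),
               rep("opposite", length(oppo)),
               rep("below_background", length(lowbg))),
      stringsAsFactors = FALSE)
    probes <- probes[order(probes$gene, probes$role), ]
    probes$probeset <- sprintf("PS%05d_at", seq_len(nrow(probes)))

    ## condition means per probeset
    base <- rnorm(nrow(probes), config@baselineMean, config@baselineSd)
    condMean <- matrix(rep(base, 4L), ncol = 4L)
    for (r in seq_len(nrow(probes))) {
      a <- arch[probes$gene[r]]
      if (a > 0L) {
        scale <- switch(probes$role[r], main = 1, secondary = 0.4,
                        opposite = -1, below_background = 0)
        condMean[r, ] <- condMean[r, ] + scale * prof[a, ]
      }
      if (probes$role[r] == "below_background")
        condMean[r, ] <- config@backgroundSignal
    }

    nR <- config@nReps
    design <- expand.grid(batch = seq_len(nR),
                          stimulus = c("0", "30"),
                          treatment = c("control", "knockdown"),
                          stringsAsFactors = FALSE)[, 3:1]
    sampleNames <- sprintf("%s_%s_b%d",
                           ifelse(design$treatment == "control", "ctrl", "kd"),
                           design$stimulus, design$batch)
    condIdx <- match(paste(design$treatment, design$stimulus, sep = "_"),
                     c("control_0", "control_30",
                       "knockdown_0", "knockdown_30"))
    batchOff <- matrix(rnorm(nrow(probes) * nR, 0, config@batchSd),
                       ncol = nR)
    sig <- condMean[, condIdx] + batchOff[, design$batch] +
      matrix(rnorm(nrow(probes) * nrow(design), 0, config@noiseSd),
             ncol = nrow(design))
    dimnames(sig) <- list(probes$probeset, sampleNames)

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(signal = sig),
      colData = DataFrame(treatment = design$treatment,
                          stimulus = design$stimulus,
                          batch = design$batch,
                          row.names = sampleNames),
      rowData = DataFrame(gene = probes$gene, role = probes$role,
                          row.names = probes$probeset))
    list(se = se,
         truth = list(geneArchetype = arch, geneDirection = direction,
                      oppositePairGenes = oppo))
  })
}
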