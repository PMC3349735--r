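## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L, ...) {
  simConfig(seed = seed, nUnique = 40L, nRedundant = 30L, nChrom = 2L,
            chromLength = 500000L, nGenes = 150L, ...)
}

smallBundle <- function() {
  if (is.null(.fixtures$smallBundle))
    .fixtures$smallBundle <- simulateBundle(smallConfig())
  .fixtures$smallBundle
}

## default ("study-scale") bundle and its full report, shared by the
## acceptance blocks
defaultBundle <- function() {
  if (is.null(.fixtures$defaultBundle))
    .fixtures$defaultBundle <- simulateBundle(simConfig(seed = 101L))
  .fixtures$defaultBundle
}

defaultReport <- function() {
  if (is.null(.fixtures$defaultReport))
    .fixtures$defaultReport <- runAll(defaultBundle())
  .fixtures$defaultReport
}

## A tiny expression experiment built by hand: per-probeset condition
## means (4-vector, order control_0 / control_30 / knockdown_0 /
## knockdown_30), constant across batches plus optional noise.
makeSe <- function(condMeans, genes, nReps = 3L, noiseSd = 0,
                   seed = 1L) {
  stopifnot(ncol(condMeans) == 4L, nrow(condMeans) == length(genes))
  design <- expand.grid(batch = seq_len(nReps),
                        stimulus = c("0", "30"),
                        treatment = c("control", "knockdown"),
                        stringsAsFactors = FALSE)[, 3:1]
  cond <- match(paste(design$treatment, design$stimulus, sep = "_"),
                c("control_0", "control_30", "knockdown_0",
                  "knockdown_30"))
  set.seed(seed)
  sig <- condMeans[, cond, drop = FALSE] +
    matrix(rnorm(nrow(condMeans) * nrow(design), 0, noiseSd),
           nrow = nrow(condMeans))
  rn <- sprintf("PS%03d", seq_len(nrow(condMeans)))
  colnames(sig) <- sprintf("%s_%s_b%d",
                           ifelse(design$treatment == "control", "c", "k"),
                           design$stimulus, design$batch)
  rownames(sig) <- rn
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = sig),
    colData = S4Vectors::DataFrame(treatment = design$treatment,
                                   stimulus = design$stimulus,
                                   batch = design$batch,
                                   row.names = colnames(sig)),
    rowData = S4Vectors::DataFrame(gene = genes, row.names = rn))
}

## small peak set from vectors (1-based closed coordinates)
makePeaks <- function(chrom, start, end, summit = NULL, fdr = 1,
                      name = "test", chromSizes = NULL) {
  n <- length(start)
  if (is.null(summit)) summit <- as.integer((start + end) / 2)
  PeakSet(data.frame(chrom = chrom, start = start, end = end,
                     summit = summit, score = rep_len(50L, n),
                     fdrPct = rep_len(fdr, n),
                     id = sprintf("%s_%03d", name, seq_len(n))),
          name = name, chromSizes = chromSizes)
}
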