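test_that("probeset collapsing applies the three rules in order", {
  ## gene G: +0.4 and +0.1 probesets -> keep the larger change
  ## gene H: +0.4 and -0.4 (both significant) -> excluded
  ## gene L: probeset at background in EGF-treated controls -> dropped
  cm <- rbind(c(3, 3, 3.4, 3.4),    # G main (+0.4 on knockdown)
              c(3, 3, 3.1, 3.1),    # G secondary (+0.1)
              c(3, 3, 3.4, 3.4),    # H up
              c(3, 3, 2.6, 2.6),    # H down
              c(3, 0.5, 3, 3),      # L: background at control 30'
              c(3, 3, 3, 3))        # M: flat reference
  se <- makeSe(cm, c("G", "G", "H", "H", "L", "M"), noiseSd = 0.01)
  out <- collapseProbesets(se, backgroundLevel = 1)
  expect_setequal(rownames(out$se), c("G", "M"))
  ## G keeps the large-change probeset
  gSig <- SummarizedExperiment::assay(out$se)["G", ]
  kd <- grepl("^k", names(gSig))
  expect_gt(mean(gSig[kd]) - mean(gSig[!kd]), 0.3)
  expect_setequal(out$exclusions$rule[out$exclusions$gene == "H"],
                  "opposite_directions")
  expect_true("below_background" %in%
                out$exclusions$rule[out$exclusions$gene == "L"])
  expect_true("smaller_change" %in%
                out$exclusions$rule[out$exclusions$gene == "G"])
})

test_that("differential response finds planted effects with analytic power", {
  ## planted log10 effect with 3 batch pairs and known noise: the
  ## detection rate must match the noncentral-t closed form
  nGenes <- 400L
  effect <- 0.3; noise <- 0.1
  cm <- cbind(3, 3, 3 + effect, 3 + effect)[rep(1, nGenes), ]
  se <- makeSe(cm, sprintf("G%03d", seq_len(nGenes)), noiseSd = noise,
               seed = 5)
  de <- differentialResponse(collapseProbesets(se, backgroundLevel = 0)$se)
  de0 <- de[de$contrast == "knockdown_0", ]
  hit <- mean(de0$p < 0.05)
  ## closed form: ncp = effect / (sd_diff / sqrt(nPairs)), df = nPairs - 1
  ncp <- effect / (sqrt(2) * noise / sqrt(3))
  power <- 1 - pt(qt(0.975, 2), 2, ncp) + pt(-qt(0.975, 2), 2, ncp)
  expect_lt(abs(hit - power), 4 * sqrt(power * (1 - power) / nGenes))
  expect_true(all(de0$direction[de0$p < 0.05] == "up"))
  ## effects are recovered without bias
  expect_lt(abs(mean(de0$effect) - effect), 0.01)
})

test_that("null genes are BH-controlled and degenerate genes flagged", {
  nGenes <- 300L
  cm <- matrix(3, nGenes, 4)
  se <- makeSe(cm, sprintf("N%03d", seq_len(nGenes)), noiseSd = 0.1,
               seed = 6)
  de <- differentialResponse(collapseProbesets(se, backgroundLevel = 0)$se)
  ## all-null data: q-values nearly never call positives
  expect_lt(sum(de$q < 0.1, na.rm = TRUE), 5)
  ## constant gene: zero paired variance -> NA p, flagged
  se2 <- makeSe(rbind(c(3, 3, 3, 3), c(3, 3, 4, 4)), c("A", "B"),
                noiseSd = 0)
  de2 <- differentialResponse(collapseProbesets(se2,
                                                backgroundLevel = 0)$se)
  a <- de2[de2$gene == "A" & de2$contrast == "knockdown_0", ]
  expect_true(a$degenerate)
  expect_true(is.na(a$p))
})

test_that("regulated filtering requires both thresholds", {
  res <- data.frame(gene = c("A", "B", "C"),
                    contrast = "knockdown_0",
                    effect = c(0.5, -0.5, 0.4),
                    p = c(0.04, 0.01, 0.2),
                    q = c(0.12, 0.05, 0.01),
                    direction = c("up", "down", "up"),
                    stringsAsFactors = FALSE)
  out <- filterRegulated(res)
  expect_identical(out$knockdown_0$down, "B")
  expect_length(out$knockdown_0$up, 0)   # A fails q, C fails p
  ## partition: no gene in both lists
  expect_length(intersect(out$knockdown_0$up, out$knockdown_0$down), 0)
})

test_that("z-transform centres, scales and excludes flat profiles", {
  se <- makeSe(rbind(c(1, 2, 3, 4), c(2, 2, 2, 2)), c("A", "B"))
  rownames(se) <- c("A", "B")
  z <- zTransformProfiles(se)
  expect_identical(z$excluded, "B")
  expect_equal(unname(z$profiles["A", ]),
               c(-1.161895, -0.3872983, 0.3872983, 1.161895),
               tolerance = 1e-6)
  expect_equal(mean(z$profiles["A", ]), 0, tolerance = 1e-9)
  expect_equal(sd(z$profiles["A", ]), 1, tolerance = 1e-9)
})

test_that("z-transform is equivariant under condition permutation", {
  set.seed(11)
  cm <- matrix(rnorm(40, 3, 0.5), 10, 4)
  genes <- sprintf("G%02d", 1:10)
  se <- makeSe(cm, genes)
  rownames(se) <- genes
  z1 <- zTransformProfiles(se)$profiles
  ## permute the four conditions by permuting the profile columns
  perm <- c(3, 1, 4, 2)
  seP <- makeSe(cm[, perm], genes)
  rownames(seP) <- genes
  z2 <- zTransformProfiles(seP)$profiles
  expect_equal(unname(z2), unname(z1[, perm]), tolerance = 1e-12)
})

test_that("k-means recovers separable archetypes and is deterministic", {
  prof <- archetypeProfiles(1)[c(1, 5), ]
  z <- prof[rep(1:2, each = 20), ] + 0
  rownames(z) <- sprintf("G%02d", 1:40)
  z <- t(apply(z, 1, function(x) (x - mean(x)) / sd(x)))
  km <- kmeansCluster(z, k = 2, seed = 4)
  expect_equal(ariOracle(km$cluster, rep(1:2, each = 20)), 1)
  km2 <- kmeansCluster(z, k = 2, seed = 4)
  expect_identical(km$cluster, km2$cluster)
  expect_error(kmeansCluster(z[1:5, ], k = 8), "fewer profiles")
  ## objective: best-of-restarts is a fixed point (reassignment stable)
  d2 <- as.matrix(dist(rbind(z, km$centers)))[1:40, 41:42]
  expect_identical(unname(apply(d2, 1, which.min)), unname(km$cluster))
})

test_that("cluster-mode association flags planted coupling", {
  set.seed(12)
  genes <- sprintf("G%03d", 1:300)
  modes <- setNames(rep(c("unique", "redundant"), c(150, 150)), genes)
  ## clusters 1/2 hold unique genes, 3/4 redundant, with some mixing
  cl <- setNames(c(sample(1:2, 150, TRUE, prob = c(0.45, 0.45)),
                   sample(3:4, 150, TRUE)), genes)
  mix <- sample(300, 30)
  cl[mix] <- sample(1:4, 30, TRUE)
  res <- clusterModeAssociation(cl, modes)
  expect_true(all(res$perCluster$p < 0.01))
  expect_equal(sum(res$table), 300)
  ## independent assignment: mostly non-significant
  clNull <- setNames(sample(1:4, 300, TRUE), genes)
  resNull <- clusterModeAssociation(clNull, modes)
  expect_gt(min(resNull$perCluster$p) * nrow(resNull$perCluster), 0.05)
})

test_that("direction-mode split exposes the planted regulation asymmetry", {
  b <- defaultBundle()
  conf <- intersectConfidence(b@rep1, b@rep2)
  modes <- classifyByOverlap(conf$high, b@comparator)
  a <- assignNearestTss(conf$high, b@tss)
  gm <- geneModeTable(a, modes)
  coll <- collapseProbesets(b@expression)
  reg <- filterRegulated(differentialResponse(coll$se))
  dms <- directionModeSplit(reg, gm)
  t30 <- dms$knockdown_30$table
  ## uniquely bound genes predominantly down, redundant predominantly up
  expect_gt(t30["down", "unique"], t30["down", "redundant"])
  expect_gt(t30["up", "redundant"], t30["up", "unique"])
  expect_lt(dms$knockdown_30$result$p, 1e-4)
  ## counts conserve: table total = regulated genes with labels
  lab <- sum(c(reg$knockdown_30$up, reg$knockdown_30$down) %in% names(gm))
  expect_equal(sum(t30), lab)
})

test_that("pipeline results ignore row and column order", {
  b <- smallBundle()
  se <- b@expression
  set.seed(13)
  seP <- se[sample(nrow(se)), sample(ncol(se))]
  r1 <- collapseProbesets(se)
  r2 <- collapseProbesets(seP)
  expect_setequal(rownames(r1$se), rownames(r2$se))
  d1 <- differentialResponse(r1$se)
  d2 <- differentialResponse(r2$se)
  d2 <- d2[match(paste(d1$gene, d1$contrast),
                 paste(d2$gene, d2$contrast)), ]
  expect_equal(d1$effect, d2$effect, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})
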