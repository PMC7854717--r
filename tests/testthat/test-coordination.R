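test_that("the df rule follows spot redundancy", {
  expect_equal(corDf(1), 2L)
  expect_equal(corDf(2), 6L)
  expect_equal(corDf(3), 10L)
  expect_equal(corDf(3, 2), 2L)   # unequal: spots averaged, 4 points
  expect_error(corDf(0), "domain error")
})

test_that("pairwiseCor pairs points within replicas and handles redundancy", {
  ## self-correlation is 1
  fs <- randomFabric(4, Rchoices = 2, seed = 80)
  pc <- pairwiseCor(fs, "g001", "g001", "LA")
  expect_equal(pc$rho, 1)
  expect_equal(pc$df, 4L * 2L - 2L)

  ## exact anti-linearity on the log2 scale
  fsLin <- toyFabric(list(a = matrix(rep(2^c(1, 2, 3, 4), 4), 1, 16),
                          b = matrix(rep(2^c(8, 6, 4, 2), 4), 1, 16)))
  pcLin <- pairwiseCor(fsLin, "a", "b", "LA")
  expect_equal(pcLin$rho, -1)
  expect_equal(pcLin$df, 2L)

  ## unequal redundancy: spots averaged per replica, df = 2
  fsMix <- randomFabric(4, Rchoices = 1, seed = 81)
  fsMix2 <- toyFabric(list(a = matrix(rlnorm(32), 2, 16),
                           b = matrix(rlnorm(16), 1, 16)))
  pcMix <- pairwiseCor(fsMix2, "a", "b", "LA")
  expect_equal(pcMix$df, 2L)
  va <- log2(colMeans(GenomicFabric:::.geneMatrix(fsMix2, "a", "LA")))
  vb <- log2(as.vector(GenomicFabric:::.geneMatrix(fsMix2, "b", "LA")))
  expect_equal(pcMix$rho, cor(va, vb), tolerance = 1e-12)

  ## zero variance -> undefined -> undecided
  fsZ <- toyFabric(list(a = matrix(2, 1, 16), b = matrix(rlnorm(16), 1, 16)))
  expect_true(is.na(pairwiseCor(fsZ, "a", "b", "LA")$rho))

  ## planted latent-factor correlation 0.99 recovered in >= 95% of sims
  set.seed(99)
  hits <- 0L; nSim <- 1000L
  for (i in seq_len(nSim)) {
    f <- rnorm(4)
    l <- sqrt(0.99)
    g1 <- l * f + sqrt(1 - l^2) * rnorm(4)
    g2 <- l * f + sqrt(1 - l^2) * rnorm(4)
    if (cor(g1, g2) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.95)
})

test_that("correlation significance matches the t reference", {
  expect_equal(corSignificance(0, 2), 1)
  expect_equal(corSignificance(1, 10), 0)
  expect_equal(corSignificance(-1, 2), 0)
  ## critical value: rho = 0.95 at df = 2 sits at p = 0.05
  expect_equal(corSignificance(0.95, 2), 0.05, tolerance = 1e-3)
  expect_equal(corSignificance(0.5, 10),
               2 * pt(-0.5 * sqrt(10 / 0.75), 10), tolerance = 1e-12)
})

test_that("significance ranks agree with a brute-force permutation test", {
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  set.seed(7)
  res <- t(replicate(100, {
    x <- rnorm(4); y <- rnorm(4)
    r0 <- abs(cor(x, y))
    pPerm <- mean(apply(perms, 1, function(pm)
      abs(cor(x, y[pm])) >= r0 - 1e-12))
    c(pPerm, corSignificance(cor(x, y), 2))
  }))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.9)
})

test_that("pairs classify into synergistic, antagonistic, independent, undecided", {
  expect_equal(classifyPair(0.999, corSignificance(0.999, 2)), "synergistic")
  expect_equal(classifyPair(-0.999, corSignificance(-0.999, 2)),
               "antagonistic")
  expect_equal(classifyPair(0.02, corSignificance(0.02, 2)), "independent")
  expect_equal(classifyPair(0.6, corSignificance(0.6, 2)), "undecided")
  expect_equal(classifyPair(NA_real_, NA_real_), "undecided")
})

test_that("edge enumeration is complete and tiling-independent", {
  fs <- randomFabric(12, Rchoices = 1:3, seed = 85)
  e <- coordinationEdges(fs, "LA")
  expect_equal(nrow(e), pairCount(12))
  ## per-pair recomputation matches the bulk path exactly
  for (i in sample(nrow(e), 20)) {
    pc <- pairwiseCor(fs, e$geneA[i], e$geneB[i], "LA")
    expect_equal(e$rho[i], pc$rho, tolerance = 1e-12)
    expect_equal(e$df[i], as.integer(pc$df))
  }
  ## synchrony evaluations: 4 adjacent pairings x n genes
  sy <- synchronyTable(fs)
  expect_equal(nrow(sy), crossChamberCount(12))

  ## full-transcriptome enumeration arithmetic
  expect_equal(pairCount(16866), 142222545)
  expect_equal(crossChamberCount(16866), 67464)
})

test_that("null pairs are significant at about the nominal 5% rate", {
  fs <- randomFabric(120, Rchoices = 1, seed = 90)
  e <- coordinationEdges(fs, "LA")
  sigFrac <- mean(e$category %in% c("synergistic", "antagonistic"))
  expect_gt(sigFrac, 0.02)
  expect_lt(sigFrac, 0.08)
})

test_that("synchrony pairs replicas by animal and detects planted in-phase genes", {
  ## identical per-animal profiles -> rho 1, synchronous
  v <- 2^c(1, 3, 2, 5)
  fsSame <- toyFabric(list(g = matrix(rep(v, 4), 1, 16)))
  s1 <- synchrony(fsSame, "g", "LA", "RA")
  expect_equal(s1$rho, 1)
  expect_true(s1$synchronous)
  ## per-animal profiles reversed across animals -> rho -1
  fsRev <- toyFabric(list(g = matrix(c(2^c(1, 2, 3, 4), rev(2^c(1, 2, 3, 4)),
                                       rep(1, 8)), 1, 16)))
  expect_equal(synchrony(fsRev, "g", "LA", "RA")$rho, -1)

  ## planted synchronous genes recovered with sensitivity >= 0.9 (20 seeds)
  sens <- vapply(1:20, function(sd_) {
    cfg <- simConfig(nGenes = 60, seed = 100 + sd_,
                     redundancyWeights = c("1" = 1), techCV = 0,
                     violationFraction = 0, corruptedFraction = 0,
                     plantedSynchrony = lapply(simGeneNames(30), function(g)
                       list(gene = g, chambers = c("LA", "RA"),
                            loading = 0.995)))
    fs <- fabricFromTruth(simulateFabric(cfg))
    sy <- synchronyTable(fs, pairs = list(c("LA", "RA")))
    mean(sy$synchronous[sy$gene %in% simGeneNames(30)])
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})

test_that("partner profiles report the synergistic percentage", {
  ## all partners perfectly co-varying -> 100%
  v <- 2^c(1, 2, 4, 3)
  fsAll <- toyFabric(list(hub = matrix(rep(v, 4), 1, 16),
                          p1 = matrix(rep(2 * v, 4), 1, 16),
                          p2 = matrix(rep(v^1.5, 4), 1, 16)))
  pp <- partnerProfile(fsAll, "hub", c("p1", "p2"), "LA")
  expect_equal(pp$percentSynergistic, 100)
  expect_equal(nrow(pp$edges), 2L)

  ## no quantified partner is an error
  expect_error(partnerProfile(fsAll, "hub", "absent", "LA"),
               "no quantified partner")

  ## 10 of 27 partners planted co-varying -> about 37% over seeds
  pct <- vapply(1:10, function(sd_) {
    cfg <- simConfig(nGenes = 28, seed = 200 + sd_,
                     redundancyWeights = c("1" = 1), techCV = 0,
                     violationFraction = 0, corruptedFraction = 0,
                     plantedModules = list(list(
                       genes = simGeneNames(11), chamber = "LA",
                       loading = 0.999)))
    fs <- fabricFromTruth(simulateFabric(cfg))
    partnerProfile(fs, "g00001", simGeneNames(28)[-1],
                   "LA")$percentSynergistic
  }, numeric(1))
  expect_gt(mean(pct), 30)
  expect_lt(mean(pct), 45)
})
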