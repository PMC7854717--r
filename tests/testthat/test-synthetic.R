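test_that("generation is deterministic and hash-stable under a fixed seed", {
  cfg <- simConfig(nGenes = 80, seed = 42)
  s1 <- simulateFabric(cfg)
  s2 <- simulateFabric(cfg)
  expect_identical(s1$spots, s2$spots)
  expect_identical(s1$truth$values, s2$truth$values)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(s1, d1); writeSimulation(s2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "expression.tsv"))),
                   unname(tools::md5sum(file.path(d2, "expression.tsv"))))
  ## a different seed changes the data
  s3 <- simulateFabric(simConfig(nGenes = 80, seed = 43))
  expect_false(identical(s1$spots$foreground, s3$spots$foreground))
})

test_that("zero-noise configurations are exactly deterministic", {
  cfg <- simConfig(nGenes = 30, seed = 1, bioCVRange = c(0, 0), techCV = 0,
                   violationFraction = 0, corruptedFraction = 0,
                   plantedDE = data.frame(gene = "g00007", ref = "LA",
                                          tgt = "LV", fold = 4,
                                          direction = 1,
                                          stringsAsFactors = FALSE))
  sim <- simulateFabric(cfg)
  fs <- normalizeSpots(filterSpots(sim$spots)$retained)
  ## all replicas equal -> REV vanishes for every gene (up to the
  ## floating-point residue of the per-sample scale division)
  suppressWarnings(summ <- fabricSummary(fs))
  expect_lt(max(summ$REV), 1e-9)
  suppressWarnings(summT <- fabricSummary(fabricFromTruth(sim)))
  expect_true(all(summT$REV == 0))
  ## planted fold recovered exactly
  expect_equal(expressionRatio(fs, "g00007", "LA", "LV"), 4)
  expect_equal(expressionRatio(fs, "g00007", "LV", "LA"), -4)
  expect_equal(expressionRatio(fs, "g00002", "LA", "LV"), 1)
})

test_that("planted genes must exist in the universe", {
  expect_error(simulateFabric(simConfig(nGenes = 10, plantedDE = data.frame(
    gene = "g99999", ref = "LA", tgt = "LV", fold = 2, direction = 1,
    stringsAsFactors = FALSE))), "config error")
  expect_error(simulateFabric(simConfig(nGenes = 10, plantedModules = list(
    list(genes = c("g00001", "gXX"), chamber = "LA", loading = 0.5)))),
    "config error")
})

test_that("empirical per-gene CV converges to the configured CV", {
  cfg <- simConfig(nGenes = 100, nReplicas = 100, chambers = "LA",
                   redundancyWeights = c("1" = 1), techCV = 0,
                   violationFraction = 0, corruptedFraction = 0,
                   bioCVRange = c(0.1, 0.4), seed = 8)
  sim <- simulateFabric(cfg)
  vals <- sim$truth$values
  empCV <- apply(vals, 1, sd) / rowMeans(vals)
  relErr <- abs(empCV / sim$truth$bioCV - 1)
  expect_lt(median(relErr), 0.10)
})

test_that("latent modules induce pairwise correlation close to loading^2", {
  loading <- 0.8
  cfg <- simConfig(nGenes = 8, nReplicas = 1000, chambers = "LA",
                   redundancyWeights = c("1" = 1), techCV = 0,
                   violationFraction = 0, corruptedFraction = 0,
                   bioCVRange = c(0.2, 0.2), seed = 9,
                   plantedModules = list(list(genes = simGeneNames(6),
                                              chamber = "LA",
                                              loading = loading)))
  sim <- simulateFabric(cfg)
  lv <- log(sim$truth$values[1:6, ])
  cc <- cor(t(lv))
  offDiag <- cc[upper.tri(cc)]
  ## Monte-Carlo error of r at n = 1000 and rho = 0.64 is about 0.019
  expect_lt(abs(mean(offDiag) - loading^2), 0.02)
  expect_true(all(abs(offDiag - loading^2) < 0.06))
  ## sign patterns flip the correlation
  cfg2 <- simConfig(nGenes = 4, nReplicas = 1000, chambers = "LA",
                    redundancyWeights = c("1" = 1), techCV = 0,
                    violationFraction = 0, corruptedFraction = 0,
                    bioCVRange = c(0.2, 0.2), seed = 10,
                    plantedModules = list(list(genes = simGeneNames(2),
                                               chamber = "LA",
                                               loading = loading,
                                               signs = c(1, -1))))
  sim2 <- simulateFabric(cfg2)
  lv2 <- log(sim2$truth$values[1:2, ])
  expect_lt(cor(lv2[1, ], lv2[2, ]), -loading^2 + 0.02)
})

test_that("configurations round-trip losslessly through YAML", {
  cfg <- simConfig(nGenes = 25, seed = 17,
                   redundancyWeights = c("1" = 0.6, "3" = 0.4),
                   bioCVRange = c(0.07, 0.33), techCV = 0.04,
                   plantedDE = data.frame(gene = "g00003", ref = "RA",
                                          tgt = "RV", fold = 2.5,
                                          direction = -1,
                                          stringsAsFactors = FALSE),
                   plantedModules = list(list(genes = simGeneNames(3),
                                              chamber = "LV",
                                              loading = 0.9)),
                   plantedSynchrony = list(list(gene = "g00009",
                                                chambers = c("LA", "RA"),
                                                loading = 0.75)))
  tf <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, tf)
  back <- readSimConfig(tf)
  for (sl in methods::slotNames("SimConfig"))
    expect_equal(methods::slot(back, sl), methods::slot(cfg, sl),
                 info = sl)
  ## and the generated data are identical
  expect_identical(simulateFabric(cfg)$spots, simulateFabric(back)$spots)
})
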