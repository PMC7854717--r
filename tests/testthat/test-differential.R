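test_that("expression ratio is signed, bounded away from (-1,1) and antisymmetric", {
  fs <- toyFabric(list(
    eq = matrix(2, 1, 16),
    up = matrix(rep(c(1, 1, 2, 1), each = 4), 1, 16)))  # LV = 2 x LA
  expect_equal(expressionRatio(fs, "eq", "LA", "RA"), 1)
  expect_equal(expressionRatio(fs, "up", "LA", "LV"), 2)
  expect_equal(expressionRatio(fs, "up", "LV", "LA"), -2)

  ## antisymmetry over many random genes (vectorized route)
  fs2 <- randomFabric(1000, Rchoices = 1:2, seed = 55)
  ab <- chamberComparison(fs2, "LA", "RA")
  ba <- chamberComparison(fs2, "RA", "LA")
  nontriv <- abs(ab$x) > 1
  expect_true(all(ab$x[nontriv] == -ba$x[nontriv]))
  expect_true(all(abs(ab$x) >= 1))
})

test_that("the adaptive cut-off combines both chambers' variabilities", {
  expect_equal(computeCUT(0, 0), 1)
  expect_equal(computeCUT(0.21, 0.21), 1.42)
  expect_equal(computeCUT(0.03, 0.04), 1 + sqrt(0.005))
  expect_equal(computeCUT(0.1, 0.3), computeCUT(0.3, 0.1))
  expect_error(computeCUT(-0.1, 0.2), "domain error")
})

test_that("the means test is the two-tail Welch t-test with degenerate guards", {
  fs <- randomFabric(10, Rchoices = 1:3, seed = 60)
  for (g in geneNames(fs)[1:5]) {
    va <- colMeans(GenomicFabric:::.geneMatrix(fs, g, "LA"))
    vb <- colMeans(GenomicFabric:::.geneMatrix(fs, g, "RV"))
    expect_equal(testMeans(fs, g, "LA", "RV"),
                 t.test(va, vb, var.equal = FALSE)$p.value,
                 tolerance = 1e-12)
  }
  ## identical replica vectors
  fsEq <- toyFabric(list(g = matrix(rep(c(1, 2, 3, 4), 4), 1, 16)))
  expect_equal(testMeans(fsEq, "g", "LA", "RA"), 1)
  ## constant but different: near-certain difference
  fsC <- toyFabric(list(g = matrix(rep(c(1, 1, 9, 9), each = 4), 1, 16)))
  expect_equal(testMeans(fsC, "g", "LA", "RA"), 1)   # both constant, equal
  expect_equal(testMeans(fsC, "g", "LA", "LV"), 0)   # both constant, unequal
  fsD <- toyFabric(list(g = matrix(c(rep(1, 4), rep(1, 4),
                                     9, 9, 9, 9.0001, rep(1, 4)), 1, 16)))
  expect_lt(testMeans(fsD, "g", "LA", "LV"), 0.001)
})

test_that("regulation calls gate on both the cut-off and the p-value", {
  expect_true(callRegulation(2.0, 1.42, 0.01)$regulated)
  expect_false(callRegulation(2.0, 2.5, 0.01)$regulated)
  expect_false(callRegulation(-3.0, 1.5, 0.2)$regulated)
})

test_that("WPR weights excess fold by reference AVE and confidence", {
  mkCalls <- function(x, CUT, p, ave, genes) {
    wpr <- ifelse(abs(x) > CUT, ave * (abs(x) - CUT) * (1 - p), 0)
    data.frame(gene = genes, comparison = "LA:RA", x = x, CUT = CUT,
               p = p, regulated = abs(x) > CUT & p < 0.05,
               wprTerm = wpr, stringsAsFactors = FALSE)
  }
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("solo\td\tgA", "pair\td\tgA\tgB"), gmt)
  gs <- readGeneSets(gmt)

  ## single-gene pathway: 100 x (2 - 1.5) x 0.99 = 49.5
  calls <- mkCalls(x = c(2, 1.2), CUT = c(1.5, 1.5), p = c(0.01, 0.01),
                   ave = c(100, 50), genes = c("gA", "gB"))
  pr <- pathwayRegulation(calls, gs)
  expect_equal(pr$WPR[pr$set == "solo"], 49.5)
  expect_equal(pr$WPR[pr$set == "pair"], 49.5 / 2)  # below-CUT member adds 0
  expect_equal(pr$percentRegulated[pr$set == "pair"], 50)

  ## member exactly at its cut-off contributes zero
  atCut <- mkCalls(2, 2, 0.01, 100, "gA")
  expect_equal(pathwayRegulation(atCut, gs)$WPR[1], 0)
  ## no member above CUT -> WPR 0
  none <- mkCalls(c(1.1, 1.2), 1.5, 0.01, c(100, 50), c("gA", "gB"))
  expect_equal(pathwayRegulation(none, gs)$WPR, c(0, 0))

  ## monotone non-decreasing in any member's |x|
  lo <- mkCalls(c(1.8, 1.2), 1.5, 0.01, c(100, 50), c("gA", "gB"))
  hi <- mkCalls(c(2.6, 1.2), 1.5, 0.01, c(100, 50), c("gA", "gB"))
  expect_gt(pathwayRegulation(hi, gs)$WPR[2],
            pathwayRegulation(lo, gs)$WPR[2])
})

test_that("the full comparison matches a brute-force spreadsheet oracle", {
  fs <- randomFabric(20, Rchoices = 1:3, seed = 77)
  summ <- fabricSummary(fs)
  got <- chamberComparison(fs, "LA", "LV", summary = summ)
  a <- SummarizedExperiment::assay(fs, "expr")
  rd <- SummarizedExperiment::rowData(fs)
  cd <- SummarizedExperiment::colData(fs)
  med <- attr(summ, "medianREV")
  for (g in geneNames(fs)) {
    rows <- which(rd$gene == g)
    R <- length(rows)
    oracle <- list()
    for (ch in c("LA", "LV")) {
      cols <- which(cd$chamber == ch)
      block <- a[rows, cols, drop = FALSE]
      mu <- apply(block, 1, mean)
      s <- apply(block, 1, sd)
      corr <- (sqrt((4 * R - 1) / qchisq(0.975, 4 * R - 1)) +
               sqrt((4 * R - 1) / qchisq(0.025, 4 * R - 1))) / 2
      oracle[[ch]] <- list(
        sumMu = sum(mu),
        rev = corr * sqrt(sum((s / mu)^2) / R),
        reps = colMeans(block))
    }
    x <- if (oracle$LV$sumMu >= oracle$LA$sumMu)
      oracle$LV$sumMu / oracle$LA$sumMu else
      -oracle$LA$sumMu / oracle$LV$sumMu
    CUT <- 1 + sqrt(2 * (oracle$LA$rev^2 + oracle$LV$rev^2))
    p <- t.test(oracle$LA$reps, oracle$LV$reps)$p.value
    row <- got[got$gene == g, ]
    expect_equal(row$x, x, tolerance = 1e-10)
    expect_equal(row$CUT, CUT, tolerance = 1e-10)
    expect_equal(row$p, p, tolerance = 1e-10)
    aveLA <- sum(apply(a[rows, cd$chamber == "LA", drop = FALSE], 1, mean)) / R
    wpr <- if (abs(x) > CUT) aveLA * (abs(x) - CUT) * (1 - p) else 0
    expect_equal(row$wprTerm, wpr, tolerance = 1e-10)
  }
})
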