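#' Signed expression ratio between two chambers
#'
#' Compares the sums over a gene's spot replica-means in the referred
#' chamber \code{B} against the reference chamber \code{A}:
#' the ratio B/A if B >= A, else the negative reciprocal -A/B, so
#' \code{|x| >= 1} always and \code{x} is negative when the gene is
#' down-regulated in \code{B} versus \code{A}. Antisymmetric:
#' \code{x(A,B) = -x(B,A)} (with the convention \code{x = 1} for exact
#' equality).
#'
#' @param fset a [FabricSet-class].
#' @param gene gene symbol.
#' @param chamberA reference chamber.
#' @param chamberB referred chamber.
#' @return signed ratio with \code{|x| >= 1}.
#' @export
expressionRatio <- function(fset, gene, chamberA, chamberB) {
  sumA <- sum(.spotStats(fset, gene, chamberA)$mu)
  sumB <- sum(.spotStats(fset, gene, chamberB)$mu)
  if (sumA <= 0 || sumB <= 0)
    stop("numeric error: non-positive expression sum for gene '", gene,
         "'", call. = FALSE)
  if (sumB >= sumA) sumB / sumA else -sumA / sumB
}

#' Per-gene adaptive fold-change cut-off (CUT)
#'
#' \deqn{CUT = 1 + \sqrt{2\,(rev_A^2 + rev_B^2)}}
#' where the REVs enter as fractions (percent / 100): a gene with 21\%
#' REV in both chambers gets CUT = 1.42. The cut-off grows with the
#' combined biological variability and technical noise of the gene in
#' the two compared chambers, replacing a uniform fold-change threshold.
#'
#' @param revA,revB relative expression variabilities of the gene in the
#'   two chambers, as fractions (e.g. 0.21 for 21\%).
#' @return CUT >= 1 (vectorized); 1 iff both REVs are 0; symmetric in
#'   its arguments.
#' @export
computeCUT <- function(revA, revB) {
  if (any(revA < 0) || any(revB < 0))
    stop("domain error: REV must be non-negative", call. = FALSE)
  1 + sqrt(2 * (revA^2 + revB^2))
}

#' Welch test of mean expression equality between two chambers
#'
#' Two-tail heteroscedastic (unequal-variance) two-sample t-test of the
#' gene's per-replica means (mean over the gene's spots within each
#' replica, linear scale) between the two chambers, via
#' \code{stats::t.test}. Replicas are treated as unpaired. When both
#' groups are constant the test degenerates: p = 1 for equal means,
#' p = 0 otherwise (the limit of the Welch statistic).
#'
#' @inheritParams expressionRatio
#' @param logScale test on log2 scale instead of linear (default FALSE).
#' @return two-tail p-value.
#' @export
testMeans <- function(fset, gene, chamberA, chamberB, logScale = FALSE) {
  va <- .replicaMeans(fset, gene, chamberA)
  vb <- .replicaMeans(fset, gene, chamberB)
  if (logScale) { va <- log2(va); vb <- log2(vb) }
  .welchP(va, vb)
}

## Welch p with degenerate-variance guards: t.test rejects (essentially)
## constant data, where the test's limit is p = 1 for equal means and
## p = 0 otherwise
.welchP <- function(va, vb) {
  tryCatch(stats::t.test(va, vb, var.equal = FALSE)$p.value,
           error = function(e)
             if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
}

#' Assemble a regulation call from its three statistics
#'
#' A gene is called regulated between two chambers when its absolute
#' expression ratio exceeds its per-gene cut-off and the Welch p-value
#' is below 0.05 (no multiple-testing correction, by design; see
#' [chamberComparison()] for an optional Benjamini-Hochberg flag).
#'
#' @param x signed expression ratio ([expressionRatio()]).
#' @param CUT adaptive cut-off ([computeCUT()]).
#' @param p Welch p-value ([testMeans()]).
#' @param alpha significance level (default 0.05).
#' @return a one-row data frame with columns \code{x}, \code{CUT},
#'   \code{p}, \code{regulated}.
#' @export
callRegulation <- function(x, CUT, p, alpha = 0.05) {
  data.frame(x = x, CUT = CUT, p = p,
             regulated = abs(x) > CUT & p < alpha)
}

#' Two-chamber differential expression over all genes
#'
#' For every gene, the signed expression ratio \code{x}, the adaptive
#' cut-off \code{CUT} (from the two chambers' REVs as fractions), the
#' Welch p-value, the regulation call (\code{|x| > CUT} and
#' \code{p < alpha}) and the weighted-regulation term
#' \code{wprTerm = AVE_A * (|x| - CUT) * (1 - p)} when \code{|x| > CUT},
#' else 0 (a gene exactly at its cut-off contributes 0).
#'
#' @param fset a [FabricSet-class].
#' @param chamberA reference chamber (denominator of the ratio).
#' @param chamberB referred chamber.
#' @param summary optional precomputed [fabricSummary()] (recomputed if
#'   omitted).
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment, \code{"none"} (default, matching
#'   the original procedure) or \code{"BH"}.
#' @param logScale pass to [testMeans()].
#' @return a data frame with one row per gene: \code{gene},
#'   \code{comparison}, \code{x}, \code{CUT}, \code{p},
#'   \code{regulated}, \code{wprTerm}.
#' @export
chamberComparison <- function(fset, chamberA, chamberB, summary = NULL,
                              alpha = 0.05, adjust = c("none", "BH"),
                              logScale = FALSE) {
  adjust <- match.arg(adjust)
  summary <- summary %||% fabricSummary(fset)
  genes <- geneNames(fset)
  sA <- summary[summary$chamber == chamberA, ]
  sB <- summary[summary$chamber == chamberB, ]
  revA <- sA$REV[match(genes, sA$gene)] / 100
  revB <- sB$REV[match(genes, sB$gene)] / 100
  aveA <- sA$AVE[match(genes, sA$gene)]
  if (anyNA(revA) || anyNA(revB))
    stop("chamber '", chamberA, "' or '", chamberB,
         "' missing from summary", call. = FALSE)
  ## vectorized per-replica gene means per chamber
  rmA <- .allReplicaMeans(fset, chamberA)
  rmB <- .allReplicaMeans(fset, chamberB)
  p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    va <- rmA[i, ]; vb <- rmB[i, ]
    if (logScale) p[i] <- .welchP(log2(va), log2(vb))
    else p[i] <- .welchP(va, vb)
  }
  muSumA <- rowSums(.allSpotMeans(fset, chamberA))
  muSumB <- rowSums(.allSpotMeans(fset, chamberB))
  x <- ifelse(muSumB >= muSumA, muSumB / muSumA, -muSumA / muSumB)
  CUT <- computeCUT(revA, revB)
  pUse <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  regulated <- abs(x) > CUT & pUse < alpha
  wprTerm <- ifelse(abs(x) > CUT, aveA * (abs(x) - CUT) * (1 - pUse), 0)
  data.frame(gene = genes,
             comparison = paste(chamberA, chamberB, sep = ":"),
             x = x, CUT = CUT, p = pUse, regulated = regulated,
             wprTerm = wprTerm, stringsAsFactors = FALSE)
}

## gene x replica matrix of spot-mean expression in one chamber
.allReplicaMeans <- function(fset, chamber) {
  rd <- SummarizedExperiment::rowData(fset)
  cd <- SummarizedExperiment::colData(fset)
  a <- SummarizedExperiment::assay(fset, "expr")
  genes <- unique(rd$gene)
  gf <- factor(rd$gene, levels = genes)
  reps <- replicas(fset)
  cols <- vapply(reps, function(r)
    which(cd$chamber == chamber & cd$replica == r)[1], integer(1))
  if (anyNA(cols))
    stop("missing replica sample(s) in chamber '", chamber, "'",
         call. = FALSE)
  m <- rowsum(a[, cols, drop = FALSE], gf) / as.vector(table(gf))
  rownames(m) <- genes
  colnames(m) <- reps
  m
}

## per-gene sum over spots of the spot replica-means mu_ik in one chamber
.allSpotMeans <- function(fset, chamber) {
  rd <- SummarizedExperiment::rowData(fset)
  cd <- SummarizedExperiment::colData(fset)
  a <- SummarizedExperiment::assay(fset, "expr")
  cols <- which(cd$chamber == chamber)
  mu <- rowMeans(a[, cols, drop = FALSE])
  genes <- unique(rd$gene)
  gf <- factor(rd$gene, levels = genes)
  m <- rowsum(mu, gf)
  rownames(m) <- genes
  m
}

#' Weighted pathway regulation (WPR) and percent regulated per gene set
#'
#' For each gene set, the arithmetic mean over its quantified members of
#' the per-gene weighted-regulation terms from [chamberComparison()]
#' (AVE-weighted excess fold over the adaptive cut-off, discounted by the
#' p-value), together with the percentage of members called regulated.
#' WPR is 0 iff no member exceeds its cut-off, and is monotone
#' non-decreasing in any member's \code{|x|}.
#'
#' @param calls output of [chamberComparison()].
#' @param geneSets a [GeneSets-class].
#' @return data frame with columns \code{set}, \code{comparison},
#'   \code{nQuantified}, \code{nMissing}, \code{percentRegulated},
#'   \code{WPR}.
#' @export
pathwayRegulation <- function(calls, geneSets) {
  stopifnot(methods::is(geneSets, "GeneSets"))
  rows <- list()
  for (nm in geneSetNames(geneSets)) {
    members <- geneSet(geneSets, nm)
    hit <- .matchSet(members, calls$gene)
    if (length(hit) == 0L)
      stop("empty-pathway error: no quantified member of '", nm, "'",
           call. = FALSE)
    sub <- calls[calls$gene %in% hit, ]
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, comparison = sub$comparison[1],
      nQuantified = nrow(sub), nMissing = length(members) - length(hit),
      percentRegulated = 100 * mean(sub$regulated),
      WPR = mean(sub$wprTerm), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
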