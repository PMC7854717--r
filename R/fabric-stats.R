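#' Chi-square redundancy correction coefficient for the pooled CV
#'
#' For a gene probed by \code{R} redundant spots across 4 biological
#' replicas, the pooled coefficient of variation is corrected by the
#' mid-interval chi-square factor
#' \deqn{\frac{1}{2}\left(\sqrt{r/\chi^2(r;0.975)} +
#'       \sqrt{r/\chi^2(r;0.025)}\right), \quad r = 4R - 1,}
#' where the two quantiles bound the central 95\% chi-square interval.
#' Because both terms are summed, swapping the tail-labeling convention
#' leaves the coefficient unchanged. The coefficient is > 1 for all
#' finite \code{R}, strictly decreasing in \code{R}, and tends to 1 as
#' \code{R} grows (about 2.1475 at R = 1 and 1.0391 at R = 13).
#'
#' @param R integer spot count(s), \code{R >= 1}.
#' @param nReplicas number of biological replicas (default 4).
#' @return numeric correction coefficient(s), each >= 1.
#' @export
chi2Correction <- function(R, nReplicas = 4) {
  if (any(R < 1) || any(R != floor(R)))
    stop("domain error: R must be a positive integer", call. = FALSE)
  r <- nReplicas * R - 1
  0.5 * (sqrt(r / stats::qchisq(0.975, df = r)) +
         sqrt(r / stats::qchisq(0.025, df = r)))
}

#' Average expression level (AVE) of one gene in one chamber
#'
#' The mean over a gene's redundant spots of each spot's replica-mean
#' expression, in median-gene units: AVE = 20 means the gene is expressed
#' twenty times higher than the median gene over all samples.
#'
#' @param fset a [FabricSet-class].
#' @param gene gene symbol.
#' @param chamber condition label.
#' @return positive scalar.
#' @seealso [fabricSummary()] for the vectorized all-genes version.
#' @export
computeAVE <- function(fset, gene, chamber) {
  st <- .spotStats(fset, gene, chamber)
  mean(st$mu)
}

#' Relative expression variability (REV) of one gene in one chamber
#'
#' The spot-pooled coefficient of variation across biological replicas,
#' \eqn{\sqrt{\frac{1}{R}\sum_k (s_k/\mu_k)^2}}, multiplied by the
#' chi-square redundancy correction ([chi2Correction()]) and expressed in
#' percent. REV is 0 exactly when every spot has zero replica variance,
#' and is invariant under multiplying all of the gene's values by a
#' constant.
#'
#' @inheritParams computeAVE
#' @return REV in percent (>= 0).
#' @export
computeREV <- function(fset, gene, chamber) {
  st <- .spotStats(fset, gene, chamber)
  if (any(st$mu <= 0))
    stop("numeric error: non-positive spot mean for gene '", gene, "'",
         call. = FALSE)
  pooled <- sqrt(mean((st$s / st$mu)^2))
  chi2Correction(length(st$mu), nReplicas = length(replicas(fset))) *
    pooled * 100
}

#' Relative expression control (REC) of one gene
#'
#' \code{REC = medianRevAll / rev - 1}. REC is 0 for a gene whose REV
#' equals the transcriptome-median REV; larger REC indicates tighter
#' homeostatic control of the gene's expression. A zero REV yields
#' \code{+Inf} with a warning (rankings use a capped sentinel instead;
#' see [fabricSummary()]).
#'
#' @param rev the gene's REV (percent).
#' @param medianRevAll transcriptome-median REV in the same chamber
#'   (percent).
#' @return dimensionless scalar > -1 (or \code{Inf} for \code{rev = 0}).
#' @export
computeREC <- function(rev, medianRevAll) {
  if (rev < 0 || medianRevAll < 0)
    stop("REV values must be non-negative", call. = FALSE)
  if (rev == 0) {
    warning("zero REV: REC reported as +Inf sentinel")
    return(Inf)
  }
  medianRevAll / rev - 1
}

#' Pathway relative expression control (PREC)
#'
#' \code{PREC = medianRevAll / median(revs) - 1}, the pathway analogue of
#' [computeREC()] using the median REV over the pathway's quantified
#' members. PREC of the whole transcriptome is 0 by construction.
#'
#' @param revs REV values (percent) of the pathway's quantified members.
#' @param medianRevAll transcriptome-median REV (percent).
#' @return dimensionless scalar > -1.
#' @export
computePREC <- function(revs, medianRevAll) {
  if (length(revs) == 0L)
    stop("empty-pathway error: no quantified member", call. = FALSE)
  m <- stats::median(revs)
  if (m == 0) {
    warning("zero median REV in pathway: PREC reported as +Inf sentinel")
    return(Inf)
  }
  medianRevAll / m - 1
}

#' Per-gene fabric summary: AVE, REV and REC for every gene and chamber
#'
#' Computes, for every gene in every chamber, the average expression
#' level (AVE, median-gene units), the chi-square corrected relative
#' expression variability (REV, percent) and the relative expression
#' control (REC). Genes with zero REV (possible only in degenerate
#' noise-free data) receive a capped REC sentinel equal to ten times the
#' largest finite REC in that chamber, with a warning, so that rankings
#' remain finite.
#'
#' @param fset a [FabricSet-class].
#' @return a data frame with columns \code{gene}, \code{chamber},
#'   \code{AVE}, \code{REV}, \code{REC}; the per-chamber median REV is
#'   attached as attribute \code{medianREV} (named numeric).
#' @export
fabricSummary <- function(fset) {
  rd <- SummarizedExperiment::rowData(fset)
  cd <- SummarizedExperiment::colData(fset)
  a <- SummarizedExperiment::assay(fset, "expr")
  genes <- unique(rd$gene)
  gf <- factor(rd$gene, levels = genes)
  Rn <- as.vector(table(gf))
  chams <- chambers(fset)
  nrep <- length(replicas(fset))
  out <- vector("list", length(chams))
  medianREV <- stats::setNames(numeric(length(chams)), chams)
  for (ci in seq_along(chams)) {
    cols <- which(cd$chamber == chams[ci])
    sub <- a[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- rowSums((sub - mu)^2) / (ncol(sub) - 1)
    ave <- as.vector(rowsum(mu, gf)) / Rn
    pooled <- sqrt(as.vector(rowsum(s2 / mu^2, gf)) / Rn)
    rev <- chi2Correction(Rn, nReplicas = nrep) * pooled * 100
    medAll <- stats::median(rev)
    rec <- medAll / rev - 1
    if (any(rev == 0)) {
      finiteMax <- suppressWarnings(max(rec[is.finite(rec)]))
      cap <- if (is.finite(finiteMax) && finiteMax > 0) finiteMax * 10 else 10
      warning(sum(rev == 0), " gene(s) with zero REV in chamber ",
              chams[ci], ": REC capped at sentinel ", cap)
      rec[rev == 0] <- cap
    }
    medianREV[ci] <- medAll
    out[[ci]] <- data.frame(gene = genes, chamber = chams[ci],
                            AVE = ave, REV = rev, REC = rec,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "medianREV") <- medianREV
  res
}

#' Pathway-level expression control (median REV and PREC)
#'
#' For each gene set and chamber, the median REV over the set's
#' quantified members and the pathway relative expression control
#' \code{PREC = medianREV_all / medianREV_set - 1}. Members absent from
#' the data are dropped (case-insensitive symbol matching) and counted in
#' \code{nMissing}.
#'
#' @param summary output of [fabricSummary()].
#' @param geneSets a [GeneSets-class] collection.
#' @return a data frame with columns \code{set}, \code{chamber},
#'   \code{nQuantified}, \code{nMissing}, \code{medianREV}, \code{PREC}.
#' @export
pathwayControl <- function(summary, geneSets) {
  stopifnot(methods::is(geneSets, "GeneSets"))
  medAll <- attr(summary, "medianREV")
  if (is.null(medAll))
    stop("summary must be the output of fabricSummary()", call. = FALSE)
  chams <- names(medAll)
  rows <- list()
  for (nm in geneSetNames(geneSets)) {
    members <- geneSet(geneSets, nm)
    for (ch in chams) {
      sub <- summary[summary$chamber == ch, ]
      hit <- .matchSet(members, sub$gene)
      if (length(hit) == 0L)
        stop("empty-pathway error: no quantified member of '", nm,
             "' in chamber ", ch, call. = FALSE)
      revs <- sub$REV[sub$gene %in% hit]
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, chamber = ch,
        nQuantified = length(hit), nMissing = length(members) - length(hit),
        medianREV = stats::median(revs),
        PREC = computePREC(revs, medAll[[ch]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
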