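#' Gene commanding height (GCH) score
#'
#' \deqn{GCH = (REC + 1)\,\exp(4\,\overline{\rho^2})}
#' combining how tightly a gene's expression is controlled (REC) with how
#' strongly it is coordinated with its partners (sign-blind mean of the
#' squared Pearson correlations). Bounded by \eqn{(REC+1)e^4}; equals 1
#' for a gene at baseline control with no coordination. Undefined
#' correlations (NA) are excluded from the mean.
#'
#' @param rec relative expression control of the gene (> -1).
#' @param rhos Pearson correlations with the partner genes (non-empty,
#'   each in [-1, 1]; NAs dropped).
#' @return positive scalar.
#' @export
computeGCH <- function(rec, rhos) {
  if (rec <= -1) stop("domain error: rec must be > -1", call. = FALSE)
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0L)
    stop("empty partner list (or all correlations undefined)",
         call. = FALSE)
  if (any(abs(rhos) > 1 + 1e-12))
    stop("domain error: |rho| must be <= 1", call. = FALSE)
  (rec + 1) * exp(4 * mean(pmin(rhos^2, 1)))
}

#' GCH scores and ranks for every gene in a chamber
#'
#' Computes each gene's REC (from [fabricSummary()]) and its mean
#' squared correlation over the partner universe (all other quantified
#' genes by default, or a restricted partner set), then the GCH score
#' and its descending rank. Ties are broken by higher REC, then by
#' gene symbol; the rank-1 gene is the chamber's gene master regulator
#' (GMR).
#'
#' @param fset a [FabricSet-class].
#' @param chamber condition label.
#' @param summary optional precomputed [fabricSummary()].
#' @param partners optional character vector restricting the partner
#'   universe (genes correlate with the partners other than themselves);
#'   default all quantified genes.
#' @return data frame ordered by rank: \code{gene}, \code{chamber},
#'   \code{REC}, \code{meanSqCor}, \code{GCH}, \code{rank}.
#' @export
gchTable <- function(fset, chamber, summary = NULL, partners = NULL) {
  summary <- summary %||% fabricSummary(fset)
  genes <- geneNames(fset)
  partners <- partners %||% genes
  partners <- .matchSet(partners, genes)
  universe <- union(genes, partners)
  cm <- .corMatrix(fset, chamber, universe)
  rho2 <- cm$rho^2
  diag(rho2) <- NA
  pidx <- match(partners, universe)
  meanSq <- vapply(seq_along(genes), function(i) {
    v <- rho2[match(genes[i], universe), pidx]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  nUndef <- sum(is.na(cm$rho[match(genes, universe), pidx]))
  if (nUndef > 0)
    warning(nUndef, " undefined partner correlation(s) excluded")
  sub <- summary[summary$chamber == chamber, ]
  rec <- sub$REC[match(genes, sub$gene)]
  gch <- (rec + 1) * exp(4 * meanSq)
  res <- data.frame(gene = genes, chamber = chamber, REC = rec,
                    meanSqCor = meanSq, GCH = gch,
                    stringsAsFactors = FALSE)
  rankGenes(res)
}

#' Rank genes by GCH
#'
#' Orders GCH records descending by score, breaking ties by higher REC
#' then lexicographic gene symbol, and assigns ranks 1..n. The rank-1
#' gene is the chamber's gene master regulator.
#'
#' @param records data frame with columns \code{gene}, \code{REC},
#'   \code{GCH} (e.g. from [gchTable()]).
#' @return the records ordered by rank with a \code{rank} column.
#' @export
rankGenes <- function(records) {
  ord <- order(-records$GCH, -records$REC, records$gene)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
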