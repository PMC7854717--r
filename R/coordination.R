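#' Degrees of freedom for the correlation significance test
#'
#' With \code{nReplicas} biological replicas and spot redundancies
#' \code{Ra}, \code{Rb} for the two correlated genes: when the
#' redundancies are equal (R), spots are paired within replicas and the
#' correlation uses all \code{nReplicas * R} points, so
#' \code{df = nReplicas * R - 2} (one spot: df = 2; two spots: df = 6;
#' three spots: df = 10). When the redundancies differ, each gene's spots
#' are averaged within every replica and only \code{nReplicas} points are
#' correlated, so \code{df = nReplicas - 2}.
#'
#' @param Ra,Rb integer spot counts of the two genes.
#' @param nReplicas number of biological replicas (default 4).
#' @return integer degrees of freedom.
#' @export
corDf <- function(Ra, Rb = Ra, nReplicas = 4) {
  if (any(Ra < 1) || any(Rb < 1))
    stop("domain error: spot counts must be >= 1", call. = FALSE)
  ifelse(Ra == Rb, nReplicas * Ra - 2L, nReplicas - 2L)
}

#' Pearson coordination of two genes within one chamber
#'
#' Correlates the log2 normalized expressions of two genes across
#' biological replicas. When both genes have the same spot redundancy R,
#' spots are paired in index order within replicas and all 4R points are
#' used (df = 4R - 2); with unequal redundancy each gene's spots are
#' averaged within every replica before taking log2, leaving 4 points
#' (df = 2).
#'
#' @param fset a [FabricSet-class].
#' @param geneA,geneB gene symbols.
#' @param chamber condition label.
#' @return list with \code{rho} (NA if either vector has zero variance),
#'   \code{df}.
#' @export
pairwiseCor <- function(fset, geneA, geneB, chamber) {
  ma <- .geneMatrix(fset, geneA, chamber)
  mb <- .geneMatrix(fset, geneB, chamber)
  nrep <- ncol(ma)
  if (nrow(ma) == nrow(mb)) {
    va <- log2(as.vector(ma))   # replica-major, spots in index order
    vb <- log2(as.vector(mb))
    df <- nrep * nrow(ma) - 2L
  } else {
    va <- log2(colMeans(ma))
    vb <- log2(colMeans(mb))
    df <- nrep - 2L
  }
  rho <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
         else stats::cor(va, vb)
  list(rho = rho, df = df)
}

#' Two-tail significance of a Pearson correlation
#'
#' Refers \eqn{t = \rho\sqrt{df/(1-\rho^2)}} to the t distribution with
#' \code{df} degrees of freedom, two-tail. \code{|rho| = 1} gives p = 0;
#' an undefined correlation (NA) propagates.
#'
#' @param rho Pearson coefficient(s) in [-1, 1].
#' @param df degrees of freedom (>= 1); see [corDf()].
#' @return two-tail p-value(s).
#' @export
corSignificance <- function(rho, df) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("domain error: |rho| must be <= 1", call. = FALSE)
  if (any(df < 1)) stop("domain error: df must be >= 1", call. = FALSE)
  rho <- pmin(pmax(rho, -1), 1)
  p <- ifelse(abs(rho) >= 1, 0,
              2 * stats::pt(-abs(rho) * sqrt(df / (1 - rho^2)), df))
  p
}

#' Classify a gene pair's coordination
#'
#' Significantly positive correlations (p < alpha, rho > 0) are
#' synergistic; significantly negative ones antagonistic; correlations
#' inside the independence band (\code{|rho| <= band}, default 0.05) are
#' independent; everything else — non-significant but not near zero —
#' is undecided, never counted as independent. Undefined correlations
#' (NA rho) are undecided.
#'
#' @param rho Pearson coefficient(s).
#' @param p two-tail p-value(s) from [corSignificance()].
#' @param independenceBand half-width of the near-zero band (default
#'   0.05).
#' @param alpha significance level (default 0.05).
#' @return character vector: \code{"synergistic"},
#'   \code{"antagonistic"}, \code{"independent"} or \code{"undecided"}.
#' @export
classifyPair <- function(rho, p, independenceBand = 0.05, alpha = 0.05) {
  out <- rep("undecided", length(rho))
  sig <- !is.na(rho) & !is.na(p) & p < alpha
  out[sig & rho > 0] <- "synergistic"
  out[sig & rho < 0] <- "antagonistic"
  out[!sig & !is.na(rho) & abs(rho) <= independenceBand] <- "independent"
  out
}

## full n x n correlation and df matrices for the genes of one chamber:
## same-redundancy pairs use spot-paired stacked points (df = 4R - 2),
## mixed-redundancy pairs use per-replica spot averages (df = 2).
.corMatrix <- function(fset, chamber, genes = NULL) {
  genes <- genes %||% geneNames(fset)
  rd <- SummarizedExperiment::rowData(fset)
  cd <- SummarizedExperiment::colData(fset)
  a <- SummarizedExperiment::assay(fset, "expr")
  reps <- replicas(fset)
  nrep <- length(reps)
  cols <- vapply(reps, function(r)
    which(cd$chamber == chamber & cd$replica == r)[1], integer(1))
  if (anyNA(cols))
    stop("missing replica sample(s) in chamber '", chamber, "'",
         call. = FALSE)
  sub <- a[, cols, drop = FALSE]
  gidx <- lapply(genes, function(g) which(rd$gene == g))
  if (any(lengths(gidx) == 0L))
    stop("gene(s) not present: ",
         paste(genes[lengths(gidx) == 0L], collapse = ", "), call. = FALSE)
  R <- lengths(gidx)
  n <- length(genes)
  ## averaged 4-point matrix (log2 of per-replica spot means)
  avg <- vapply(gidx, function(ix) log2(colMeans(sub[ix, , drop = FALSE])),
                numeric(nrep))
  rhoM <- suppressWarnings(stats::cor(avg))
  dfM <- matrix(nrep - 2L, n, n)
  for (r in unique(R)) {
    idx <- which(R == r)
    ## stacked 4R-point matrix, replica-major with spots in index order
    ## (column-major flattening of the spots x replicas block)
    X <- vapply(gidx[idx], function(ix)
      log2(as.vector(sub[ix, , drop = FALSE])), numeric(nrep * r))
    rhoM[idx, idx] <- suppressWarnings(stats::cor(X))
    dfM[idx, idx] <- nrep * r - 2L
  }
  dimnames(rhoM) <- list(genes, genes)
  dimnames(dfM) <- list(genes, genes)
  list(rho = rhoM, df = dfM)
}

#' All-pairs coordination edges within a chamber
#'
#' Enumerates every unordered pair among the selected genes (all
#' quantified genes by default), yielding exactly n(n-1)/2 edges, each
#' with its Pearson rho, degrees of freedom per the redundancy rule
#' ([corDf()]), two-tail p-value and coordination class. Results are
#' deterministic and identical whether computed in one pass or per pair
#' via [pairwiseCor()].
#'
#' @param fset a [FabricSet-class].
#' @param chamber condition label.
#' @param genes optional gene subset (default all quantified genes).
#' @param independenceBand,alpha passed to [classifyPair()].
#' @return data frame with columns \code{geneA}, \code{geneB},
#'   \code{chamber}, \code{rho}, \code{df}, \code{p}, \code{category}.
#' @export
coordinationEdges <- function(fset, chamber, genes = NULL,
                              independenceBand = 0.05, alpha = 0.05) {
  genes <- genes %||% geneNames(fset)
  cm <- .corMatrix(fset, chamber, genes)
  n <- length(genes)
  if (n < 2L) stop("need at least two genes", call. = FALSE)
  ut <- which(upper.tri(cm$rho), arr.ind = TRUE)
  rho <- cm$rho[ut]
  df <- cm$df[ut]
  nUndef <- sum(is.na(rho))
  if (nUndef > 0)
    warning(nUndef, " pair(s) with undefined correlation ",
            "(zero variance); classified undecided")
  p <- ifelse(is.na(rho), NA_real_, corSignificance(rho, df))
  data.frame(geneA = genes[ut[, 1]], geneB = genes[ut[, 2]],
             chamber = chamber, rho = rho, df = as.integer(df), p = p,
             category = classifyPair(rho, p, independenceBand, alpha),
             stringsAsFactors = FALSE)
}

#' Cross-chamber expression synchrony of one gene
#'
#' Correlates a gene's log2 expression in two chambers across biological
#' replicas, paired by animal and by spot (the gene's redundancy is the
#' same in both chambers, so all 4R points are paired; df = 4R - 2).
#' The gene is synchronous in the two chambers when the pair is
#' classified synergistic.
#'
#' @param fset a [FabricSet-class].
#' @param gene gene symbol.
#' @param chamberA,chamberB the two chambers.
#' @param independenceBand,alpha passed to [classifyPair()].
#' @return one-row data frame: \code{gene}, \code{chamberA},
#'   \code{chamberB}, \code{rho}, \code{df}, \code{p}, \code{category},
#'   \code{synchronous}.
#' @export
synchrony <- function(fset, gene, chamberA, chamberB,
                      independenceBand = 0.05, alpha = 0.05) {
  ma <- .geneMatrix(fset, gene, chamberA)
  mb <- .geneMatrix(fset, gene, chamberB)
  if (!identical(dim(ma), dim(mb)) ||
      !identical(colnames(ma), colnames(mb)))
    stop("integrity error: replicas not pairable between chambers",
         call. = FALSE)
  va <- log2(as.vector(ma))
  vb <- log2(as.vector(mb))
  df <- length(va) - 2L
  rho <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
         else stats::cor(va, vb)
  p <- if (is.na(rho)) NA_real_ else corSignificance(rho, df)
  cat_ <- classifyPair(rho, p, independenceBand, alpha)
  data.frame(gene = gene, chamberA = chamberA, chamberB = chamberB,
             rho = rho, df = df, p = p, category = cat_,
             synchronous = identical(cat_, "synergistic"),
             stringsAsFactors = FALSE)
}

#' Synchrony of every gene across chamber pairings
#'
#' Evaluates [synchrony()] for every quantified gene over each requested
#' chamber pairing. For the canonical four-chamber design the default
#' pairings are the four adjacent ones: LA-RA, LV-RV, LA-LV and RA-RV,
#' giving 4n evaluations for n genes.
#'
#' @param fset a [FabricSet-class].
#' @param pairs list of length-2 character vectors of chamber labels;
#'   default the four adjacent pairings when the chambers are
#'   LA, RA, LV, RV, otherwise all unordered chamber pairs.
#' @param independenceBand,alpha passed to [classifyPair()].
#' @return data frame, one row per gene per pairing.
#' @export
synchronyTable <- function(fset, pairs = NULL, independenceBand = 0.05,
                           alpha = 0.05) {
  ch <- chambers(fset)
  if (is.null(pairs)) {
    if (setequal(ch, c("LA", "RA", "LV", "RV")))
      pairs <- list(c("LA", "RA"), c("LV", "RV"),
                    c("LA", "LV"), c("RA", "RV"))
    else {
      cmb <- utils::combn(ch, 2)
      pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }
  }
  rows <- list()
  for (pr in pairs)
    for (g in geneNames(fset))
      rows[[length(rows) + 1L]] <-
        synchrony(fset, g, pr[1], pr[2], independenceBand, alpha)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Synergistic-partner profile of a hub gene
#'
#' Classifies the coordination of a hub gene with each quantified
#' partner in one chamber and reports the percentage of partners
#' classified synergistic, e.g. a hub synergistically expressed with 10
#' of 27 quantified partners scores 37\%. Partner symbols are matched
#' case-insensitively.
#'
#' @param fset a [FabricSet-class].
#' @param hub hub gene symbol (must be quantified).
#' @param partners character vector of partner symbols.
#' @param chamber condition label.
#' @param independenceBand,alpha passed to [classifyPair()].
#' @return list with \code{percentSynergistic} and \code{edges}, a data
#'   frame with one row per quantified partner.
#' @export
partnerProfile <- function(fset, hub, partners, chamber,
                           independenceBand = 0.05, alpha = 0.05) {
  genes <- geneNames(fset)
  if (!hub %in% genes)
    stop("hub gene '", hub, "' not quantified", call. = FALSE)
  hit <- .matchSet(partners, genes)
  hit <- setdiff(hit, hub)
  if (length(hit) == 0L)
    stop("no quantified partner of '", hub, "'", call. = FALSE)
  rows <- lapply(hit, function(g) {
    pc <- pairwiseCor(fset, hub, g, chamber)
    p <- if (is.na(pc$rho)) NA_real_ else corSignificance(pc$rho, pc$df)
    data.frame(hub = hub, partner = g, chamber = chamber, rho = pc$rho,
               df = pc$df, p = p,
               category = classifyPair(pc$rho, p, independenceBand, alpha),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  list(percentSynergistic = 100 * mean(edges$category == "synergistic"),
       edges = edges)
}

#' Pair-enumeration arithmetic
#'
#' \code{pairCount(n)} is the number of unordered gene pairs n(n-1)/2
#' evaluated by the all-pairs coordination analysis;
#' \code{crossChamberCount(n, nPairings)} the number of same-gene
#' cross-chamber synchrony evaluations over the adjacent chamber
#' pairings (default 4).
#'
#' @param n number of quantified genes.
#' @param nPairings number of chamber pairings (default 4).
#' @return a count (double, exact for counts below 2^53).
#' @export
pairCount <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' @rdname pairCount
#' @export
crossChamberCount <- function(n, nPairings = 4) {
  as.numeric(n) * nPairings
}
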