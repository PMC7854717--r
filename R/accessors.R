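#' Construct a FabricSet from a spot-by-sample expression matrix
#'
#' Low-level constructor used by [normalizeSpots()] and by tests. Most
#' users should build a \code{FabricSet} from raw measurements via
#' [readExpressionTable()], [filterSpots()] and [normalizeSpots()].
#'
#' @param expr numeric matrix, rows = spots, columns = samples, strictly
#'   positive, no missing values.
#' @param gene character vector of gene symbols, one per row.
#' @param spotId character vector of unique spot identifiers, one per row.
#' @param chamber,replica character vectors, one per column, giving each
#'   sample's condition label and replica (animal) label.
#' @return a validated [FabricSet-class] object.
#' @export
FabricSet <- function(expr, gene, spotId, chamber, replica) {
  expr <- as.matrix(expr)
  stopifnot(length(gene) == nrow(expr), length(spotId) == nrow(expr),
            length(chamber) == ncol(expr), length(replica) == ncol(expr))
  rownames(expr) <- spotId
  colnames(expr) <- paste(chamber, replica, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    rowData = S4Vectors::DataFrame(gene = as.character(gene),
                                   spot_id = as.character(spotId)),
    colData = S4Vectors::DataFrame(chamber = as.character(chamber),
                                   replica = as.character(replica),
                                   row.names = colnames(expr)))
  methods::new("FabricSet", se)
}

#' Accessors for FabricSet objects
#'
#' \code{geneNames} returns the unique gene symbols (in order of first
#' appearance); \code{chambers} and \code{replicas} the ordered condition
#' and replica labels; \code{redundancy} the per-gene spot count
#' \eqn{R_i} as a named integer vector.
#'
#' @param x a [FabricSet-class].
#' @param ... unused.
#' @name FabricSet-accessors
NULL

#' @rdname FabricSet-accessors
#' @export
setMethod("geneNames", "FabricSet", function(x, ...) {
  unique(SummarizedExperiment::rowData(x)$gene)
})

#' @rdname FabricSet-accessors
#' @export
setMethod("chambers", "FabricSet", function(x, ...) {
  unique(SummarizedExperiment::colData(x)$chamber)
})

#' @rdname FabricSet-accessors
#' @export
setMethod("replicas", "FabricSet", function(x, ...) {
  unique(SummarizedExperiment::colData(x)$replica)
})

#' @rdname FabricSet-accessors
#' @export
setMethod("redundancy", "FabricSet", function(x, ...) {
  g <- SummarizedExperiment::rowData(x)$gene
  tab <- table(factor(g, levels = unique(g)))
  stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "FabricSet", function(object) {
  g <- SummarizedExperiment::rowData(object)$gene
  cat("FabricSet with", length(unique(g)), "genes on", nrow(object),
      "spots\n")
  cat("  chambers:", paste(chambers(object), collapse = ", "), "\n")
  cat("  replicas:", paste(replicas(object), collapse = ", "), "\n")
  r <- redundancy(object)
  cat("  spot redundancy: ", min(r), "-", max(r), " spots per gene\n",
      sep = "")
})

## ---- internal extraction helpers ----

## spot x replica matrix of one gene in one chamber (spots in spot_id order
## of first appearance; replicas in the object's replica order)
.geneMatrix <- function(fset, gene, chamber) {
  rd <- SummarizedExperiment::rowData(fset)
  cd <- SummarizedExperiment::colData(fset)
  ri <- which(rd$gene == gene)
  if (length(ri) == 0L)
    stop("gene '", gene, "' not present in FabricSet", call. = FALSE)
  reps <- replicas(fset)
  ci <- vapply(reps, function(r)
    which(cd$chamber == chamber & cd$replica == r)[1], integer(1))
  if (anyNA(ci))
    stop("missing replica sample(s) for chamber '", chamber, "'",
         call. = FALSE)
  m <- SummarizedExperiment::assay(fset, "expr")[ri, ci, drop = FALSE]
  dimnames(m) <- list(rd$spot_id[ri], reps)
  m
}

## per-replica means over a gene's spots (length = number of replicas)
.replicaMeans <- function(fset, gene, chamber) {
  colMeans(.geneMatrix(fset, gene, chamber))
}

## per-spot mean and sd across replicas (mu_ik, s_ik)
.spotStats <- function(fset, gene, chamber) {
  m <- .geneMatrix(fset, gene, chamber)
  list(mu = rowMeans(m), s = apply(m, 1, stats::sd))
}

#' Accessors for GeneSets objects
#'
#' \code{geneSetNames} returns the set names; \code{geneSet} the member
#' symbols of one named set; \code{length} the number of sets.
#'
#' @param x a [GeneSets-class].
#' @param name a set name.
#' @name GeneSets-accessors
NULL

#' @rdname GeneSets-accessors
#' @export
setMethod("geneSetNames", "GeneSets", function(x) names(x@sets))

#' @rdname GeneSets-accessors
#' @export
setMethod("geneSet", "GeneSets", function(x, name) {
  if (!name %in% names(x@sets))
    stop("no gene set named '", name, "'", call. = FALSE)
  x@sets[[name]]
})

#' @rdname GeneSets-accessors
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets collection of", length(object@sets), "sets\n")
  if (length(object@sets)) {
    n <- lengths(object@sets)
    info <- paste0(names(object@sets), " (", n, ")")
    cat(" ", paste(utils::head(info, 8), collapse = ", "),
        if (length(info) > 8) ", ..." else "", "\n", sep = "")
  }
})
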