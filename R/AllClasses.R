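#' FabricSet: container for a normalized, replicated, spot-redundant
#' expression experiment
#'
#' A \code{FabricSet} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} with the
#' structure of a multi-condition, replicated experiment in which each gene
#' may be probed by several redundant spots. Rows are spots, columns are
#' condition ("chamber") x replica samples, and the single assay
#' \code{"expr"} holds normalized expression values in median-gene units
#' (the median gene over all genes and samples is 1).
#'
#' Row metadata must carry \code{gene} (symbol) and \code{spot_id};
#' column metadata must carry \code{chamber} and \code{replica}. The
#' object is complete by construction: every spot has a strictly positive
#' value in every sample.
#'
#' @slot .. see \code{SummarizedExperiment}; no additional slots.
#' @seealso [normalizeSpots()] which builds a \code{FabricSet} from
#'   filtered spot measurements, [fabricSummary()], [chamberComparison()],
#'   [coordinationEdges()], [gchTable()].
#' @export
setClass("FabricSet", contains = "SummarizedExperiment")

.validFabricSet <- function(object) {
  msg <- character()
  if (!("expr" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'expr' is required")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("gene", "spot_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene' and 'spot_id'")
  if (!all(c("chamber", "replica") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'chamber' and 'replica'")
  if (length(msg) == 0L) {
    a <- SummarizedExperiment::assay(object, "expr")
    if (anyNA(a))
      msg <- c(msg, "expression values must be complete (no NA)")
    else if (any(a <= 0))
      msg <- c(msg, "expression values must be strictly positive")
    if (anyDuplicated(paste(cd$chamber, cd$replica)))
      msg <- c(msg, "duplicate chamber x replica samples")
    if (anyDuplicated(rd$spot_id))
      msg <- c(msg, "duplicate spot_id")
  }
  if (length(msg)) msg else TRUE
}

setValidity("FabricSet", .validFabricSet)

#' GeneSets: a collection of named gene sets (pathways)
#'
#' Holds named member lists such as KEGG pathway gene lists read from a
#' GMT file. Set names are unique and member lists non-empty; duplicate
#' member symbols are collapsed. Matching against expression data is
#' case-insensitive (mouse symbol capitalization varies across exports).
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot descriptions named character vector (GMT description field).
#' @seealso [readGeneSets()], [pathwayControl()], [pathwayRegulation()]
#' @export
setClass("GeneSets",
  representation(sets = "list", descriptions = "character"),
  prototype(sets = list(), descriptions = character()))

.validGeneSets <- function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "set names must be present and unique")
    if (any(lengths(s) == 0L))
      msg <- c(msg, "every set must have at least one member")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "set members must be character vectors")
  }
  if (length(msg)) msg else TRUE
}

setValidity("GeneSets", .validGeneSets)

#' SimConfig: configuration for the synthetic-experiment generator
#'
#' Describes a replica-structured, spot-redundant, multi-condition
#' expression experiment with planted ground truth: log-normal baseline
#' gene means (median-normalized), per-gene biological CV, technical spot
#' noise, planted between-condition fold changes, planted within-chamber
#' correlation modules (single shared latent factor per module, so the
#' pairwise log-scale correlation equals loading^2), and planted
#' cross-chamber synchrony. See [simConfig()] for field semantics and
#' defaults.
#'
#' @seealso [simConfig()], [simulateFabric()], [writeSimConfig()]
#' @export
setClass("SimConfig",
  representation(
    nGenes            = "integer",
    redundancyWeights = "numeric",
    chambers          = "character",
    nReplicas         = "integer",
    baselineSdlog     = "numeric",
    bioCVRange        = "numeric",
    techCV            = "numeric",
    plantedDE         = "data.frame",
    plantedModules    = "list",
    plantedSynchrony  = "list",
    violationFraction = "numeric",
    corruptedFraction = "numeric",
    seed              = "integer"
  ))

.validSimConfig <- function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  w <- object@redundancyWeights
  if (is.null(names(w)) || any(is.na(suppressWarnings(as.integer(names(w))))))
    msg <- c(msg, "redundancyWeights must be named by integer spot counts")
  else if (any(as.integer(names(w)) < 1L))
    msg <- c(msg, "redundancy spot counts must be >= 1")
  if (any(w < 0) || sum(w) <= 0)
    msg <- c(msg, "redundancyWeights must be non-negative and sum > 0")
  if (length(object@chambers) < 1L || anyDuplicated(object@chambers))
    msg <- c(msg, "chambers must be unique labels")
  if (object@nReplicas < 2L) msg <- c(msg, "nReplicas must be >= 2")
  if (object@baselineSdlog < 0) msg <- c(msg, "baselineSdlog must be >= 0")
  if (length(object@bioCVRange) != 2L || any(object@bioCVRange < 0) ||
      diff(object@bioCVRange) < 0)
    msg <- c(msg, "bioCVRange must be an increasing non-negative pair")
  if (object@techCV < 0) msg <- c(msg, "techCV must be >= 0")
  de <- object@plantedDE
  if (nrow(de)) {
    need <- c("gene", "ref", "tgt", "fold", "direction")
    if (!all(need %in% colnames(de)))
      msg <- c(msg, "plantedDE needs columns gene, ref, tgt, fold, direction")
    else {
      if (any(de$fold < 1)) msg <- c(msg, "planted folds must be >= 1")
      if (!all(de$direction %in% c(-1, 1)))
        msg <- c(msg, "planted directions must be +1 or -1")
      if (!all(c(de$ref, de$tgt) %in% object@chambers))
        msg <- c(msg, "plantedDE chambers must be among configured chambers")
    }
  }
  for (m in object@plantedModules) {
    if (!all(c("genes", "chamber", "loading") %in% names(m)))
      msg <- c(msg, "each planted module needs genes, chamber, loading")
    else if (m$loading < 0 || m$loading > 1)
      msg <- c(msg, "module loadings must be in [0, 1]")
  }
  for (s in object@plantedSynchrony) {
    if (!all(c("gene", "chambers", "loading") %in% names(s)))
      msg <- c(msg, "each planted synchrony needs gene, chambers, loading")
    else {
      if (length(s$chambers) != 2L)
        msg <- c(msg, "synchrony chambers must be a pair")
      if (s$loading < 0 || s$loading > 1)
        msg <- c(msg, "synchrony loadings must be in [0, 1]")
    }
  }
  if (object@violationFraction < 0 || object@violationFraction > 1)
    msg <- c(msg, "violationFraction must be in [0, 1]")
  if (object@corruptedFraction < 0 || object@corruptedFraction > 1)
    msg <- c(msg, "corruptedFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
}

setValidity("SimConfig", .validSimConfig)
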