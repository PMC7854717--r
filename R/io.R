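#' Read a replicated spot-level expression table
#'
#' Reads a tab-delimited table with one row per spot x chamber x replica
#' measurement and returns a canonical spot-measurement data frame with
#' columns \code{spot_id}, \code{gene}, \code{chamber}, \code{replica},
#' \code{foreground}, \code{background}, \code{corrupted}. Column names in
#' the file are mapped through \code{schema}, so arbitrary exports can be
#' ingested without renaming.
#'
#' Numeric fields that fail to parse raise an error rather than being
#' silently coerced to \code{NA}, and duplicated
#' (spot, chamber, replica) combinations are rejected.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param schema named list (or vector) mapping the canonical fields
#'   \code{gene}, \code{spot}, \code{foreground}, \code{background},
#'   \code{flag}, \code{chamber}, \code{replica} to column names in the
#'   file. Defaults to the identity mapping with \code{spot = "spot_id"}
#'   and \code{flag = "corrupted"} (the dialect written by
#'   [writeSimulation()]).
#' @return a data frame of spot measurements, one per input data row.
#' @seealso [filterSpots()], [normalizeSpots()]
#' @export
readExpressionTable <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .completeSchema(schema)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing <- setdiff(unlist(schema), colnames(raw))
  if (length(missing))
    stop("schema error: column(s) not in file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(field) {
    txt <- raw[[schema[[field]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !(trimws(txt) %in% c("NA", "")))
    if (length(bad))
      stop("unparseable numeric value '", txt[bad[1]], "' in column '",
           schema[[field]], "' (row ", bad[1], ")", call. = FALSE)
    if (anyNA(val))
      stop("missing numeric value in column '", schema[[field]], "'",
           call. = FALSE)
    val
  }
  flag <- raw[[schema[["flag"]]]]
  corrupted <- trimws(tolower(flag)) %in% c("true", "t", "1", "yes")
  df <- data.frame(
    spot_id    = raw[[schema[["spot"]]]],
    gene       = raw[[schema[["gene"]]]],
    chamber    = raw[[schema[["chamber"]]]],
    replica    = raw[[schema[["replica"]]]],
    foreground = num("foreground"),
    background = num("background"),
    corrupted  = corrupted,
    stringsAsFactors = FALSE)
  if (any(df$foreground < 0) || any(df$background < 0))
    stop("negative intensities are not allowed", call. = FALSE)
  key <- paste(df$spot_id, df$chamber, df$replica, sep = "\r")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (spot, chamber, replica): ",
         key[anyDuplicated(key)], call. = FALSE)
  df
}

.completeSchema <- function(schema) {
  default <- list(gene = "gene", spot = "spot_id", foreground = "foreground",
                  background = "background", flag = "corrupted",
                  chamber = "chamber", replica = "replica")
  if (is.null(schema)) return(default)
  schema <- as.list(schema)
  unknown <- setdiff(names(schema), names(default))
  if (length(unknown))
    stop("schema error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  utils::modifyList(default, schema)
}

#' Filter spots by quality across all samples
#'
#' Applies the global spot-filtration rule: a spot is removed from every
#' sample if, in any single sample, its quality flag marks it corrupted
#' or its foreground fluorescence is less than twice its background.
#' A spot whose foreground equals exactly twice the background is
#' retained (the rule is a strict inequality). Filtering is idempotent.
#'
#' @param spots spot-measurement data frame from [readExpressionTable()].
#' @param nSamples expected number of chamber x replica samples; defaults
#'   to the number observed. Each spot must appear in all of them.
#' @return a list with \code{retained} (the surviving measurements),
#'   and \code{removed}, a report data frame with one row per removed
#'   spot giving the first offending sample and the reason
#'   (\code{"corrupted"} or \code{"foreground<2x background"}).
#' @export
filterSpots <- function(spots, nSamples = NULL) {
  samples <- unique(paste(spots$chamber, spots$replica, sep = "."))
  nSamples <- nSamples %||% length(samples)
  counts <- table(spots$spot_id)
  if (any(counts != nSamples))
    stop("integrity error: spot(s) not observed in all ", nSamples,
         " samples: ",
         paste(utils::head(names(counts)[counts != nSamples], 5),
               collapse = ", "), call. = FALSE)
  bad <- spots$corrupted | (spots$foreground < 2 * spots$background)
  badRows <- spots[bad, , drop = FALSE]
  if (nrow(badRows)) {
    first <- !duplicated(badRows$spot_id)
    report <- data.frame(
      spot_id = badRows$spot_id[first],
      chamber = badRows$chamber[first],
      replica = badRows$replica[first],
      reason = ifelse(badRows$corrupted[first], "corrupted",
                      "foreground<2x background"),
      stringsAsFactors = FALSE)
  } else {
    report <- data.frame(spot_id = character(), chamber = character(),
                         replica = character(), reason = character(),
                         stringsAsFactors = FALSE)
  }
  retained <- spots[!(spots$spot_id %in% report$spot_id), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, removed = report)
}

#' Normalize filtered spot measurements into a FabricSet
#'
#' Background-subtracts each measurement (floored at a small positive
#' epsilon, 1e-6 times the sample median of the subtracted intensities),
#' scales each chamber x replica sample so its median spot value is 1,
#' then rescales globally so that the median over genes and samples of
#' the per-gene sample means (mean over a gene's spots within one
#' sample) equals 1. The result is expressed in median-gene units:
#' a value of 20 means twenty times the median gene.
#'
#' Median scaling makes the result invariant to per-sample multiplicative
#' rescaling of the raw intensities.
#'
#' @param spots filtered spot-measurement data frame (the \code{retained}
#'   element of [filterSpots()]).
#' @return a [FabricSet-class].
#' @export
normalizeSpots <- function(spots) {
  if (nrow(spots) == 0L) stop("no spots to normalize", call. = FALSE)
  chamber <- unique(spots$chamber)
  replica <- unique(spots$replica)
  spotIds <- unique(spots$spot_id)
  geneOf <- spots$gene[match(spotIds, spots$spot_id)]
  samples <- expand.grid(replica = replica, chamber = chamber,
                         stringsAsFactors = FALSE)[, c("chamber", "replica")]
  sampleKey <- paste(samples$chamber, samples$replica, sep = "\r")
  rowIdx <- match(paste(spots$spot_id), spotIds)
  colIdx <- match(paste(spots$chamber, spots$replica, sep = "\r"), sampleKey)
  m <- matrix(NA_real_, length(spotIds), nrow(samples))
  m[cbind(rowIdx, colIdx)] <- spots$foreground - spots$background
  if (anyNA(m))
    stop("integrity error: incomplete spot x sample matrix", call. = FALSE)
  ## per-sample epsilon floor, then median scaling
  for (j in seq_len(ncol(m))) {
    med <- stats::median(m[, j])
    if (med <= 0)
      stop("numeric error: non-positive median intensity in sample ",
           sampleKey[j], call. = FALSE)
    m[, j] <- pmax(m[, j], 1e-6 * med)
    m[, j] <- m[, j] / stats::median(m[, j])
  }
  ## global rescale: median over genes x samples of per-gene sample means
  gf <- factor(geneOf, levels = unique(geneOf))
  geneSampleMeans <- rowsum(m, gf) / as.vector(table(gf))
  m <- m / stats::median(geneSampleMeans)
  FabricSet(m, gene = geneOf, spotId = spotIds,
            chamber = samples$chamber, replica = samples$replica)
}

#' Read gene sets from a GMT file
#'
#' Parses the standard GMT dialect (set name, description, then member
#' symbols, tab-separated). Duplicate member symbols within a set are
#' collapsed; an empty member list is a format error. Members absent
#' from a given expression data set are retained here and flagged at use
#' time by the pathway-level routines.
#'
#' @param path path to a GMT file.
#' @return a [GeneSets-class] collection.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L || !any(nzchar(parts[-(1:2)])))
      stop("format error: gene set '", parts[1],
           "' has an empty member list", call. = FALSE)
    members <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    sets[[parts[1]]] <- members
    desc[parts[1]] <- parts[2]
  }
  methods::new("GeneSets", sets = sets, descriptions = desc)
}

## case-insensitive intersection of a gene set with quantified genes;
## returns the quantified symbols (case preserved) that match the set
.matchSet <- function(members, quantified) {
  quantified[tolower(quantified) %in% tolower(members)]
}
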