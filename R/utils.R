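## internal utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

## run code under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## format a numeric column for TSV output with full round-trip precision
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a result table as TSV
#'
#' Writes a data frame with a fixed header, tab separators and numeric
#' columns rendered at 17 significant digits, so write-then-read round
#' trips recover every double exactly (well beyond 12 significant
#' digits).
#'
#' @param df a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path TSV file path.
#' @return a data frame.
#' @export
readResultTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
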