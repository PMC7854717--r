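#' Run the fabric analysis pipeline
#'
#' Orchestrates the stages end to end: \code{simulate} (synthetic data
#' generation from a configuration), \code{fabric} (filter, normalize,
#' per-gene AVE/REV/REC and pathway control), \code{de} (two-chamber
#' differential expression and weighted pathway regulation),
#' \code{coord} (coordination edges, cross-chamber synchrony and
#' optional hub partner profile), \code{gch} (gene commanding heights
#' and top-k report) and \code{all} (every stage in order). Each stage
#' reads its predecessor's TSV outputs from \code{outDir}, so running
#' \code{"all"} equals running the stages separately. Re-running with
#' identical inputs and seeds reproduces byte-identical result tables.
#'
#' A \code{manifest.yaml} in \code{outDir} records input paths, the
#' configuration hash, seeds, package version, per-stage row counts and
#' accumulated warnings.
#'
#' @param stage one of \code{"simulate"}, \code{"fabric"}, \code{"de"},
#'   \code{"coord"}, \code{"gch"}, \code{"all"}.
#' @param outDir output directory (created if needed).
#' @param configFile YAML simulation configuration (see
#'   [writeSimConfig()]); required by \code{simulate}/\code{all} unless
#'   \code{config} is given.
#' @param config a [SimConfig-class] (alternative to \code{configFile}).
#' @param inputFile expression table for \code{fabric} when not produced
#'   by \code{simulate} (default \code{outDir/expression.tsv}).
#' @param seed overrides the configuration seed.
#' @param comparisons character vector of ordered "reference:referred"
#'   chamber pairs (the reference chamber is the denominator of the
#'   expression ratio); default the four adjacent pairings for the
#'   canonical LA/RA/LV/RV design, else all unordered pairs.
#' @param geneSetsFile optional GMT file for pathway-level outputs and
#'   for restricting the coordination edge enumeration.
#' @param hub,partnersFile optional hub gene symbol and partner list
#'   (one symbol per line) for the partner-profile output.
#' @param topK genes reported in the top-GCH table (default 5).
#' @param independenceBand,alpha passed to the coordination classifiers.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(stage = c("simulate", "fabric", "de", "coord",
                                  "gch", "all"),
                        outDir,
                        configFile = NULL, config = NULL,
                        inputFile = NULL, seed = NULL,
                        comparisons = NULL, geneSetsFile = NULL,
                        hub = NULL, partnersFile = NULL, topK = 5,
                        independenceBand = 0.05, alpha = 0.05) {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "GenomicFabric",
                   version = as.character(utils::packageVersion("GenomicFabric")),
                   stage = stage,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   inputs = list(), seed = seed, counts = list(),
                   warnings = character())
  note <- function(...) message("INFO: ", ...)
  warns <- character()
  withCallingHandlers({
    geneSets <- NULL
    if (!is.null(geneSetsFile)) {
      geneSets <- readGeneSets(geneSetsFile)
      manifest$inputs$geneSets <- geneSetsFile
    }

    if (stage %in% c("simulate", "all")) {
      if (is.null(config)) {
        if (is.null(configFile))
          stop("simulate requires a configuration", call. = FALSE)
        config <- readSimConfig(configFile)
        manifest$inputs$config <- configFile
        manifest$configHash <- unname(tools::md5sum(configFile))
      }
      if (!is.null(seed)) config@seed <- as.integer(seed)
      manifest$seed <- config@seed
      sim <- simulateFabric(config)
      writeSimulation(sim, outDir)
      manifest$counts$expression <- nrow(sim$spots)
      note(nrow(sim$spots), " measurements simulated (seed ",
           config@seed, ")")
    }

    if (stage %in% c("fabric", "all")) {
      inputFile <- inputFile %||% file.path(outDir, "expression.tsv")
      if (!file.exists(inputFile))
        stop("fabric stage requires ", inputFile,
             " (run simulate first or pass inputFile)", call. = FALSE)
      manifest$inputs$expression <- inputFile
      spots <- readExpressionTable(inputFile)
      flt <- filterSpots(spots)
      note(nrow(flt$removed), " spots removed by quality filtration")
      writeResultTable(flt$removed, file.path(outDir, "removed_spots.tsv"))
      manifest$counts$removed_spots <- nrow(flt$removed)
      fset <- normalizeSpots(flt$retained)
      norm <- data.frame(
        spot_id = rep(SummarizedExperiment::rowData(fset)$spot_id,
                      times = ncol(fset)),
        gene = rep(SummarizedExperiment::rowData(fset)$gene,
                   times = ncol(fset)),
        chamber = rep(SummarizedExperiment::colData(fset)$chamber,
                      each = nrow(fset)),
        replica = rep(SummarizedExperiment::colData(fset)$replica,
                      each = nrow(fset)),
        value = as.vector(SummarizedExperiment::assay(fset, "expr")),
        stringsAsFactors = FALSE)
      writeResultTable(norm, file.path(outDir, "normalized_expression.tsv"))
      summary <- fabricSummary(fset)
      writeResultTable(summary, file.path(outDir, "fabric_summary.tsv"))
      medrev <- data.frame(chamber = names(attr(summary, "medianREV")),
                           medianREV = as.numeric(attr(summary, "medianREV")),
                           stringsAsFactors = FALSE)
      writeResultTable(medrev, file.path(outDir, "chamber_median_rev.tsv"))
      manifest$counts$fabric_summary <- nrow(summary)
      if (!is.null(geneSets))
        writeResultTable(pathwayControl(summary, geneSets),
                         file.path(outDir, "pathway_control.tsv"))
    }

    ## downstream stages always consume the written fabric tables, so
    ## "all" is exactly the composition of the individual stages
    if (stage %in% c("de", "coord", "gch", "all")) {
      fset <- .readNormalized(outDir)
      summary <- .readSummary(outDir)
    }

    if (stage %in% c("de", "all")) {
      cmp <- .resolveComparisons(comparisons, chambers(fset))
      allCalls <- list()
      for (cc in cmp) {
        calls <- chamberComparison(fset, cc[1], cc[2], summary = summary,
                                   alpha = alpha)
        fn <- sprintf("de_%s_%s.tsv", cc[1], cc[2])
        writeResultTable(calls, file.path(outDir, fn))
        manifest$counts[[fn]] <- nrow(calls)
        note("comparison ", cc[1], ":", cc[2], " - ",
             sum(calls$regulated), " regulated genes")
        allCalls[[paste(cc, collapse = ":")]] <- calls
      }
      if (!is.null(geneSets)) {
        pr <- do.call(rbind, lapply(allCalls, pathwayRegulation, geneSets))
        rownames(pr) <- NULL
        writeResultTable(pr, file.path(outDir, "pathway_regulation.tsv"))
      }
    }

    if (stage %in% c("coord", "all")) {
      coordGenes <- NULL
      if (!is.null(geneSets))
        coordGenes <- .matchSet(unique(unlist(geneSets@sets)),
                                geneNames(fset))
      edges <- do.call(rbind, lapply(chambers(fset), function(ch)
        coordinationEdges(fset, ch, genes = coordGenes,
                          independenceBand = independenceBand,
                          alpha = alpha)))
      writeResultTable(edges, file.path(outDir, "coordination_edges.tsv"))
      manifest$counts$coordination_edges <- nrow(edges)
      sync <- synchronyTable(fset, independenceBand = independenceBand,
                             alpha = alpha)
      writeResultTable(sync, file.path(outDir, "synchrony.tsv"))
      manifest$counts$synchrony <- nrow(sync)
      if (!is.null(hub)) {
        partners <- if (!is.null(partnersFile))
          readLines(partnersFile, warn = FALSE) else geneNames(fset)
        partners <- partners[nzchar(trimws(partners))]
        pp <- do.call(rbind, lapply(chambers(fset), function(ch)
          partnerProfile(fset, hub, partners, ch,
                         independenceBand = independenceBand,
                         alpha = alpha)$edges))
        writeResultTable(pp, file.path(outDir, "partner_profile.tsv"))
        manifest$counts$partner_profile <- nrow(pp)
      }
    }

    if (stage %in% c("gch", "all")) {
      gch <- do.call(rbind, lapply(chambers(fset), function(ch)
        gchTable(fset, ch, summary = summary)))
      rownames(gch) <- NULL
      writeResultTable(gch, file.path(outDir, "gch.tsv"))
      top <- do.call(rbind, lapply(chambers(fset), function(ch)
        utils::head(gch[gch$chamber == ch, ], topK)))
      rownames(top) <- NULL
      writeResultTable(top, file.path(outDir, "gch_top.tsv"))
      manifest$counts$gch <- nrow(gch)
      note("top GCH gene per chamber: ",
           paste(top$gene[top$rank == 1], collapse = ", "))
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  manifest$warnings <- warns
  if (length(warns)) message("WARNING: ", paste(warns, collapse = "; "))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

.resolveComparisons <- function(comparisons, chams) {
  if (!is.null(comparisons))
    return(lapply(strsplit(comparisons, ":", fixed = TRUE), function(p) {
      if (length(p) != 2L || !all(p %in% chams))
        stop("bad comparison spec (expect 'reference:referred'): ",
             paste(p, collapse = ":"), call. = FALSE)
      p
    }))
  if (setequal(chams, c("LA", "RA", "LV", "RV")))
    return(list(c("LA", "RA"), c("LV", "RV"), c("LA", "LV"),
                c("RA", "RV")))
  cmb <- utils::combn(chams, 2)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

.readNormalized <- function(outDir) {
  path <- file.path(outDir, "normalized_expression.tsv")
  if (!file.exists(path))
    stop("stage requires ", path, " (run the fabric stage first)",
         call. = FALSE)
  norm <- readResultTable(path)
  norm$chamber <- as.character(norm$chamber)
  norm$replica <- as.character(norm$replica)
  spotIds <- unique(norm$spot_id)
  samples <- unique(norm[, c("chamber", "replica")])
  key <- paste(samples$chamber, samples$replica, sep = "\r")
  m <- matrix(NA_real_, length(spotIds), nrow(samples))
  m[cbind(match(norm$spot_id, spotIds),
          match(paste(norm$chamber, norm$replica, sep = "\r"), key))] <-
    norm$value
  FabricSet(m, gene = norm$gene[match(spotIds, norm$spot_id)],
            spotId = spotIds, chamber = samples$chamber,
            replica = samples$replica)
}

.readSummary <- function(outDir) {
  path <- file.path(outDir, "fabric_summary.tsv")
  if (!file.exists(path))
    stop("stage requires ", path, " (run the fabric stage first)",
         call. = FALSE)
  summary <- readResultTable(path)
  summary$gene <- as.character(summary$gene)
  summary$chamber <- as.character(summary$chamber)
  med <- readResultTable(file.path(outDir, "chamber_median_rev.tsv"))
  attr(summary, "medianREV") <- stats::setNames(med$medianREV,
                                                as.character(med$chamber))
  summary
}
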