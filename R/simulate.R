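#' Configure a synthetic fabric experiment
#'
#' Builds a [SimConfig-class] describing a replica-structured,
#' spot-redundant, multi-condition expression experiment with planted
#' ground truth. The defaults emulate a four-condition (LA, RA, LV, RV)
#' x four-biological-replica two-color microarray design: log-normal
#' baseline gene means normalized to median 1, per-gene biological CV
#' drawn uniformly from \code{bioCVRange}, multiplicative technical spot
#' noise, and spot redundancies drawn from \code{redundancyWeights}.
#'
#' Planted structure:
#' \itemize{
#'   \item \code{plantedDE}: data frame with columns \code{gene},
#'     \code{ref}, \code{tgt}, \code{fold} (>= 1), \code{direction}
#'     (+1 up / -1 down in \code{tgt} vs \code{ref}).
#'   \item \code{plantedModules}: list of
#'     \code{list(genes =, chamber =, loading =, signs =)} — genes
#'     sharing one latent factor per replica in one chamber, so any two
#'     members' log-scale correlation is \code{loading^2} (times the
#'     product of their signs, default all +1).
#'   \item \code{plantedSynchrony}: list of
#'     \code{list(gene =, chambers = c(A, B), loading =)} — a shared
#'     per-animal factor across the two chambers.
#' }
#'
#' @param nGenes number of genes (default 2000).
#' @param redundancyWeights named weights over spot counts (default 70\%
#'   R = 1, 20\% R = 2, 10\% R = 3; any R in 1..13 may be named).
#' @param chambers condition labels (default LA, RA, LV, RV).
#' @param nReplicas biological replicas per condition (default 4).
#' @param baselineSdlog natural-log sd of the baseline gene means
#'   (default 1.2, spanning roughly 0.1x-10x the median gene).
#' @param bioCVRange per-gene biological CV range (default 0.05-0.40).
#' @param techCV technical spot noise CV (default 0.05).
#' @param plantedDE,plantedModules,plantedSynchrony see Details.
#' @param violationFraction fraction of spots given one sample that
#'   fails the foreground >= 2x background filter (default 0.02).
#' @param corruptedFraction fraction of spots flagged corrupted in one
#'   sample (default 0.005).
#' @param seed RNG seed (default 1).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 2000,
                      redundancyWeights = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                      chambers = c("LA", "RA", "LV", "RV"),
                      nReplicas = 4,
                      baselineSdlog = 1.2,
                      bioCVRange = c(0.05, 0.40),
                      techCV = 0.05,
                      plantedDE = NULL,
                      plantedModules = list(),
                      plantedSynchrony = list(),
                      violationFraction = 0.02,
                      corruptedFraction = 0.005,
                      seed = 1) {
  if (is.null(plantedDE))
    plantedDE <- data.frame(gene = character(), ref = character(),
                            tgt = character(), fold = numeric(),
                            direction = numeric(),
                            stringsAsFactors = FALSE)
  methods::new("SimConfig",
    nGenes = as.integer(nGenes),
    redundancyWeights = redundancyWeights,
    chambers = as.character(chambers),
    nReplicas = as.integer(nReplicas),
    baselineSdlog = as.numeric(baselineSdlog),
    bioCVRange = as.numeric(bioCVRange),
    techCV = as.numeric(techCV),
    plantedDE = plantedDE,
    plantedModules = plantedModules,
    plantedSynchrony = plantedSynchrony,
    violationFraction = as.numeric(violationFraction),
    corruptedFraction = as.numeric(corruptedFraction),
    seed = as.integer(seed))
}

#' Default synthetic gene names
#'
#' The symbols [simulateFabric()] assigns to the gene universe, useful
#' for naming planted genes in a [simConfig()].
#'
#' @param n number of genes.
#' @return character vector "g00001", ...
#' @export
simGeneNames <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic fabric experiment with planted ground truth
#'
#' Draws, per gene: a baseline mean (log-normal, median-normalized) and
#' a chamber mean obtained by applying any planted fold; per replica: a
#' biological log-deviation built from an optional shared latent factor
#' (planted modules / synchrony) plus independent noise, scaled to the
#' gene's biological CV; per spot: multiplicative technical noise.
#' Foreground/background intensities are synthesized so that clean spots
#' always pass the 2x background filter (backgrounds are small relative
#' to the per-sample intensity scale) while a configurable fraction of
#' spots violates it in exactly one sample; another fraction is flagged
#' corrupted. Identical seeds give identical output.
#'
#' @param config a [SimConfig-class].
#' @return list with \code{spots} (the measurement table in the dialect
#'   [readExpressionTable()] consumes), \code{truth} (genes, redundancy,
#'   per-chamber true means, biological CVs, clean normalized-scale spot
#'   values, per-sample scale factors, planted violations) and
#'   \code{config}.
#' @export
simulateFabric <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  .withSeed(config@seed, {
    n <- config@nGenes
    ch <- config@chambers
    nch <- length(ch)
    nrep <- config@nReplicas
    reps <- as.character(seq_len(nrep))
    genes <- simGeneNames(n)
    de <- config@plantedDE
    if (nrow(de) && !all(de$gene %in% genes))
      stop("config error: planted gene(s) not in universe: ",
           paste(setdiff(de$gene, genes), collapse = ", "), call. = FALSE)
    for (m in config@plantedModules)
      if (!all(m$genes %in% genes))
        stop("config error: planted module gene(s) not in universe",
             call. = FALSE)
    for (s in config@plantedSynchrony)
      if (!s$gene %in% genes)
        stop("config error: planted synchrony gene not in universe",
             call. = FALSE)

    Rvals <- as.integer(names(config@redundancyWeights))
    R <- Rvals[sample.int(length(Rvals), n, replace = TRUE,
                          prob = config@redundancyWeights)]
    base <- stats::rlnorm(n, 0, config@baselineSdlog)
    base <- base / stats::median(base)
    mChamber <- matrix(base, n, nch, dimnames = list(genes, ch))
    if (nrow(de))
      for (k in seq_len(nrow(de))) {
        gi <- match(de$gene[k], genes)
        mChamber[gi, de$tgt[k]] <-
          mChamber[gi, de$ref[k]] * de$fold[k]^de$direction[k]
      }
    bioCV <- stats::runif(n, config@bioCVRange[1], config@bioCVRange[2])
    sigBio <- sqrt(log(1 + bioCV^2))
    sigTech <- sqrt(log(1 + config@techCV^2))

    ## latent assignment per gene x chamber: loading (0 = none), sign,
    ## factor matrix index
    loadG <- matrix(0, n, nch, dimnames = list(genes, ch))
    signG <- matrix(1, n, nch, dimnames = list(genes, ch))
    facId <- matrix(0L, n, nch, dimnames = list(genes, ch))
    nFac <- 0L
    facList <- list()
    for (m in config@plantedModules) {
      nFac <- nFac + 1L
      facList[[nFac]] <- stats::rnorm(nrep)
      gi <- match(m$genes, genes)
      if (any(loadG[gi, m$chamber] != 0))
        stop("config error: overlapping latent assignments", call. = FALSE)
      loadG[gi, m$chamber] <- m$loading
      signs <- m$signs %||% rep(1, length(gi))
      signG[gi, m$chamber] <- signs
      facId[gi, m$chamber] <- nFac
    }
    for (s in config@plantedSynchrony) {
      nFac <- nFac + 1L
      facList[[nFac]] <- stats::rnorm(nrep)
      gi <- match(s$gene, genes)
      if (any(loadG[gi, s$chambers] != 0))
        stop("config error: overlapping latent assignments", call. = FALSE)
      loadG[gi, s$chambers] <- s$loading
      facId[gi, s$chambers] <- nFac
    }

    ## biological log-deviations: gene x (chamber x replica)
    nsamp <- nch * nrep
    sampleChamber <- rep(ch, each = nrep)
    sampleReplica <- rep(reps, times = nch)
    z <- matrix(stats::rnorm(n * nsamp), n, nsamp)
    dev <- matrix(0, n, nsamp)
    for (j in seq_len(nsamp)) {
      cidx <- match(sampleChamber[j], ch)
      l <- loadG[, cidx]
      fv <- vapply(seq_len(n), function(i)
        if (facId[i, cidx] > 0L)
          facList[[facId[i, cidx]]][as.integer(sampleReplica[j])]
        else 0, numeric(1))
      dev[, j] <- sigBio *
        (signG[, cidx] * l * fv + sqrt(1 - l^2) * z[, j])
    }
    baseVal <- mChamber[, match(sampleChamber, ch)] * exp(dev)

    ## expand to spots with technical noise
    spotGene <- rep(seq_len(n), times = R)
    spotK <- sequence(R)
    nSpots <- length(spotGene)
    spotIds <- sprintf("s%05d_%02d", spotGene, spotK)
    tech <- matrix(stats::rnorm(nSpots * nsamp, sd = sigTech), nSpots, nsamp)
    if (sigTech == 0) tech[] <- 0
    vals <- baseVal[spotGene, , drop = FALSE] * exp(tech)
    dimnames(vals) <- list(spotIds,
                           paste(sampleChamber, sampleReplica, sep = "."))

    ## intensities: small backgrounds, per-sample scale factors
    scale <- stats::rlnorm(nsamp, log(1000), 0.2)
    bg0 <- stats::runif(nsamp, 0.5, 1.5)
    fg <- sweep(vals, 2, scale, `*`) + rep(bg0, each = nSpots)
    bg <- matrix(rep(bg0, each = nSpots), nSpots, nsamp)
    corrupted <- matrix(FALSE, nSpots, nsamp)

    nViol <- round(config@violationFraction * nSpots)
    nCorr <- round(config@corruptedFraction * nSpots)
    marked <- sample.int(nSpots, min(nSpots, nViol + nCorr))
    violSpots <- utils::head(marked, nViol)
    corrSpots <- utils::tail(marked, length(marked) - nViol)
    violations <- data.frame(spot_id = character(), chamber = character(),
                             replica = character(), type = character(),
                             stringsAsFactors = FALSE)
    for (si in violSpots) {
      j <- sample.int(nsamp, 1)
      fg[si, j] <- bg[si, j] * stats::runif(1, 1.0, 1.9)
      violations <- rbind(violations, data.frame(
        spot_id = spotIds[si], chamber = sampleChamber[j],
        replica = sampleReplica[j], type = "low_foreground",
        stringsAsFactors = FALSE))
    }
    for (si in corrSpots) {
      j <- sample.int(nsamp, 1)
      corrupted[si, j] <- TRUE
      violations <- rbind(violations, data.frame(
        spot_id = spotIds[si], chamber = sampleChamber[j],
        replica = sampleReplica[j], type = "corrupted",
        stringsAsFactors = FALSE))
    }

    spots <- data.frame(
      spot_id = rep(spotIds, times = nsamp),
      gene = rep(genes[spotGene], times = nsamp),
      chamber = rep(sampleChamber, each = nSpots),
      replica = rep(sampleReplica, each = nSpots),
      foreground = as.vector(fg),
      background = as.vector(bg),
      corrupted = as.vector(corrupted),
      stringsAsFactors = FALSE)

    truth <- list(genes = genes, redundancy = R, chamberMeans = mChamber,
                  bioCV = bioCV, values = vals,
                  sampleChamber = sampleChamber,
                  sampleReplica = sampleReplica, sampleScale = scale,
                  sampleBackground = bg0, violations = violations,
                  plantedDE = de, plantedModules = config@plantedModules,
                  plantedSynchrony = config@plantedSynchrony,
                  seed = config@seed)
    list(spots = spots, truth = truth, config = config)
  })
}

#' Build a FabricSet from a simulation's emitted expression values
#'
#' Bypasses the intensity synthesis and quality filtration and
#' constructs the expression container directly from the generator's
#' clean per-spot values, rescaled by a single global constant so the
#' median of per-gene sample means is 1. Because no per-sample median
#' scaling is involved, the planted correlation structure is preserved
#' exactly (per-sample median rescaling of a small synthetic
#' transcriptome adds replica-level offsets that slightly attenuate
#' cross-sample correlations; at realistic spot counts the effect is
#' negligible). Intended for calibration and recovery studies against
#' the planted ground truth.
#'
#' @param sim output of [simulateFabric()].
#' @return a [FabricSet-class].
#' @export
fabricFromTruth <- function(sim) {
  v <- sim$truth$values
  genes <- sim$spots$gene[match(rownames(v), sim$spots$spot_id)]
  gf <- factor(genes, levels = unique(genes))
  gm <- rowsum(v, gf) / as.vector(table(gf))
  v <- v / stats::median(gm)
  FabricSet(v, gene = genes, spotId = rownames(v),
            chamber = sim$truth$sampleChamber,
            replica = sim$truth$sampleReplica)
}

#' Write a simulated experiment to disk
#'
#' Writes the measurement table (the exact dialect
#' [readExpressionTable()] consumes), the gene-level ground truth, the
#' planted-removal truth, and the configuration (YAML).
#'
#' @param sim output of [simulateFabric()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeResultTable(sim$spots, file.path(dir, "expression.tsv"))
  tg <- data.frame(gene = sim$truth$genes,
                   redundancy = sim$truth$redundancy,
                   bioCV = sim$truth$bioCV,
                   stringsAsFactors = FALSE)
  tg <- cbind(tg, as.data.frame(sim$truth$chamberMeans))
  writeResultTable(tg, file.path(dir, "truth_genes.tsv"))
  writeResultTable(sim$truth$violations,
                   file.path(dir, "truth_removals.tsv"))
  if (nrow(sim$truth$plantedDE))
    writeResultTable(sim$truth$plantedDE, file.path(dir, "truth_de.tsv"))
  writeSimConfig(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write / read a simulation configuration as YAML
#'
#' The round trip is lossless: \code{readSimConfig(writeSimConfig(x))}
#' reproduces an identical configuration.
#'
#' @param config a [SimConfig-class].
#' @param path YAML file path.
#' @return `path` invisibly / the restored [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  de <- config@plantedDE
  obj <- list(
    nGenes = config@nGenes,
    redundancyWeights = as.list(config@redundancyWeights),
    chambers = config@chambers,
    nReplicas = config@nReplicas,
    baselineSdlog = config@baselineSdlog,
    bioCVRange = config@bioCVRange,
    techCV = config@techCV,
    plantedDE = if (nrow(de)) lapply(seq_len(nrow(de)), function(i)
      as.list(de[i, ])) else list(),
    plantedModules = config@plantedModules,
    plantedSynchrony = config@plantedSynchrony,
    violationFraction = config@violationFraction,
    corruptedFraction = config@corruptedFraction,
    seed = config@seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  de <- if (length(obj$plantedDE))
    do.call(rbind, lapply(obj$plantedDE, function(r)
      data.frame(gene = r$gene, ref = r$ref, tgt = r$tgt,
                 fold = as.numeric(r$fold),
                 direction = as.numeric(r$direction),
                 stringsAsFactors = FALSE)))
  else NULL
  modules <- lapply(obj$plantedModules, function(m) {
    m$genes <- as.character(unlist(m$genes))
    m$loading <- as.numeric(m$loading)
    if (!is.null(m$signs)) m$signs <- as.numeric(unlist(m$signs))
    m
  })
  synch <- lapply(obj$plantedSynchrony, function(s) {
    s$chambers <- as.character(unlist(s$chambers))
    s$loading <- as.numeric(s$loading)
    s
  })
  simConfig(nGenes = obj$nGenes,
            redundancyWeights = unlist(obj$redundancyWeights),
            chambers = obj$chambers,
            nReplicas = obj$nReplicas,
            baselineSdlog = obj$baselineSdlog,
            bioCVRange = obj$bioCVRange,
            techCV = obj$techCV,
            plantedDE = de,
            plantedModules = modules,
            plantedSynchrony = synch,
            violationFraction = obj$violationFraction,
            corruptedFraction = obj$corruptedFraction,
            seed = obj$seed)
}
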