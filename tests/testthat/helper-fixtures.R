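## fixture builders shared across test files

## FabricSet from a named list of per-gene matrices: each element is a
## R_i x (nChambers * nReplicas) matrix of positive values, columns
## chamber-major (all replicas of chamber 1, then chamber 2, ...)
toyFabric <- function(geneValues, chambers = c("LA", "RA", "LV", "RV"),
                      nReplicas = 4) {
  mats <- lapply(geneValues, as.matrix)
  m <- do.call(rbind, mats)
  genes <- rep(names(mats), vapply(mats, nrow, integer(1)))
  spotId <- paste0(genes, "_k", unlist(lapply(mats, function(x)
    seq_len(nrow(x)))))
  FabricSet(m, gene = genes, spotId = spotId,
            chamber = rep(chambers, each = nReplicas),
            replica = rep(as.character(seq_len(nReplicas)),
                          times = length(chambers)))
}

## random positive fabric: n genes, redundancy sampled from Rchoices
randomFabric <- function(n, chambers = c("LA", "RA", "LV", "RV"),
                         nReplicas = 4, Rchoices = 1, sdlog = 0.5,
                         seed = 1) {
  set.seed(seed)
  vals <- lapply(seq_len(n), function(i) {
    R <- if (length(Rchoices) == 1) Rchoices else sample(Rchoices, 1)
    matrix(rlnorm(R * length(chambers) * nReplicas, 0, sdlog), nrow = R)
  })
  names(vals) <- sprintf("g%03d", seq_len(n))
  toyFabric(vals, chambers, nReplicas)
}

## spot-measurement data frame covering all chamber x replica samples,
## from a vector of net intensities per spot (constant across samples
## unless a matrix is given); background defaults to 1
toySpots <- function(net, genes = names(net),
                     chambers = c("LA", "RA", "LV", "RV"), nReplicas = 4,
                     background = 1) {
  spotIds <- if (is.matrix(net)) rownames(net) else names(net)
  nSpots <- if (is.matrix(net)) nrow(net) else length(net)
  nsamp <- length(chambers) * nReplicas
  vals <- if (is.matrix(net)) net else matrix(net, nSpots, nsamp)
  data.frame(
    spot_id = rep(spotIds, times = nsamp),
    gene = rep(genes, times = nsamp),
    chamber = rep(rep(chambers, each = nReplicas), each = nSpots),
    replica = rep(rep(as.character(seq_len(nReplicas)), length(chambers)),
                  each = nSpots),
    foreground = as.vector(vals) + background,
    background = background,
    corrupted = FALSE,
    stringsAsFactors = FALSE)
}

## the independently coded chi-square correction oracle (numerical
## quantiles applied to the printed formula)
chi2Oracle <- function(R, nReplicas = 4) {
  r <- nReplicas * R - 1
  (sqrt(r / qchisq(0.975, r)) + sqrt(r / qchisq(0.025, r))) / 2
}

## write a GMT file with synthetic member symbols of given set sizes
writeToyGMT <- function(sizes, path) {
  lines <- vapply(seq_along(sizes), function(i) {
    members <- sprintf("set%d_gene%03d", i, seq_len(sizes[i]))
    paste(c(names(sizes)[i], "desc", members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
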