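# Synthetic GWAS generator: LD-block-structured genotypes via a
# founder-haplotype copying model, and binary phenotypes from an additive
# liability-threshold model with fixed case/control margins.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study generator.
#' Genotypes arise from a haplotype-copying model: within each LD block a
#' small pool of founder haplotypes is drawn, each subject haplotype picks
#' one founder per block and copies its allele at every SNP with probability
#' `copyProb`, otherwise drawing a fresh Bernoulli(MAF) allele.  Phenotypes
#' come from an additive liability `L_i = sum_j beta_j g_ij + eps_i`,
#' `eps_i ~ N(0, noiseSd^2)`; the `nCases` subjects with the largest
#' liability become cases, matching the fixed-row-sum case-control design.
#'
#' @param nCases,nControls subject counts.
#' @param d number of SNPs.
#' @param blockLength SNPs per LD block (default 20, the typical number of
#'   array SNPs an r^2 > 0.8 block harbors).
#' @param copyProb per-SNP probability of copying the founder allele
#'   (default 0.9; 0 gives independent SNPs, 1 perfect within-block LD when
#'   `poolSize = 1`).
#' @param poolSize founder haplotypes per block (default 4).
#' @param mafRange MAF sampling interval, a subset of (0, 0.5].
#' @param nCausal number of causal SNPs (0 = global null).
#' @param causalIndices optional explicit causal SNP indices; default
#'   `nCausal` indices evenly spaced over `1..d`.
#' @param effectSizes per-causal-SNP additive liability coefficients
#'   (recycled; default 1).
#' @param noiseSd liability noise standard deviation (default 1).
#' @param seed RNG seed for [simulateStudy()] and friends.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nCases = 500, nControls = 500, d = 500,
                             blockLength = 20, copyProb = 0.9, poolSize = 4,
                             mafRange = c(0.05, 0.5), nCausal = 0,
                             causalIndices = NULL, effectSizes = 1,
                             noiseSd = 1, seed = NULL) {
  cfg <- list(
    nCases = .assertCount(nCases, "nCases"),
    nControls = .assertCount(nControls, "nControls"),
    d = .assertCount(d, "d"),
    blockLength = .assertCount(blockLength, "blockLength"),
    copyProb = .assertProb(copyProb, "copyProb", open = FALSE),
    poolSize = .assertCount(poolSize, "poolSize"),
    mafRange = as.numeric(mafRange),
    nCausal = .assertCount(nCausal, "nCausal", min = 0L),
    causalIndices = causalIndices,
    effectSizes = as.numeric(effectSizes),
    noiseSd = as.numeric(noiseSd),
    seed = seed)
  if (length(cfg$mafRange) != 2L || cfg$mafRange[1] > cfg$mafRange[2] ||
      cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5)
    stop("mafRange must be an ordered pair within (0, 0.5]", call. = FALSE)
  if (cfg$nCausal > cfg$d) stop("nCausal must not exceed d", call. = FALSE)
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (is.null(cfg$causalIndices) && cfg$nCausal > 0) {
    idx <- round(seq(1, cfg$d, length.out = cfg$nCausal + 2L))
    idx <- idx[-c(1L, cfg$nCausal + 2L)]
    if (anyDuplicated(idx)) idx <- seq_len(cfg$nCausal)
    cfg$causalIndices <- idx
  }
  if (!is.null(cfg$causalIndices)) {
    cfg$causalIndices <- as.integer(cfg$causalIndices)
    if (anyDuplicated(cfg$causalIndices) ||
        any(cfg$causalIndices < 1L | cfg$causalIndices > cfg$d))
      stop("causalIndices must be distinct indices in 1..d", call. = FALSE)
    cfg$nCausal <- length(cfg$causalIndices)
  }
  cfg$effectSizes <- rep_len(cfg$effectSizes, cfg$nCausal)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Known causal truth of a simulated study
#'
#' @param causalIndices distinct SNP indices.
#' @param effectSizes matching liability coefficients.
#' @return list of class `TruthSet`.
#' @export
truthSet <- function(causalIndices = integer(), effectSizes = numeric()) {
  causalIndices <- as.integer(causalIndices)
  if (anyDuplicated(causalIndices))
    stop("causal indices must be distinct", call. = FALSE)
  if (length(effectSizes) != length(causalIndices))
    stop("one effect size per causal SNP required", call. = FALSE)
  structure(list(causalIndices = causalIndices,
                 effectSizes = as.numeric(effectSizes)),
            class = "TruthSet")
}

#' Simulate LD-structured genotypes
#'
#' Runs the founder-copying model of [simulationConfig()] under the current
#' RNG stream (seed handling lives in [simulateStudy()]).
#'
#' @param config a `SimulationConfig`.
#' @return list with `genotypes` (d x n integer matrix over 0/1/2) and
#'   `snpInfo` (a `DataFrame`).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$nCases + config$nControls
  d <- config$d
  nh <- 2L * n
  maf <- runif(d, config$mafRange[1], config$mafRange[2])
  g <- matrix(0L, nrow = d, ncol = n)
  starts <- seq(1L, d, by = config$blockLength)
  for (s in starts) {
    e <- min(s + config$blockLength - 1L, d)
    L <- e - s + 1L
    mafB <- maf[s:e]
    founders <- matrix(rbinom(config$poolSize * L, 1L, rep(mafB,
                              each = config$poolSize)),
                       nrow = config$poolSize, ncol = L)
    pick <- sample.int(config$poolSize, nh, replace = TRUE)
    copied <- founders[pick, , drop = FALSE]               # nh x L
    copyMask <- matrix(rbinom(nh * L, 1L, config$copyProb), nh, L)
    fresh <- matrix(rbinom(nh * L, 1L, rep(mafB, each = nh)), nh, L)
    hap <- copyMask * copied + (1L - copyMask) * fresh
    g[s:e, ] <- t(hap[seq(1L, nh, 2L), , drop = FALSE] +
                  hap[seq(2L, nh, 2L), , drop = FALSE])
  }
  # founder copying can push a realized frequency past 1/2; re-orient such
  # columns so stored counts always count the realized minor allele (at an
  # exact tie the lexicographically smaller character "A" is minor,
  # matching the file readers' convention)
  freq <- rowMeans(g) / 2
  flip <- freq > 0.5 | freq == 0.5
  if (any(flip)) g[flip, ] <- 2L - g[flip, , drop = FALSE]
  info <- DataFrame(snp_id = sprintf("snp%05d", seq_len(d)),
                    chromosome = rep("1", d),
                    position = seq_len(d) * 1000L,
                    allele_major = ifelse(flip, "B", "A"),
                    allele_minor = ifelse(flip, "A", "B"))
  list(genotypes = g, snpInfo = info, maf = maf)
}

#' Simulate phenotypes from genotypes under a liability-threshold model
#'
#' Liability is the additive causal burden plus Gaussian noise; the
#' `nCases` subjects with the largest liability are labelled cases (+1),
#' the rest controls (-1), so the case/control margins are fixed and
#' non-random.  Liability ties are broken by subject index.
#'
#' @param genotypes d x n genotype matrix.
#' @param truth a `TruthSet`.
#' @param config a `SimulationConfig` (supplies `nCases` and `noiseSd`).
#' @return list with `phenotypes` (+1/-1 vector) and `liability`.
#' @export
simulatePhenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(truth, "TruthSet"))
  n <- ncol(genotypes)
  if (config$nCases + config$nControls != n)
    stop("config margins do not match the genotype matrix", call. = FALSE)
  liab <- rnorm(n, 0, config$noiseSd)
  if (length(truth$causalIndices)) {
    gz <- genotypes[truth$causalIndices, , drop = FALSE]
    liab <- liab + as.numeric(crossprod(gz, truth$effectSizes))
  }
  ord <- order(-liab, seq_len(n))      # ties -> lower subject index first
  y <- rep(-1L, n)
  y[ord[seq_len(config$nCases)]] <- 1L
  list(phenotypes = y, liability = liab)
}

#' Simulate a complete case-control study with known truth
#'
#' Deterministic given `config$seed`: genotypes, then phenotypes, are drawn
#' under one seeded stream.
#'
#' @param config a `SimulationConfig`.
#' @return list with `study` (a [GenotypeStudy-class]) and `truth`
#'   (a `TruthSet`).
#' @examples
#' sim <- simulateStudy(simulationConfig(nCases = 50, nControls = 50,
#'                                       d = 60, seed = 1))
#' sim$study
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    geno <- simulateGenotypes(config)
    truth <- truthSet(config$causalIndices %||% integer(),
                      config$effectSizes)
    ph <- simulatePhenotypes(geno$genotypes, truth, config)
    study <- GenotypeStudy(geno$genotypes, ph$phenotypes,
                           snpInfo = geno$snpInfo)
    list(study = study, truth = truth, maf = geno$maf,
         liability = ph$liability)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a global-null study (no informative SNPs)
#'
#' @param config a `SimulationConfig`; its causal set is ignored.
#' @return as [simulateStudy()], with an empty `TruthSet`.
#' @export
simulateNullStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  config$nCausal <- 0L
  config$causalIndices <- integer()
  config$effectSizes <- numeric()
  simulateStudy(config)
}

#' Write a simulated study to disk (PLINK text + truth JSON)
#'
#' @param sim result of [simulateStudy()].
#' @param basePath path prefix for `.ped`, `.map` and `.truth.json`.
#' @param config the generating `SimulationConfig` (echoed into the JSON).
#' @return invisibly, the written paths.
#' @export
writeSimulatedStudy <- function(sim, basePath, config = NULL) {
  paths <- writePlinkText(sim$study, basePath)
  truthPath <- paste0(basePath, ".truth.json")
  payload <- list(causal_indices = sim$truth$causalIndices,
                  effect_sizes = sim$truth$effectSizes)
  if (!is.null(config)) {
    payload$seed <- config$seed
    payload$config <- config[setdiff(names(config), "causalIndices")]
  }
  jsonlite::write_json(payload, truthPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, truth = truthPath))
}

#' Read a truth JSON written by [writeSimulatedStudy()]
#'
#' @param path the `.truth.json` file.
#' @return a `TruthSet`.
#' @export
readTruthSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truthSet(obj$causal_indices %||% integer(),
           obj$effect_sizes %||% numeric())
}
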