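# Machine-learning screening: linear SVM on the one-hot encoding, per-SNP
# weight collapse, LD-aware moving-average filtering, top-k selection.

#' Screening parameters
#'
#' @param C SVM trade-off between margin (`||w||`) and hinge loss; must be
#'   positive.  Default 1.
#' @param windowSize moving-average filter length `l` (odd; default 35, on
#'   the scale of an LD block on a dense array).
#' @param filterOrder the filter exponent `p > 0`; `p = 1` is a plain
#'   moving average, the default `p = 2` a windowed quadratic mean.
#' @param k SNPs to keep per screening unit (default 100 per chromosome).
#' @param perChromosome train one SVM per chromosome (default) or a single
#'   genome-wide model.
#' @param collapse how encoded weights are collapsed per SNP; see
#'   [collapseWeights()].  Default `"absolute_average"`, the mean of the
#'   three absolute block weights.
#' @param tol dual stopping tolerance of the SVM solver (default 0.1, the
#'   customary working tolerance for linear-SVM screening; the solver is
#'   deterministic at any tolerance).
#' @param maxPasses hard cap on solver sweeps.
#' @return validated list of class `ScreeningConfig`.
#' @export
screeningConfig <- function(C = 1, windowSize = 35, filterOrder = 2,
                            k = 100, perChromosome = TRUE,
                            collapse = c("absolute_average", "average"),
                            tol = 0.1, maxPasses = 2000) {
  collapse <- match.arg(collapse)
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("'C' must be a positive number", call. = FALSE)
  windowSize <- .assertCount(windowSize, "windowSize")
  if (windowSize %% 2L == 0L)
    stop("'windowSize' (filter length) is required to be an odd number",
         call. = FALSE)
  if (!is.numeric(filterOrder) || length(filterOrder) != 1L ||
      filterOrder <= 0)
    stop("'filterOrder' must be a positive number", call. = FALSE)
  structure(list(C = as.numeric(C), windowSize = windowSize,
                 filterOrder = as.numeric(filterOrder),
                 k = .assertCount(k, "k"),
                 perChromosome = .assertFlag(perChromosome, "perChromosome"),
                 collapse = collapse,
                 tol = as.numeric(tol),
                 maxPasses = .assertCount(maxPasses, "maxPasses")),
            class = "ScreeningConfig")
}

#' Train the screening SVM
#'
#' Minimizes the soft-margin objective
#' `(1/2)||w||^2 + C * sum_i hinge(y_i w'x_i)` over the one-hot encoded
#' genotypes augmented with an all-ones constant feature (the offset is the
#' weight of that feature, not a solver-internal bias).  The solver is a
#' deterministic cyclic dual coordinate descent, so results are exactly
#' reproducible for fixed inputs.
#'
#' @param encoded an [EncodedGenotypes-class] (or plain n x 3d matrix).
#' @param phenotypes +1/-1 labels, one per subject.
#' @param C positive trade-off parameter.
#' @param tol dual stopping tolerance.
#' @param maxPasses sweep cap.
#' @return list with `w` (length-3d weight vector over the encoded
#'   features), `b` (the constant-feature weight), `converged`, `passes`.
#' @export
trainLinearSvm <- function(encoded, phenotypes, C = 1, tol = 1e-4,
                           maxPasses = 2000) {
  enc <- if (is(encoded, "EncodedGenotypes")) encoded@encoding
         else as.matrix(encoded)
  if (nrow(enc) == 0L || ncol(enc) == 0L)
    stop("empty encoding matrix", call. = FALSE)
  y <- as.numeric(phenotypes)
  if (length(y) != nrow(enc))
    stop("one phenotype per subject required", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both phenotype classes must be present", call. = FALSE)
  if (C <= 0) stop("'C' must be positive", call. = FALSE)
  Xt <- rbind(t(enc), 1)          # features x subjects, constant last
  fit <- .dcdLinearSvm(Xt, y, C, tol, as.integer(maxPasses))
  m <- length(fit$w)
  list(w = fit$w[-m], b = fit$w[m], converged = fit$converged,
       passes = fit$passes)
}

#' Collapse encoded SVM weights to one score per SNP
#'
#' Reduces the three encoding weights of each SNP to a single nonnegative
#' importance score; the constant-feature weight must already be excluded.
#' `"absolute_average"` (default) takes the mean of the three absolute
#' weights; `"average"` takes the absolute value of the mean.  The default
#' is preferred because on a balanced study the three block weights of the
#' strongly-regularized solution sum to (nearly) zero for every SNP, so the
#' plain block mean cancels exactly the marginal signal the screen is after.
#'
#' @param w numeric vector of length 3d.
#' @param d number of SNPs; default `length(w)/3`.
#' @param method `"absolute_average"` or `"average"`.
#' @return nonnegative numeric vector of length d.
#' @examples
#' collapseWeights(c(3, 0, 0, 0, 3, 0))  # c(1, 1) under either method
#' @export
collapseWeights <- function(w, d = length(w) / 3,
                            method = c("absolute_average", "average")) {
  method <- match.arg(method)
  if (length(w) %% 3L != 0L)
    stop("length(w) must be divisible by 3", call. = FALSE)
  d <- .assertCount(d, "d")
  if (length(w) != 3L * d)
    stop("length(w) must equal 3*d", call. = FALSE)
  m <- matrix(w, nrow = 3L)
  if (method == "absolute_average") colMeans(abs(m)) else abs(colMeans(m))
}

#' p-th order moving-average filter
#'
#' Smooths a nonnegative score vector with the windowed power mean
#' `s~_j = ( mean_{i in W_j} s_i^p )^(1/p)`, where `W_j` is the window of
#' half-width `(l-1)/2` around `j` truncated at the vector bounds and
#' renormalized by its actual size (so constant vectors are fixed points,
#' boundaries included).  `p = 1` is the standard moving average.
#'
#' @param s nonnegative numeric vector (e.g. collapsed SVM scores of one
#'   chromosome, in position order).
#' @param windowSize odd filter length `l`, at most `length(s)`.
#' @param order the exponent `p > 0`.
#' @return filtered vector, same length as `s`.
#' @examples
#' movingAverageFilter(c(1, 2, 3), windowSize = 3, order = 2)
#' @export
movingAverageFilter <- function(s, windowSize, order = 1) {
  d <- length(s)
  windowSize <- .assertCount(windowSize, "windowSize")
  if (windowSize %% 2L == 0L)
    stop("'windowSize' is required to be an odd number", call. = FALSE)
  if (windowSize > d)
    stop("'windowSize' must not exceed length(s)", call. = FALSE)
  if (!is.numeric(order) || order <= 0)
    stop("'order' must be positive", call. = FALSE)
  if (any(s < 0)) stop("scores must be nonnegative", call. = FALSE)
  if (windowSize == 1L) return(s)   # exact identity, no roundoff
  h <- (windowSize - 1L) / 2L
  lo <- pmax(seq_len(d) - h, 1L)
  hi <- pmin(seq_len(d) + h, d)
  cs <- cumsum(c(0, s^order))
  ((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))^(1 / order)
}

#' Select the k highest-scoring SNPs
#'
#' Exactly `min(k, length(scores))` SNPs are selected; ties at the k-th
#' largest score are broken towards the lower index.
#'
#' @param scores numeric vector.
#' @param k number to select.
#' @return logical mask of the same length.
#' @export
selectTopK <- function(scores, k) {
  k <- .assertCount(k, "k")
  d <- length(scores)
  ord <- order(-scores, seq_len(d))
  mask <- logical(d)
  mask[ord[seq_len(min(k, d))]] <- TRUE
  mask
}

# encode one unit's genotypes directly into the solver layout
# (features x subjects, constant-feature row appended)
.encodeUnitXt <- function(g) {
  d <- nrow(g); n <- ncol(g)
  Xt <- matrix(0, nrow = 3L * d + 1L, ncol = n)
  for (cat3 in 0:2) {
    hit <- which(g == cat3, arr.ind = TRUE)
    if (nrow(hit))
      Xt[cbind(3L * (hit[, 1L] - 1L) + cat3 + 1L, hit[, 2L])] <- 1
  }
  Xt[3L * d + 1L, ] <- 1
  Xt
}

# core screening on one unit given a precomputed solver matrix;
# windowSize is clamped to the largest odd number <= d for short units
.screenUnitXt <- function(Xt, y, config) {
  d <- (nrow(Xt) - 1L) / 3L
  fit <- .dcdLinearSvm(Xt, y, config$C, config$tol, config$maxPasses)
  raw <- collapseWeights(fit$w[-length(fit$w)], d, config$collapse)
  wlen <- min(config$windowSize, if (d %% 2L == 1L) d else d - 1L)
  filtered <- movingAverageFilter(raw, wlen, config$filterOrder)
  list(raw = raw, filtered = filtered,
       selected = selectTopK(filtered, config$k))
}

#' Screen one chromosome
#'
#' Runs the full screening composition (encode, SVM, collapse, filter,
#' top-k) on the SNPs of a single chromosome.  For chromosomes shorter than
#' the configured filter length, the window is clamped to the largest odd
#' number not exceeding the chromosome size.
#'
#' @param study a [GenotypeStudy-class].
#' @param chromosome chromosome label to screen.
#' @param config a [screeningConfig()].
#' @return a [S4Vectors::DataFrame] with columns `snp_id`, `chromosome`,
#'   `position`, `raw_score`, `filtered_score`, `selected`, in SNP order.
#' @export
screenChromosome <- function(study, chromosome, config = screeningConfig()) {
  stopifnot(inherits(config, "ScreeningConfig"))
  idx <- which(rowData(study)$chromosome == chromosome)
  if (!length(idx))
    stop(sprintf("chromosome '%s' not present", chromosome), call. = FALSE)
  g <- genotypes(study)[idx, , drop = FALSE]
  res <- .screenUnitXt(.encodeUnitXt(g), as.numeric(phenotypes(study)),
                       config)
  info <- rowData(study)[idx, ]
  DataFrame(snp_id = info$snp_id, chromosome = info$chromosome,
            position = info$position, raw_score = res$raw,
            filtered_score = res$filtered, selected = res$selected)
}

#' Screen a whole study
#'
#' Applies [screenChromosome()] per chromosome (or to the study as one unit
#' when `config$perChromosome` is `FALSE`) and assembles genome-wide score
#' and selection vectors.
#'
#' @inheritParams screenChromosome
#' @return a `DataFrame` as in [screenChromosome()], one row per SNP of the
#'   study, in the study's SNP order.
#' @export
screenStudy <- function(study, config = screeningConfig()) {
  units <- .studyUnits(study, config$perChromosome)
  y <- as.numeric(phenotypes(study))
  g <- genotypes(study)
  raw <- filtered <- numeric(nSnps(study))
  selected <- logical(nSnps(study))
  for (idx in units) {
    res <- .screenUnitXt(.encodeUnitXt(g[idx, , drop = FALSE]), y, config)
    raw[idx] <- res$raw
    filtered[idx] <- res$filtered
    selected[idx] <- res$selected
  }
  info <- rowData(study)
  DataFrame(snp_id = info$snp_id, chromosome = info$chromosome,
            position = info$position, raw_score = raw,
            filtered_score = filtered, selected = selected)
}

# split SNP indices into calibration/screening units
.studyUnits <- function(study, perChromosome) {
  chr <- as.character(rowData(study)$chromosome)
  if (perChromosome) split(seq_along(chr), factor(chr, unique(chr)))
  else list(all = seq_along(chr))
}
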