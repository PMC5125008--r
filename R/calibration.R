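# Threshold calibration: Westfall-Young style permutation of the entire
# screening + testing workflow, with FWER / gFWER / ENFR criteria, plus the
# analytic Bonferroni rule and the MinP special case (k = d).

#' Permutation distribution of the smallest masked p-value
#'
#' Repeatedly assigns a uniformly random permutation of the observed
#' phenotypes to the fixed genotypes and re-runs the *entire* workflow —
#' SVM training, weight collapse and filtering, top-k selection, masked
#' p-value computation — recording per calibration unit (chromosome, or the
#' study as a whole) the smallest of the k masked p-values, and optionally
#' all of them (required for gFWER and ENFR calibration).  The same
#' permutation is applied across all units within one repetition, and the
#' one-hot encoding is computed once and shared by all repetitions.
#'
#' @param study a [GenotypeStudy-class].
#' @param screening a [screeningConfig()]; its `perChromosome` flag fixes
#'   the calibration units.
#' @param test `"trend"` or `"chi2"`.
#' @param B number of permutations.
#' @param seed RNG seed for the permutation draws.
#' @param keepAll retain all selected p-values per permutation (not just
#'   the minimum).
#' @param skipScreening select every SNP instead of running the SVM screen;
#'   this is the classical MinP resampling scheme.
#' @return a [PermutationNull-class].
#' @export
permutationNull <- function(study, screening = screeningConfig(),
                            test = c("trend", "chi2"), B = 300,
                            seed = NULL, keepAll = FALSE,
                            skipScreening = FALSE) {
  test <- match.arg(test)
  B <- .assertCount(B, "B")
  keepAll <- .assertFlag(keepAll, "keepAll")
  skipScreening <- .assertFlag(skipScreening, "skipScreening")
  stopifnot(inherits(screening, "ScreeningConfig"))

  units <- .studyUnits(study, screening$perChromosome)
  g <- genotypes(study)
  y <- as.numeric(phenotypes(study))
  n <- length(y)
  Xts <- if (skipScreening) NULL
         else lapply(units, function(idx) .encodeUnitXt(g[idx, ,
                                                          drop = FALSE]))

  minP <- matrix(NA_real_, nrow = B, ncol = length(units),
                 dimnames = list(NULL, names(units)))
  allP <- if (keepAll) vector("list", B) else NULL
  kUnit <- integer(length(units))

  .withSeed(seed, {
    for (b in seq_len(B)) {
      yb <- y[sample.int(n)]
      rowP <- vector("list", length(units))
      for (u in seq_along(units)) {
        idx <- units[[u]]
        sel <- if (skipScreening) rep(TRUE, length(idx))
               else .screenUnitXt(Xts[[u]], yb, screening)$selected
        kUnit[u] <- sum(sel)
        pv <- .assocStats(g[idx[sel], , drop = FALSE], yb, test)$p_value
        minP[b, u] <- min(pv)
        if (keepAll) rowP[[u]] <- pv
      }
      if (keepAll) allP[[b]] <- rowP
    }
  })
  new("PermutationNull", B = B, units = names(units), minP = minP,
      pValues = allP, k = kUnit, test = test,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf("PermutationNull: B = %d permutations, %d unit(s), test = %s\n",
              object@B, length(object@units), object@test))
  q <- stats::quantile(object@minP, c(0.01, 0.05, 0.5))
  cat(sprintf("min-p quantiles: 1%% = %.3g, 5%% = %.3g, 50%% = %.3g\n",
              q[1], q[2], q[3]))
})

# empirical lower quantile convention shared by all criteria:
# the floor(alpha*B)-th smallest value; index 0 means "reject nothing"
.lowerQuantile <- function(x, alpha, B) {
  m <- floor(alpha * B)
  if (m < 1) 0 else sort(x, partial = m)[m]
}

#' FWER-calibrating threshold from a permutation distribution
#'
#' `t*` is the empirical lower alpha-quantile — the `floor(alpha*B)`-th
#' smallest — of the per-permutation smallest masked p-values, computed per
#' calibration unit.  When `floor(alpha*B) = 0` the threshold is 0 and
#' nothing can be rejected.
#'
#' @param dist a [PermutationNull-class].
#' @param alpha target family-wise error rate, in (0, 1).
#' @return a [ThresholdResult-class].
#' @export
fwerThreshold <- function(dist, alpha = 0.05) {
  alpha <- .assertProb(alpha, "alpha")
  t <- vapply(seq_along(dist@units),
              function(u) .lowerQuantile(dist@minP[, u], alpha, dist@B),
              numeric(1))
  new("ThresholdResult", tStar = setNames(t, dist@units),
      criterion = "fwer", level = alpha, gfwerOrder = 0L)
}

#' Generalized-FWER threshold
#'
#' Controls the probability of more than `order` false rejections: per
#' permutation the `(order+1)`-th smallest of the k masked p-values is
#' taken, and `t*` is the empirical lower alpha-quantile of those values.
#' `order = 0` reduces to [fwerThreshold()].
#'
#' @param dist a [PermutationNull-class] built with `keepAll = TRUE`.
#' @param alpha target gFWER level.
#' @param order the number of tolerated false rejections (>= 0, < k).
#' @return a [ThresholdResult-class].
#' @export
gfwerThreshold <- function(dist, alpha = 0.05, order = 1) {
  alpha <- .assertProb(alpha, "alpha")
  order <- .assertCount(order, "order", min = 0L)
  if (order == 0L) {
    res <- fwerThreshold(dist, alpha)
    res@criterion <- "gfwer"
    return(res)
  }
  if (is.null(dist@pValues))
    stop("gfwerThreshold needs a distribution built with keepAll = TRUE",
         call. = FALSE)
  if (any(order >= dist@k))
    stop("'order' must be smaller than the number of selected SNPs",
         call. = FALSE)
  t <- vapply(seq_along(dist@units), function(u) {
    os <- vapply(dist@pValues,
                 function(row) sort(row[[u]], partial = order + 1L)[order + 1L],
                 numeric(1))
    .lowerQuantile(os, alpha, dist@B)
  }, numeric(1))
  new("ThresholdResult", tStar = setNames(t, dist@units),
      criterion = "gfwer", level = alpha, gfwerOrder = order)
}

#' ENFR-calibrating threshold
#'
#' Controls the expected number of false rejections: all `B*k` resampled
#' p-values of a unit are pooled, and `t*` is the `floor(level*B)`-th
#' smallest of the pool, so the average number of rejections per
#' permutation at `t*` is `floor(level*B)/B <= level`.
#'
#' @param dist a [PermutationNull-class] built with `keepAll = TRUE`.
#' @param level target expected number of false rejections (>= 0).
#' @return a [ThresholdResult-class].
#' @export
enfrThreshold <- function(dist, level = 1) {
  if (!is.numeric(level) || length(level) != 1L || level < 0)
    stop("'level' must be a nonnegative number", call. = FALSE)
  if (is.null(dist@pValues))
    stop("enfrThreshold needs a distribution built with keepAll = TRUE",
         call. = FALSE)
  t <- vapply(seq_along(dist@units), function(u) {
    pool <- unlist(lapply(dist@pValues, `[[`, u), use.names = FALSE)
    .lowerQuantile(pool, level, dist@B)
  }, numeric(1))
  new("ThresholdResult", tStar = setNames(t, dist@units),
      criterion = "enfr", level = as.numeric(level), gfwerOrder = 0L)
}

#' Bonferroni threshold
#'
#' The analytic single-step correction `t* = alpha / d`; with `d` the
#' number of screened SNPs this is the sample-splitting variant
#' `alpha / k`.
#'
#' @param d number of tests.
#' @param alpha target FWER.
#' @return a [ThresholdResult-class] with a single unit `"all"`.
#' @export
bonferroniThreshold <- function(d, alpha = 0.05) {
  d <- .assertCount(d, "d")
  alpha <- .assertProb(alpha, "alpha")
  new("ThresholdResult", tStar = c(all = alpha / d),
      criterion = "bonferroni", level = alpha, gfwerOrder = 0L)
}

#' Westfall-Young MinP threshold
#'
#' The classical MinP procedure: the permutation distribution of the
#' smallest p-value over *all* SNPs (screening bypassed, equivalently
#' `k = d`), followed by the empirical lower alpha-quantile.  With the same
#' seed this is bit-identical to running the full workflow with `k = d`.
#'
#' @param study a [GenotypeStudy-class].
#' @param test `"trend"` or `"chi2"`.
#' @param B permutations.
#' @param alpha target FWER.
#' @param seed RNG seed.
#' @param perChromosome calibrate per chromosome (default `FALSE`:
#'   genome-wide).
#' @return list with `threshold` (a [ThresholdResult-class]) and `dist`
#'   (the [PermutationNull-class]).
#' @export
minpThreshold <- function(study, test = c("trend", "chi2"), B = 300,
                          alpha = 0.05, seed = NULL, perChromosome = FALSE) {
  test <- match.arg(test)
  screening <- screeningConfig(perChromosome = perChromosome, windowSize = 1,
                               k = nSnps(study))
  dist <- permutationNull(study, screening, test, B, seed,
                          skipScreening = TRUE)
  list(threshold = fwerThreshold(dist, alpha), dist = dist)
}

setMethod("tStar", "ThresholdResult", function(x) x@tStar)

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult (%s, level %g):\n", object@criterion,
              object@level))
  print(signif(object@tStar, 4))
})
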