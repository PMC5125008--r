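# Scoring against simulation ground truth: LD-window confusion counts,
# ROC/PR curves, Fisher comparison of two methods' replication counts, and
# a subsampling stability measure.

#' Confusion counts against a known causal truth
#'
#' A rejection is credited as a true positive when it lies within
#' `ldWindow` SNP positions (index distance) of a causal SNP; each causal
#' SNP is credited at most once, and rejections with no causal SNP in their
#' window count as false positives.  A causal SNP with no rejection in its
#' window is a false negative.  The index window stands in for a physical
#' LD window when coordinates are synthetic.
#'
#' @param rejections a [GwasReport-class] or an integer vector of rejected
#'   SNP indices.
#' @param truth a [truthSet()].
#' @param ldWindow nonnegative index half-width (default 10).
#' @return list with `TP`, `FP`, `FN`.
#' @export
confusionCounts <- function(rejections, truth, ldWindow = 10) {
  if (is(rejections, "GwasReport")) rejections <- rejectedSnps(rejections)
  rejections <- as.integer(rejections)
  ldWindow <- .assertCount(ldWindow, "ldWindow", min = 0L)
  causal <- truth$causalIndices
  if (!length(rejections))
    return(list(TP = 0L, FP = 0L, FN = length(causal)))
  if (!length(causal))
    return(list(TP = 0L, FP = length(rejections), FN = 0L))
  distMat <- abs(outer(rejections, causal, "-"))
  TP <- sum(apply(distMat <= ldWindow, 2L, any))        # credited causal
  FP <- sum(!apply(distMat <= ldWindow, 1L, any))       # uncredited hits
  list(TP = as.integer(TP), FP = as.integer(FP),
       FN = as.integer(length(causal) - TP))
}

#' ROC and precision-recall curves over per-SNP scores
#'
#' SNPs within `ldWindow` of a causal SNP are the positive class; the
#' threshold sweeps over the distinct values of the score (e.g. `-log10 p`
#' or the filtered SVM weight), declaring SNPs with score at or above the
#' threshold as hits.
#'
#' @param scores numeric vector, one score per SNP (larger = stronger).
#' @param truth a [truthSet()]; must contain at least one causal SNP.
#' @param ldWindow index half-width defining the positive class.
#' @return list with `roc` (threshold, FPR, TPR), `pr` (threshold, recall,
#'   precision) data frames and `auroc` (trapezoidal).
#' @export
rocPrCurves <- function(scores, truth, ldWindow = 10) {
  if (!length(truth$causalIndices))
    stop("ROC is undefined for a truth set with no causal SNP",
         call. = FALSE)
  d <- length(scores)
  pos <- rep(FALSE, d)
  for (c0 in truth$causalIndices)
    pos[max(1L, c0 - ldWindow):min(d, c0 + ldWindow)] <- TRUE
  nPos <- sum(pos); nNeg <- d - nPos
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    hit <- scores >= th[i]
    tp <- sum(hit & pos); fp <- sum(hit & !pos)
    tpr[i] <- tp / nPos
    fpr[i] <- if (nNeg) fp / nNeg else 0
    rec[i] <- tp / nPos
    prec[i] <- if (tp + fp) tp / (tp + fp) else 1
  }
  roc <- data.frame(threshold = th, FPR = fpr, TPR = tpr)
  pr <- data.frame(threshold = th, recall = rec, precision = prec)
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  auroc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  list(roc = roc, pr = pr, auroc = auroc)
}

#' Compare two methods' replication counts by Fisher's exact test
#'
#' One-sided exact test that method A is enriched for replicated
#' (confirmed) associations relative to method B, on the 2x2 table
#' `[[a_rep, a_unrep], [b_rep, b_unrep]]`.  The p-value is the
#' hypergeometric tail `P(X >= a_rep)` with all margins fixed.
#'
#' @param countsA,countsB length-2 integer vectors
#'   `(replicated, unreplicated)` for methods A and B.
#' @return the one-sided p-value.
#' @examples
#' fisherCompareMethods(c(28, 18), c(24, 52))  # 0.0014
#' @export
fisherCompareMethods <- function(countsA, countsB) {
  a <- as.integer(countsA); b <- as.integer(countsB)
  if (length(a) != 2L || length(b) != 2L || any(c(a, b) < 0))
    stop("each method needs nonnegative (replicated, unreplicated) counts",
         call. = FALSE)
  if (sum(a) + sum(b) == 0L)
    stop("the comparison table is empty", call. = FALSE)
  r1 <- sum(a)                 # method A total
  c1 <- a[1L] + b[1L]          # replicated total
  N <- sum(a) + sum(b)
  xs <- a[1L]:min(r1, c1)
  sum(dhyper(xs, c1, N - c1, r1))
}

#' Subsampling stability of a method's rejections
#'
#' Runs a method on stratified subsamples of the subjects and reports the
#' mean pairwise Jaccard index of the rejection sets; two identical sets
#' (including two empty ones) score 1, disjoint non-empty sets score 0.
#' Higher values indicate findings that survive resampling of subjects.
#'
#' @param study a [GenotypeStudy-class].
#' @param runner function taking a `GenotypeStudy` and returning a
#'   [GwasReport-class] (e.g. `function(s) runRpvt(s, threshold="fixed")`).
#' @param nSubsamples number of subsamples (>= 2).
#' @param subsampleFraction fraction of cases and of controls retained.
#' @param seed RNG seed for the subsample draws.
#' @return list with `overlap` (mean pairwise Jaccard) and `rejections`
#'   (list of rejected snp_id sets).
#' @export
stabilitySelectionOverlap <- function(study, runner, nSubsamples = 5,
                                      subsampleFraction = 0.8,
                                      seed = NULL) {
  nSubsamples <- .assertCount(nSubsamples, "nSubsamples", min = 2L)
  subsampleFraction <- .assertProb(subsampleFraction, "subsampleFraction")
  y <- phenotypes(study)
  ids <- rowData(study)$snp_id
  subs <- .withSeed(seed, {
    lapply(seq_len(nSubsamples), function(i) {
      cases <- which(y == 1L); controls <- which(y == -1L)
      sort(c(sample(cases, round(subsampleFraction * length(cases))),
             sample(controls, round(subsampleFraction * length(controls)))))
    })
  })
  sets <- lapply(subs, function(idx) ids[rejectedSnps(runner(study[, idx]))])
  jac <- function(u, v) {
    if (!length(u) && !length(v)) return(1)
    length(intersect(u, v)) / length(union(u, v))
  }
  pairs <- utils::combn(nSubsamples, 2L)
  overlap <- mean(vapply(seq_len(ncol(pairs)),
                         function(i) jac(sets[[pairs[1L, i]]],
                                         sets[[pairs[2L, i]]]),
                         numeric(1)))
  list(overlap = overlap, rejections = sets)
}
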