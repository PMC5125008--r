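# End-to-end orchestration: the two-step screening+testing workflow with
# permutation calibration, raw p-value thresholding baselines, and the
# sample-splitting two-step baseline.

.makeReport <- function(masked, screen, threshold, method, config, seed) {
  res <- masked
  if (!is.null(screen)) {
    res$raw_score <- screen$raw_score
    res$filtered_score <- screen$filtered_score
  } else {
    res$raw_score <- NA_real_
    res$filtered_score <- NA_real_
  }
  t <- tStar(threshold)
  tu <- if (length(t) == 1L) rep(unname(t), nrow(res))
        else unname(t[as.character(res$chromosome)])
  res$significant <- res$selected & res$p_value <= tu
  new("GwasReport", results = res, threshold = threshold, method = method,
      config = config, seed = if (is.null(seed)) NA_real_
                              else as.numeric(seed))
}

#' Run the two-step screening + permutation-calibrated testing workflow
#'
#' The complete method: per chromosome (or on the study as one unit), a
#' linear SVM is trained on the one-hot encoded genotypes, its collapsed
#' and moving-average-filtered weight magnitudes rank the SNPs, and the
#' top-k enter single-SNP testing; all other SNPs get p = 1 without a test.
#' The significance threshold is then calibrated by re-running this entire
#' workflow on `B` phenotype permutations ([permutationNull()]) and taking
#' the empirical quantile dictated by the chosen error criterion, per
#' calibration unit.  A SNP is reported significant when it was selected
#' and its p-value is at most its unit's `t*`.
#'
#' With `screening$k >= nSnps(study)` the screen selects everything and the
#' procedure coincides with the MinP baseline (given the same seed, the
#' thresholds agree bit for bit).
#'
#' @param study a [GenotypeStudy-class].
#' @param screening a [screeningConfig()].
#' @param test `"trend"` (default) or `"chi2"`.
#' @param criterion `"fwer"` (default), `"gfwer"` or `"enfr"`.
#' @param alpha FWER / gFWER level.
#' @param gfwerOrder tolerated false rejections for `"gfwer"`.
#' @param enfrLevel target expected number of false rejections for
#'   `"enfr"`.
#' @param B number of permutations.
#' @param seed RNG seed governing the permutation draws.
#' @return a [GwasReport-class].
#' @examples
#' sim <- simulateStudy(simulationConfig(nCases = 40, nControls = 40,
#'                                       d = 50, seed = 7))
#' rep <- runCombi(sim$study, screeningConfig(k = 5, windowSize = 5),
#'                 B = 50, seed = 7)
#' rep
#' @export
runCombi <- function(study, screening = screeningConfig(),
                     test = c("trend", "chi2"),
                     criterion = c("fwer", "gfwer", "enfr"),
                     alpha = 0.05, gfwerOrder = 1, enfrLevel = 1,
                     B = 300, seed = NULL) {
  test <- match.arg(test)
  criterion <- match.arg(criterion)
  stopifnot(inherits(screening, "ScreeningConfig"))

  screen <- screenStudy(study, screening)
  masked <- maskedPValues(study, screen$selected, test)
  dist <- permutationNull(study, screening, test, B, seed,
                          keepAll = criterion %in% c("gfwer", "enfr"))
  threshold <- switch(criterion,
    fwer = fwerThreshold(dist, alpha),
    gfwer = gfwerThreshold(dist, alpha, gfwerOrder),
    enfr = enfrThreshold(dist, enfrLevel))
  cfg <- list(screening = unclass(screening), test = test,
              criterion = criterion, alpha = alpha,
              gfwerOrder = gfwerOrder, enfrLevel = enfrLevel, B = B)
  .makeReport(masked, screen, threshold, "combi", cfg, seed)
}

#' Raw p-value thresholding baselines
#'
#' Computes the single-SNP test for every SNP and declares significant
#' those with `p <= t*`, where `t*` is either the Bonferroni correction
#' `alpha/d`, a fixed a-priori genome-wide threshold (the conventional
#' reporting levels being 1e-5 for weak and 5e-7 for strong associations),
#' or the Westfall-Young MinP permutation threshold.
#'
#' @param study a [GenotypeStudy-class].
#' @param test `"trend"` or `"chi2"`.
#' @param threshold `"bonferroni"`, `"fixed"` or `"minp"`.
#' @param alpha FWER level (bonferroni / minp).
#' @param fixedThreshold the fixed `t*` for `threshold = "fixed"`.
#' @param B,seed permutation settings for `threshold = "minp"`.
#' @return a [GwasReport-class].
#' @export
runRpvt <- function(study, test = c("trend", "chi2"),
                    threshold = c("bonferroni", "fixed", "minp"),
                    alpha = 0.05, fixedThreshold = 1e-5, B = 300,
                    seed = NULL) {
  test <- match.arg(test)
  threshold <- match.arg(threshold)
  masked <- maskedPValues(study, rep(TRUE, nSnps(study)), test)
  thr <- switch(threshold,
    bonferroni = bonferroniThreshold(nSnps(study), alpha),
    fixed = new("ThresholdResult",
                tStar = c(all = as.numeric(fixedThreshold)),
                criterion = "fwer", level = NA_real_, gfwerOrder = 0L),
    minp = minpThreshold(study, test, B, alpha, seed)$threshold)
  if (threshold == "minp" && length(tStar(thr)) > 1L)
    stop("minp RPVT expects a genome-wide threshold", call. = FALSE)
  cfg <- list(test = test, threshold = threshold, alpha = alpha,
              fixedThreshold = fixedThreshold, B = B)
  .makeReport(masked, NULL, thr, "rpvt", cfg, seed)
}

#' Sample-splitting two-step baseline
#'
#' Screens on one stratified subsample of subjects and computes p-values
#' exclusively on the held-out remainder, so selection and testing use
#' disjoint data; the selected SNPs are then thresholded at the
#' Bonferroni-type level `alpha / k` (k = number selected), which is valid
#' because only k hypotheses are tested on the second subsample.
#'
#' @param study a [GenotypeStudy-class].
#' @param screening a [screeningConfig()].
#' @param test `"trend"` or `"chi2"`.
#' @param alpha FWER level.
#' @param splitFraction fraction of subjects used for screening,
#'   in (0, 1); the split is stratified by case/control status.
#' @param seed RNG seed for the split.
#' @return a [GwasReport-class].
#' @export
runSplitScreen <- function(study, screening = screeningConfig(),
                           test = c("trend", "chi2"), alpha = 0.05,
                           splitFraction = 0.5, seed = NULL) {
  test <- match.arg(test)
  splitFraction <- .assertProb(splitFraction, "splitFraction")
  y <- phenotypes(study)
  part1 <- .withSeed(seed, {
    cases <- which(y == 1L); controls <- which(y == -1L)
    sort(c(sample(cases, round(splitFraction * length(cases))),
           sample(controls, round(splitFraction * length(controls)))))
  })
  part2 <- setdiff(seq_along(y), part1)
  if (!all(c(-1L, 1L) %in% y[part1]) || !all(c(-1L, 1L) %in% y[part2]))
    stop("each subsample must contain both cases and controls",
         call. = FALSE)
  s1 <- study[, part1]
  s2 <- study[, part2]
  screen <- screenStudy(s1, screening)
  masked <- maskedPValues(s2, screen$selected, test)
  k <- sum(screen$selected)
  thr <- bonferroniThreshold(k, alpha)
  cfg <- list(screening = unclass(screening), test = test, alpha = alpha,
              splitFraction = splitFraction, k = k)
  .makeReport(masked, screen, thr, "split_screen", cfg, seed)
}

# accessors & output -------------------------------------------------------

setMethod("snpResults", "GwasReport", function(x) x@results)

setMethod("tStar", "GwasReport", function(x) tStar(x@threshold))

setMethod("rejectedSnps", "GwasReport",
          function(x) which(x@results$significant))

setMethod("show", "GwasReport", function(object) {
  res <- object@results
  cat(sprintf("GwasReport [%s]: %d SNPs, %d selected, %d significant\n",
              object@method, nrow(res), sum(res$selected),
              sum(res$significant)))
  cat(sprintf("threshold criterion: %s; t* = %s\n",
              object@threshold@criterion,
              paste(signif(tStar(object), 3), collapse = ", ")))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant SNPs:\n")
    print(as.data.frame(head(sig[, c("snp_id", "chromosome", "position",
                                     "statistic", "p_value")], 10)))
  }
})

#' Write a report as results TSV + provenance JSON
#'
#' @param report a [GwasReport-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default the method name.
#' @return invisibly, the written paths.
#' @export
writeReport <- function(report, dir, prefix = report@method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resPath <- file.path(dir, paste0(prefix, "_results.tsv"))
  provPath <- file.path(dir, paste0(prefix, "_provenance.json"))
  .writeTsv(as.data.frame(report@results), resPath)
  prov <- list(method = report@method, config = report@config,
               seed = report@seed,
               threshold = list(criterion = report@threshold@criterion,
                                level = report@threshold@level,
                                t_star = as.list(tStar(report))),
               package_version = as.character(packageVersion("combiscreen")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(results = resPath, provenance = provPath))
}
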