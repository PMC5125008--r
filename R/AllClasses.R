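#' GenotypeStudy: a case-control genotype study
#'
#' An S4 container for a biallelic case-control study, extending
#' [SummarizedExperiment::SummarizedExperiment].  Rows are SNPs and columns
#' are subjects.  The single assay `"genotype"` holds minor-allele counts
#' (0, 1, 2, or `NA` for missing calls); `rowData` carries per-SNP metadata
#' (`snp_id`, `chromosome`, `position`, `allele_major`, `allele_minor`) and
#' `colData` the binary phenotype coded case = `+1`, control = `-1`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [GenotypeStudy()] for construction, [genotypes()],
#'   [phenotypes()], [snpInfo()] for access.
#' @export
setClass("GenotypeStudy", contains = "SummarizedExperiment")

setValidity("GenotypeStudy", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is missing")
  g <- assay(object, "genotype")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotype values must be 0, 1, 2 or NA")
  cd <- colData(object)
  if (!"phenotype" %in% colnames(cd))
    msg <- c(msg, "colData column 'phenotype' is missing")
  else if (!all(cd$phenotype %in% c(-1L, 1L)))
    msg <- c(msg, "phenotypes must be coded +1 (case) / -1 (control)")
  rd <- rowData(object)
  need <- c("snp_id", "chromosome", "position", "allele_major", "allele_minor")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData columns missing: ",
                         paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(rd$snp_id)) msg <- c(msg, "snp_ids must be unique")
    if (any(rd$position < 1)) msg <- c(msg, "positions must be >= 1")
    if (any(rd$allele_major == rd$allele_minor))
      msg <- c(msg, "major and minor allele must differ")
  }
  if (length(msg)) msg else TRUE
})

#' EncodedGenotypes: one-hot genotype expansion for SVM training
#'
#' Binary expansion of an n-subject-by-d-SNP genotype matrix into an
#' n x 3d matrix: minor-allele count 0 maps to (1,0,0), 1 to (0,1,0),
#' 2 to (0,0,1), and a missing call to (0,0,0) so it contributes nothing
#' to the decision function.  SNP `j` occupies columns `3j-2 .. 3j`.
#'
#' @slot encoding numeric matrix, n x 3d.
#' @slot d number of SNPs.
#' @seealso [encodeBinary()]
#' @export
setClass("EncodedGenotypes",
         representation(encoding = "matrix", d = "integer"))

setValidity("EncodedGenotypes", function(object) {
  if (ncol(object@encoding) != 3L * object@d)
    return("encoding must have 3*d columns")
  TRUE
})

#' PermutationNull: permutation distribution of masked p-values
#'
#' Holds, for each of `B` random phenotype permutations and each calibration
#' unit (chromosome, or the whole study in single-unit mode), the smallest
#' masked p-value produced by re-running the complete screening-plus-testing
#' workflow, and optionally all selected p-values (needed for gFWER and ENFR
#' calibration).
#'
#' @slot B number of permutations.
#' @slot units character vector of calibration unit labels.
#' @slot minP B x length(units) matrix of per-permutation smallest p-values.
#' @slot pValues either `NULL` or a list of length B; element b is a list of
#'   the selected p-value vectors per unit.
#' @slot k integer vector: number of selected SNPs per unit.
#' @slot test which single-SNP test was used.
#' @slot seed the RNG seed the permutations were drawn under (NA if none).
#' @seealso [permutationNull()], [fwerThreshold()], [enfrThreshold()]
#' @export
setClass("PermutationNull",
         representation(B = "integer", units = "character", minP = "matrix",
                        pValues = "ANY", k = "integer", test = "character",
                        seed = "numeric"))

setValidity("PermutationNull", function(object) {
  msg <- character()
  if (nrow(object@minP) != object@B)
    msg <- c(msg, "minP must have B rows")
  if (ncol(object@minP) != length(object@units))
    msg <- c(msg, "minP must have one column per unit")
  v <- object@minP[!is.na(object@minP)]
  if (length(v) && (any(v <= 0) || any(v > 1)))
    msg <- c(msg, "min p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ThresholdResult: a calibrated significance threshold
#'
#' A p-value threshold `t*` per calibration unit, together with the error
#' criterion it calibrates: `"fwer"` (family-wise error rate, level alpha),
#' `"gfwer"` (probability of more than `gfwerOrder` false rejections),
#' `"enfr"` (expected number of false rejections), or the analytic
#' `"bonferroni"` rule.  SNPs are declared significant when `p <= t*`.
#'
#' @slot tStar named numeric vector of thresholds between 0 and 1, one per
#'   unit.
#' @slot criterion one of `"fwer"`, `"gfwer"`, `"enfr"`, `"bonferroni"`.
#' @slot level alpha (fwer/gfwer/bonferroni) or the target ENFR.
#' @slot gfwerOrder the gFWER order parameter (0 = ordinary FWER).
#' @export
setClass("ThresholdResult",
         representation(tStar = "numeric", criterion = "character",
                        level = "numeric", gfwerOrder = "integer"))

setValidity("ThresholdResult", function(object) {
  if (any(object@tStar < 0 | object@tStar > 1))
    return("t* must lie in [0, 1]")
  if (!object@criterion %in% c("fwer", "gfwer", "enfr", "bonferroni"))
    return("unknown criterion")
  TRUE
})

#' GwasReport: per-SNP results of an association workflow
#'
#' The end product of [runCombi()], [runRpvt()] or [runSplitScreen()]:
#' a per-SNP table (statistic, p-value, screening scores, selection and
#' significance flags), the calibrated threshold(s), and provenance
#' (method, configuration echo, seed, package version).
#'
#' @slot results a [S4Vectors::DataFrame] with one row per SNP.
#' @slot threshold a [ThresholdResult-class].
#' @slot method character: `"combi"`, `"rpvt"` or `"split_screen"`.
#' @slot config list echoing the configuration of the run.
#' @slot seed numeric seed (NA if none given).
#' @export
setClass("GwasReport",
         representation(results = "DataFrame", threshold = "ThresholdResult",
                        method = "character", config = "list",
                        seed = "numeric"))

setValidity("GwasReport", function(object) {
  res <- object@results
  need <- c("snp_id", "chromosome", "position", "statistic", "p_value",
            "selected", "significant")
  miss <- setdiff(need, colnames(res))
  if (length(miss))
    return(paste0("results columns missing: ", paste(miss, collapse = ", ")))
  if (any(res$significant & !res$selected))
    return("significant SNPs must be selected")
  TRUE
})
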