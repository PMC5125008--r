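#' @rdname GenotypeStudy
#' @param x,object a `GenotypeStudy` (or, where documented, another class).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeStudy
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname GenotypeStudy
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname GenotypeStudy
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname GenotypeStudy
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname GenotypeStudy
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeStudy
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Threshold accessor
#'
#' Extract the calibrated p-value threshold(s) `t*` from a
#' [ThresholdResult-class] or a [GwasReport-class].
#' @param x the object.
#' @return named numeric vector of thresholds (one per calibration unit).
#' @export
setGeneric("tStar", function(x) standardGeneric("tStar"))

#' Per-SNP results accessor
#'
#' @param x a [GwasReport-class].
#' @return a [S4Vectors::DataFrame] with one row per SNP.
#' @export
setGeneric("snpResults", function(x) standardGeneric("snpResults"))

#' Rejected (significant) SNPs of a report
#'
#' @param x a [GwasReport-class].
#' @return integer vector of SNP row indices declared significant.
#' @export
setGeneric("rejectedSnps", function(x) standardGeneric("rejectedSnps"))
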