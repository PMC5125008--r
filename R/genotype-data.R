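#' Construct a GenotypeStudy
#'
#' @param genotypes integer matrix of minor-allele counts with SNPs in rows
#'   and subjects in columns; entries 0, 1, 2 or `NA` (missing call).
#' @param phenotypes vector of length `ncol(genotypes)` coded `+1` (case) /
#'   `-1` (control).
#' @param snpInfo optional `data.frame`/`DataFrame` with columns `snp_id`,
#'   `chromosome`, `position`, `allele_major`, `allele_minor`.  When omitted,
#'   synthetic identifiers (`snp00001` ...), a single chromosome `"1"`,
#'   unit-spaced positions and alleles A/B are filled in.
#' @param sampleIds optional character vector of subject identifiers.
#' @return a [GenotypeStudy-class].
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3)
#' study <- GenotypeStudy(g, phenotypes = c(1, -1))
#' nSnps(study); nCases(study)
#' @export
GenotypeStudy <- function(genotypes, phenotypes, snpInfo = NULL,
                          sampleIds = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  d <- nrow(genotypes)
  n <- ncol(genotypes)
  if (length(phenotypes) != n)
    stop("length(phenotypes) must equal ncol(genotypes)", call. = FALSE)
  phenotypes <- as.integer(phenotypes)
  if (is.null(snpInfo)) {
    snpInfo <- DataFrame(
      snp_id = sprintf("snp%05d", seq_len(d)),
      chromosome = rep("1", d),
      position = seq_len(d),
      allele_major = rep("A", d),
      allele_minor = rep("B", d))
  } else {
    snpInfo <- as(as.data.frame(snpInfo), "DataFrame")
  }
  if (nrow(snpInfo) != d)
    stop("snpInfo must have one row per SNP", call. = FALSE)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample%05d", seq_len(n))
  dimnames(genotypes) <- list(snpInfo$snp_id, sampleIds)
  se <- SummarizedExperiment(
    assays = list(genotype = genotypes),
    rowData = snpInfo,
    colData = DataFrame(sample_id = sampleIds, phenotype = phenotypes,
                        row.names = sampleIds))
  new("GenotypeStudy", se)
}

#' @rdname GenotypeStudy
#' @export
setMethod("genotypes", "GenotypeStudy",
          function(x) assay(x, "genotype"))

#' @rdname GenotypeStudy
#' @export
setMethod("phenotypes", "GenotypeStudy",
          function(x) colData(x)$phenotype)

#' @rdname GenotypeStudy
#' @export
setMethod("snpInfo", "GenotypeStudy",
          function(x) rowData(x))

#' @rdname GenotypeStudy
#' @export
setMethod("nCases", "GenotypeStudy",
          function(x) sum(colData(x)$phenotype == 1L))

#' @rdname GenotypeStudy
#' @export
setMethod("nControls", "GenotypeStudy",
          function(x) sum(colData(x)$phenotype == -1L))

#' @rdname GenotypeStudy
#' @export
setMethod("nSnps", "GenotypeStudy", function(x) nrow(x))

#' @rdname GenotypeStudy
#' @export
setMethod("nSubjects", "GenotypeStudy", function(x) ncol(x))

setMethod("show", "GenotypeStudy", function(object) {
  cat(sprintf("GenotypeStudy: %d SNPs x %d subjects (%d cases, %d controls)\n",
              nSnps(object), nSubjects(object), nCases(object),
              nControls(object)))
  chr <- unique(rowData(object)$chromosome)
  cat(sprintf("chromosomes: %s\n",
              paste(head(chr, 10), collapse = ", ")))
  miss <- sum(is.na(assay(object, "genotype")))
  if (miss > 0) cat(sprintf("missing genotype calls: %d\n", miss))
})

#' One-hot (binary) genotypic encoding
#'
#' Expands minor-allele counts to the 3-bit-per-SNP binary encoding used for
#' SVM training: 0 -> (1,0,0), 1 -> (0,1,0), 2 -> (0,0,1).  A missing call
#' encodes as (0,0,0) and thus contributes nothing to the linear decision
#' function.  The result has subjects in rows and SNP `j` in columns
#' `3j-2 .. 3j`.
#'
#' @param study a [GenotypeStudy-class], or a genotype matrix
#'   (SNPs x subjects) over 0/1/2/NA.
#' @return an [EncodedGenotypes-class].
#' @examples
#' study <- GenotypeStudy(matrix(c(0L, 2L), 1), c(1, -1))
#' encodeBinary(study)@encoding
#' @export
encodeBinary <- function(study) {
  g <- if (is(study, "GenotypeStudy")) genotypes(study) else as.matrix(study)
  d <- nrow(g)
  n <- ncol(g)
  enc <- matrix(0, nrow = n, ncol = 3L * d)
  for (cat3 in 0:2) {
    hit <- which(g == cat3, arr.ind = TRUE)   # (snp, subject)
    if (nrow(hit))
      enc[cbind(hit[, 2L], 3L * (hit[, 1L] - 1L) + cat3 + 1L)] <- 1
  }
  new("EncodedGenotypes", encoding = enc, d = as.integer(d))
}

#' Columns of the encoding belonging to one SNP
#'
#' @param j SNP index (1-based).
#' @return integer vector `c(3j-2, 3j-1, 3j)`.
#' @export
blockColumns <- function(j) {
  j <- .assertCount(j, "j")
  (3L * j - 2L):(3L * j)
}

setMethod("show", "EncodedGenotypes", function(object) {
  cat(sprintf("EncodedGenotypes: %d subjects x %d columns (%d SNPs)\n",
              nrow(object@encoding), ncol(object@encoding), object@d))
})

#' 2x3 genotype-by-phenotype contingency table for one SNP
#'
#' Cross-tabulates subjects by phenotype (rows: case, control) and genotype
#' category (columns: 0, 1 or 2 minor alleles, i.e. major homozygote,
#' heterozygote, minor homozygote).  Subjects with a missing genotype at the
#' SNP are excluded from the table.
#'
#' @param study a [GenotypeStudy-class].
#' @param snpIndex SNP row index, 1-based.
#' @return 2x3 integer matrix with dimnames; under the case-control design
#'   the two rows are independent multinomial draws with fixed row sums.
#' @export
buildContingencyTable <- function(study, snpIndex) {
  snpIndex <- .assertCount(snpIndex, "snpIndex")
  if (snpIndex > nSnps(study))
    stop("snpIndex exceeds the number of SNPs", call. = FALSE)
  g <- genotypes(study)[snpIndex, ]
  y <- phenotypes(study)
  tab <- matrix(0L, 2L, 3L,
                dimnames = list(c("case", "control"), c("0", "1", "2")))
  for (k in 0:2) {
    tab["case", k + 1L] <- sum(g == k & y == 1L, na.rm = TRUE)
    tab["control", k + 1L] <- sum(g == k & y == -1L, na.rm = TRUE)
  }
  tab
}

# fast path used by the test/permutation machinery: per-SNP 2x3 counts for
# every SNP at once; returns list(cases = d x 3, controls = d x 3)
.genotypeCounts <- function(g, y) {
  gc <- g[, y == 1L, drop = FALSE]
  gn <- g[, y == -1L, drop = FALSE]
  count3 <- function(m) {
    cbind(rowSums(m == 0L, na.rm = TRUE),
          rowSums(m == 1L, na.rm = TRUE),
          rowSums(m == 2L, na.rm = TRUE))
  }
  list(cases = count3(gc), controls = count3(gn))
}
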