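# Single-SNP association tests on 2x3 case-control tables: Pearson's
# chi-square test for association (2 df) and the Cochran-Armitage trend
# test (1 df), plus selection-masked p-value vectors.

#' Pearson chi-square test for association on a 2x3 table
#'
#' Computes `sum((obs - exp)^2 / exp)` against the independence
#' expectations.  Genotype columns with zero margin are dropped and the
#' degrees of freedom reduced accordingly; with fewer than two non-empty
#' columns the statistic is 0 and p = 1.  The p-value is the upper tail of
#' the chi-square distribution at the effective df (no continuity
#' correction).
#'
#' @param table 2x3 matrix of counts, cases in row 1, controls in row 2,
#'   genotype categories 0/1/2 minor alleles in columns (as produced by
#'   [buildContingencyTable()]).
#' @return list with `statistic`, `p_value` and `df`.
#' @export
chiSquareAssociation <- function(table) {
  tab <- .checkTable(table)
  keep <- colSums(tab) > 0
  eff <- tab[, keep, drop = FALSE]
  if (ncol(eff) < 2L)
    return(list(statistic = 0, p_value = 1, df = 0L))
  expd <- outer(rowSums(eff), colSums(eff)) / sum(eff)
  stat <- sum((eff - expd)^2 / expd)
  df <- ncol(eff) - 1L
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' Cochran-Armitage trend test on a 2x3 table
#'
#' One-degree-of-freedom score test for a linear trend in case proportion
#' across the genotype dose, with scores `(0, 1, 2)` by default:
#' `Z^2 = N (N T1 - n1. Tall)^2 / (n1. n2. (N T2 - Tall^2))` with
#' `T1 = sum_k s_k n_1k`, `Tall = sum_k s_k n_.k`, `T2 = sum_k s_k^2 n_.k`.
#' If the dose has zero variance (all subjects in one category) the
#' statistic is 0 and p = 1 by convention.
#'
#' @param table 2x3 count matrix (cases row 1).
#' @param scores genotype scores, default `c(0, 1, 2)` (additive dose).
#' @return list with `statistic`, `p_value` and `df = 1`.
#' @export
cochranArmitageTrend <- function(table, scores = c(0, 1, 2)) {
  tab <- .checkTable(table)
  if (length(scores) != ncol(tab))
    stop("one score per genotype category required", call. = FALSE)
  n1 <- unname(rowSums(tab)[1L]); n2 <- unname(rowSums(tab)[2L])
  N <- n1 + n2
  colsum <- colSums(tab)
  T1 <- sum(scores * tab[1L, ])
  Tall <- sum(scores * colsum)
  T2 <- sum(scores^2 * colsum)
  den <- n1 * n2 * (N * T2 - Tall^2)
  if (den <= 0) return(list(statistic = 0, p_value = 1, df = 1L))
  stat <- N * (N * T1 - n1 * Tall)^2 / den
  list(statistic = stat, p_value = pchisq(stat, 1L, lower.tail = FALSE),
       df = 1L)
}

.checkTable <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L) stop("a 2-row table is required", call. = FALSE)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0))
    stop("each phenotype class must contain at least one subject",
         call. = FALSE)
  tab
}

# vectorized statistics for all SNPs of a genotype matrix at once;
# returns list(statistic, p_value), each length nrow(g)
.assocStats <- function(g, y, test = c("trend", "chi2")) {
  test <- match.arg(test)
  if (!any(y == 1L) || !any(y == -1L))
    stop("each phenotype class must contain at least one subject",
         call. = FALSE)
  cnt <- .genotypeCounts(g, y)
  n1k <- cnt$cases; n2k <- cnt$controls
  n1 <- rowSums(n1k); n2 <- rowSums(n2k)
  # a SNP with one phenotype class fully missing is degenerate: stat 0, p 1
  rowOk <- n1 > 0 & n2 > 0
  N <- n1 + n2
  if (test == "trend") {
    s <- c(0, 1, 2)
    T1 <- as.numeric(n1k %*% s)
    colsum <- n1k + n2k
    Tall <- as.numeric(colsum %*% s)
    T2 <- as.numeric(colsum %*% s^2)
    den <- n1 * n2 * (N * T2 - Tall^2)
    ok <- den > 0 & rowOk
    stat <- ifelse(ok, N * (N * T1 - n1 * Tall)^2 / pmax(den, 1), 0)
    p <- ifelse(ok, pchisq(stat, 1, lower.tail = FALSE), 1)
  } else {
    colsum <- n1k + n2k
    stat <- numeric(nrow(n1k))
    df <- integer(nrow(n1k))
    for (k in 1:3) {
      mk <- colsum[, k]
      e1 <- n1 * mk / N
      e2 <- n2 * mk / N
      contrib <- ifelse(mk > 0,
                        (n1k[, k] - e1)^2 / pmax(e1, 1e-300) +
                        (n2k[, k] - e2)^2 / pmax(e2, 1e-300), 0)
      stat <- stat + contrib
      df <- df + as.integer(mk > 0)
    }
    df <- df - 1L
    ok <- df >= 1L & rowOk
    stat <- ifelse(ok, stat, 0)
    p <- ifelse(ok, pchisq(stat, pmax(df, 1L), lower.tail = FALSE), 1)
  }
  list(statistic = unname(stat), p_value = unname(p))
}

#' Selection-masked p-values
#'
#' Computes the configured single-SNP test only for the selected SNPs; the
#' p-value of every unselected SNP is set to 1 without computing a test
#' statistic (its statistic is reported as `NA`).  With a full selection
#' this is exactly the per-SNP p-value vector of raw p-value thresholding.
#'
#' @param study a [GenotypeStudy-class].
#' @param selection logical mask, one entry per SNP.
#' @param test `"trend"` (Cochran-Armitage, default) or `"chi2"`.
#' @return a [S4Vectors::DataFrame] with columns `snp_id`, `chromosome`,
#'   `position`, `test`, `statistic`, `p_value`, `selected`.
#' @export
maskedPValues <- function(study, selection, test = c("trend", "chi2")) {
  test <- match.arg(test)
  d <- nSnps(study)
  if (length(selection) != d)
    stop("selection mask must have one entry per SNP", call. = FALSE)
  selection <- as.logical(selection)
  stat <- rep(NA_real_, d)
  p <- rep(1, d)
  if (any(selection)) {
    g <- genotypes(study)[selection, , drop = FALSE]
    res <- .assocStats(g, phenotypes(study), test)
    stat[selection] <- res$statistic
    p[selection] <- res$p_value
  }
  info <- rowData(study)
  DataFrame(snp_id = info$snp_id, chromosome = info$chromosome,
            position = info$position, test = test, statistic = stat,
            p_value = p, selected = selection)
}
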