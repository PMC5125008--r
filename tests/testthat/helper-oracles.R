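# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity from its defining formula (loops, enumeration),
# never through the package's own code paths.

# Pearson chi-square on a 2x3 table, plain loops, zero-margin columns dropped
oracleChisq <- function(tab) {
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) return(list(statistic = 0, p = 1))
  stat <- 0
  N <- sum(tab)
  for (i in 1:2) for (k in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, k]) / N
    stat <- stat + (tab[i, k] - e)^2 / e
  }
  df <- ncol(tab) - 1
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE), df = df)
}

# Cochran-Armitage trend statistic from its defining formula, plain loops
oracleTrend <- function(tab, s = c(0, 1, 2)) {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); N <- n1 + n2
  T1 <- 0; Tall <- 0; T2 <- 0
  for (k in 1:3) {
    T1 <- T1 + s[k] * tab[1, k]
    Tall <- Tall + s[k] * (tab[1, k] + tab[2, k])
    T2 <- T2 + s[k]^2 * (tab[1, k] + tab[2, k])
  }
  den <- n1 * n2 * (N * T2 - Tall^2)
  if (den <= 0) return(list(statistic = 0, p = 1))
  stat <- N * (N * T1 - n1 * Tall)^2 / den
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# windowed power mean by direct enumeration
oracleFilter <- function(s, l, p) {
  d <- length(s)
  h <- (l - 1) / 2
  out <- numeric(d)
  for (j in seq_len(d)) {
    w <- max(1, j - h):min(d, j + h)
    out[j] <- (mean(s[w]^p))^(1 / p)
  }
  out
}

# one-sided Fisher p by enumeration over all admissible 2x2 tables
oracleFisher <- function(a, b) {
  r1 <- sum(a); c1 <- a[1] + b[1]; N <- sum(a) + sum(b)
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- sapply(xs, function(x)
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1))
  sum(probs[xs >= a[1]])
}

# random 2x3 case-control table with positive row sums
randomTable <- function(maxN = 40) {
  repeat {
    tab <- matrix(rpois(6, lambda = runif(1, 1, maxN)), 2, 3)
    if (all(rowSums(tab) > 0)) return(tab)
  }
}

# tiny deterministic study builder: explicit genotype matrix + phenotypes
makeStudy <- function(g, y, chromosome = NULL) {
  g <- as.matrix(g)
  info <- S4Vectors::DataFrame(
    snp_id = sprintf("s%03d", seq_len(nrow(g))),
    chromosome = chromosome %||% rep("1", nrow(g)),
    position = seq_len(nrow(g)),
    allele_major = "A", allele_minor = "B")
  GenotypeStudy(g, y, snpInfo = info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# generic box-constrained QP oracle for the no-bias SVM dual
#   min_a  a'Qa/2 - sum(a)   s.t.  0 <= a <= C
# solved by projected gradient descent -- an algorithm family independent
# of the coordinate-descent implementation under test
oracleSvmDual <- function(X, y, C, iters = 2e5) {
  n <- nrow(X)
  Q <- (y %*% t(y)) * tcrossprod(X)
  eta <- 1 / (max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
              + 1e-12)
  a <- rep(0, n)
  for (i in seq_len(iters)) {
    a2 <- pmin(pmax(a - eta * (Q %*% a - 1), 0), C)
    if (max(abs(a2 - a)) < 1e-12) { a <- a2; break }
    a <- a2
  }
  as.numeric(t(X) %*% (as.numeric(a) * y))
}

# simulateGenotypes runs under the ambient RNG stream; fix it first
.withSeedCfg <- function(cfg) { set.seed(cfg$seed); cfg }

# small simulated study shared by several files
quickSim <- function(seed = 1, n = 60, d = 40, nCausal = 0, beta = 1,
                     copyProb = 0.9) {
  simulateStudy(simulationConfig(nCases = n / 2, nControls = n / 2, d = d,
                                 blockLength = 10, copyProb = copyProb,
                                 nCausal = nCausal, effectSizes = beta,
                                 seed = seed))
}
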