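scrSmall <- function(k = 5) screeningConfig(C = 0.01, windowSize = 3, k = k)

test_that("permutation null obeys its contract and determinism", {
  sim <- quickSim(seed = 21, n = 40, d = 20)
  d1 <- permutationNull(sim$study, scrSmall(), B = 8, seed = 99)
  d2 <- permutationNull(sim$study, scrSmall(), B = 8, seed = 99)
  expect_identical(d1@minP, d2@minP)
  expect_equal(dim(d1@minP), c(8L, 1L))
  expect_true(all(d1@minP > 0 & d1@minP <= 1))

  one <- permutationNull(sim$study, scrSmall(), B = 1, seed = 1)
  expect_length(one@minP, 1L)

  keep <- permutationNull(sim$study, scrSmall(), B = 4, seed = 5,
                          keepAll = TRUE)
  expect_length(keep@pValues, 4L)
  expect_length(keep@pValues[[1]][[1]], 5L)
  expect_equal(min(keep@pValues[[2]][[1]]), unname(keep@minP[2, 1]))
})

test_that("fwer threshold is the stated empirical lower quantile", {
  mk <- function(minp) new("PermutationNull", B = length(minp),
                           units = "all",
                           minP = matrix(minp, ncol = 1), pValues = NULL,
                           k = 5L, test = "trend", seed = NA_real_)
  dist <- mk(c(0.001, 0.01, 0.02, 0.2, 0.5))
  expect_equal(unname(tStar(fwerThreshold(dist, 0.2))), 0.001)
  # all-ones distribution is degenerate at 1
  expect_equal(unname(tStar(fwerThreshold(mk(rep(1, 5)), 0.2))), 1)
  # alpha below 1/B: nothing can be rejected
  expect_equal(unname(tStar(fwerThreshold(dist, 0.1))), 0)
  # at most a fraction alpha of permutations fall strictly below t*
  set.seed(22)
  for (r in 1:20) {
    mp <- runif(50)
    t <- unname(tStar(fwerThreshold(mk(mp), 0.13)))
    expect_lte(mean(mp < t), 0.13)
  }
})

test_that("gfwer threshold generalizes the fwer quantile", {
  rows <- list(list(c(0.01, 0.5, 1, 1, 1)), list(c(0.02, 0.6, 1, 1, 1)))
  dist <- new("PermutationNull", B = 2L, units = "all",
              minP = matrix(c(0.01, 0.02), ncol = 1), pValues = rows,
              k = 5L, test = "trend", seed = NA_real_)
  expect_equal(unname(tStar(gfwerThreshold(dist, 0.5, order = 1))), 0.5)
  # order 0 reduces to the fwer rule
  expect_equal(unname(tStar(gfwerThreshold(dist, 0.5, order = 0))),
               unname(tStar(fwerThreshold(dist, 0.5))))
  # monotone in the order parameter
  expect_lte(unname(tStar(gfwerThreshold(dist, 0.5, order = 1))),
             unname(tStar(gfwerThreshold(dist, 0.5, order = 2))))
  expect_error(gfwerThreshold(dist, 0.5, order = 5), "smaller")
})

test_that("enfr threshold counts pooled rejections", {
  rows <- list(list(c(0.01, 0.04, 1)), list(c(0.02, 0.5, 1)))
  dist <- new("PermutationNull", B = 2L, units = "all",
              minP = matrix(c(0.01, 0.02), ncol = 1), pValues = rows,
              k = 3L, test = "trend", seed = NA_real_)
  # pooled sorted: 0.01 0.02 0.04 0.5 1 1; floor(1*2)=2nd smallest
  expect_equal(unname(tStar(enfrThreshold(dist, 1))), 0.02)
  expect_equal(unname(tStar(enfrThreshold(dist, 0))), 0)
  expect_lte(unname(tStar(enfrThreshold(dist, 0.5))),
             unname(tStar(enfrThreshold(dist, 1.5))))
})

test_that("bonferroni threshold is alpha over d", {
  expect_equal(unname(tStar(bonferroniThreshold(1, 0.05))), 0.05)
  expect_equal(unname(tStar(bonferroniThreshold(500, 0.05))), 1e-4)
  expect_error(bonferroniThreshold(0, 0.05), "d")
})

test_that("minp equals the k = d workflow bit for bit", {
  for (sd in 1:3) {
    sim <- quickSim(seed = 30 + sd, n = 40, d = 15)
    mp <- minpThreshold(sim$study, "trend", B = 40, alpha = 0.1, seed = sd)
    full <- runCombi(sim$study,
                     screeningConfig(C = 0.01, windowSize = 3, k = 15,
                                     perChromosome = FALSE),
                     test = "trend", alpha = 0.1, B = 40, seed = sd)
    expect_identical(unname(tStar(mp$threshold)), unname(tStar(full)))
  }
})

test_that("minp controls the family-wise error rate under the null", {
  # Monte-Carlo FWER of the MinP baseline on global-null studies
  reps <- 60; B <- 60; alpha <- 0.05
  fw <- 0
  for (r in seq_len(reps)) {
    sim <- simulateNullStudy(simulationConfig(nCases = 50, nControls = 50,
                                              d = 40, seed = 4000 + r))
    rp <- runRpvt(sim$study, threshold = "minp", alpha = alpha, B = B,
                  seed = r)
    fw <- fw + (length(rejectedSnps(rp)) > 0)
  }
  expect_lte(fw / reps, alpha + 3 * sqrt(alpha * (1 - alpha) / reps))
})

test_that("p* under a causal law is not stochastically smaller than under
           the matched global null", {
  # relaxed subset pivotality, checked empirically at desk scale: the
  # smallest masked p-value over true-null SNPs of a causal study versus
  # the same functional of a matched null study.  True nulls exclude the
  # causal SNP's entire LD block (SNPs in LD with a causal locus are
  # genuinely associated with the phenotype, not null).
  scr <- scrSmall(k = 6)
  causal <- nullv <- numeric(30)
  for (r in 1:30) {
    cfg <- simulationConfig(nCases = 40, nControls = 40, d = 30,
                            blockLength = 10, nCausal = 1,
                            causalIndices = 15, effectSizes = 1.5,
                            seed = 8000 + r)
    simC <- simulateStudy(cfg)
    selC <- screenStudy(simC$study, scr)$selected
    pvC <- maskedPValues(simC$study, selC, "trend")$p_value
    keep <- selC & !(seq_len(30) %in% 11:20)   # true-null positions only
    causal[r] <- if (any(keep)) min(pvC[keep]) else 1
    simN <- simulateNullStudy(cfg)
    selN <- screenStudy(simN$study, scr)$selected
    nullv[r] <- min(maskedPValues(simN$study, selN, "trend")$p_value)
  }
  w <- suppressWarnings(stats::wilcox.test(causal, nullv,
                                           alternative = "less"))
  expect_gt(w$p.value, 0.01)
})

test_that("min-p laws match between observed and permuted workflows under
           the global null", {
  # exchangeability: the observed min masked p-value and one permutation
  # draw come from the same law; compare the two samples across seeds
  obs <- perm <- numeric(40)
  scr <- scrSmall(k = 4)
  for (r in 1:40) {
    sim <- simulateNullStudy(simulationConfig(nCases = 30, nControls = 30,
                                              d = 20, seed = 5000 + r))
    sel <- screenStudy(sim$study, scr)$selected
    obs[r] <- min(maskedPValues(sim$study, sel, "trend")$p_value)
    perm[r] <- permutationNull(sim$study, scr, B = 1, seed = r)@minP[1, 1]
  }
  expect_gt(suppressWarnings(ks.test(obs, perm))$p.value, 0.01)
})
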