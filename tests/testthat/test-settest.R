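# Combined-evidence set test: statistic, closed-form independence null,
# Monte-Carlo copula null and the LD-driven correlation model; plus the
# multiple-testing utilities.

test_that("the combined statistic is the sum of -log10 p", {
  expect_equal(combinedStatistic(c(0.1, 0.1)), 2)
  expect_equal(combinedStatistic(rep(1, 7)), 0)
  expect_error(combinedStatistic(c(0.5, 0)), "floor")
  p <- runif(20)
  expect_equal(combinedStatistic(p), -sum(log10(p)), tolerance = 1e-10)
})

test_that("the independence closed form is Fisher's method up to 2 ln 10", {
  expect_equal(overallP(fisherIndependent(0.05)), 0.05, tolerance = 1e-12)
  # n = 2, p = (0.1, 0.1): P(product < 0.01) = 0.01 (1 - ln 0.01)
  expect_equal(overallP(fisherIndependent(c(0.1, 0.1))),
               0.01 * (1 - log(0.01)), tolerance = 1e-12)
  # equivalence with pchisq at 2 ln10 T, df = 2n
  p <- c(0.2, 0.01, 0.7)
  Tobs <- combinedStatistic(p)
  expect_equal(overallP(fisherIndependent(p)),
               pchisq(2 * log(10) * Tobs, df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Monte-Carlo under identity correlation agrees with the closed form", {
  p <- c(0.02, 0.3, 0.6, 0.15, 0.8)
  B <- 200000
  mc <- simulateSetNull(p, nReplicates = B, seed = 101)
  exact <- overallP(fisherIndependent(p))
  se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(overallP(mc) - exact), 3 * se)
  expect_equal(mc@statistic, combinedStatistic(p), tolerance = 1e-10)
})

test_that("perfect correlation collapses the null onto n * (-log10 U)", {
  n <- 3
  corr <- matrix(1, n, n)
  p <- rep(0.5, n)
  set.seed(30)
  # reproduce the null sample the same way the tested code draws it
  ev <- eigen(corr, symmetric = TRUE)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Z <- L %*% matrix(rnorm(n * 50000), n)
  Tnull <- -colSums(log10(2 * pnorm(-abs(Z))))
  # all columns of Z identical => T/n maps back to a uniform
  u <- 10^(-Tnull / n)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
  # the tested path accepts the singular matrix and gives a sane answer
  mc <- simulateSetNull(p, corr, nReplicates = 50000, seed = 31)
  # T = 3 * -log10(0.5); null P(T' > T) = P(U < 0.5) = 0.5
  expect_lt(abs(overallP(mc) - 0.5), 0.02)
})

test_that("an observed statistic of zero has overall p near 1", {
  mc <- simulateSetNull(rep(1, 4), nReplicates = 20000, seed = 32)
  expect_gt(overallP(mc), 0.999)
})

test_that("the Monte-Carlo null is reproducible and monotone in T", {
  p1 <- c(0.05, 0.2, 0.4)
  a <- simulateSetNull(p1, nReplicates = 50000, seed = 7)
  b <- simulateSetNull(p1, nReplicates = 50000, seed = 7)
  expect_identical(overallP(a), overallP(b))
  p2 <- c(0.01, 0.1, 0.2)  # strictly smaller -> larger T
  c_ <- simulateSetNull(p2, nReplicates = 50000, seed = 7)
  expect_gt(combinedStatistic(p2), combinedStatistic(p1))
  expect_lte(overallP(c_), overallP(a))
  # add-one smoothing is the conservative variant
  d <- simulateSetNull(p1, nReplicates = 50000, seed = 7, addOne = TRUE)
  expect_gt(overallP(d), overallP(a))
})

test_that("the correlation model applies the product rule within phenotypes", {
  si <- data.frame(snp_id = c("a", "b", "c", "d"),
                   chromosome = c(1L, 1L, 2L, 3L),
                   position = c(1e6, 2e6, 1e6, 1e6))
  r2 <- diag(4); r2[1, 2] <- r2[2, 1] <- 0.25
  dimnames(r2) <- list(si$snp_id, si$snp_id)
  ld <- ldMatrix(r2, si)

  # single-SNP tests, same phenotype, within 2 Mb: latent corr sqrt(r2)
  ps <- pValueSet(c("t1", "t2"), c(0.5, 0.5), snp1 = c("a", "b"),
                  chr1 = c(1, 1), pos1 = c(1e6, 2e6), phenotype = "DBP")
  C <- buildTestCorrelation(ps, ld)
  expect_equal(C[1, 2], 0.5)

  # all SNPs on different chromosomes -> identity
  ps2 <- pValueSet(c("t1", "t2"), c(0.5, 0.5), snp1 = c("c", "d"),
                   chr1 = c(2, 3), pos1 = c(1e6, 1e6), phenotype = "DBP")
  expect_equal(unname(buildTestCorrelation(ps2, ld)), diag(2))

  # interaction tests sharing both SNPs, same phenotype -> correlation 1
  ps3 <- pValueSet(c("t1", "t2"), c(0.5, 0.5), snp1 = c("a", "a"),
                   chr1 = 1, pos1 = 1e6, snp2 = c("c", "c"), chr2 = 2,
                   pos2 = 1e6, phenotype = "expr1")
  expect_equal(buildTestCorrelation(ps3, ld)[1, 2], 1)

  # pair tests sharing one SNP, the others differing with r2 = 0.25:
  # product rule gives 1 * sqrt(0.25) = 0.5
  ps4 <- pValueSet(c("t1", "t2"), c(0.5, 0.5), snp1 = c("a", "b"),
                   chr1 = 1, pos1 = c(1e6, 2e6), snp2 = c("c", "c"),
                   chr2 = 2, pos2 = 1e6, phenotype = "expr1")
  expect_equal(buildTestCorrelation(ps4, ld)[1, 2], 0.5)

  # different phenotypes are independent under the null even with
  # identical SNPs; the override switch restores the SNP-only rule
  ps5 <- pValueSet(c("t1", "t2"), c(0.5, 0.5), snp1 = c("a", "a"),
                   chr1 = 1, pos1 = 1e6, snp2 = c("c", "c"), chr2 = 2,
                   pos2 = 1e6, phenotype = c("probeA", "probeB"))
  expect_equal(unname(buildTestCorrelation(ps5, ld)), diag(2))
  expect_equal(buildTestCorrelation(ps5, ld, respectPhenotype = FALSE)[1, 2], 1)

  expect_error(buildTestCorrelation(
    pValueSet("t1", 0.5, snp1 = "zz", chr1 = 1, pos1 = 1), ld), "missing")
})

test_that("Bonferroni thresholds reproduce the standard corrected levels", {
  expect_equal(signif(bonferroniThreshold(0.05, 75), 2), 0.00067)
  expect_equal(signif(bonferroniThreshold(0.05, 12), 2), 0.0042)
  expect_equal(signif(bonferroniThreshold(0.05, 14), 2), 0.0036)
  expect_error(bonferroniThreshold(1.2, 10))
})

test_that("Benjamini-Yekutieli adjustment matches the harmonic-number formula", {
  expect_equal(byAdjust(0.03), 0.03)  # single test: adjusted = raw
  n <- 6
  p <- rep(0.01, n)
  H <- sum(1 / seq_len(n))
  expect_equal(byAdjust(p), pmin(1, p * H * n / n), tolerance = 1e-12)
  set.seed(33)
  q <- runif(10)
  expect_true(all(byAdjust(q) >= q))
})

test_that("the set test keeps its own type-I error under the uniform null", {
  set.seed(34)
  rej <- mean(replicate(1000, {
    overallP(fisherIndependent(runif(10))) < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})
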