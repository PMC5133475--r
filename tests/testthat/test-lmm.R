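# Spectral LMM core: OLS equivalence at K = I, noise-free recovery,
# variance-component recovery, grid dominance and the scan contracts.

test_that("with K = I the mixed model reduces to ordinary least squares", {
  set.seed(11)
  n <- 80
  X <- cbind(intercept = 1, x = rnorm(n), z = rbinom(n, 2, 0.3))
  y <- as.numeric(X %*% c(1, 0.5, -0.3) + rnorm(n))
  f <- fitLMM(y, X, diag(n), method = "ML")
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_lt(max(abs(f@beta - coef(ols))), 1e-8)
  # total variance matches the ML residual variance regardless of the split
  expect_equal(f@sigmaG2 + f@sigmaE2, sum(residuals(ols)^2) / n,
               tolerance = 1e-6)
})

test_that("noise-free data are interpolated exactly", {
  set.seed(12)
  n <- 50
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(2, -1))
  K <- as.matrix(pedigreeKinship(unrelatedPed(n)))
  f <- fitLMM(y, X, K)
  expect_lt(max(abs(f@beta - c(2, -1))), 1e-8)
  expect_lt(f@sigmaE2, 1e-10)
})

test_that("the returned delta dominates every grid point", {
  set.seed(13)
  nFam <- 10
  ped <- pedigree(
    family_id = rep(paste0("F", seq_len(nFam)), each = 4),
    individual_id = rep(c("1", "2", "3", "4"), nFam),
    father_id = rep(c(NA, NA, "1", "1"), nFam),
    mother_id = rep(c(NA, NA, "2", "2"), nFam),
    sex = rep(c(1L, 2L, 1L, 2L), nFam))
  K <- as.matrix(pedigreeKinship(ped))
  n <- nrow(K)
  y <- drawTrait(K, 1, 1)
  X <- cbind(intercept = rep(1, n))
  f <- fitLMM(y, X, K)
  e <- eigen(K, symmetric = TRUE)
  ytil <- as.numeric(crossprod(e$vectors, y))
  Xtil <- crossprod(e$vectors, X)
  llAt <- function(delta) {
    w <- 1 / (pmax(e$values, 0) + delta)
    b <- sum(w * Xtil[, 1] * ytil) / sum(w * Xtil[, 1]^2)
    r <- ytil - Xtil[, 1] * b
    sg2 <- sum(w * r^2) / n
    -0.5 * (n * log(2 * pi) + sum(log(pmax(e$values, 0) + delta)) +
            n * log(sg2) + n)
  }
  grid <- 10^seq(-5, 5, length.out = 64)
  expect_gte(f@logLik + 1e-7, max(vapply(grid, llAt, 0)))
  expect_equal(f@logLik, llAt(f@delta), tolerance = 1e-8)
})

test_that("variance-component recovery: delta-hat centers on truth", {
  # sigma_g^2 = sigma_e^2 = 1 on ~800 family-structured individuals
  nFam <- 16
  cfg <- simConfig(nFamilies = nFam, familySizeMean = 50, seed = 61)
  ped <- simulatePedigree(cfg)
  K <- as.matrix(pedigreeKinship(ped))
  n <- nrow(K)
  expect_gt(n, 600)
  X <- cbind(intercept = rep(1, n))
  set.seed(14)
  deltas <- replicate(20, {
    y <- drawTrait(K, 1, 1)
    fitLMM(y, X, K)@delta
  })
  expect_gt(mean(deltas), 0.7)
  expect_lt(mean(deltas), 1.4)
})

test_that("h2 is recovered within 0.1 at n ~ 1000", {
  cfg <- simConfig(nFamilies = 20, familySizeMean = 48, seed = 67)
  ped <- simulatePedigree(cfg)
  K <- as.matrix(pedigreeKinship(ped))
  n <- nrow(K)
  expect_gt(n, 800)
  X <- cbind(intercept = rep(1, n))
  h2true <- 0.5
  set.seed(15)
  h2hat <- replicate(20, {
    y <- drawTrait(K, h2true, 1 - h2true)
    f <- fitLMM(y, X, K)
    f@sigmaG2 / (f@sigmaG2 + f@sigmaE2)
  })
  expect_lt(abs(mean(h2hat) - h2true), 0.1)
})

test_that("assoc scan p-values agree with the OLS likelihood-ratio oracle at K = I", {
  set.seed(16)
  n <- 120
  gen <- handGenotypes(cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4)))
  y <- rnorm(n) + 0.4 * dosage(gen)[, 1]
  names(y) <- sampleKeys(gen)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  res <- assocScan(gen, y, K)
  for (j in 1:2) {
    g <- dosage(gen)[, j]
    rss1 <- sum(residuals(lm(y ~ g))^2)
    rss0 <- sum(residuals(lm(y ~ 1))^2)
    lrtOracle <- n * log(rss0 / rss1)
    expect_equal(res$statistic[j], lrtOracle, tolerance = 1e-6)
    expect_equal(res$p[j],
                 pchisq(lrtOracle, 1, lower.tail = FALSE), tolerance = 1e-6)
  }
})

test_that("scan p-values are invariant to trait affine maps and allele recoding", {
  cfg <- simConfig(nFamilies = 6, familySizeMean = 12, nSnps = 10,
                   blockSize = 5, seed = 71)
  ped <- simulatePedigree(cfg)
  gen <- geneDrop(ped, cfg)
  K <- repairPSD(rrmKinship(gen))
  set.seed(17)
  y <- drawTrait(as.matrix(K), 0.5, 0.5)
  names(y) <- sampleKeys(gen)
  ids <- snpInfo(gen)$snp_id[1:4]
  p0 <- assocScan(gen, y, K, ids)$p
  p1 <- assocScan(gen, 10 * y - 3, K, ids)$p
  expect_equal(p1, p0, tolerance = 1e-6)
  flip <- genotypeMatrix(2 - dosage(gen), snpInfo(gen), samples(gen))
  p2 <- assocScan(flip, y, K, ids)$p
  expect_equal(p2, p0, tolerance = 1e-6)
})

test_that("a strong causal SNP in noise-free data is detected at p < 1e-12", {
  set.seed(18)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  gen <- handGenotypes(cbind(g, rbinom(n, 2, 0.3)))
  y <- 2 * g + 0.001 * rnorm(n)
  names(y) <- sampleKeys(gen)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  expect_lt(assocScan(gen, y, K, "rs1")$p[1], 1e-12)
})

test_that("monomorphic SNPs yield NA rows; missing dosages drop per SNP", {
  set.seed(19)
  n <- 40
  d <- cbind(rbinom(n, 2, 0.3), rep(0, n), rbinom(n, 2, 0.4))
  d[1:5, 3] <- NA
  gen <- handGenotypes(d)
  y <- rnorm(n); names(y) <- sampleKeys(gen)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  expect_message(res <- assocScan(gen, y, K), "monomorphic")
  expect_true(is.na(res$p[2]))
  expect_false(anyNA(res$p[c(1, 3)]))
  # the SNP with missing data was fit on n - 5 individuals; its oracle
  g3 <- d[!is.na(d[, 3]), 3]; y3 <- y[!is.na(d[, 3])]
  lrtOracle <- length(y3) * log(sum(residuals(lm(y3 ~ 1))^2) /
                                sum(residuals(lm(y3 ~ g3))^2))
  expect_equal(res$statistic[3], lrtOracle, tolerance = 1e-6)
})

test_that("rank-deficient designs error after pruning", {
  set.seed(20)
  n <- 30
  x <- rnorm(n)
  X <- cbind(1, x, 2 * x)
  expect_error(fitLMM(rnorm(n), X, diag(n)), "rank-deficient")
})

test_that("OLS scan matches the scan at K = I up to Wald-vs-LRT asymptotics", {
  set.seed(21)
  n <- 1900
  d <- cbind(rbinom(n, 2, 0.25), rbinom(n, 2, 0.4), rbinom(n, 2, 0.1))
  gen <- handGenotypes(d)
  med <- rbinom(n, 1, 0.2)
  y <- rnorm(n) + 0.3 * med
  names(y) <- sampleKeys(gen)
  covs <- cbind(medication = med)
  rownames(covs) <- names(y)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  wald <- olsAssoc(gen, y, covariates = covs)
  lrt <- assocScan(gen, y, K, covariates = covs)
  expect_lt(max(abs(wald$p - lrt$p)), 0.002)
  expect_error(olsAssoc(gen, y, covariates = cbind(snpcopy = d[, 1]),
                        snpIds = "rs1"),
               "collinear|rank")
})

test_that("OLS null p-values are uniform at large n", {
  set.seed(22)
  n <- 1000
  m <- 60
  gen <- handGenotypes(sapply(seq_len(m), function(i) rbinom(n, 2, 0.3)))
  y <- rnorm(n); names(y) <- sampleKeys(gen)
  res <- olsAssoc(gen, y)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})
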