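# Synthetic family-study generator: pedigree structure, gene-dropping
# (allele frequencies, LD, inheritance), phenotype and expression
# models, and determinism.

test_that("simulated pedigrees have the declared family structure", {
  cfg <- simConfig(nFamilies = 20, familySizeMean = 10, seed = 3)
  ped <- simulatePedigree(cfg)
  p <- as.data.frame(ped)
  expect_equal(length(unique(p$family_id)), 20L)
  founder <- is.na(p$father_id) & is.na(p$mother_id)
  # non-founders always have both parents, in-pedigree (validity enforces)
  expect_true(all(!is.na(p$father_id[!founder]) & !is.na(p$mother_id[!founder])))
  expect_s4_class(ped, "Pedigree")  # validity (incl. acyclicity) passed

  # expected total size tracks nFamilies * familySizeMean
  cfg2 <- simConfig(nFamilies = 12, familySizeMean = 48, seed = 11)
  n <- nrow(as.data.frame(simulatePedigree(cfg2)))
  expect_gt(n, 12 * 48 * 0.6)
  expect_lt(n, 12 * 48 * 1.4)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  cfg <- simConfig(nFamilies = 2, familySizeMean = 10, nSnps = 30,
                   blockSize = 5, seed = 21)
  pedA <- simulatePedigree(cfg)
  pedB <- simulatePedigree(cfg)
  expect_identical(as.data.frame(pedA), as.data.frame(pedB))
  expect_identical(dosage(geneDrop(pedA, cfg)), dosage(geneDrop(pedA, cfg)))
  cfgOther <- simConfig(nFamilies = 2, familySizeMean = 10, nSnps = 30,
                        blockSize = 5, seed = 22)
  expect_false(identical(dosage(geneDrop(pedA, cfg)),
                         dosage(geneDrop(pedA, cfgOther))))
  ph1 <- simulateLongitudinalPhenotypes(geneDrop(pedA, cfg), pedA, cfg)
  ph2 <- simulateLongitudinalPhenotypes(geneDrop(pedA, cfg), pedA, cfg)
  expect_identical(ph1, ph2)
})

test_that("founder allele frequencies match the binomial oracle", {
  n <- 400
  ped <- unrelatedPed(n)
  cfg <- simConfig(nFamilies = n, nSnps = 1, blockSize = 1, seed = 7)
  gen <- geneDrop(ped, cfg, mafs = 0.3)
  # 2n founder alleles, each minor with probability 0.3
  freq <- mean(dosage(gen)) / 2
  se <- sqrt(0.3 * 0.7 / (2 * n))
  expect_lt(abs(freq - 0.3), 3 * se)
})

test_that("founders obey Hardy-Weinberg and block-free SNPs are uncorrelated", {
  n <- 500
  ped <- unrelatedPed(n)
  m <- 120
  cfg <- simConfig(nFamilies = n, nSnps = m, blockSize = 4,
                   withinBlockR = 0, seed = 13)
  d <- dosage(geneDrop(ped, cfg))
  # HW chi-square GoF per SNP at alpha = 0.001: failures should be rare
  fails <- 0L
  for (j in seq_len(m)) {
    f <- mean(d[, j]) / 2
    if (f == 0 || f == 1) next
    expc <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- tabulate(d[, j] + 1L, 3L)
    stat <- sum((obs - expc)^2 / pmax(expc, 1e-12))
    if (pchisq(stat, df = 1, lower.tail = FALSE) < 0.001) fails <- fails + 1L
  }
  expect_lte(fails, qbinom(0.999, m, 0.001) + 1L)

  # withinBlockR = 0: adjacent-SNP genotype correlation is null
  rs <- vapply(seq_len(m - 1), function(j) {
    if (sd(d[, j]) == 0 || sd(d[, j + 1]) == 0) return(NA_real_)
    cor(d[, j], d[, j + 1])
  }, 0)
  expect_lt(abs(mean(rs, na.rm = TRUE)), 3 / sqrt(n))
})

test_that("within-block LD is present and decays across blocks", {
  n <- 500
  ped <- unrelatedPed(n)
  cfg <- simConfig(nFamilies = n, nSnps = 40, blockSize = 10,
                   withinBlockR = 0.9, seed = 17)
  d <- dosage(geneDrop(ped, cfg))
  within <- abs(cor(d[, 1], d[, 2]))
  across <- abs(cor(d[, 10], d[, 11]))  # last of block 1, first of block 2
  expect_gt(within, 0.4)
  expect_lt(across, 3 / sqrt(n))
})

test_that("parent-offspring dosage covariance matches kinship theory", {
  # cov(d_parent, d_child) = 2 maf (1 - maf) * 2Phi with 2Phi = 0.5
  nFam <- 250
  ped <- pedigree(
    family_id = rep(paste0("F", seq_len(nFam)), each = 3),
    individual_id = rep(c("1", "2", "3"), nFam),
    father_id = rep(c(NA, NA, "1"), nFam),
    mother_id = rep(c(NA, NA, "2"), nFam),
    sex = rep(c(1L, 2L, 1L), nFam))
  m <- 60
  cfg <- simConfig(nFamilies = nFam, nSnps = m, blockSize = 1, seed = 29)
  maf <- 0.3
  d <- dosage(geneDrop(ped, cfg, mafs = rep(maf, m)))
  fathers <- seq(1, 3 * nFam, by = 3)
  kids <- fathers + 2
  covs <- vapply(seq_len(m), function(j) cov(d[fathers, j], d[kids, j]), 0)
  theory <- 2 * maf * (1 - maf) * 0.5
  expect_lt(abs(mean(covs) - theory), 0.15 * theory + 3 * sd(covs) / sqrt(m))
})

test_that("null phenotypes are noise and causal effects surface", {
  cfg <- simConfig(nFamilies = 30, familySizeMean = 10, nSnps = 20,
                   blockSize = 5, traitHeritability = 0,
                   covariateEffects = c(age = 0, smoking = 0, medication = 0),
                   nExams = 1, seed = 31)
  ped <- simulatePedigree(cfg)
  gen <- geneDrop(ped, cfg)
  ph <- simulateLongitudinalPhenotypes(gen, ped, cfg)
  # h2 = 0, betas 0: DBP is iid noise; no family clustering
  fit <- summary(aov(DBP ~ family_id, data = ph))
  expect_gt(fit[[1]][["Pr(>F)"]][1], 0.001)

  # residual_sd -> 0 with one causal SNP: trait ~ dosage after adjustment
  cfg2 <- simConfig(nFamilies = 30, familySizeMean = 10, nSnps = 20,
                    blockSize = 5, traitHeritability = 0, residualSd = 1e-4,
                    nExams = 1, seed = 33)
  causal <- data.frame(snp_id = "snp00001", beta = 5)
  ph2 <- simulateLongitudinalPhenotypes(gen, ped, cfg2, causalSnps = causal)
  dt <- adjustAndAverage(ph2, "DBP")
  r <- cor(traitVector(dt)[sampleKeys(gen)], dosage(gen)[, "snp00001"])
  expect_gt(abs(r), 0.99)

  expect_error(
    simulateLongitudinalPhenotypes(gen, ped, cfg,
      causalSnps = data.frame(snp_id = "absent", beta = 1)),
    "absent")
})

test_that("expression generator encodes the product-term interaction", {
  cfg <- simConfig(nFamilies = 40, familySizeMean = 10, nSnps = 10,
                   blockSize = 1, traitHeritability = 0,
                   interactionEffect = 3, residualSd = 0.05, seed = 37)
  ped <- simulatePedigree(cfg)
  gen <- geneDrop(ped, cfg)
  pair <- c("snp00001", "snp00002")
  ex <- simulateExpression(gen, ped, cfg, pair)
  K <- diag(length(ex)); dimnames(K) <- list(names(ex), names(ex))
  res <- interactionTest(ex, gen, pair, K)
  expect_lt(res$p, 1e-6)  # strong signal, tiny noise
  expect_error(simulateExpression(gen, ped, cfg, c("snp00001", "nope")),
               "absent")
})

test_that("empirical founder RRM approaches the identity as SNPs grow", {
  n <- 150
  ped <- unrelatedPed(n)
  offdiag <- vapply(c(200, 1600), function(m) {
    cfg <- simConfig(nFamilies = n, nSnps = m, blockSize = 1, seed = 41)
    k <- as.matrix(rrmKinship(geneDrop(ped, cfg)))
    mean(abs(k[upper.tri(k)]))
  }, 0)
  expect_lt(offdiag[2], offdiag[1])       # shrinks with m
  expect_lt(offdiag[2], 2 / sqrt(1600) * 2)
})
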