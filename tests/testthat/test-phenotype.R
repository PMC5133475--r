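# Derived blood-pressure traits and the adjust-then-average reduction.

test_that("MAP and PP follow their defining formulas", {
  expect_equal(deriveMAP(80, 120), 2 / 3 * 80 + 1 / 3 * 120)
  expect_equal(deriveMAP(60, 150), 90)
  expect_equal(derivePP(80, 120), 40)
  expect_equal(derivePP(90, 91), 1)
  # MAP lies strictly between DBP and SBP; degenerate limit MAP -> DBP
  eps <- 1e-9
  expect_lt(abs(deriveMAP(80, 80 + eps) - 80), 1e-8)
  dbp <- runif(50, 60, 100); sbp <- dbp + runif(50, 5, 60)
  m <- deriveMAP(dbp, sbp)
  expect_true(all(m > dbp & m < sbp))
  # swapped arguments violate the SBP > DBP precondition
  expect_error(deriveMAP(120, 80), "exceed")
  expect_error(derivePP(120, 80), "exceed")
})

mkPheno <- function(n, exams = 1, trait, age = NULL, smoking = NULL,
                    medication = NULL) {
  do.call(rbind, lapply(seq_len(exams), function(e) data.frame(
    family_id = "F1", individual_id = as.character(seq_len(n)), exam = e,
    SBP = trait + 40, DBP = trait, HTN = 0L,
    age = if (is.null(age)) rep(50, n) + e else age,
    smoking = if (is.null(smoking)) rep(0L, n) else smoking,
    medication = if (is.null(medication)) rep(0L, n) else medication)))
}

test_that("with no covariate signal and one exam the output is the z-scored trait", {
  set.seed(1)
  y <- rnorm(40, 90, 12)
  ph <- mkPheno(40, 1, y)
  expect_warning(adjustAndAverage(ph, "DBP"), "constant covariate")
  out <- suppressWarnings(adjustAndAverage(ph, "DBP"))
  expect_equal(out$value[order(as.integer(out$individual_id))],
               as.numeric(scale(y)), tolerance = 1e-12)
})

test_that("covariate adjustment removes a known age effect", {
  set.seed(2)
  n <- 300
  age <- runif(n, 30, 80)
  y <- 70 + 0.8 * age + rnorm(n, 0, 5)
  smoking <- rbinom(n, 1, 0.3)
  ph <- mkPheno(n, 1, y, age = age, smoking = smoking)
  out <- suppressWarnings(adjustAndAverage(ph, "DBP"))
  v <- out$value[order(as.integer(out$individual_id))]
  expect_lt(abs(cor(v, age)), 2 / sqrt(n))
  # exact orthogonality to each retained covariate (pre-averaging this is
  # an OLS residual property; with one exam it survives averaging)
  expect_lt(abs(sum(v * (age - mean(age)))) / n, 1e-8)
  expect_lt(abs(sum(v * (smoking - mean(smoking)))) / n, 1e-8)
})

test_that("averaging over identical exams equals the one-exam answer", {
  set.seed(3)
  n <- 60
  age <- runif(n, 30, 80)
  y <- 75 + 0.5 * age + rnorm(n)
  ph1 <- mkPheno(n, 1, y, age = age)
  ph2 <- rbind(ph1, transform(ph1, exam = 2))  # same values twice
  suppressWarnings({
    out1 <- adjustAndAverage(ph1, "DBP")
    out2 <- adjustAndAverage(ph2, "DBP")
  })
  expect_equal(out2$value, out1$value, tolerance = 1e-10)
  expect_equal(out2$n_exams_used, rep(2L, n))
})

test_that("the derived trait is invariant to affine rescaling of the raw trait", {
  set.seed(4)
  n <- 80
  age <- runif(n, 30, 80)
  y <- 75 + 0.5 * age + rnorm(n, 0, 8)
  suppressWarnings({
    a <- adjustAndAverage(mkPheno(n, 1, y, age = age), "DBP")
    b <- adjustAndAverage(mkPheno(n, 1, 3 * y + 7, age = age), "DBP")
  })
  expect_equal(a$value, b$value, tolerance = 1e-10)
})

test_that("missing exams are averaged over what is available, never zero-filled", {
  set.seed(5)
  n <- 30
  ph <- mkPheno(n, 2, rnorm(n, 90, 10))
  ph$DBP[ph$exam == 2 & ph$individual_id == "1"] <- NA   # one exam missing
  ph$DBP[ph$individual_id == "2"] <- NA                  # all exams missing
  out <- suppressWarnings(adjustAndAverage(ph, "DBP"))
  expect_false("2" %in% out$individual_id)
  expect_equal(out$n_exams_used[out$individual_id == "1"], 1L)
  expect_equal(nrow(out), n - 1L)
})

test_that("both adjustment orders run and entirely-missing traits error", {
  cfg <- simConfig(nFamilies = 4, familySizeMean = 12, nSnps = 10,
                   blockSize = 5, seed = 43)
  ped <- simulatePedigree(cfg)
  ph <- simulateLongitudinalPhenotypes(geneDrop(ped, cfg), ped, cfg)
  a <- adjustAndAverage(ph, "MAP", order = "adjust_first")
  b <- adjustAndAverage(ph, "MAP", order = "average_first")
  expect_equal(nrow(a), nrow(b))
  expect_gt(cor(a$value, b$value[match(rownames(a), rownames(b))]), 0.95)
  ph$DBP <- NA_real_
  expect_error(adjustAndAverage(ph, "DBP"), "entirely missing")
})

test_that("HTN passes through the pipeline as a 0/1 quantitative trait", {
  cfg <- simConfig(nFamilies = 4, familySizeMean = 12, nSnps = 10,
                   blockSize = 5, seed = 47)
  ped <- simulatePedigree(cfg)
  ph <- simulateLongitudinalPhenotypes(geneDrop(ped, cfg), ped, cfg)
  out <- adjustAndAverage(ph, "HTN")
  expect_equal(mean(out$value), 0, tolerance = 1e-12)
  expect_equal(sd(out$value), 1, tolerance = 1e-12)
})
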