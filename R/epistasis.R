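## Additive-by-additive SNP-SNP interaction test on expression traits:
## two nested kinship LMMs -- M0 with intercept and the two minor-allele
## dosages, M1 adding their element-wise product -- compared by a
## 1-df likelihood-ratio test with per-model maximum-likelihood fits.

#' Nested mixed-model likelihood-ratio test for SNP-SNP interaction
#'
#' Fits M0 (intercept + d1 + d2) and M1 (M0 + d1*d2) by maximum
#' likelihood via \code{\link{fitLMM}}, with delta re-optimized under
#' each model, and reports \eqn{LRT = 2(\ell_1 - \ell_0)} (clamped at 0
#' against numerical jitter) against chi-squared with 1 df. Individuals
#' missing either dosage are dropped for this test only.
#'
#' @param expr named numeric expression trait vector (covariate-adjusted
#'   upstream; see \code{\link{expressionPrep}}).
#' @param genotypes \code{GenotypeMatrix} containing both SNPs.
#' @param pair character vector of two SNP ids.
#' @param K kinship matrix aligned by sample keys.
#' @param gene,probe labels carried into the result row.
#' @return one-row data.frame: test_id, snp1, snp2, chr1, chr2,
#'   phenotype (the probe label), beta (product-term coefficient), se,
#'   statistic, df = 1, p.
#' @export
interactionTest <- function(expr, genotypes, pair, K,
                            gene = NA_character_, probe = NA_character_) {
  stopifnot(length(pair) == 2)
  miss <- setdiff(pair, snpInfo(genotypes)$snp_id)
  if (length(miss)) stop("SNP(s) absent: ", paste(miss, collapse = ", "))
  al <- alignInputs(genotypes, expr, K)
  d1 <- al$d[, pair[1]]
  d2 <- al$d[, pair[2]]
  obs <- !is.na(d1) & !is.na(d2)
  if (sum(obs) < 10L)
    stop("fewer than 10 individuals after missing-data drop")
  d1 <- d1[obs]; d2 <- d2[obs]
  if (length(unique(d1)) < 2L || length(unique(d2)) < 2L)
    stop("SNP monomorphic in the analysis subsample")
  X0 <- cbind(intercept = 1, d1 = d1, d2 = d2)
  X1 <- cbind(X0, product = d1 * d2)
  if (qr(X1)$rank < 4L)
    stop("product column d1*d2 is collinear with {1, d1, d2}: ",
         "degenerate dosage configuration for pair ",
         paste(pair, collapse = " x "))
  y <- al$y[obs]
  Ksub <- al$K[obs, obs, drop = FALSE]
  f0 <- fitLMM(y, X0, Ksub, method = "ML")
  f1 <- fitLMM(y, X1, Ksub, method = "ML")
  lrt <- 2 * (f1@logLik - f0@logLik)
  if (is.nan(lrt)) lrt <- 0
  lrt <- max(lrt, 0)
  si <- snpInfo(genotypes)
  data.frame(
    test_id = paste(gene, probe, pair[1], pair[2], sep = ":"),
    snp1 = pair[1], snp2 = pair[2],
    chr1 = si$chromosome[si$snp_id == pair[1]],
    chr2 = si$chromosome[si$snp_id == pair[2]],
    phenotype = if (is.na(probe)) paste(pair, collapse = "x") else probe,
    beta = unname(f1@beta["product"]),
    se = sqrt(f1@vcovBeta["product", "product"]),
    statistic = lrt, df = 1L,
    p = pchisq(lrt, df = 1, lower.tail = FALSE),
    gene = gene, probe = probe,
    stringsAsFactors = FALSE)
}

#' Run interaction tests for a table of SNP pairs
#'
#' @param expr a named vector (used for every pair) or a named list /
#'   matrix of probe-level expression vectors indexed by
#'   \code{pairs$probe}.
#' @param pairs data.frame with columns gene, probe, snp1, snp2.
#' @inheritParams interactionTest
#' @return data.frame with one row per (pair, probe) test.
#' @export
interactionScan <- function(expr, genotypes, pairs, K) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    e <- if (is.list(expr)) expr[[pairs$probe[i]]] else expr
    interactionTest(e, genotypes, c(pairs$snp1[i], pairs$snp2[i]), K,
                    gene = pairs$gene[i], probe = pairs$probe[i])
  })
  do.call(rbind, rows)
}

#' Covariate-adjust and standardize an expression probe
#'
#' Delegates to the same per-exam adjustment used for the blood-pressure
#' phenotypes, with a single "exam": least-squares adjustment for the
#' covariates followed by z-standardization.
#'
#' @param rawExpr named numeric probe vector.
#' @param covariates data.frame of covariates aligned with
#'   \code{rawExpr} (rownames = sample keys), or NULL for plain
#'   z-scoring.
#' @return named numeric adjusted expression vector.
#' @export
expressionPrep <- function(rawExpr, covariates = NULL) {
  if (sd(rawExpr) == 0) stop("constant expression probe")
  if (is.null(covariates)) return(setNames(zscore(rawExpr), names(rawExpr)))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(rawExpr))
  setNames(zscore(adjustOnce(as.numeric(rawExpr), covariates)),
           names(rawExpr))
}
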