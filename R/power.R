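## Analytic power for a single-SNP additive effect on a quantitative
## trait, under the unrelated-sample approximation (so family data get
## an upper limit on power).

#' Analytic power for a single-SNP quantitative-trait test
#'
#' For an additive effect of \code{beta} trait units per minor allele at
#' minor-allele frequency \code{maf}, the 1-df association test has
#' noncentrality \eqn{\lambda = 2 n \, maf (1 - maf) \beta^2 / \sigma^2};
#' power is the noncentral chi-squared survival at the central
#' chi-squared critical value for \code{alpha}. Individuals are assumed
#' unrelated, so for family samples this is an upper limit.
#'
#' @param n sample size.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param beta additive effect, trait units per allele.
#' @param residualSd residual trait standard deviation (same units).
#' @param alpha significance level.
#' @return power in (0, 1).
#' @examples
#' analyticPower(954, maf = 0.3, beta = 0.5, residualSd = 10)
#' @export
analyticPower <- function(n, maf, beta, residualSd, alpha = 0.05) {
  stopifnot(n > 0, maf > 0, maf <= 0.5, residualSd > 0,
            alpha > 0, alpha < 1)
  lambda <- n * 2 * maf * (1 - maf) * beta^2 / residualSd^2
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' @rdname analyticPower
#' @param varExplained fraction of trait variance explained by the SNP,
#'   in (0, 1) -- the parameterization meta-analysis tables usually
#'   report. Equivalent to \code{analyticPower} with
#'   \eqn{\lambda = n \cdot ve / (1 - ve)}.
#' @export
powerFromVarianceExplained <- function(n, varExplained, alpha = 0.05) {
  stopifnot(n > 0, varExplained > 0, varExplained < 1,
            alpha > 0, alpha < 1)
  lambda <- n * varExplained / (1 - varExplained)
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}
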