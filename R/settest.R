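## Combined-evidence set statistic T = -sum_i log10 p_i over a set of
## association or interaction tests, with
##   * a Monte-Carlo null that draws latent multivariate-normal scores
##     with LD-induced correlation between nearby tests (Gaussian
##     copula), maps them to two-sided uniform p-values and recomputes T
##     per replicate, and
##   * the closed-form independence null: T * ln(10) ~ Gamma(n, 1)
##     (Fisher's statistic up to the factor 2 ln 10), used as an oracle
##     and a fast approximation.

#' Combined evidence statistic over a set of tests
#'
#' \eqn{T = -\sum_i \log_{10} p_i}: the untruncated variant of the rank
#' truncated product statistic. Large T means the set as a whole carries
#' more association evidence than expected.
#'
#' @param pset a \code{\linkS4class{PValueSet}} or a numeric vector of
#'   p-values in (0, 1].
#' @return the statistic (non-negative).
#' @examples
#' combinedStatistic(c(0.1, 0.1))  # 2
#' @export
combinedStatistic <- function(pset) {
  p <- if (is(pset, "PValueSet")) as.data.frame(pset)$p else as.numeric(pset)
  if (length(p) == 0L) stop("empty p-value set")
  if (any(p <= 0))
    stop("p = 0 is not representable; floor p at the smallest positive double before combining")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  -sum(log10(p))
}

#' Latent correlation model for the set-test null
#'
#' Builds the test-level correlation matrix used by
#' \code{\link{simulateSetNull}}. SNP-level latent correlation is
#' \eqn{+\sqrt{r^2}} for same-chromosome SNP pairs closer than
#' \code{window} base pairs and 0 otherwise (PLINK-style r² carries no
#' sign, so the positive root is used). For two interaction tests the
#' test-level correlation is the product of the two constituent SNP
#' correlations under the pair alignment that maximizes the product;
#' single-SNP tests use the SNP correlation directly; a single-SNP test
#' against a pair test takes the largest correlation with either
#' constituent. Tests computed on different phenotypes (or expression
#' probes) are uncorrelated under the null -- conditional on genotypes
#' their statistics are functions of independent traits -- so the
#' correlation is zeroed across phenotype labels. The result is
#' PSD-repaired.
#'
#' @param pset a \code{\linkS4class{PValueSet}} carrying SNP coordinates
#'   and phenotype labels.
#' @param ld an \code{\linkS4class{LDMatrix}} indexing every SNP named
#'   in \code{pset}.
#' @param window base-pair window for "nearby" (default 2 Mb; the
#'   interval is open: distance strictly less than \code{window}).
#' @param respectPhenotype set to \code{FALSE} to apply the SNP-overlap
#'   rule regardless of phenotype labels.
#' @return symmetric PSD correlation matrix with test ids as dimnames.
#' @export
buildTestCorrelation <- function(pset, ld, window = 2e6,
                                 respectPhenotype = TRUE) {
  tab <- as.data.frame(pset)
  si <- snpInfo(ld)
  r2 <- as.matrix(ld)
  used <- unique(c(tab$snp1, tab$snp2[!is.na(tab$snp2)]))
  miss <- setdiff(used, si$snp_id)
  if (length(miss)) stop("SNP(s) missing from LD matrix: ",
                         paste(miss, collapse = ", "))
  idx <- match(used, si$snp_id)
  chr <- si$chromosome[idx]
  pos <- si$position[idx]
  names(chr) <- names(pos) <- used
  # SNP-level latent correlation
  snpCor <- function(a, b) {
    if (a == b) return(1)
    if (is.na(chr[a]) || is.na(chr[b]) || chr[a] != chr[b]) return(0)
    if (is.na(pos[a]) || is.na(pos[b]) ||
        abs(pos[a] - pos[b]) >= window) return(0)
    sqrt(max(0, r2[a, b]))
  }
  n <- nrow(tab)
  C <- diag(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (respectPhenotype && tab$phenotype[i] != tab$phenotype[j]) next
      ai <- c(tab$snp1[i], tab$snp2[i]); ai <- ai[!is.na(ai)]
      aj <- c(tab$snp1[j], tab$snp2[j]); aj <- aj[!is.na(aj)]
      v <- if (length(ai) == 2 && length(aj) == 2) {
        max(snpCor(ai[1], aj[1]) * snpCor(ai[2], aj[2]),
            snpCor(ai[1], aj[2]) * snpCor(ai[2], aj[1]))
      } else if (length(ai) == 1 && length(aj) == 1) {
        snpCor(ai, aj)
      } else {
        v0 <- 0
        for (a in ai) for (b in aj) v0 <- max(v0, snpCor(a, b))
        v0
      }
      C[i, j] <- C[j, i] <- v
    }
  }
  dimnames(C) <- list(tab$test_id, tab$test_id)
  repairPSD(C)
}

#' Monte-Carlo null for the combined set statistic
#'
#' Draws latent multivariate-normal scores Z with the given test-level
#' correlation, maps each to a two-sided tail p-value
#' \eqn{p_i = 2\Phi(-|Z_i|)} (uniform marginally), computes T per
#' replicate and reports the strictly-greater tail proportion
#' \eqn{\#\{T^{null} > T^{obs}\}/B}. \code{addOne = TRUE} gives the
#' conservative \eqn{(\#+1)/(B+1)} variant.
#'
#' @param pset a \code{PValueSet} (the observed tests).
#' @param corr test-level correlation matrix from
#'   \code{\link{buildTestCorrelation}} (identity if omitted).
#' @param nReplicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @param addOne add-one smoothing of the tail proportion.
#' @param chunkSize replicates per vectorized block (memory knob).
#' @return a \code{\linkS4class{SetTestResult}} with
#'   \code{method = "monte_carlo"}.
#' @export
simulateSetNull <- function(pset, corr = NULL, nReplicates = 500000,
                            seed = 1, addOne = FALSE, chunkSize = 250000L) {
  n <- if (is(pset, "PValueSet")) nrow(as.data.frame(pset)) else length(pset)
  Tobs <- combinedStatistic(pset)
  if (is.null(corr)) corr <- diag(n)
  stopifnot(nrow(corr) == n, ncol(corr) == n)
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("correlation matrix is not PSD; apply repairPSD() first")
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  set.seed(as.integer(seed))
  nReplicates <- as.numeric(nReplicates)
  count <- 0
  done <- 0
  while (done < nReplicates) {
    b <- as.integer(min(chunkSize, nReplicates - done))
    Z <- L %*% matrix(rnorm(n * b), n, b)
    P <- 2 * pnorm(-abs(Z))
    Tnull <- -colSums(log10(P))
    count <- count + sum(Tnull > Tobs)
    done <- done + b
  }
  p <- if (addOne) (count + 1) / (nReplicates + 1) else count / nReplicates
  new("SetTestResult", statistic = Tobs, nTests = as.integer(n),
      overallP = p, nReplicates = nReplicates, method = "monte_carlo",
      seed = as.integer(seed))
}

#' Closed-form combined p-value under independence
#'
#' Under independent null p-values, \eqn{T \ln 10} is Gamma(n, 1)
#' distributed (equivalently \eqn{2 \ln 10 \cdot T \sim \chi^2_{2n}}:
#' Fisher's method up to a constant), so the overall p-value is the
#' Gamma survival at the observed statistic.
#'
#' @param pset a \code{PValueSet} or numeric p-value vector.
#' @return a \code{SetTestResult} with
#'   \code{method = "fisher_independent"}.
#' @examples
#' overallP(fisherIndependent(c(0.1, 0.1)))  # 0.01 * (1 - log(0.01))
#' @export
fisherIndependent <- function(pset) {
  p <- if (is(pset, "PValueSet")) as.data.frame(pset)$p else as.numeric(pset)
  Tobs <- combinedStatistic(p)
  n <- length(p)
  new("SetTestResult", statistic = Tobs, nTests = as.integer(n),
      overallP = pgamma(Tobs * log(10), shape = n, rate = 1,
                        lower.tail = FALSE),
      nReplicates = 0, method = "fisher_independent", seed = NA_integer_)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param nTests number of tests.
#' @return \code{alpha / nTests} (exact; round to 2 significant figures
#'   for display).
#' @examples
#' signif(bonferroniThreshold(0.05, 75), 2)  # 0.00067
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence: the
#' Benjamini-Hochberg adjustment inflated by the harmonic number
#' \eqn{H(n) = \sum_{k \le n} 1/k}.
#'
#' @param pset a \code{PValueSet} or numeric p-value vector.
#' @return adjusted p-values in input order.
#' @export
byAdjust <- function(pset) {
  p <- if (is(pset, "PValueSet")) as.data.frame(pset)$p else as.numeric(pset)
  p.adjust(p, method = "BY")
}
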