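## Spectrally transformed linear mixed model. The model is
##   y = X beta + g + e,  g ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I).
## With K = U S U' the rotated data U'y, U'X have diagonal covariance
## sigma_g^2 (S + delta I), delta = sigma_e^2 / sigma_g^2, so the
## (restricted) likelihood profiles analytically over beta and sigma_g^2
## and only delta needs a 1-D search: a 64-point log grid on
## [1e-5, 1e5] followed by golden-section/parabolic refinement.

deltaGrid <- function(nPoints = 64L, range = c(1e-5, 1e5)) {
  10^seq(log10(range[1]), log10(range[2]), length.out = nPoints)
}

# Profile (restricted) log-likelihood pieces at a fixed delta, on
# rotated data. Returns the GLS beta, profiled sigma_g^2 and the value.
profileAtDelta <- function(ytil, Xtil, S, delta, method) {
  n <- length(ytil)
  p <- ncol(Xtil)
  w <- 1 / (S + delta)
  XtWX <- crossprod(Xtil, w * Xtil)
  XtWy <- crossprod(Xtil, w * ytil)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ytil - Xtil %*% beta
  q <- sum(w * r^2)
  # an interpolating fit (sigma_g^2 -> 0) sends the profile likelihood
  # to +infinity; cap it at a huge finite value so the 1-D optimizer
  # and LRT differences stay well-defined
  llCap <- 1e300
  if (method == "ML") {
    sg2 <- q / n
    ll <- if (sg2 <= 1e-300) llCap else
      -0.5 * (n * log(2 * pi) + sum(log(S + delta)) + n * log(sg2) + n)
  } else {
    sg2 <- q / (n - p)
    ldXtWX <- 2 * sum(log(diag(ch)))
    ll <- if (sg2 <= 1e-300) llCap else
      -0.5 * ((n - p) * log(2 * pi) + sum(log(S + delta)) + ldXtWX +
              (n - p) * log(sg2) + (n - p))
  }
  list(ll = ll, beta = as.numeric(beta), sg2 = sg2, XtWX = XtWX)
}

# Full delta optimization on rotated data; shared by fitLMM and the
# scan functions (which reuse one eigendecomposition across many fits).
fitRotated <- function(ytil, Xtil, S, method = "ML",
                       gridPoints = 64L, gridRange = c(1e-5, 1e5),
                       tol = 1e-6) {
  lg <- seq(log10(gridRange[1]), log10(gridRange[2]),
            length.out = gridPoints)
  lls <- vapply(lg, function(l)
    profileAtDelta(ytil, Xtil, S, 10^l, method)$ll, 0)
  i <- which.max(lls)  # first maximum -> smaller delta on ties
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(length(lg), i + 1L)]
  opt <- optimize(function(l) profileAtDelta(ytil, Xtil, S, 10^l, method)$ll,
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  # keep whichever of grid-best and refined is higher, so the returned
  # optimum dominates every grid point
  best <- if (opt$objective >= lls[i]) opt$maximum else lg[i]
  delta <- 10^best
  pf <- profileAtDelta(ytil, Xtil, S, delta, method)
  list(delta = delta, ll = pf$ll, beta = pf$beta, sg2 = pf$sg2,
       XtWX = pf$XtWX, gridLL = lls)
}

# Validate and decompose a kinship argument; accepts a KinshipMatrix or
# a plain symmetric matrix.
kinshipEigen <- function(K, n) {
  k <- if (is(K, "KinshipMatrix")) as.matrix(K) else as.matrix(K)
  if (nrow(k) != n) stop("kinship dimension does not match data")
  e <- eigen(k, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("kinship matrix is not PSD; apply repairPSD() first")
  e$values <- pmax(e$values, 0)
  e
}

# Drop zero-variance non-intercept columns, then require full rank.
pruneDesign <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  v <- apply(X, 2, function(c) max(c) - min(c))
  keep <- v > 0
  if (any(!keep)) {
    # retain a single intercept column among the constants
    first <- which(!keep)[1]
    keep[first] <- TRUE
    X <- X[, keep, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient after pruning")
  X
}

#' Fit a kinship-structured linear mixed model
#'
#' Maximizes the (restricted) likelihood of
#' \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, \sigma_g^2 K)},
#' \eqn{e \sim N(0, \sigma_e^2 I)} by eigendecomposing K once and
#' profiling everything but \eqn{\delta = \sigma_e^2/\sigma_g^2}, which
#' is optimized on a 64-point log grid over [1e-5, 1e5] with bounded
#' scalar refinement (ties resolved toward smaller \eqn{\delta}).
#'
#' @param y numeric response.
#' @param X design matrix (include your own intercept column).
#' @param K \code{\linkS4class{KinshipMatrix}} or plain symmetric PSD
#'   matrix aligned with \code{y}.
#' @param method "ML" (default; used for all likelihood-ratio tests) or
#'   "REML" (for variance reporting).
#' @return an \code{\linkS4class{LMMFit}}.
#' @examples
#' set.seed(1)
#' n <- 40
#' X <- cbind(1, rnorm(n))
#' y <- X %*% c(1, 2) + rnorm(n)
#' fitLMM(y, X, diag(n))  # K = I: beta equals ordinary least squares
#' @export
fitLMM <- function(y, X, K, method = c("ML", "REML")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- pruneDesign(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  e <- kinshipEigen(K, n)
  ytil <- as.numeric(crossprod(e$vectors, y))
  Xtil <- crossprod(e$vectors, X)
  fr <- fitRotated(ytil, Xtil, e$values, method)
  sg2 <- fr$sg2
  vc <- tryCatch(sg2 * solve(fr$XtWX), error = function(err) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  new("LMMFit", beta = setNames(fr$beta, colnames(X)), vcovBeta = vc,
      sigmaG2 = sg2, sigmaE2 = fr$delta * sg2, delta = fr$delta,
      logLik = fr$ll, method = method, nObs = as.integer(n))
}

# Align genotype/trait/kinship inputs on the intersection of sample
# keys; returns the pieces the scan functions need.
alignInputs <- function(genotypes, trait, K = NULL, covariates = NULL) {
  keys <- sampleKeys(genotypes)
  common <- intersect(keys, names(trait))
  kmat <- NULL
  if (!is.null(K)) {
    kmat <- if (is(K, "KinshipMatrix")) as.matrix(K) else as.matrix(K)
    if (!is.null(rownames(kmat))) common <- intersect(common, rownames(kmat))
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates))) {
      if (nrow(covariates) != length(keys))
        stop("covariates lack sample-key rownames and do not match the genotypes")
      rownames(covariates) <- keys
    }
    common <- intersect(common, rownames(covariates))
    covariates <- covariates[common, , drop = FALSE]
  }
  if (length(common) < 3L) stop("fewer than 3 individuals shared across inputs")
  if (!is.null(kmat)) {
    kmat <- if (!is.null(rownames(kmat))) kmat[common, common]
            else kmat[match(common, keys), match(common, keys)]
  }
  list(keys = common,
       d = dosage(genotypes)[common, , drop = FALSE],
       y = as.numeric(trait[common]),
       K = kmat, covariates = covariates)
}

#' Single-SNP mixed-model association scan
#'
#' For each SNP, fits the null model (intercept + covariates) and the
#' alternative (plus the SNP dosage) by maximum likelihood with the
#' same delta-profiling machinery, and reports the likelihood-ratio
#' statistic against chi-squared with 1 df. Individuals with a missing
#' dosage are dropped for that SNP only (the null model is refitted per
#' missingness pattern). A SNP monomorphic in the analysis subsample
#' yields a row with \code{p = NA} and a message.
#'
#' @param genotypes \code{GenotypeMatrix}.
#' @param trait named numeric vector (see \code{\link{traitVector}}).
#' @param K kinship matrix aligned by sample keys.
#' @param snpIds SNPs to test (default: all).
#' @param covariates optional matrix with sample-key rownames.
#' @param phenotype label recorded in the result rows.
#' @param method "ML" or "REML" ("ML" is the tested path).
#' @return data.frame of association results (one row per SNP): test_id,
#'   snp1, snp2, chr1, chr2, phenotype, beta, se, statistic, df, p.
#' @export
assocScan <- function(genotypes, trait, K, snpIds = NULL,
                      covariates = NULL, phenotype = "trait",
                      method = "ML") {
  if (is.null(snpIds)) snpIds <- snpInfo(genotypes)$snp_id
  stopifnot(all(snpIds %in% snpInfo(genotypes)$snp_id))
  al <- alignInputs(genotypes, trait, K, covariates)
  n <- length(al$y)
  X0full <- cbind(intercept = rep(1, n), al$covariates)
  si <- snpInfo(genotypes)

  cache <- new.env(parent = emptyenv())
  rotatedFor <- function(obs) {
    keyStr <- paste0("miss:", paste(which(!obs), collapse = ","))
    if (!is.null(cache[[keyStr]])) return(cache[[keyStr]])
    e <- kinshipEigen(al$K[obs, obs, drop = FALSE], sum(obs))
    X0 <- pruneDesign(X0full[obs, , drop = FALSE])
    ytil <- as.numeric(crossprod(e$vectors, al$y[obs]))
    X0til <- crossprod(e$vectors, X0)
    null <- fitRotated(ytil, X0til, e$values, method)
    out <- list(e = e, ytil = ytil, X0 = X0, X0til = X0til, null = null)
    cache[[keyStr]] <- out
    out
  }

  rows <- lapply(snpIds, function(s) {
    g <- al$d[, s]
    obs <- !is.na(g)
    meta <- si[si$snp_id == s, ]
    row <- data.frame(test_id = s, snp1 = s, snp2 = NA_character_,
                      chr1 = meta$chromosome, chr2 = NA_integer_,
                      phenotype = phenotype, beta = NA_real_, se = NA_real_,
                      statistic = NA_real_, df = 1L, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(unique(g[obs])) < 2L) {
      message("SNP ", s, " is monomorphic in the analysis subsample; p set to NA")
      return(row)
    }
    rc <- rotatedFor(obs)
    Xg <- crossprod(rc$e$vectors, g[obs])
    alt <- fitRotated(rc$ytil, cbind(rc$X0til, snp = Xg), rc$e$values, method)
    lrt <- 2 * (alt$ll - rc$null$ll)
    if (is.nan(lrt)) lrt <- 0  # both models interpolate (noise-free)
    lrt <- max(lrt, 0)
    j <- length(alt$beta)
    se <- tryCatch(sqrt(alt$sg2 * solve(alt$XtWX)[j, j]),
                   error = function(e) NA_real_)
    row$beta <- alt$beta[j]
    row$se <- se
    row$statistic <- lrt
    row$p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    row
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares association scan (identity-kinship case)
#'
#' Per-SNP Wald t-test of the dosage coefficient in a linear regression
#' with optional covariates -- the analysis applied to unrelated
#' samples. Asymptotically equivalent to \code{\link{assocScan}} with
#' \code{K = I}.
#'
#' @inheritParams assocScan
#' @return data.frame in the same layout as \code{\link{assocScan}}
#'   (statistic is the t value, df the residual df).
#' @export
olsAssoc <- function(genotypes, trait, covariates = NULL,
                     snpIds = NULL, phenotype = "trait") {
  if (is.null(snpIds)) snpIds <- snpInfo(genotypes)$snp_id
  al <- alignInputs(genotypes, trait, K = NULL, covariates = covariates)
  si <- snpInfo(genotypes)
  rows <- lapply(snpIds, function(s) {
    g <- al$d[, s]
    obs <- !is.na(g)
    meta <- si[si$snp_id == s, ]
    row <- data.frame(test_id = s, snp1 = s, snp2 = NA_character_,
                      chr1 = meta$chromosome, chr2 = NA_integer_,
                      phenotype = phenotype, beta = NA_real_, se = NA_real_,
                      statistic = NA_real_, df = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(unique(g[obs])) < 2L) {
      message("SNP ", s, " is monomorphic in the analysis subsample; p set to NA")
      return(row)
    }
    X <- if (is.null(al$covariates)) cbind(snp = g[obs])
         else cbind(al$covariates[obs, , drop = FALSE], snp = g[obs])
    df <- data.frame(y = al$y[obs], X, check.names = TRUE)
    fit <- lm(y ~ ., data = df)
    co <- summary(fit)$coefficients
    if (!"snp" %in% rownames(co))
      stop("SNP dosage collinear with covariates for ", s)
    row$beta <- co["snp", 1]
    row$se <- co["snp", 2]
    row$statistic <- co["snp", 3]
    row$df <- fit$df.residual
    row$p <- co["snp", 4]
    row
  })
  do.call(rbind, rows)
}
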