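## Relatedness estimators and the PSD repair used before spectral LMM
## fitting. Two genotype-based estimators are provided: the realized
## relationship matrix (per-SNP standardized genotypes) and the centered
## (mean-only) cross-product; pedigree-expected relatedness (2*Phi) is
## available as a simulation input and test oracle.

# Shared preprocessing: mean-impute missing dosages, drop monomorphic
# columns. Returns the imputed matrix and column means.
imputedPolymorphic <- function(genotypes) {
  d <- dosage(genotypes)
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  v <- apply(d, 2, stats::var)
  poly <- which(v > 0 & !is.na(v))
  if (length(poly) == 0L) stop("no polymorphic SNPs")
  nMono <- ncol(d) - length(poly)
  if (nMono > 0)
    message(nMono, " monomorphic SNP(s) excluded from kinship estimation")
  list(d = d[, poly, drop = FALSE], mu = mu[poly])
}

#' Realized relationship matrix (RRM)
#'
#' Each SNP column is standardized to mean 0 and variance 1 (missing
#' dosages are mean-imputed first, so they contribute 0), and
#' \eqn{K = W W^T / m} over the m polymorphic SNPs. For unrelated
#' individuals E[K] is the identity; for a relative pair E[K] equals
#' twice their kinship coefficient (0.5 for parent-offspring or full
#' sibs).
#'
#' @param genotypes a \code{\linkS4class{GenotypeMatrix}} with at least
#'   two individuals and one polymorphic SNP.
#' @return a \code{\linkS4class{KinshipMatrix}} tagged \code{"RRM"}.
#' @export
rrmKinship <- function(genotypes) {
  stopifnot(nSamples(genotypes) >= 2)
  ip <- imputedPolymorphic(genotypes)
  w <- scale(ip$d)  # column mean 0, sd 1
  k <- tcrossprod(w) / ncol(w)
  dimnames(k) <- list(sampleKeys(genotypes), sampleKeys(genotypes))
  kinshipMatrix((k + t(k)) / 2, estimator = "RRM")
}

#' Centered kinship matrix
#'
#' \eqn{K = C C^T / m} where C is the mean-centered (not
#' variance-scaled) dosage matrix over polymorphic SNPs -- the default
#' relatedness estimate of mixed-model association tools that take raw
#' dosages.
#'
#' @inheritParams rrmKinship
#' @return a \code{KinshipMatrix} tagged \code{"centered"}.
#' @export
centeredKinship <- function(genotypes) {
  stopifnot(nSamples(genotypes) >= 2)
  ip <- imputedPolymorphic(genotypes)
  cmat <- sweep(ip$d, 2, colMeans(ip$d))
  k <- tcrossprod(cmat) / ncol(cmat)
  dimnames(k) <- list(sampleKeys(genotypes), sampleKeys(genotypes))
  kinshipMatrix((k + t(k)) / 2, estimator = "centered")
}

#' Clip eigenvalues to restore positive semidefiniteness
#'
#' Eigendecomposes a symmetric matrix and clips eigenvalues below
#' \code{floor} up to \code{floor}; among reconstructions with clipped
#' spectra this minimizes the Frobenius distance to the input. A matrix
#' that is already PSD is returned unchanged (up to round-off).
#'
#' @param kinship a \code{KinshipMatrix} (or plain symmetric matrix).
#' @param floor eigenvalue floor, default 0.
#' @return object of the same kind as the input.
#' @export
repairPSD <- function(kinship, floor = 0) {
  k <- if (is(kinship, "KinshipMatrix")) as.matrix(kinship) else as.matrix(kinship)
  if (max(abs(k - t(k))) > 1e-8) stop("matrix is asymmetric beyond 1e-8")
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) {
    out <- (k + t(k)) / 2
  } else {
    vals <- pmax(e$values, floor)
    out <- e$vectors %*% (vals * t(e$vectors))
    out <- (out + t(out)) / 2
    dimnames(out) <- dimnames(k)
  }
  if (is(kinship, "KinshipMatrix"))
    kinshipMatrix(out, estimator = estimator(kinship))
  else out
}

#' Pedigree-expected relatedness matrix (2 * kinship coefficients)
#'
#' Recursive expected kinship: \eqn{\phi_{ii} = (1 + \phi_{fm})/2} and
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for j not a descendant of
#' i; individuals in different families are unrelated. Returned scaled
#' by 2, so self = 1 + inbreeding and parent-offspring = 0.5. Used as
#' the covariance of simulated polygenic effects and as the oracle that
#' genotype-based estimators are tested against.
#'
#' @param pedigree a \code{\linkS4class{Pedigree}}.
#' @return a \code{KinshipMatrix} tagged \code{"pedigree"}.
#' @export
pedigreeKinship <- function(pedigree) {
  p <- as.data.frame(pedigree)
  n <- nrow(p)
  key <- makeSampleKeys(p$family_id, p$individual_id)
  fa <- match(makeSampleKeys(p$family_id, p$father_id), key)
  mo <- match(makeSampleKeys(p$family_id, p$mother_id), key)
  # order so parents precede children
  depth <- rep(0L, n)
  repeat {
    nd <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
               ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (all(nd == depth)) break
    depth <- nd
  }
  ord <- order(depth)
  phi <- matrix(0, n, n)
  for (oi in seq_len(n)) {
    i <- ord[oi]
    f <- fa[i]; m <- mo[i]
    phi[i, i] <- if (!is.na(f) && !is.na(m)) 0.5 * (1 + phi[f, m]) else 0.5
    for (oj in seq_len(oi - 1L)) {
      j <- ord[oj]
      if (p$family_id[i] != p$family_id[j]) next
      v <- 0
      if (!is.na(f)) v <- v + 0.5 * phi[f, j]
      if (!is.na(m)) v <- v + 0.5 * phi[m, j]
      phi[i, j] <- phi[j, i] <- v
    }
  }
  k <- 2 * phi
  dimnames(k) <- list(key, key)
  kinshipMatrix(k, estimator = "pedigree")
}
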