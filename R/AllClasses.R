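#' @import methods
NULL

#' Genotype matrix with SNP map metadata
#'
#' Holds minor-allele dosages (0, 1, 2 or \code{NA}) for a set of
#' individuals at a set of biallelic SNPs, together with the map
#' information (chromosome, base-pair position, minor/major allele) and
#' the family/individual identifiers. Rows are individuals, columns are
#' SNPs; \code{rownames(dosage)} are the sample keys
#' (\code{family_id/individual_id}) and \code{colnames(dosage)} the SNP ids.
#'
#' @slot dosage numeric matrix of minor-allele counts, entries in
#'   \{0, 1, 2, \code{NA}\}.
#' @slot snpInfo \code{data.frame} with columns \code{snp_id},
#'   \code{chromosome}, \code{position}, \code{allele_minor},
#'   \code{allele_major}.
#' @slot samples \code{data.frame} with columns \code{family_id},
#'   \code{individual_id}.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snpInfo = "data.frame",
                 samples = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  si <- object@snpInfo
  sm <- object@samples
  need <- c("snp_id", "chromosome", "position", "allele_minor", "allele_major")
  if (!all(need %in% names(si)))
    msg <- c(msg, paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  if (!all(c("family_id", "individual_id") %in% names(sm)))
    msg <- c(msg, "samples must have columns family_id, individual_id")
  if (length(msg)) return(msg)
  if (nrow(d) != nrow(sm)) msg <- c(msg, "dosage rows must match samples")
  if (ncol(d) != nrow(si)) msg <- c(msg, "dosage columns must match snpInfo")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
  if (anyDuplicated(si$snp_id)) msg <- c(msg, "snp_id must be unique")
  if (any(si$position < 1)) msg <- c(msg, "positions must be >= 1")
  if (any(si$allele_minor == si$allele_major))
    msg <- c(msg, "allele_minor must differ from allele_major")
  if (length(msg)) msg else TRUE
})

#' Pedigree structure
#'
#' Family/individual/parent records used for gene-dropping simulation and
#' for the pedigree-expected kinship oracle. Founders have \code{NA}
#' parents; every named parent must exist in the same family and the
#' parent-offspring graph must be acyclic.
#'
#' @slot ped \code{data.frame} with columns \code{family_id},
#'   \code{individual_id}, \code{father_id}, \code{mother_id},
#'   \code{sex} (1 = male, 2 = female).
#' @exportClass Pedigree
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(p)))
    return(paste("pedigree must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  key <- paste(p$family_id, p$individual_id)
  if (anyDuplicated(key)) msg <- c(msg, "duplicated individual within family")
  for (side in c("father_id", "mother_id")) {
    pk <- paste(p$family_id, p[[side]])
    bad <- !is.na(p[[side]]) & !(pk %in% key)
    if (any(bad))
      msg <- c(msg, paste0(side, " not present in the same family for: ",
                           paste(utils::head(p$individual_id[bad], 3), collapse = ", ")))
  }
  # acyclicity: follow parent links; depth cannot exceed the pedigree size
  idx <- match(key, key)
  fa <- match(paste(p$family_id, p$father_id), key)
  mo <- match(paste(p$family_id, p$mother_id), key)
  n <- nrow(p)
  depth <- rep(NA_integer_, n)
  resolve <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% seen) return(-1L)  # cycle
    seen <- c(seen, i)
    dd <- 0L
    for (par in c(fa[i], mo[i])) {
      if (!is.na(par)) {
        r <- resolve(par, seen)
        if (r < 0L) return(-1L)
        dd <- max(dd, r + 1L)
      }
    }
    depth[i] <<- dd
    dd
  }
  for (i in seq_len(n)) if (resolve(i, integer()) < 0L) {
    msg <- c(msg, "pedigree contains a cycle (an individual is its own ancestor)")
    break
  }
  if (length(msg)) msg else TRUE
})

#' Kinship / relatedness matrix
#'
#' Square symmetric relatedness matrix indexed by sample keys, tagged with
#' the estimator that produced it: \code{"RRM"} (standardized-genotype
#' realized relationship matrix), \code{"centered"} (mean-centered
#' dosage cross-product), \code{"pedigree"} (expected relatedness
#' \eqn{2\Phi} from the pedigree), or \code{"external"} (read from file).
#'
#' @slot k numeric matrix, symmetric, with sample keys as dimnames.
#' @slot estimator character tag.
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(k = "matrix", estimator = "character"))

setValidity("KinshipMatrix", function(object) {
  k <- object@k
  msg <- character()
  if (nrow(k) != ncol(k)) msg <- c(msg, "kinship matrix must be square")
  else if (max(abs(k - t(k))) > 1e-10) msg <- c(msg, "kinship matrix must be symmetric (tol 1e-10)")
  if (!object@estimator %in% c("RRM", "centered", "pedigree", "identity", "external"))
    msg <- c(msg, "unknown estimator tag")
  if (length(msg)) msg else TRUE
})

#' LD (r-squared) matrix over SNPs
#'
#' @slot r2 square symmetric matrix of r² values in [0, 1], unit diagonal,
#'   with SNP ids as dimnames.
#' @slot snpInfo \code{data.frame} with at least \code{snp_id},
#'   \code{chromosome}, \code{position} for the same SNPs.
#' @exportClass LDMatrix
setClass("LDMatrix", representation(r2 = "matrix", snpInfo = "data.frame"))

setValidity("LDMatrix", function(object) {
  r2 <- object@r2
  msg <- character()
  if (nrow(r2) != ncol(r2)) msg <- c(msg, "r2 must be square")
  else {
    if (max(abs(r2 - t(r2))) > 1e-8) msg <- c(msg, "r2 must be symmetric")
    if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) msg <- c(msg, "r2 entries must lie in [0, 1]")
    if (max(abs(diag(r2) - 1)) > 1e-12) msg <- c(msg, "r2 diagonal must be 1")
  }
  if (!all(c("snp_id", "chromosome", "position") %in% names(object@snpInfo)))
    msg <- c(msg, "snpInfo must have snp_id, chromosome, position")
  else if (nrow(object@snpInfo) != nrow(r2))
    msg <- c(msg, "snpInfo rows must match r2 dimension")
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of a kinship-structured linear mixed model
#'
#' Result of \code{\link{fitLMM}}: the model is
#' \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, \sigma_g^2 K)} and
#' \eqn{e \sim N(0, \sigma_e^2 I)}; \eqn{\delta = \sigma_e^2/\sigma_g^2}
#' is profiled out by spectral decomposition of \eqn{K}.
#'
#' @slot beta named coefficient vector (GLS at the optimal delta).
#' @slot vcovBeta covariance matrix of \code{beta}.
#' @slot sigmaG2,sigmaE2 variance components (both \eqn{\ge 0}).
#' @slot delta ratio \eqn{\sigma_e^2/\sigma_g^2} at the optimum.
#' @slot logLik maximized (restricted) log-likelihood.
#' @slot method "ML" or "REML".
#' @slot nObs number of observations used.
#' @exportClass LMMFit
setClass("LMMFit",
  representation(beta = "numeric", vcovBeta = "matrix",
                 sigmaG2 = "numeric", sigmaE2 = "numeric",
                 delta = "numeric", logLik = "numeric",
                 method = "character", nObs = "integer"))

setValidity("LMMFit", function(object) {
  msg <- character()
  if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (!object@method %in% c("ML", "REML")) msg <- c(msg, "method must be ML or REML")
  if (length(msg)) msg else TRUE
})

#' Combined-evidence set-test result
#'
#' The statistic is \eqn{T = -\sum_i \log_{10} p_i} over a set of tests;
#' \code{overallP} is either the Monte-Carlo tail proportion under a
#' correlated-null copula (\code{method = "monte_carlo"}) or the
#' closed-form Gamma tail assuming independence
#' (\code{method = "fisher_independent"}).
#'
#' @slot statistic observed \eqn{T \ge 0}.
#' @slot nTests number of combined tests.
#' @slot overallP the overall p-value.
#' @slot nReplicates Monte-Carlo replicates (0 for the closed form).
#' @slot method "monte_carlo" or "fisher_independent".
#' @slot seed integer seed used (NA for the closed form).
#' @exportClass SetTestResult
setClass("SetTestResult",
  representation(statistic = "numeric", nTests = "integer",
                 overallP = "numeric", nReplicates = "numeric",
                 method = "character", seed = "integer"))

setValidity("SetTestResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
  if (object@overallP < 0 || object@overallP > 1) msg <- c(msg, "overallP must be in [0, 1]")
  if (!object@method %in% c("monte_carlo", "fisher_independent"))
    msg <- c(msg, "method must be monte_carlo or fisher_independent")
  if (length(msg)) msg else TRUE
})

#' Ordered set of p-values with SNP coordinates
#'
#' Input to the combined set test. Each row is one test: a single-SNP
#' association (leave \code{snp2}/\code{chr2}/\code{pos2} as \code{NA})
#' or a SNP-pair interaction. The \code{phenotype} column identifies the
#' trait (or expression probe) each test was computed on; it drives the
#' null-correlation model (tests on different traits are treated as
#' independent under the null).
#'
#' @slot tests \code{data.frame} with columns \code{test_id}, \code{p},
#'   \code{snp1}, \code{chr1}, \code{pos1}, \code{snp2}, \code{chr2},
#'   \code{pos2}, \code{phenotype}.
#' @exportClass PValueSet
setClass("PValueSet", representation(tests = "data.frame"))

setValidity("PValueSet", function(object) {
  t <- object@tests
  need <- c("test_id", "p", "snp1", "chr1", "pos1", "snp2", "chr2", "pos2",
            "phenotype")
  if (!all(need %in% names(t)))
    return(paste("tests must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(t) == 0) msg <- c(msg, "p-value set must be non-empty")
  if (any(t$p <= 0 | t$p > 1)) msg <- c(msg, "all p must lie in (0, 1]")
  if (anyDuplicated(t$test_id)) msg <- c(msg, "test_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic family-study generator
#'
#' Defaults emulate the study design the analysis pipeline targets:
#' 20 extended families of about 48 members (roughly 950 genotyped
#' individuals over 3 generations), biallelic SNPs in LD blocks,
#' longitudinal blood-pressure phenotypes measured at 4 exams with age,
#' smoking and antihypertensive-medication covariates, and expression
#' traits that can carry an additive-by-additive two-SNP interaction.
#'
#' @slot nFamilies number of independent families.
#' @slot familySizeMean target mean family size (members per family).
#' @slot nGenerations pedigree depth (>= 2).
#' @slot nSnps number of simulated SNPs.
#' @slot blockSize SNPs per LD block (no recombination within a block).
#' @slot withinBlockR latent adjacent-marker haplotype correlation in [0, 1).
#' @slot mafRange minor-allele-frequency range, a subset of (0, 0.5].
#' @slot nExams number of longitudinal exams.
#' @slot traitHeritability narrow-sense h² of the simulated trait in [0, 1).
#' @slot covariateEffects named numeric: age, smoking, medication effects
#'   (trait units: mmHg for blood pressure).
#' @slot interactionEffect additive-by-additive coefficient for the
#'   designated SNP pair on the expression trait.
#' @slot residualSd residual (environmental) standard deviation.
#' @slot seed master seed; every stochastic operation derives its own
#'   sub-seed deterministically from it.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nFamilies = "integer", familySizeMean = "numeric",
                 nGenerations = "integer", nSnps = "integer",
                 blockSize = "integer", withinBlockR = "numeric",
                 mafRange = "numeric", nExams = "integer",
                 traitHeritability = "numeric", covariateEffects = "numeric",
                 interactionEffect = "numeric", residualSd = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nFamilies < 1L) msg <- c(msg, "nFamilies must be >= 1")
  if (object@nGenerations < 2L) msg <- c(msg, "nGenerations must be >= 2")
  if (object@nSnps < 1L) msg <- c(msg, "nSnps must be >= 1")
  if (object@blockSize < 1L) msg <- c(msg, "blockSize must be >= 1")
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msg <- c(msg, "withinBlockR must be in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be (low, high) within (0, 0.5]")
  if (object@nExams < 1L) msg <- c(msg, "nExams must be >= 1")
  if (object@traitHeritability < 0 || object@traitHeritability >= 1)
    msg <- c(msg, "traitHeritability must be in [0, 1)")
  if (!all(c("age", "smoking", "medication") %in% names(object@covariateEffects)))
    msg <- c(msg, "covariateEffects must be named age, smoking, medication")
  if (object@residualSd <= 0) msg <- c(msg, "residualSd must be positive")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
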