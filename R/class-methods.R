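## Constructors, accessors and show methods for the core containers.

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of minor-allele counts (individuals x SNPs).
#' @param snpInfo data.frame with snp_id, chromosome, position,
#'   allele_minor, allele_major.
#' @param samples data.frame with family_id, individual_id.
#' @return a validated \code{GenotypeMatrix}.
#' @examples
#' g <- genotypeMatrix(matrix(c(0, 1, 2), 3, 1),
#'   snpInfo = data.frame(snp_id = "rs1", chromosome = 1L, position = 100L,
#'     allele_minor = "A", allele_major = "G"),
#'   samples = data.frame(family_id = "F1", individual_id = c("1", "2", "3")))
#' dosage(g)
#' @export
genotypeMatrix <- function(dosage, snpInfo, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  rownames(dosage) <- makeSampleKeys(samples$family_id, samples$individual_id)
  colnames(dosage) <- snpInfo$snp_id
  new("GenotypeMatrix", dosage = dosage,
      snpInfo = as.data.frame(snpInfo), samples = as.data.frame(samples))
}

#' Construct a Pedigree
#'
#' @param family_id,individual_id,father_id,mother_id,sex vectors of equal
#'   length; parent ids are \code{NA} for founders; sex is 1 (male) or
#'   2 (female).
#' @return a validated \code{Pedigree}.
#' @export
pedigree <- function(family_id, individual_id, father_id, mother_id, sex) {
  new("Pedigree", ped = data.frame(
    family_id = as.character(family_id),
    individual_id = as.character(individual_id),
    father_id = as.character(father_id),
    mother_id = as.character(mother_id),
    sex = as.integer(sex),
    stringsAsFactors = FALSE))
}

#' Construct a KinshipMatrix
#' @param k square symmetric numeric matrix with sample keys as dimnames.
#' @param estimator one of "RRM", "centered", "pedigree", "identity",
#'   "external".
#' @export
kinshipMatrix <- function(k, estimator = "external") {
  new("KinshipMatrix", k = as.matrix(k), estimator = estimator)
}

#' Construct an LDMatrix
#' @param r2 square symmetric matrix of r² values, unit diagonal.
#' @param snpInfo data.frame with snp_id, chromosome, position.
#' @export
ldMatrix <- function(r2, snpInfo) {
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(snpInfo$snp_id, snpInfo$snp_id)
  new("LDMatrix", r2 = r2, snpInfo = as.data.frame(snpInfo))
}

#' Construct a PValueSet
#'
#' @param test_id unique test labels.
#' @param p p-values in (0, 1].
#' @param snp1,chr1,pos1 first constituent SNP and its coordinates.
#' @param snp2,chr2,pos2 second SNP for interaction tests (\code{NA} for
#'   single-SNP tests).
#' @param phenotype trait or probe label each test was computed on;
#'   defaults to a single shared label.
#' @export
pValueSet <- function(test_id, p, snp1, chr1, pos1,
                      snp2 = NA, chr2 = NA, pos2 = NA,
                      phenotype = "trait") {
  n <- length(p)
  new("PValueSet", tests = data.frame(
    test_id = as.character(test_id), p = as.numeric(p),
    snp1 = as.character(snp1), chr1 = as.integer(chr1),
    pos1 = as.numeric(pos1),
    snp2 = as.character(rep_len(snp2, n)), chr2 = as.integer(rep_len(chr2, n)),
    pos2 = as.numeric(rep_len(pos2, n)),
    phenotype = as.character(rep_len(phenotype, n)),
    stringsAsFactors = FALSE))
}

#' Simulation configuration constructor
#'
#' See \code{\linkS4class{SimConfig}} for the meaning of each field. The
#' defaults describe the emulated family study: 20 three-generation
#' families averaging ~48 members (~950 individuals), LD blocks of 10
#' SNPs with latent adjacent correlation 0.8, MAF uniform on
#' (0.05, 0.5], 4 longitudinal exams, trait heritability 0.3 and an
#' 8 mmHg residual SD.
#'
#' @param nFamilies,familySizeMean,nGenerations pedigree structure.
#' @param nSnps,blockSize,withinBlockR,mafRange genotype structure.
#' @param nExams,traitHeritability,covariateEffects,residualSd phenotype
#'   model.
#' @param interactionEffect additive-by-additive coefficient for the
#'   expression trait.
#' @param seed master seed (mandatory for reproducibility).
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nFamilies = 2, nSnps = 20, seed = 7)
#' cfg
#' @export
simConfig <- function(nFamilies = 20, familySizeMean = 48, nGenerations = 3,
                      nSnps = 1000, blockSize = 10, withinBlockR = 0.8,
                      mafRange = c(0.05, 0.5), nExams = 4,
                      traitHeritability = 0.3,
                      covariateEffects = c(age = 0.5, smoking = 4,
                                           medication = -8),
                      interactionEffect = 0, residualSd = 8, seed = 1) {
  new("SimConfig", nFamilies = as.integer(nFamilies),
      familySizeMean = as.numeric(familySizeMean),
      nGenerations = as.integer(nGenerations), nSnps = as.integer(nSnps),
      blockSize = as.integer(blockSize),
      withinBlockR = as.numeric(withinBlockR),
      mafRange = as.numeric(mafRange), nExams = as.integer(nExams),
      traitHeritability = as.numeric(traitHeritability),
      covariateEffects = covariateEffects,
      interactionEffect = as.numeric(interactionEffect),
      residualSd = as.numeric(residualSd), seed = as.integer(seed))
}

## ---- accessors ----

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)

#' @rdname LDMatrix-class
#' @export
setMethod("snpInfo", "LDMatrix", function(x) x@snpInfo)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("samples", "GenotypeMatrix", function(x) x@samples)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleKeys", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname Pedigree-class
#' @export
setMethod("sampleKeys", "Pedigree",
  function(x) makeSampleKeys(x@ped$family_id, x@ped$individual_id))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosage))

#' @rdname KinshipMatrix-class
#' @export
setMethod("estimator", "KinshipMatrix", function(x) x@estimator)

#' @rdname SetTestResult-class
#' @export
setMethod("overallP", "SetTestResult", function(x) x@overallP)

#' @rdname KinshipMatrix-class
#' @export
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@k)

#' @rdname LDMatrix-class
#' @export
setMethod("as.matrix", "LDMatrix", function(x, ...) x@r2)

#' @rdname Pedigree-class
#' @param row.names,optional,... passed for S3/S4 compatibility, unused.
#' @export
setMethod("as.data.frame", "Pedigree",
  function(x, row.names = NULL, optional = FALSE, ...) x@ped)

#' @rdname PValueSet-class
#' @export
setMethod("as.data.frame", "PValueSet",
  function(x, row.names = NULL, optional = FALSE, ...) x@tests)

## ---- show ----

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSamples(object), "individuals x",
      nSnps(object), "SNPs\n")
  cat("  families:", length(unique(object@samples$family_id)),
      " missing dosage:", sum(is.na(object@dosage)), "\n")
  cat("  chromosomes:",
      paste(sort(unique(object@snpInfo$chromosome)), collapse = ", "), "\n")
})

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  founders <- is.na(p$father_id) & is.na(p$mother_id)
  cat("Pedigree:", nrow(p), "individuals in",
      length(unique(p$family_id)), "families (",
      sum(founders), "founders )\n")
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (", object@estimator, "): ",
      nrow(object@k), " x ", ncol(object@k), "\n", sep = "")
  cat("  mean diagonal:", signif(mean(diag(object@k)), 4), "\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix:", nrow(object@r2), "SNPs, mean off-diagonal r2:",
      signif(mean(object@r2[upper.tri(object@r2)]), 4), "\n")
})

setMethod("show", "LMMFit", function(object) {
  cat("LMMFit (", object@method, "), n = ", object@nObs, "\n", sep = "")
  cat("  logLik:", format(object@logLik, digits = 8), "\n")
  cat("  sigma_g^2:", signif(object@sigmaG2, 5),
      " sigma_e^2:", signif(object@sigmaE2, 5),
      " delta:", signif(object@delta, 5), "\n")
  print(signif(object@beta, 5))
})

setMethod("show", "SetTestResult", function(object) {
  cat("SetTestResult (", object@method, ")\n", sep = "")
  cat("  T = -sum log10 p:", format(object@statistic, digits = 8),
      "over", object@nTests, "tests\n")
  cat("  overall p:", format(object@overallP, digits = 4))
  if (object@method == "monte_carlo")
    cat("  (", format(object@nReplicates, big.mark = ","), "replicates )")
  cat("\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFamilies, "families x ~",
      object@familySizeMean, "members,", object@nGenerations,
      "generations;", object@nSnps, "SNPs in blocks of",
      object@blockSize, "\n")
  cat("  h2:", object@traitHeritability, " exams:", object@nExams,
      " residual SD:", object@residualSd, " seed:", object@seed, "\n")
})
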