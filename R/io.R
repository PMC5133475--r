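## Readers and writers for the plain-text interchange formats:
## PLINK-style .ped/.map genotypes with pedigree columns, GEMMA-style
## plain kinship matrices, LD (r2) matrices, phenotype tables and
## association/interaction results tables.

#' Read PLINK-style text genotypes and pedigree
#'
#' Parses a white-space delimited \code{.ped} file (6 leading columns:
#' family, individual, father, mother, sex, phenotype; then two allele
#' columns per SNP) together with its \code{.map} file (chromosome,
#' snp id, genetic distance, position). Dosages count \emph{minor}
#' alleles, with the minor allele determined by in-sample allele
#' frequency; frequency ties are broken by taking the alphabetically
#' first allele as minor. The PLINK missing genotype \code{"0 0"} becomes
#' \code{NA}.
#'
#' @param pedPath path to the .ped file.
#' @param mapPath path to the .map file.
#' @return a list with elements \code{genotypes} (a
#'   \code{\linkS4class{GenotypeMatrix}}) and \code{pedigree} (a
#'   \code{\linkS4class{Pedigree}}).
#' @export
readPedMap <- function(pedPath, mapPath) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mapTok <- strsplit(trimws(mapLines), "[ \t]+")
  bad <- which(lengths(mapTok) != 4L)
  if (length(bad))
    stop("map parse error: line ", bad[1], " has ", length(mapTok[[bad[1]]]),
         " fields (expected 4)")
  map <- data.frame(
    chromosome = as.integer(vapply(mapTok, `[`, "", 1L)),
    snp_id = vapply(mapTok, `[`, "", 2L),
    position = as.integer(vapply(mapTok, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  m <- nrow(map)

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  tok <- strsplit(trimws(pedLines), "[ \t]+")
  expected <- 6L + 2L * m
  bad <- which(lengths(tok) != expected)
  if (length(bad))
    stop("ped parse error: line ", bad[1], " has ", length(tok[[bad[1]]]),
         " fields (expected ", expected, ")")
  n <- length(tok)
  pedMat <- matrix(unlist(tok), nrow = n, byrow = TRUE)
  alle <- pedMat[, -(1:6), drop = FALSE]
  if (!all(alle %in% c("A", "C", "G", "T", "0")))
    stop("ped parse error: allele symbols outside {A,C,G,T,0}")

  a1 <- alle[, 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- alle[, 2L * seq_len(m), drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  minorAll <- majorAll <- character(m)
  for (j in seq_len(m)) {
    obs <- a1[, j] != "0" & a2[, j] != "0"
    half <- xor(a1[, j] == "0", a2[, j] == "0")
    if (any(half))
      stop("ped parse error: half-missing genotype at SNP ", map$snp_id[j])
    als <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(als) == 0L) als <- c("A", "C")  # all-missing column
    if (length(als) == 1L) {
      minorAll[j] <- als
      majorAll[j] <- setdiff(c("A", "C", "G", "T"), als)[1]
      dos[obs, j] <- 2
      next
    }
    if (length(als) > 2L)
      stop("multi-allelic SNP not supported: ", map$snp_id[j])
    cnt1 <- sum(a1[obs, j] == als[1]) + sum(a2[obs, j] == als[1])
    cnt2 <- sum(a1[obs, j] == als[2]) + sum(a2[obs, j] == als[2])
    # ties broken alphabetically: als is sorted, so als[1] wins a tie
    minor <- if (cnt1 <= cnt2) als[1] else als[2]
    major <- setdiff(als, minor)
    minorAll[j] <- minor
    majorAll[j] <- major
    dos[obs, j] <- (a1[obs, j] == minor) + (a2[obs, j] == minor)
  }
  snpInfo <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                        position = map$position, allele_minor = minorAll,
                        allele_major = majorAll, stringsAsFactors = FALSE)
  sampleDf <- data.frame(family_id = pedMat[, 1], individual_id = pedMat[, 2],
                         stringsAsFactors = FALSE)
  ped <- pedigree(pedMat[, 1], pedMat[, 2],
                  ifelse(pedMat[, 3] == "0", NA, pedMat[, 3]),
                  ifelse(pedMat[, 4] == "0", NA, pedMat[, 4]),
                  as.integer(pedMat[, 5]))
  list(genotypes = genotypeMatrix(dos, snpInfo, sampleDf), pedigree = ped)
}

#' Write PLINK-style text genotypes and map
#'
#' Inverse of \code{\link{readPedMap}} up to allele labels: dosage d is
#' written as d copies of the minor allele and 2-d of the major;
#' missing becomes \code{"0 0"}.
#'
#' @param genotypes a \code{GenotypeMatrix}.
#' @param pedigree a \code{Pedigree} covering the same individuals.
#' @param pedPath,mapPath output paths.
#' @export
writePedMap <- function(genotypes, pedigree, pedPath, mapPath) {
  si <- snpInfo(genotypes)
  writeLines(paste(si$chromosome, si$snp_id, 0, si$position, sep = "\t"),
             mapPath)
  p <- as.data.frame(pedigree)
  ord <- match(sampleKeys(genotypes), makeSampleKeys(p$family_id, p$individual_id))
  if (anyNA(ord)) stop("pedigree does not cover all genotyped individuals")
  p <- p[ord, ]
  d <- dosage(genotypes)
  n <- nrow(d); m <- ncol(d)
  lead <- paste(p$family_id, p$individual_id,
                ifelse(is.na(p$father_id), "0", p$father_id),
                ifelse(is.na(p$mother_id), "0", p$mother_id),
                p$sex, 0, sep = "\t")
  allelePairs <- matrix("0\t0", n, m)
  for (j in seq_len(m)) {
    mi <- si$allele_minor[j]; ma <- si$allele_major[j]
    gt <- c(paste(ma, ma, sep = "\t"), paste(mi, ma, sep = "\t"),
            paste(mi, mi, sep = "\t"))
    ok <- !is.na(d[, j])
    allelePairs[ok, j] <- gt[d[ok, j] + 1L]
  }
  writeLines(paste(lead, apply(allelePairs, 1, paste, collapse = "\t"),
                   sep = "\t"), pedPath)
  invisible(NULL)
}

#' Write / read a kinship matrix as a plain square text matrix
#'
#' The format is the plain n-by-n whitespace-separated matrix used by
#' mixed-model association tools (no header, no row names). Round-trips
#' to 12 significant digits.
#'
#' @param kinship a \code{KinshipMatrix}.
#' @param path file path.
#' @export
writeKinship <- function(kinship, path) {
  k <- as.matrix(kinship)
  stopifnot(nrow(k) == ncol(k))
  lines <- apply(k, 1, function(r) paste(format(r, digits = 15,
                                                scientific = TRUE,
                                                trim = TRUE), collapse = "\t"))
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname writeKinship
#' @param estimator tag recorded on the matrix read back in.
#' @export
readKinship <- function(path, estimator = "external") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  n <- length(tok)
  if (any(lengths(tok) != n))
    stop("kinship dimension error: ", n, " lines but row lengths ",
         paste(unique(lengths(tok)), collapse = ","))
  k <- matrix(as.numeric(unlist(tok)), n, n, byrow = TRUE)
  # symmetrize away formatting round-off
  kinshipMatrix((k + t(k)) / 2, estimator = estimator)
}

#' Write / read an LD (r-squared) matrix as TSV with SNP-id headers
#'
#' @param ld an \code{LDMatrix}.
#' @param path file path.
#' @export
writeLDMatrix <- function(ld, path) {
  r2 <- as.matrix(ld)
  si <- snpInfo(ld)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("snp_id", si$snp_id), collapse = "\t"), con)
  for (i in seq_len(nrow(r2)))
    writeLines(paste(c(si$snp_id[i],
                       format(r2[i, ], digits = 15, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(NULL)
}

#' @rdname writeLDMatrix
#' @param map optional data.frame (snp_id, chromosome, position) giving
#'   coordinates for the SNPs; coordinates are required downstream by
#'   \code{\link{buildTestCorrelation}}.
#' @export
readLDMatrix <- function(path, map = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  r2 <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(map))
    map <- data.frame(snp_id = ids, chromosome = NA_integer_,
                      position = NA_real_, stringsAsFactors = FALSE)
  map <- map[match(ids, map$snp_id), ]
  ldMatrix(r2, map)
}

#' Write association / interaction results as TSV
#'
#' Fixed column order: test_id, snp1, snp2, chr1, chr2, phenotype, beta,
#' se, statistic, df, p. \code{snp2}/\code{chr2} are left empty for
#' single-SNP rows. An empty row set produces a header-only file.
#'
#' @param rows data.frame of result records (missing columns are filled
#'   with \code{NA}).
#' @param path file path.
#' @export
writeResults <- function(rows, path) {
  cols <- c("test_id", "snp1", "snp2", "chr1", "chr2", "phenotype",
            "beta", "se", "statistic", "df", "p")
  out <- data.frame(matrix(NA, nrow = NROW(rows), ncol = length(cols)),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  if (NROW(rows) > 0)
    for (cn in intersect(cols, names(rows))) out[[cn]] <- rows[[cn]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(test_id = "character", snp1 = "character",
                                   snp2 = "character",
                                   phenotype = "character"))
}

#' Write / read a longitudinal phenotype table as TSV
#'
#' Columns: family_id, individual_id, exam, SBP, DBP, HTN, age, smoking,
#' medication. Missing cells are empty.
#'
#' @param pheno data.frame in the layout above.
#' @param path file path.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(family_id = "character",
                                   individual_id = "character"))
}
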