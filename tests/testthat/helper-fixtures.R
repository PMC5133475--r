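# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# A tiny hand-built trio pedigree: two founders and one child.
trioPed <- function() {
  pedigree(family_id = c("F1", "F1", "F1"),
           individual_id = c("1", "2", "3"),
           father_id = c(NA, NA, "1"),
           mother_id = c(NA, NA, "2"),
           sex = c(1L, 2L, 1L))
}

# Hand-built genotypes: explicit dosages, one row per individual.
handGenotypes <- function(dos, chromosome = NULL, position = NULL,
                          familyId = "F1") {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  si <- data.frame(
    snp_id = paste0("rs", seq_len(m)),
    chromosome = if (is.null(chromosome)) rep(1L, m) else chromosome,
    position = if (is.null(position)) seq_len(m) * 1000L else position,
    allele_minor = "A", allele_major = "G",
    stringsAsFactors = FALSE)
  genotypeMatrix(dos, si,
                 data.frame(family_id = familyId,
                            individual_id = as.character(seq_len(nrow(dos))),
                            stringsAsFactors = FALSE))
}

# Write a .ped/.map pair from explicit genotype strings.
# genoRows: character vector, one entry per individual, alleles
# whitespace-separated, e.g. "A A G G".
writePedFixture <- function(genoRows, nSnps, dir = NULL, lead = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("pedfix")
    dir.create(dir)
  }
  pedPath <- file.path(dir, "fix.ped")
  mapPath <- file.path(dir, "fix.map")
  n <- length(genoRows)
  if (is.null(lead))
    lead <- paste("F1", seq_len(n), 0, 0, 1, 0)
  writeLines(paste(lead, genoRows), pedPath)
  writeLines(paste(1, paste0("rs", seq_len(nSnps)), 0,
                   seq_len(nSnps) * 1000), mapPath)
  list(ped = pedPath, map = mapPath)
}

# Unrelated "founder population": one singleton family per individual.
unrelatedPed <- function(n) {
  pedigree(family_id = paste0("F", seq_len(n)),
           individual_id = rep("1", n),
           father_id = rep(NA_character_, n),
           mother_id = rep(NA_character_, n),
           sex = rep(1L, n))
}

# Multivariate-normal trait with covariance s2g * K + s2e * I.
drawTrait <- function(K, s2g, s2e) {
  n <- nrow(K)
  L <- t(chol(s2g * K + s2e * diag(n) + 1e-10 * diag(n)))
  as.numeric(L %*% rnorm(n))
}
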