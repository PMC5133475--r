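## Bundled reference table: published probe-level replication p-values
## for SNP-SNP interaction effects on gene expression in the GAW19
## 20-family GWAS + expression data (13 SNP pairs; one gene, CTSC, has
## two probes, giving 14 tests). Shipped as plain TSV so the combined
## set test can be recomputed from it.

#' Published SNP-pair interaction replication p-values
#'
#' Returns the bundled table of 14 probe-level interaction replication
#' tests (gene, probe, the two SNPs with their chromosomes, and the
#' likelihood-ratio p-value) from the GAW19 family GWAS and expression
#' replication analysis.
#'
#' @return data.frame with columns gene, probe, snp1, chr1, snp2, chr2, p.
#' @examples
#' tab <- interactionReplication()
#' median(tab$p)
#' @export
interactionReplication <- function() {
  path <- system.file("extdata", "gaw19_interaction_replication.tsv",
                      package = "famlmm", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chr1 = "integer", chr2 = "integer"))
}

#' Build the set-test inputs for the bundled interaction table
#'
#' Converts \code{\link{interactionReplication}} (or a table in the same
#' layout) into a \code{\linkS4class{PValueSet}} plus the matching
#' \code{\linkS4class{LDMatrix}}. Base-pair positions are not part of
#' the published table, so synthetic positions 5 Mb apart are assigned
#' along each chromosome: distinct SNPs are then never "nearby"
#' (< 2 Mb) and only SNPs shared verbatim between tests are correlated
#' (r² = 1 with themselves). The LD matrix is therefore the identity
#' over the involved SNPs -- the "shared-SNP tests correlated, others
#' independent" null model.
#'
#' @param tab table in the \code{interactionReplication} layout;
#'   defaults to the bundled one.
#' @param dropSignificant if \code{TRUE}, rows at or below
#'   \code{alpha / nrow(tab)} (the Bonferroni threshold) are removed
#'   before building the set -- the "remaining tests" analysis.
#' @param alpha family-wise error rate for \code{dropSignificant}.
#' @return list with elements \code{pset} (PValueSet) and \code{ld}
#'   (LDMatrix).
#' @export
interactionReplicationSet <- function(tab = interactionReplication(),
                                      dropSignificant = FALSE,
                                      alpha = 0.05) {
  if (dropSignificant) {
    thr <- bonferroniThreshold(alpha, nrow(tab))
    tab <- tab[tab$p >= thr, , drop = FALSE]
  }
  snps <- unique(data.frame(
    snp_id = c(tab$snp1, tab$snp2),
    chromosome = c(tab$chr1, tab$chr2), stringsAsFactors = FALSE))
  # synthetic far-apart positions: 5 Mb spacing within each chromosome
  snps$position <- stats::ave(seq_len(nrow(snps)), snps$chromosome,
                              FUN = seq_along) * 5e6
  ld <- ldMatrix(diag(nrow(snps)), snps)
  pos <- setNames(snps$position, snps$snp_id)
  pset <- pValueSet(
    test_id = paste(tab$gene, tab$probe, tab$snp1, tab$snp2, sep = ":"),
    p = tab$p,
    snp1 = tab$snp1, chr1 = tab$chr1, pos1 = pos[tab$snp1],
    snp2 = tab$snp2, chr2 = tab$chr2, pos2 = pos[tab$snp2],
    phenotype = tab$probe)
  list(pset = pset, ld = ld)
}
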