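## End-to-end orchestration: simulate (or read) family data, prepare
## traits, estimate kinship, run single-SNP and interaction scans, set
## tests and multiple-testing verdicts, and write a plain-text report.
## Every stochastic stage draws a deterministic sub-seed from the master
## seed, so a rerun with the same config is byte-identical.

#' Empirical LD (r-squared) matrix from genotypes
#'
#' Squared Pearson correlation of minor-allele dosages (the composite
#' genotypic r² PLINK reports), with the genotype map carried along for
#' window-based correlation modeling.
#'
#' @param genotypes a \code{GenotypeMatrix}.
#' @param snpIds subset of SNPs (default: all).
#' @return an \code{\linkS4class{LDMatrix}}.
#' @export
ldFromGenotypes <- function(genotypes, snpIds = NULL) {
  si <- snpInfo(genotypes)
  if (is.null(snpIds)) snpIds <- si$snp_id
  d <- dosage(genotypes)[, snpIds, drop = FALSE]
  r2 <- stats::cor(d, use = "pairwise.complete.obs")^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 1
  ldMatrix(r2, si[match(snpIds, si$snp_id), c("snp_id", "chromosome", "position")])
}

#' Read a pipeline run configuration
#'
#' The config is a YAML file restricted to one nesting level: top-level
#' scalars (\code{seed}, \code{out_dir}) plus the blocks
#' \code{simulate} (SimConfig fields, optional), \code{inputs} (paths:
#' ped, map, pheno, kinship, pairs, expr) and \code{analysis}
#' (method, window, replicates, interaction_replicates, alpha,
#' n_candidate_snps, n_pairs). Missing analysis fields take defaults.
#'
#' @param path YAML file path.
#' @return config list suitable for \code{\link{runReplicationStudy}}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaultRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg partially specified config list.
#' @export
defaultRunConfig <- function(cfg = list()) {
  an <- cfg$analysis
  cfg$analysis <- list(
    method = an$method %||% "ML",
    window = an$window %||% 2e6,
    replicates = an$replicates %||% 500000,
    interaction_replicates = an$interaction_replicates %||% 10000000,
    alpha = an$alpha %||% 0.05,
    n_candidate_snps = an$n_candidate_snps %||% 10,
    n_pairs = an$n_pairs %||% 5,
    kinship = an$kinship %||% "RRM")
  cfg$seed <- cfg$seed %||% 1
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simConfigFromList <- function(sim, seed) {
  args <- list(seed = seed)
  mapNames <- c(n_families = "nFamilies", family_size_mean = "familySizeMean",
                n_generations = "nGenerations", n_snps = "nSnps",
                block_size = "blockSize", within_block_r = "withinBlockR",
                maf_range = "mafRange", n_exams = "nExams",
                trait_heritability = "traitHeritability",
                interaction_effect = "interactionEffect",
                residual_sd = "residualSd")
  for (nm in names(mapNames))
    if (!is.null(sim[[nm]])) args[[mapNames[nm]]] <- sim[[nm]]
  do.call(simConfig, args)
}

#' Run the full replication-analysis pipeline
#'
#' Stages: (1) simulate family data from the \code{simulate} block, or
#' read .ped/.map + phenotype TSV from \code{inputs}; (2) collapse the
#' longitudinal phenotypes to adjusted average traits (DBP, MAP, PP,
#' SBP, HTN); (3) estimate the kinship matrix (RRM by default) and
#' PSD-repair it; (4) mixed-model single-SNP scan of the candidate SNPs
#' for each trait; (5) interaction LRT for each SNP pair on its
#' expression probe; (6) combined set test per trait and for the
#' interaction set, with the LD-aware Monte-Carlo null; (7) Bonferroni
#' verdicts and a plain-text report. All outputs are written under
#' \code{config$out_dir}.
#'
#' @param config config list (see \code{\link{readRunConfig}}).
#' @param verbose emit one timestamped log line per stage.
#' @return invisibly, a list with the per-trait association tables, the
#'   interaction table, the set-test results and the report lines.
#' @export
runReplicationStudy <- function(config, verbose = TRUE) {
  config <- defaultRunConfig(config)
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  an <- config$analysis
  seeds <- streamSeeds(config$seed, 8L)

  if (!is.null(config$simulate)) {
    stageLog("simulate: generating synthetic family study", verbose = verbose)
    sc <- simConfigFromList(config$simulate, seed = seeds[1])
    ped <- simulatePedigree(sc)
    gen <- geneDrop(ped, sc)
    si <- snpInfo(gen)
    # candidate SNPs: first SNP of distinct blocks (mutually unlinked)
    blockFirst <- si$snp_id[!duplicated(si$block)]
    cand <- utils::head(blockFirst, an$n_candidate_snps)
    causal <- NULL
    if (!is.null(config$simulate$causal_beta)) {
      causal <- data.frame(snp_id = cand[1],
                           beta = config$simulate$causal_beta)
    }
    pheno <- simulateLongitudinalPhenotypes(gen, ped, sc, causalSnps = causal)
    # SNP pairs for the interaction arm: consecutive unlinked SNPs
    nPairs <- min(an$n_pairs, floor(length(blockFirst) / 2) - 1)
    pairs <- data.frame(
      gene = sprintf("G%02d", seq_len(nPairs)),
      probe = sprintf("P%02d", seq_len(nPairs)),
      snp1 = blockFirst[an$n_candidate_snps + 2 * seq_len(nPairs) - 1],
      snp2 = blockFirst[an$n_candidate_snps + 2 * seq_len(nPairs)],
      stringsAsFactors = FALSE)
    exprCfg <- sc
    exprCfg@residualSd <- 1
    exprSeeds <- streamSeeds(seeds[2], nrow(pairs))
    exprs <- lapply(seq_len(nrow(pairs)), function(i) {
      cfgI <- exprCfg
      if (i > 1) cfgI@interactionEffect <- 0  # only the first pair is causal
      simulateExpression(gen, ped, cfgI,
                         pair = c(pairs$snp1[i], pairs$snp2[i]),
                         seed = exprSeeds[i])
    })
    names(exprs) <- pairs$probe
    writePedMap(gen, ped, file.path(outDir, "study.ped"),
                file.path(outDir, "study.map"))
    writePhenotypes(pheno, file.path(outDir, "phenotypes.tsv"))
    truth <- list(seed = config$seed,
                  causal_snps = causal,
                  true_h2 = sc@traitHeritability,
                  true_residual_sd = sc@residualSd,
                  true_interaction_effect = sc@interactionEffect,
                  causal_pair = list(snp1 = pairs$snp1[1],
                                     snp2 = pairs$snp2[1]))
    jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stageLog("read: loading study inputs", verbose = verbose)
    inp <- config$inputs
    pm <- readPedMap(inp$ped, inp$map)
    gen <- pm$genotypes
    ped <- pm$pedigree
    pheno <- readPhenotypes(inp$pheno)
    cand <- config$candidate_snps %||% snpInfo(gen)$snp_id
    pairs <- if (!is.null(inp$pairs))
      utils::read.table(inp$pairs, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    exprs <- NULL
    if (!is.null(inp$expr)) {
      etab <- utils::read.table(inp$expr, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      keys <- makeSampleKeys(etab$family_id, etab$individual_id)
      probeCols <- setdiff(names(etab), c("family_id", "individual_id"))
      exprs <- lapply(probeCols, function(cn) setNames(etab[[cn]], keys))
      names(exprs) <- probeCols
    }
  }

  stageLog("prep: adjusted average traits", verbose = verbose)
  traits <- c("DBP", "MAP", "PP", "SBP", "HTN")
  derived <- lapply(traits, function(tr) adjustAndAverage(pheno, tr))
  names(derived) <- traits

  stageLog("kinship: ", an$kinship, " estimator", verbose = verbose)
  K <- if (identical(an$kinship, "centered")) centeredKinship(gen)
       else rrmKinship(gen)
  K <- repairPSD(K)
  writeKinship(K, file.path(outDir, "kinship.txt"))

  stageLog("assoc: single-SNP mixed-model scan", verbose = verbose)
  assoc <- lapply(traits, function(tr)
    assocScan(gen, traitVector(derived[[tr]]), K, snpIds = cand,
              phenotype = tr, method = an$method))
  names(assoc) <- traits
  assocAll <- do.call(rbind, assoc)
  writeResults(assocAll, file.path(outDir, "assoc_results.tsv"))

  stageLog("settest: combined evidence per trait", verbose = verbose)
  ld <- ldFromGenotypes(gen, cand)
  setSeeds <- streamSeeds(seeds[3], length(traits) + 1L)
  setResults <- list()
  for (i in seq_along(traits)) {
    tr <- traits[i]
    rows <- assoc[[tr]]
    ok <- !is.na(rows$p)
    if (sum(ok) == 0) next
    pset <- pValueSet(rows$test_id[ok], pmax(rows$p[ok], 1e-300),
                      snp1 = rows$snp1[ok], chr1 = rows$chr1[ok],
                      pos1 = snpInfo(gen)$position[match(rows$snp1[ok], snpInfo(gen)$snp_id)],
                      phenotype = tr)
    corr <- buildTestCorrelation(pset, ld, window = an$window)
    setResults[[tr]] <- simulateSetNull(pset, corr,
                                        nReplicates = an$replicates,
                                        seed = setSeeds[i])
  }

  interact <- NULL
  if (!is.null(pairs) && !is.null(exprs)) {
    stageLog("interact: SNP-pair LRTs on expression probes", verbose = verbose)
    adjExprs <- lapply(exprs, expressionPrep)
    interact <- interactionScan(adjExprs, gen, pairs, K)
    writeResults(interact, file.path(outDir, "interaction_results.tsv"))
    ok <- !is.na(interact$p)
    si <- snpInfo(gen)
    pset <- pValueSet(interact$test_id[ok], pmax(interact$p[ok], 1e-300),
                      snp1 = interact$snp1[ok], chr1 = interact$chr1[ok],
                      pos1 = si$position[match(interact$snp1[ok], si$snp_id)],
                      snp2 = interact$snp2[ok], chr2 = interact$chr2[ok],
                      pos2 = si$position[match(interact$snp2[ok], si$snp_id)],
                      phenotype = interact$phenotype[ok])
    ldI <- ldFromGenotypes(gen, unique(c(interact$snp1[ok], interact$snp2[ok])))
    corrI <- buildTestCorrelation(pset, ldI, window = an$window)
    setResults[["interaction"]] <-
      simulateSetNull(pset, corrI, nReplicates = an$interaction_replicates,
                      seed = setSeeds[length(traits) + 1L])
  }

  summaries <- lapply(setResults, function(r) list(
    T = r@statistic, n = r@nTests, overall_p = r@overallP,
    reps = r@nReplicates, method = r@method, seed = r@seed))
  jsonlite::write_json(summaries, file.path(outDir, "set_tests.json"),
                       auto_unbox = TRUE, digits = NA)

  stageLog("report", verbose = verbose)
  rpt <- c("Replication study report",
           "========================", "")
  thrA <- bonferroniThreshold(an$alpha, sum(!is.na(assocAll$p)))
  rpt <- c(rpt, sprintf("Single-SNP tests: %d (of which %d monomorphic/NA)",
                        nrow(assocAll), sum(is.na(assocAll$p))),
           sprintf("Bonferroni threshold %g/%d = %s", an$alpha,
                   sum(!is.na(assocAll$p)), format(signif(thrA, 2))), "")
  sig <- assocAll[!is.na(assocAll$p) & assocAll$p < thrA, ]
  rpt <- c(rpt, if (nrow(sig)) c("Significant single-SNP associations:",
                                 sprintf("  %s on %s: p = %.3g", sig$snp1,
                                         sig$phenotype, sig$p))
               else "No single-SNP association passes Bonferroni.", "")
  for (tr in names(setResults)) {
    r <- setResults[[tr]]
    rpt <- c(rpt, sprintf("Set test [%s]: T = %.4f over %d tests, overall p = %.3g (%s, %g reps)",
                          tr, r@statistic, r@nTests, r@overallP, r@method,
                          r@nReplicates))
  }
  if (!is.null(interact)) {
    thrI <- bonferroniThreshold(an$alpha, sum(!is.na(interact$p)))
    sigI <- interact[!is.na(interact$p) & interact$p < thrI, ]
    rpt <- c(rpt, "",
             sprintf("Interaction tests: %d, Bonferroni threshold %s",
                     nrow(interact), format(signif(thrI, 2))),
             if (nrow(sigI)) sprintf("  significant: %s x %s (%s): p = %.3g",
                                     sigI$snp1, sigI$snp2, sigI$phenotype,
                                     sigI$p)
             else "  no interaction passes Bonferroni.")
  }
  writeLines(rpt, file.path(outDir, "report.txt"))
  invisible(list(assoc = assoc, interaction = interact,
                 setTests = setResults, report = rpt,
                 derived = derived, kinship = K))
}
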