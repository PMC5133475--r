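## Synthetic family-study generator: pedigree construction, gene-dropping
## of block-LD genotypes, longitudinal blood-pressure phenotypes with a
## polygenic component, and expression traits with an optional
## additive-by-additive two-SNP interaction. All operations are
## deterministic given the SimConfig master seed; each operation draws
## its own sub-seed so stages are invariant to one another's draw counts.

opSeed <- function(config, op, seed = NULL) {
  if (!is.null(seed)) return(as.integer(seed))
  idx <- match(op, c("pedigree", "genedrop", "phenotypes", "expression"))
  streamSeeds(config@seed, 4L)[idx]
}

#' Simulate a multi-generation family pedigree
#'
#' Each family starts from a founder couple; every couple has a
#' truncated-Poisson number of children, and in non-terminal generations
#' each child is paired with a marry-in founder spouse. The per-couple
#' offspring mean is solved from \code{familySizeMean} so that the
#' expected family size matches the target.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param seed optional integer overriding the config-derived sub-seed.
#' @return a \code{\linkS4class{Pedigree}}.
#' @examples
#' ped <- simulatePedigree(simConfig(nFamilies = 2, seed = 11))
#' ped
#' @export
simulatePedigree <- function(config, seed = NULL) {
  set.seed(opSeed(config, "pedigree", seed))
  # expected family size over G generations with per-couple mean o:
  # 2 + 2o + o^2 for G = 3; solved generally by the G = 3 formula and
  # clamped, which is adequate for the supported depths (2..4).
  o <- max(0.5, sqrt(max(config@familySizeMean - 1, 1)) - 1)
  if (config@nGenerations == 2L) o <- max(0.5, config@familySizeMean - 2)
  rows <- list()
  for (f in seq_len(config@nFamilies)) {
    fid <- sprintf("F%02d", f)
    nid <- 0L
    newId <- function() { nid <<- nid + 1L; as.character(nid) }
    recs <- list()
    add <- function(id, fa, mo, sex) {
      recs[[length(recs) + 1L]] <<- data.frame(
        family_id = fid, individual_id = id,
        father_id = fa, mother_id = mo, sex = sex,
        stringsAsFactors = FALSE)
    }
    p1 <- newId(); add(p1, NA, NA, 1L)
    p2 <- newId(); add(p2, NA, NA, 2L)
    couples <- list(c(p1, p2))
    for (g in 2:config@nGenerations) {
      nxt <- list()
      for (cp in couples) {
        nk <- max(1L, rpois(1L, o))
        for (k in seq_len(nk)) {
          sex <- sample(1:2, 1L)
          child <- newId(); add(child, cp[1], cp[2], sex)
          if (g < config@nGenerations) {
            sp <- newId(); add(sp, NA, NA, 3L - sex)
            nxt[[length(nxt) + 1L]] <-
              if (sex == 1L) c(child, sp) else c(sp, child)
          }
        }
      }
      couples <- nxt
    }
    rows[[f]] <- do.call(rbind, recs)
  }
  p <- do.call(rbind, rows)
  pedigree(p$family_id, p$individual_id, p$father_id, p$mother_id, p$sex)
}

# Parent-before-child topological depth for a pedigree data.frame.
pedDepth <- function(p) {
  key <- makeSampleKeys(p$family_id, p$individual_id)
  fa <- match(makeSampleKeys(p$family_id, p$father_id), key)
  mo <- match(makeSampleKeys(p$family_id, p$mother_id), key)
  depth <- rep(0L, nrow(p))
  repeat {
    nd <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
               ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (all(nd == depth)) break
    depth <- nd
  }
  list(depth = depth, fa = fa, mo = mo)
}

#' Gene-drop genotypes down a pedigree with block LD
#'
#' Founder haplotypes are drawn from a population with LD blocks: within
#' a block, a latent Gaussian AR(1) chain with adjacent correlation
#' \code{withinBlockR} is thresholded at \code{qnorm(maf)} so that the
#' marginal minor-allele frequency is preserved while neighbouring
#' markers are correlated; blocks are mutually independent.
#' Transmission is Mendelian with free recombination between blocks and
#' none within a block. Blocks are laid out 5 Mb apart (markers 10 kb
#' apart within a block) so that "nearby" (< 2 Mb) coincides with
#' same-block.
#'
#' @param pedigree a \code{Pedigree}.
#' @param config a \code{SimConfig}; \code{mafs} may override the
#'   per-SNP minor-allele frequencies drawn from \code{mafRange}.
#' @param mafs optional numeric vector of per-SNP MAFs.
#' @param seed optional integer sub-seed override.
#' @return a \code{\linkS4class{GenotypeMatrix}} of minor-allele counts.
#' @export
geneDrop <- function(pedigree, config, mafs = NULL, seed = NULL) {
  set.seed(opSeed(config, "genedrop", seed))
  p <- as.data.frame(pedigree)
  n <- nrow(p)
  m <- config@nSnps
  if (is.null(mafs))
    mafs <- runif(m, config@mafRange[1], config@mafRange[2])
  stopifnot(length(mafs) == m)
  blockId <- rep(seq_len(ceiling(m / config@blockSize)),
                 each = config@blockSize)[seq_len(m)]
  nBlocks <- max(blockId)
  thr <- qnorm(mafs)
  r <- config@withinBlockR

  topo <- pedDepth(p)
  ord <- order(topo$depth)
  isFounder <- is.na(topo$fa) & is.na(topo$mo)

  # founder haplotypes: latent AR(1) within blocks, thresholded
  nf <- sum(isFounder)
  nh <- 2L * nf
  z <- matrix(0, nh, m)
  for (j in seq_len(m)) {
    first <- j == 1L || blockId[j] != blockId[j - 1L]
    z[, j] <- if (first) rnorm(nh)
              else r * z[, j - 1L] + sqrt(1 - r^2) * rnorm(nh)
  }
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  fIdx <- which(isFounder)
  H1[fIdx, ] <- (z[seq_len(nf) * 2L - 1L, , drop = FALSE] <
                 matrix(thr, nf, m, byrow = TRUE)) + 0L
  H2[fIdx, ] <- (z[seq_len(nf) * 2L, , drop = FALSE] <
                 matrix(thr, nf, m, byrow = TRUE)) + 0L

  # Mendelian transmission in parent-first order, block-wise
  blockCols <- split(seq_len(m), blockId)
  for (i in ord[!isFounder[ord]]) {
    pickF <- sample(c(1L, 2L), nBlocks, replace = TRUE)
    pickM <- sample(c(1L, 2L), nBlocks, replace = TRUE)
    for (b in seq_len(nBlocks)) {
      cols <- blockCols[[b]]
      H1[i, cols] <- if (pickF[b] == 1L) H1[topo$fa[i], cols] else H2[topo$fa[i], cols]
      H2[i, cols] <- if (pickM[b] == 1L) H1[topo$mo[i], cols] else H2[topo$mo[i], cols]
    }
  }

  within <- sequence(rle(blockId)$lengths)
  si <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chromosome = 1L,
    position = (blockId - 1) * 5e6 + (within - 1) * 1e4 + 1,
    allele_minor = "A", allele_major = "G",
    maf = mafs, block = blockId,
    stringsAsFactors = FALSE)
  genotypeMatrix(H1 + H2, si,
                 data.frame(family_id = p$family_id,
                            individual_id = p$individual_id,
                            stringsAsFactors = FALSE))
}

# Polygenic draw with covariance sigmaG2 * 2*Phi from the pedigree.
polygenicDraw <- function(pedigree, sigmaG2) {
  k <- as.matrix(pedigreeKinship(pedigree))
  n <- nrow(k)
  if (sigmaG2 <= 0) return(numeric(n))
  L <- t(chol(k + 1e-10 * diag(n)))
  as.numeric(sqrt(sigmaG2) * (L %*% rnorm(n)))
}

#' Simulate longitudinal blood-pressure phenotypes
#'
#' Generates, for every pedigree member and exam, diastolic blood
#' pressure as
#' \deqn{DBP = 80 + \sum_j \beta_j d_j + \beta_{age} age + \beta_{smk} smk
#'   + \beta_{med} med + g_i + e_{ie}}
#' with polygenic \eqn{g \sim N(0, \sigma_g^2 \, 2\Phi)} (pedigree
#' kinship) and iid exam-level noise; \eqn{\sigma_g^2} is set from
#' \code{traitHeritability} and \code{residualSd}. Systolic pressure is
#' DBP plus an always-positive pulse-pressure component (30 mmHg plus a
#' Gamma(4, scale 2.5) draw), so SBP > DBP by construction. Hypertension
#' is SBP >= 140 or antihypertensive medication. Age starts from a
#' generation-dependent baseline and increments one year per exam;
#' smoking and medication are per-individual Bernoulli draws (rates 0.2
#' and 0.15).
#'
#' @param genotypes \code{GenotypeMatrix} covering the pedigree members.
#' @param pedigree \code{Pedigree}.
#' @param config \code{SimConfig}.
#' @param causalSnps optional data.frame with columns \code{snp_id},
#'   \code{beta} (mmHg per minor allele) for DBP.
#' @param seed optional integer sub-seed override.
#' @return long-format data.frame: family_id, individual_id, exam, SBP,
#'   DBP, HTN, age, smoking, medication.
#' @export
simulateLongitudinalPhenotypes <- function(genotypes, pedigree, config,
                                           causalSnps = NULL, seed = NULL) {
  set.seed(opSeed(config, "phenotypes", seed))
  p <- as.data.frame(pedigree)
  n <- nrow(p)
  d <- dosage(genotypes)
  stopifnot(identical(rownames(d), makeSampleKeys(p$family_id, p$individual_id)))

  gEffect <- numeric(n)
  if (!is.null(causalSnps) && nrow(causalSnps) > 0) {
    miss <- setdiff(causalSnps$snp_id, colnames(d))
    if (length(miss))
      stop("causal SNP(s) absent from genotypes: ", paste(miss, collapse = ", "))
    dc <- d[, causalSnps$snp_id, drop = FALSE]
    dc[is.na(dc)] <- 0
    gEffect <- as.numeric(dc %*% causalSnps$beta)
  }

  h2 <- config@traitHeritability
  sigmaE2 <- config@residualSd^2
  sigmaG2 <- if (h2 > 0) h2 / (1 - h2) * sigmaE2 else 0
  poly <- polygenicDraw(pedigree, sigmaG2)

  # generation-dependent baseline age; marry-in founders take the
  # generation of their children
  topo <- pedDepth(p)
  eff <- topo$depth
  for (i in which(!is.na(topo$fa))) {
    eff[topo$fa[i]] <- max(eff[topo$fa[i]], topo$depth[i] - 1L)
    eff[topo$mo[i]] <- max(eff[topo$mo[i]], topo$depth[i] - 1L)
  }
  age0 <- 72 - 20 * eff + rnorm(n, 0, 4)
  smoking <- rbinom(n, 1, 0.2)
  medication <- rbinom(n, 1, 0.15)
  ce <- config@covariateEffects

  out <- vector("list", config@nExams)
  for (e in seq_len(config@nExams)) {
    age <- age0 + (e - 1)
    dbp <- 80 + gEffect + ce[["age"]] * age + ce[["smoking"]] * smoking +
      ce[["medication"]] * medication + poly +
      rnorm(n, 0, config@residualSd)
    pp <- 30 + stats::rgamma(n, shape = 4, scale = 2.5)
    sbp <- dbp + pp
    out[[e]] <- data.frame(
      family_id = p$family_id, individual_id = p$individual_id,
      exam = e, SBP = sbp, DBP = dbp,
      HTN = as.integer(sbp >= 140 | medication == 1),
      age = age, smoking = smoking, medication = medication,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate an expression trait with an additive-by-additive interaction
#'
#' \deqn{expr = a_1 d_1 + a_2 d_2 + \gamma d_1 d_2 + g + e}
#' where \eqn{d_1, d_2} are the minor-allele dosages of the designated
#' SNP pair, \eqn{\gamma} is \code{interactionEffect} from the config,
#' the polygenic term has covariance \eqn{\sigma_g^2 2\Phi} and the
#' noise SD is \code{residualSd} (set it to ~1 for expression-scale
#' traits).
#'
#' @inheritParams simulateLongitudinalPhenotypes
#' @param pair character vector of two SNP ids.
#' @param mainEffects numeric length-2 additive main effects.
#' @return named numeric vector of expression values (names are sample
#'   keys).
#' @export
simulateExpression <- function(genotypes, pedigree, config, pair,
                               mainEffects = c(0, 0), seed = NULL) {
  set.seed(opSeed(config, "expression", seed))
  d <- dosage(genotypes)
  miss <- setdiff(pair, colnames(d))
  if (length(miss))
    stop("pair SNP(s) absent from genotypes: ", paste(miss, collapse = ", "))
  stopifnot(length(pair) == 2)
  d1 <- d[, pair[1]]; d2 <- d[, pair[2]]
  h2 <- config@traitHeritability
  sigmaE2 <- config@residualSd^2
  sigmaG2 <- if (h2 > 0) h2 / (1 - h2) * sigmaE2 else 0
  poly <- polygenicDraw(pedigree, sigmaG2)
  expr <- mainEffects[1] * d1 + mainEffects[2] * d2 +
    config@interactionEffect * d1 * d2 + poly +
    rnorm(length(d1), 0, config@residualSd)
  names(expr) <- rownames(d)
  expr
}
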