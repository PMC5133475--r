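---
title: "Methods: kinship LMMs, epistasis LRTs and combined-evidence set tests for family replication studies"
author: "famlmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship LMMs, epistasis LRTs and combined-evidence set tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlmm)
```

## What the package is for

Replication studies of blood-pressure and expression-trait genetics in
extended families face three recurring statistical tasks:

1. testing candidate SNPs one at a time while correcting for the strong
   phenotypic correlation that relatedness induces;
2. testing previously reported SNP–SNP (additive-by-additive) interaction
   effects on expression traits under the same relatedness correction; and
3. asking whether a *set* of candidate tests carries more evidence in
   aggregate than any single test does on its own — the typical situation
   when individual replication power is low.

famlmm implements all three, together with a pedigree-based data
generator so that every stage can be exercised, calibrated and
regression-tested without access to restricted family data sets (the
bundled reference table comes from a GAW19-style 20-family
blood-pressure cohort of roughly 950 genotyped members, a design the
generator's defaults emulate).

## The mixed model

All association and interaction tests are built on one model:

$$y = X\beta + g + e, \qquad
  g \sim N(0, \sigma_g^2 K), \qquad
  e \sim N(0, \sigma_e^2 I),$$

where $K$ is a genetic relatedness matrix. Two genotype-based
estimators are provided, selected to match the conventions of the two
mixed-model tools practitioners use most:

* **RRM** (`rrmKinship`): per-SNP standardized genotypes,
  $K = WW^\top/m$. Unrelated pairs have expectation 0; a
  parent–offspring or full-sib pair has expectation 0.5.
* **centered** (`centeredKinship`): mean-centered but not
  variance-scaled dosages, $K = CC^\top/m$ — the default of tools that
  operate on raw dosage cross-products.

Both mean-impute missing dosages and silently drop monomorphic columns
(with a logged count); which of the two an upstream study used is
rarely documented, so both are first-class and tests demonstrate they
agree up to per-SNP scale when all allele frequencies are equal.
`pedigreeKinship` supplies the expected relatedness $2\Phi$ by the
classic recursion; it is used as the covariance of simulated polygenic
effects and as the oracle the genotype estimators are tested against,
never as the analysis matrix.

### Fitting

`fitLMM` eigendecomposes $K = USU^\top$ once, rotates $y$ and $X$ by
$U^\top$, and profiles the likelihood analytically over $\beta$ and
$\sigma_g^2$, leaving a one-dimensional problem in
$\delta = \sigma_e^2/\sigma_g^2$. The profile is maximized on a
64-point log-spaced grid over $[10^{-5}, 10^5]$ followed by bounded
scalar refinement (relative tolerance $10^{-6}$); ties resolve to the
smaller $\delta$, and the returned optimum is guaranteed to dominate
every grid point. With $K = I$ the profile is flat in how the total
variance splits and the fit reduces exactly to ordinary least squares —
the tested degenerate case that covers unrelated-sample analyses
(`olsAssoc` provides the per-SNP Wald version).

Maximum likelihood (not REML) is the default everywhere because every
test in the package is a likelihood-ratio test between nested models,
and ML keeps one coherent inferential path; REML is available for
variance reporting. $\delta$ is re-optimized under each model rather
than reused from the null fit — the conservative reading of
"maximum-likelihood estimates for each model" — and a negative LRT from
numerical jitter is clamped to zero. A noise-free (interpolating) fit
sends the profile likelihood to $+\infty$; it is capped at a large
finite value so optimizer and LRT arithmetic stay well defined.

### Single-SNP and interaction tests

`assocScan` compares null (intercept + covariates) against alternative
(+ dosage) per SNP, dropping individuals with a missing dosage for that
SNP only and refitting the null per missingness pattern; the statistic
is referred to $\chi^2_1$. `interactionTest` compares
$M_0: 1 + d_1 + d_2$ against $M_1: M_0 + d_1 d_2$ — the
additive-by-additive encoding in which the interaction is the product
of minor-allele counts. The product column must not be collinear with
$\{1, d_1, d_2\}$ (a dosage configuration with no heterozygotes can
degenerate this way); such pairs error with a message naming the
degeneracy rather than returning a meaningless p-value. Because
$\{1, d_1, d_2, d_1 d_2\}$ and $\{1, 2-d_1, d_2, (2-d_1) d_2\}$ span
the same column space, the LRT p-value is invariant to which allele is
counted — tested, since upstream studies rarely document the coding.

## The combined set test

For a set of $n$ tests with p-values $p_i$ the evidence statistic is

$$T = -\sum_{i=1}^{n} \log_{10} p_i,$$

the untruncated member of the rank-truncated-product family. Under
independent nulls $T\ln 10 \sim \mathrm{Gamma}(n, 1)$ (Fisher's method
up to the constant $2\ln 10$), which `fisherIndependent` evaluates in
closed form. Nearby tests are not independent, however: SNPs in LD
within a 2 Mb window produce correlated statistics. `simulateSetNull`
therefore draws latent Gaussian vectors $Z$ with a test-level
correlation matrix, maps them to uniforms via the two-sided tail
$p_i = 2\Phi(-|Z_i|)$, recomputes $T$ per replicate, and reports the
strictly-greater tail proportion (an `addOne` flag gives the
conservative $(\#+1)/(B+1)$ variant).

### The correlation model and its rationale

`buildTestCorrelation` assembles the test-level matrix from three
rules, each of which deserves its justification because none is forced:

* **SNP level.** Latent correlation $+\sqrt{r^2}$ for same-chromosome
  SNPs closer than 2 Mb, else 0. Genotypic $r^2$ carries no sign, so
  the positive root is an approximation that can only overstate
  dependence; it matters only for sets with substantial cross-test LD.
* **Pair tests.** For two interaction tests the correlation is the
  product of the two constituent SNP correlations, under the alignment
  maximizing the product. The product rule is exact for bilinear forms
  of independent Gaussians and reduces correctly at $r^2 \in \{0,1\}$.
* **Phenotype conditioning.** Tests computed on *different* traits (or
  different expression probes) are uncorrelated under the null
  regardless of SNP overlap: conditional on genotypes, their statistics
  are functions of independent trait vectors. The SNP-overlap rules
  therefore apply only within a phenotype label
  (`respectPhenotype = FALSE` restores the raw SNP rule). This matters
  in practice: two probes of the same gene tested against the same SNP
  pair would otherwise be forced to correlation 1, which doubles-counts
  one test and visibly distorts the null tail of $T$. With the
  conditioning in place, the bundled 14-test expression set reduces to
  an (effectively) independent null, and the Monte-Carlo tail agrees
  with the Gamma closed form — both desk-checks in the test suite.

For the bundled replication table no base-pair positions are published,
so `interactionReplicationSet` assigns synthetic positions 5 Mb apart:
distinct SNPs are never "nearby", and only verbatim-shared SNPs are
correlated. That is a deliberate, documented stand-in for the original
LD structure, not an estimate of it.

### Multiple testing

`bonferroniThreshold` is $\alpha/n$ (displayed at 2 significant
figures, e.g. $0.05/75 = 0.00067$, $0.05/12 = 0.0042$,
$0.05/14 = 0.0036$); `byAdjust` wraps the Benjamini–Yekutieli step-up
adjustment, valid under arbitrary dependence.

## Phenotype preparation

Longitudinal blood-pressure records (SBP, DBP, derived MAP
$= \tfrac23\,\mathrm{DBP} + \tfrac13\,\mathrm{SBP}$ and PP
$= \mathrm{SBP} - \mathrm{DBP}$, and binary HTN treated as a 0/1
quantitative trait) are reduced to one value per individual by
`adjustAndAverage`: per-exam least-squares adjustment for age, smoking
and antihypertensive medication, averaging of the residuals over each
individual's available exams, and z-standardization. The
adjust-then-average order is a package decision — the averaging
literature is split on it — and the alternative
(`order = "average_first"`) is exposed; the two agree closely on
complete data and neither claims fidelity to any particular historical
pipeline. Medication enters only as a covariate (no +10/+5 mmHg
imputation): treating medication handling as a data-quality question
rather than a method step keeps the pipeline free of untestable
constants. Individuals with no usable exam are absent from the output,
never zero-filled.

## The synthetic study generator

`simConfig()` defaults describe the emulated design and are the
conditions under which the calibration tests run:

| parameter | default | why |
|---|---|---|
| `nFamilies`, `familySizeMean`, `nGenerations` | 20, 48, 3 | 20 extended three-generation families, ≈950 members |
| `nSnps`, `blockSize`, `withinBlockR` | 1000, 10, 0.8 | LD blocks; latent adjacent-marker correlation 0.8 gives realistic within-block $r^2$ |
| `mafRange` | (0.05, 0.5] | common variants, as on GWAS arrays |
| `nExams` | 4 | longitudinal design measured over 4 years |
| `traitHeritability` | 0.3 | mid-range for blood-pressure traits |
| `covariateEffects` | age 0.5, smoking 4, medication −8 (mmHg) | conventional signs/magnitudes |
| `residualSd` | 8 mmHg | typical exam-level DBP noise |

Founder haplotypes come from a Gaussian threshold model: a latent AR(1)
chain within each block, thresholded at $\Phi^{-1}(\mathrm{maf})$, so
marginal allele frequencies are exact while neighbouring markers are
correlated; blocks are independent and laid out 5 Mb apart (10 kb
between markers within a block), making "nearby (< 2 Mb)" coincide
with "same block". Transmission is Mendelian with free recombination
between blocks and none within — no genetic map, because the analyses
need LD windows and relatedness, not recombination realism. Phenotypes
add a polygenic term with covariance $\sigma_g^2\, 2\Phi$ from the
pedigree, exam-level iid noise, covariate effects, and an
always-positive pulse-pressure component so SBP > DBP holds by
construction; HTN is thresholded SBP (≥ 140 mmHg) or medication — any
monotone link suffices for pipeline testing, which is all HTN is used
for. Expression traits are
$a_1 d_1 + a_2 d_2 + \gamma d_1 d_2 + g + e$ with $\gamma$ the
designed interaction effect.

Every stochastic operation derives its own sub-seed deterministically
from the master seed, so reruns are byte-identical and stages are
insensitive to one another's draw counts.

What the generator does *not* emulate: sequence-level variation,
imputation artefacts, genotyping-chip ascertainment, and
ethnicity/admixture structure. Calibration results on synthetic data
therefore speak to the correctness of the statistics under the stated
model, not to robustness against those real-data complications.

## Calibration and problem sizes

The test suite fixes its own problem sizes, chosen to make the
binomial/Monte-Carlo error small relative to the assertion bands:

* type-I error of the single-SNP scan and the interaction LRT is
  estimated from 1000 null replicates on a 20-family pedigree of ≈480
  members with a 300-SNP RRM — 20 families because the $\chi^2_1$
  asymptotics of variance-component LRTs degrade visibly when the same
  total n is packed into a handful of large (hence highly correlated)
  families, which is a finding of the suite itself, not an assumption;
* heritability and $\delta$ recovery use the full ≈950-member design
  over 20 trait replicates;
* Monte-Carlo set-test checks run $10^6$–$10^7$ replicates, where the
  relative standard error at the quantities of interest is a few
  percent.

## Known limitations

* Variance-component LRT p-values are asymptotic; with few large
  families they become anticonservative, and nothing in the package
  corrects for that beyond documenting it.
* The $+\sqrt{r^2}$ latent-correlation choice ignores LD sign; for
  strongly cross-correlated test sets the Monte-Carlo null is an
  approximation validated only at the independence and
  perfect-correlation limits.
* Power calculations assume unrelated individuals and therefore bound
  family-design power from above.
* Binary traits are analyzed as 0/1 quantitative values throughout; no
  generalized (logistic) mixed model is provided.
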