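---
title: "SNP heritability and genetic correlations by EM-REML: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP heritability and genetic correlations by EM-REML: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snpherit)
```

## The model

For $m$ individuals, $n$ biallelic loci, and $t$ traits, snpherit fits the
multivariate linear mixed-effects model

$$\mathbf{y}_i = \mathbf{X}\mathbf{v}_i + \mathbf{Z}\mathbf{u}_i + \mathbf{e}_i,
\qquad i = 1, \dots, t,$$

where $\mathbf{y}_i$ is the $m \times 1$ vector of trait $i$, $\mathbf{X}$ an
$m \times s$ fixed-effect design shared across traits, $\mathbf{Z}$ the
$m \times n$ matrix of standardized genotypes, and the random effects satisfy
$\mathrm{cov}(\mathbf{Z u}_i, \mathbf{Z u}_j) = \mathrm{cov}_{g,ij}\,\mathbf{A}$
and $\mathrm{cov}(\mathbf{e}_i, \mathbf{e}_j) = \mathrm{cov}_{e,ij}\,\mathbf{I}_m$,
with $\mathbf{A}$ the genomic relationship matrix (GRM). Stacking traits, the
phenotypic covariance is the tensor-product form
$\mathbf{V} = \mathbf{G}_{t} \otimes \mathbf{A} + \mathbf{R}_{t} \otimes \mathbf{I}_m$
with $\mathbf{G}_t = (\mathrm{cov}_{g,ij})$ and $\mathbf{R}_t = (\mathrm{cov}_{e,ij})$.
Heritability for trait $i$ is $h^2 = \mathrm{var}_g / (\mathrm{var}_g +
\mathrm{var}_e)$, and the genetic correlation between traits $i$ and $j$ is the
genetic covariance normalized by the geometric mean of the genetic variances.
When $\mathbf{A}$ is estimated from common SNPs and the cohort is restricted
to unrelated individuals, the same ratio estimates $h_g^2$, the heritability
captured by the genotyped common variants; with a cohort of close relatives it
estimates the full narrow-sense $h^2$.

Genotypes are standardized under Hardy-Weinberg equilibrium: a dosage $x$ at a
locus with minor allele frequency $p$ becomes $(x - 2p)/\sqrt{2p(1-p)}$
(mean $2p$, variance $2p(1-p)$). The GRM has off-diagonal entries
$A_{jk} = n^{-1} \sum_i z_{ij} z_{ik}$ and a modified diagonal
$A_{jj} = 1 + n^{-1} \sum_i \frac{x_{ij}^2 - (1 + 2p_i) x_{ij} + 2p_i^2}{2 p_i (1-p_i)}$,
which has expectation 1 under HWE and lower sampling noise than the naive
average of $z^2$. Missing calls standardize to exactly zero (mean imputation),
so they contribute nothing to relatedness; as a consequence the mean
off-diagonal carries a small finite-sample bias of order $-1/m$ when allele
frequencies are estimated from the sample itself.

## REML by EM

The restricted log-likelihood is, up to an additive constant that we drop
consistently,

$$L = -\tfrac12\left[\log\det\mathbf{V} + \log\det(\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})
+ \mathbf{y}'\mathbf{P}\mathbf{y}\right],
\qquad
\mathbf{P} = \mathbf{V}^{-1} - \mathbf{V}^{-1}\mathbf{X}
(\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})^{-1}\mathbf{X}'\mathbf{V}^{-1},$$

with gradient $\partial L/\partial\theta_a = -\tfrac12[\mathrm{tr}(\mathbf{P}
\mathbf{V}_a) - \mathbf{y}'\mathbf{P}\mathbf{V}_a\mathbf{P}\mathbf{y}]$ where
$\mathbf{V}_a = \mathbf{E}_{ij} \otimes \mathbf{A}$ for genetic parameters and
$\mathbf{E}_{ij} \otimes \mathbf{I}$ for residual ones ($\mathbf{E}_{ij}$ the
symmetric basis matrix). Two EM algorithms maximize $L$:

* **Direct EM** (`reml_fit(..., algorithm = "direct")`). The standard
  variance-component EM: with $\hat{\mathbf{g}}_i = \sum_j \mathrm{cov}_{g,ij}
  \mathbf{A} (\mathbf{P}\mathbf{y})_j$ the conditional means of the genetic
  values, the M-step is
  $\mathrm{cov}_{g,ij} \leftarrow m^{-1}[\hat{\mathbf{g}}_i'\mathbf{A}^{-1}
  \hat{\mathbf{g}}_j + m\,\mathrm{cov}_{g,ij} - \mathrm{tr}(\mathbf{A}
  (\mathbf{\Gamma P \Gamma})_{ij})]$, and the residual update replaces
  $\mathbf{A}$ by $\mathbf{I}$. For one trait this reduces to the familiar
  scalar updates. Convergence is declared when the log-likelihood change falls
  below `tol_loglik` (default $10^{-4}$) *and* the summed squared parameter
  change falls below `tol_param` (default $10^{-8}$).
* **Canonical EM** (`algorithm = "canonical"`). The current $(\mathbf{G}_t,
  \mathbf{R}_t)$ are recoded by the canonical transformation $\mathbf{Q}$ with
  $\mathbf{Q}\mathbf{R}_t\mathbf{Q}' = \mathbf{I}$ and
  $\mathbf{Q}\mathbf{G}_t\mathbf{Q}' = \mathbf{D}$ diagonal ($\mathbf{Q}$ from
  the Cholesky factor of $\mathbf{R}_t$ and the eigenvectors of the whitened
  genetic covariance, equivalently the left eigenvectors of
  $\mathbf{G}_t\mathbf{R}_t^{-1}$). Under the current guess the transformed
  model decouples: one univariate EM step per transformed trait updates the
  diagonal components, and -- because the projection is block-diagonal in this
  basis -- the cross moments of the per-trait projections supply the
  covariance updates at the same cost. The result is transformed back and
  $\mathbf{Q}$ recomputed. Convergence is declared when the largest absolute
  gradient component falls below `tol_grad` (default $10^{-4}$; we recommend
  $10^{-3}$ for simultaneous fits of many traits, where each iteration is more
  expensive).

A note on the canonical scheme: restricting the per-iteration update to the
*diagonal* (univariate) components only -- a literal reading of "one univariate
EM step per transformed trait" -- leaves the likelihood monotone but nearly
freezes the covariance components, because covariance information then enters
only through the slow rotation of $\mathbf{Q}$. The complete EM map in
canonical coordinates (diagonals via univariate steps, covariances via the
cross moments) has the same fixed points as the direct algorithm and is the
scheme implemented; the two algorithms agree component-wise to well below
$10^{-3}$ on synthetic fits, and both log-likelihood traces are
non-decreasing.

Both algorithms initialize at half the phenotypic (co)variances, so the
initial genetic correlations equal the phenotypic correlations -- a good
starting point given the near-proportionality of the two (see below).
Parameters are unconstrained during iteration; the univariate updates floor
non-positive variance updates at $10^{-8}$ times the phenotypic variance with
a warning, and a final positive-semidefiniteness check is reported
(`fit$psd_ok`), not enforced.

### Numerical strategy

All dense formulas above are implemented in a doubly transformed basis: the
GRM is eigendecomposed once per model ($\mathbf{A} = \mathbf{U}\Lambda
\mathbf{U}'$), and within each iteration the traits are recoded canonically.
In that basis $\mathbf{V}$ is diagonal and the REML problem separates into $t$
univariate weighted least-squares problems sharing the design, so one EM
iteration costs $O(m\,t\,s^2)$ after the single $O(m^3)$ eigendecomposition.
The implementation is validated in the test suite against a literal
dense-matrix evaluation of $L$, central-difference gradients and Hessians, and
a brute-force likelihood grid on small instances. Because the E-step is
expanded in the eigenbasis, $\mathbf{A}^{-1}$ is never formed and no ridge
regularization is required even for near-singular GRMs.

### Standard errors

Parameter errors come from the inverse of the information matrix at the fit,
ordered genetic block then residual block with pairs $(i, j)$, $i \le j$. The
default is the *observed* information -- the negative Hessian of the restricted
log-likelihood, $F_{ab} = \mathbf{y}'\mathbf{P}\mathbf{V}_a\mathbf{P}
\mathbf{V}_b\mathbf{P}\mathbf{y} - \tfrac12\mathrm{tr}(\mathbf{P}\mathbf{V}_a
\mathbf{P}\mathbf{V}_b)$ -- which matches a finite-difference Hessian to
numerical precision; the *expected* information
$\tfrac12\mathrm{tr}(\mathbf{P}\mathbf{V}_a\mathbf{P}\mathbf{V}_b)$ is
available via `fisher_information(..., type = "expected")` and agrees with the
observed form up to $O(m^{-1/2})$ fluctuations. Errors for derived quantities
-- $h^2$ and the genetic/residual correlations -- use first-order Taylor
(delta-method) propagation through the joint parameter covariance
$F^{-1}$; the tests confirm agreement with Monte-Carlo propagation at
moderate error levels (the delta method degrades, as expected, when a genetic
variance approaches zero).

## Cohort selection

Empirical relatedness drives two cohort definitions. The *related* cohort
keeps subjects with at least one partner at relatedness in $[0.35, 0.65]$
(sib pairs and parent-offspring); the pruning loop removes a uniformly random
currently-violating row until none remain, iterating to a fixed point under a
caller-supplied seed (the retained set can depend on the order when violations
overlap). The *unrelated* cohort requires every pairwise relatedness below
$0.025$ -- below the expected relatedness of second cousins -- and is selected
greedily by repeatedly removing the subject incident to the most offending
pairs (ties to the lower index), which is deterministic and retains a maximal
set in the common sparse-violation regime. Note the cutoff interacts with the
panel size: GRM off-diagonals among truly unrelated subjects have standard
deviation $\approx 1/\sqrt{n}$, so panels with fewer than roughly 3,000
markers push many null pairs over 0.025 and shrink the cohort; simulations
meant to retain most founders should use larger panels or a relaxed cutoff.

## Synthetic data

The generator (`sim_config()`, `simulate_genotypes()`,
`simulate_phenotypes()`) emulates the statistical structure the estimator
assumes: unlinked biallelic loci in HWE with minor allele frequencies uniform
on a configurable window inside $[0.05, 0.5]$ (loci whose empirical founder
frequency drifts outside the window are redrawn, so QC thresholds and the
simulation agree); an unrelated founder majority plus sib-pair families
produced by gene-dropping from two unobserved parents (empirical sib
relatedness centers at 0.5); per-locus effect vectors drawn multivariate
normal with covariance $\mathbf{G}_{\mathrm{true}}/n$ on the standardized
scale, making the total additive covariance -- and hence the REML recovery
target -- exactly $\mathbf{G}_{\mathrm{true}}$; residuals with covariance
$\mathbf{R}_{\mathrm{true}}$; and two generated covariates (standardized
age-like, Bernoulli(0.5) sex-like) times configurable coefficients. True
per-subject genetic values are retained for testing. What the generator does
*not* emulate: linkage disequilibrium, rare variants, selection or
ascertainment, non-additive effects, population stratification (available
separately in the PCA tests), and sex chromosomes. Passing tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to the full complexity of real GWAS data -- in particular, the
distinction between $h^2$ and $h_g^2$ in real data rests on LD patterns the
generator deliberately omits.

Default study conditions used by the heavier tests follow the recovery
design: univariate $h^2 \in \{0.3, 0.6\}$ and bivariate genetic correlations
$\{0, 0.5, 0.9\}$ at $m = 500$ unrelated founders and $n = 5{,}000$ markers
with 20 replicates (a scaled-down version, at identical per-replicate
conditions, of the 50-replicate $m = 1{,}000$ design; the problem sizes are
stated here as the package's test design). Because SE calibration compares a
per-fit standard error against a standard deviation across replicates -- whose
own sampling error at 20 replicates is ~16% -- the calibration check draws
three phenotype realizations per genotype replicate (60 estimates per
setting); the Fisher SE is conditional on the realized GRM, so phenotype
replication over a fixed GRM is the quantity it predicts.

## Post-hoc analyses

* `phenotypic_correlation()`: least-squares slope between standardized traits
  (identical to the Pearson coefficient) with the regression slope error.
* `fisher_significance()`: standardizes $r$ as $\mathrm{atanh}(r)/
  \mathrm{atanh}(\mathrm{se})$, two-tailed normal p-value, Bonferroni over
  $t(t-1)/2$ hypotheses. The variance-stabilizing transform is `atanh` (the
  Fisher z-transform); an `arctan` variant is exposed as a configuration
  switch but is less sensitive and does not reproduce the published
  significance patterns, so `atanh` is the default.
* `mc_proportionality()`: the proportionality constant between two sets of
  correlation estimates, by sampling both axes from
  $N(\text{estimate}, \text{SE})$ independently per draw, fitting least
  squares through the origin per draw, and averaging. Sampling *both* axes
  matters: noise on the abscissa attenuates the slope (by roughly
  $\sum x^2 / (\sum x^2 + \sum s_x^2)$), and the published constants are only
  reproduced with that attenuation. A free-intercept pre-test on the point
  estimates (skipped below three pairs) warns if the origin constraint is
  inappropriate; slope significance uses a t-distribution with
  $n_{\text{pairs}} - 1$ degrees of freedom.
* `haseman_elston()`: regression of squared pairwise phenotype differences on
  relatedness; $-\text{slope}/2$ estimates $h^2$ on the standardized scale.
  Pairs are not independent, so the naive regression SE is approximate; the
  tests use it only in 2-SE-level consistency checks against REML.
* `hg2_snp_scan()`: rebuilds the GRM, reselects the unrelated cohort, and
  refits the univariate model on growing SNP panels (in allele-frequency
  order or panel order). The SE of $\hat h_g^2$ *increases* with the number
  of markers -- the Haseman-Elston view explains this: the slope error is
  inversely proportional to the variance of the relatedness estimates, which
  shrinks as $1/n$.

## Published summary tables

`mets_tables()` ships the printed summary estimates (univariate $h^2$ and
$h_g^2$, and the 21 pairwise genetic, residual, and phenotypic correlations
with standard errors and significance flags for the related and unrelated
ARIC cohorts) for seven metabolic syndrome traits. The underlying cohort
genotype data are access-restricted, so the package reproduces the analyses
*of* these printed numbers -- the proportionality constants, the significance
patterns, and the $h_g^2\!/h^2$ ratio summaries -- rather than the cohort point
estimates themselves; `scripts/acceptance.R` recomputes the three
proportionality slopes from these tables end to end.

## Design choices and limitations

* The printed standardization denominator $(2p(1-2p))^{1/2}$ conflicts with
  the stated HWE variance $2p(1-p)$; the variance form is used (the other is
  negative for $p > 0.5$).
* The HWE test is the mid-p exact test (PLINK convention); the chi-square
  alternative differs only for sparse genotype classes.
* Missing genotypes: mean imputation only. Subject filtering precedes SNP
  statistics; allele frequencies are recomputed after subject removal, which
  makes a second QC pass a no-op in practice.
* One fixed-effect design shared by all traits (default: intercept after
  pre-adjustment). Pre-adjustment (residualize, then standardize) and
  in-model covariates are both supported; the canonical algorithm requires
  the shared design and complete cases, which `prepare_traits()` enforces.
* LD pruning for the stratification PCA uses a 50-SNP window, step 5,
  $r^2 < 0.2$ by default -- conventional values, configurable.
* Degenerate inputs: monomorphic loci are rejected at standardization with a
  pointer to QC; a non-positive-definite $\mathbf{V}$ aborts naming the
  offending canonical component; a singular information matrix falls back to
  a pseudo-inverse with a warning; an empty related window is a legal,
  reported outcome.
* The delta-method correlation SE is undefined when a genetic variance is
  non-positive; the estimate is reported missing rather than zero.
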