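#' Simulation configuration for synthetic GWAS data
#'
#' Bundles the parameters of the synthetic genotype/phenotype generator:
#' the number of unrelated founders, the number of sib-pair families, the
#' number of unlinked biallelic loci, the minor-allele-frequency range, and
#' the true genetic and residual covariance structure of the traits.
#'
#' Genotypes are drawn in Hardy-Weinberg equilibrium at a minor allele
#' frequency sampled uniformly from `maf_range`. Each family contributes two
#' full siblings obtained by gene-dropping from two unobserved founder
#' parents, so sib pairs have expected genomic relatedness 0.5 while all
#' other pairs are unrelated. Phenotypes follow an additive polygenic model:
#' per-locus effect vectors across traits are multivariate normal with
#' covariance `G_true / n_snps` on the standardized-genotype scale, so the
#' total additive genetic covariance equals `G_true`; residuals are
#' multivariate normal with covariance `R_true`.
#'
#' @param m_unrelated Number of unrelated founder subjects.
#' @param n_families Number of sib-pair families (each adds two siblings).
#' @param n_snps Number of unlinked biallelic loci.
#' @param maf_range Closed interval for the minor allele frequency, within
#'   `[0.05, 0.5]`.
#' @param t_traits Number of traits.
#' @param G_true `t x t` symmetric positive-semidefinite genetic covariance
#'   matrix (a scalar is promoted when `t_traits = 1`).
#' @param R_true `t x t` symmetric positive-definite residual covariance
#'   matrix.
#' @param fixed_effects `t x 2` matrix of per-trait coefficients for the two
#'   generated covariates (age-like standardized, sex-like 0/1); defaults to
#'   all-zero.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed; fully determines the generated data.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_genotypes()], [simulate_phenotypes()]
#' @export
sim_config <- function(m_unrelated,
                       n_families = 0,
                       n_snps,
                       maf_range = c(0.05, 0.5),
                       t_traits = 1,
                       G_true = diag(0.5, t_traits),
                       R_true = diag(0.5, t_traits),
                       fixed_effects = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be a non-empty closed interval c(low, high).")
  }
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12) {
    abort("`maf_range` must lie within [0.05, 0.5].")
  }
  G_true <- as_cov_matrix(G_true, t_traits, "G_true")
  R_true <- as_cov_matrix(R_true, t_traits, "R_true")
  check_psd(G_true, "G_true", strict = FALSE)
  check_psd(R_true, "R_true", strict = TRUE)
  if (any(diag(G_true) + diag(R_true) <= 0)) {
    abort("Each trait needs positive total variance G_true[i,i] + R_true[i,i].")
  }
  if (is.null(fixed_effects)) {
    fixed_effects <- matrix(0, t_traits, 2)
  }
  fixed_effects <- matrix(as.numeric(fixed_effects), t_traits, 2)
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  structure(
    list(
      m_unrelated = as.integer(m_unrelated),
      n_families = as.integer(n_families),
      n_snps = as.integer(n_snps),
      maf_range = as.numeric(maf_range),
      t_traits = as.integer(t_traits),
      G_true = G_true,
      R_true = R_true,
      fixed_effects = fixed_effects,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

as_cov_matrix <- function(x, t, name) {
  if (is.null(dim(x))) {
    if (length(x) == 1 && t == 1) x <- matrix(x, 1, 1)
    else abort(sprintf("`%s` must be a %d x %d matrix.", name, t, t))
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(t, t))) {
    abort(sprintf("`%s` must be %d x %d.", name, t, t))
  }
  if (max(abs(x - t(x))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  (x + t(x)) / 2
}

check_psd <- function(x, name, strict = FALSE) {
  ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(1, abs(ev[1]))
  if (strict && min(ev) <= tol) {
    abort(sprintf("`%s` must be positive definite.", name))
  }
  if (!strict && min(ev) < -tol) {
    abort(sprintf("`%s` must be positive semidefinite.", name))
  }
  invisible(TRUE)
}

#' Simulate biallelic genotypes with founders and sib-pair families
#'
#' Draws founder genotypes in Hardy-Weinberg equilibrium at per-locus minor
#' allele frequencies sampled uniformly from `config$maf_range`, then adds
#' sib-pair families by gene-dropping: for each family, two unobserved
#' parents are drawn as founders and each transmits one allele to each of
#' two offspring. Only the founders and the offspring appear in the output.
#' Loci whose empirical founder minor allele frequency falls outside
#' `maf_range` are redrawn (at a freshly sampled frequency) so the released
#' panel respects the configured frequency window. Missing calls are then
#' injected uniformly at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix`: a list with elements `dosage` (subjects x
#'   SNPs minor-allele counts in `{0, 1, 2}`, `NA` for missing),
#'   `subject_ids`, `snp_ids`, `map` (tibble with chrom/snp/pos/alleles),
#'   `p_true` (the drawn per-locus allele frequencies), and `families`
#'   (tibble pairing the sib ids, empty when `n_families = 0`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m_f <- config$m_unrelated
  n_fam <- config$n_families
  n <- config$n_snps
  m <- m_f + 2L * n_fam
  lo <- config$maf_range[1]
  hi <- config$maf_range[2]

  p <- runif(n, lo, hi)
  draw_founder <- function(p_i, n_subj) rbinom(n_subj, 2L, p_i)

  # founders: m_f x n
  founders <- matrix(rbinom(m_f * n, 2L, rep(p, each = m_f)), m_f, n)

  # redraw loci whose empirical founder MAF leaves the configured window
  if (m_f > 0) {
    for (attempt in seq_len(50)) {
      f_hat <- colMeans(founders) / 2
      maf_hat <- pmin(f_hat, 1 - f_hat)
      bad <- which(maf_hat < lo - 1e-12 | maf_hat > hi + 1e-12)
      if (length(bad) == 0) break
      p[bad] <- runif(length(bad), lo, hi)
      founders[, bad] <- matrix(
        rbinom(m_f * length(bad), 2L, rep(p[bad], each = m_f)),
        m_f, length(bad)
      )
    }
  }

  transmit <- function(parent_dosage) {
    # one allele per locus, Bernoulli(dosage / 2)
    rbinom(length(parent_dosage), 1L, parent_dosage / 2)
  }

  sibs <- NULL
  families <- tibble(family = integer(), sib1 = character(), sib2 = character())
  if (n_fam > 0) {
    sibs <- matrix(0L, 2L * n_fam, n)
    for (f in seq_len(n_fam)) {
      pa <- rbinom(n, 2L, p)
      ma <- rbinom(n, 2L, p)
      sibs[2L * f - 1L, ] <- transmit(pa) + transmit(ma)
      sibs[2L * f, ] <- transmit(pa) + transmit(ma)
    }
  }

  dosage <- rbind(founders, sibs)
  subject_ids <- c(
    if (m_f > 0) sprintf("U%04d", seq_len(m_f)) else character(),
    if (n_fam > 0) as.vector(t(outer(seq_len(n_fam), 1:2,
      function(f, s) sprintf("F%04d_%d", f, s)
    ))) else character()
  )
  if (n_fam > 0) {
    families <- tibble(
      family = seq_len(n_fam),
      sib1 = sprintf("F%04d_1", seq_len(n_fam)),
      sib2 = sprintf("F%04d_2", seq_len(n_fam))
    )
  }

  if (config$missing_rate > 0) {
    miss <- runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA_integer_
  }

  snp_ids <- sprintf("snp%06d", seq_len(n))
  dimnames(dosage) <- list(subject_ids, snp_ids)
  new_genotype_matrix(
    dosage = dosage,
    map = tibble(
      chrom = 1L, snp_id = snp_ids, cm = 0, pos = seq_len(n),
      a1 = "A", a2 = "B"
    ),
    p_true = p,
    families = families
  )
}

new_genotype_matrix <- function(dosage, map, p_true = NULL,
                                families = NULL) {
  structure(
    list(
      dosage = dosage,
      subject_ids = rownames(dosage),
      snp_ids = colnames(dosage),
      map = map,
      p_true = p_true,
      families = families
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d subjects x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Simulate correlated polygenic traits on top of simulated genotypes
#'
#' Generates `t_traits` phenotypes under the additive model
#' `y_i = X v_i + Z u_i + e_i`: per-locus effect vectors across traits are
#' drawn multivariate normal with covariance `G_true / n_snps` and applied
#' to the standardized genotypes, so the per-subject additive genetic values
#' have covariance `G_true`; residual vectors are multivariate normal with
#' covariance `R_true`. Two covariates are generated (a standardized
#' age-like variable and a 0/1 sex indicator) and multiplied by
#' `config$fixed_effects`. Missing genotypes enter the genetic values as the
#' standardized mean (zero). The true additive genetic values are retained
#' for testing.
#'
#' @param geno A `genotype_matrix` from [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @return A list of class `sim_phenotypes` with elements `phenotypes`
#'   (tibble: `FID`, `IID`, `age`, `sex`, then one column per trait),
#'   `genetic_values` (subjects x traits matrix of true additive values),
#'   and `config`.
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- nrow(geno$dosage)
  n <- ncol(geno$dosage)
  t <- config$t_traits
  check_psd(config$G_true, "G_true", strict = FALSE)
  check_psd(config$R_true, "R_true", strict = TRUE)

  p <- geno$p_true
  if (is.null(p)) p <- allele_freq(geno)
  Z <- scale_dosage(geno$dosage, p)

  # per-locus effects: rows iid N(0, G / n)
  sqrtG <- mat_sqrt(config$G_true / n)
  u <- matrix(rnorm(n * t), n, t) %*% sqrtG
  g <- Z %*% u

  sqrtR <- mat_sqrt(config$R_true)
  e <- matrix(rnorm(m * t), m, t) %*% sqrtR

  age <- rnorm(m)
  sex <- rbinom(m, 1L, 0.5)
  fixed <- cbind(age, sex) %*% t(config$fixed_effects)

  y <- fixed + g + e
  trait_names <- sprintf("trait%d", seq_len(t))
  colnames(y) <- trait_names
  colnames(g) <- trait_names
  rownames(g) <- geno$subject_ids

  phen <- tibble(
    FID = geno$subject_ids,
    IID = geno$subject_ids,
    age = age,
    sex = as.integer(sex)
  )
  phen <- dplyr::bind_cols(phen, as_tibble(y))

  structure(
    list(phenotypes = phen, genetic_values = g, config = config),
    class = "sim_phenotypes"
  )
}

# symmetric matrix square root via eigendecomposition; tolerates PSD input
mat_sqrt <- function(S) {
  if (nrow(S) == 1) {
    return(matrix(sqrt(max(S[1, 1], 0)), 1, 1))
  }
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values), 1)) {
    abort("Covariance matrix is not positive semidefinite.")
  }
  es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
}

# standardize dosages at given allele frequencies; missing -> 0
scale_dosage <- function(dosage, p) {
  denom <- sqrt(2 * p * (1 - p))
  Z <- sweep(dosage, 2, 2 * p, "-")
  Z <- sweep(Z, 2, denom, "/")
  Z[is.na(Z)] <- 0
  Z
}

#' Write simulated truth alongside the data files
#'
#' Serializes the true variance components and per-subject additive genetic
#' values of a simulated dataset as tab-delimited text, for use as an oracle
#' by downstream tests.
#'
#' @param sim A `sim_phenotypes` object.
#' @param prefix Output path prefix; writes `<prefix>.truth_cov.tsv` and
#'   `<prefix>.truth_genetic_values.tsv`.
#' @return The two file paths, invisibly.
#' @export
write_truth <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_phenotypes"))
  t <- sim$config$t_traits
  trait <- sprintf("trait%d", seq_len(t))
  covs <- tidyr::expand_grid(i = trait, j = trait) |>
    dplyr::mutate(
      cov_g = as.vector(t(sim$config$G_true)),
      cov_e = as.vector(t(sim$config$R_true))
    )
  f1 <- paste0(prefix, ".truth_cov.tsv")
  f2 <- paste0(prefix, ".truth_genetic_values.tsv")
  utils::write.table(covs, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  gv <- data.frame(IID = rownames(sim$genetic_values), sim$genetic_values,
    check.names = FALSE
  )
  utils::write.table(gv, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
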