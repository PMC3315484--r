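test_that("founder genotypes follow HWE at the configured frequency", {
  cfg <- sim_config(
    m_unrelated = 400, n_snps = 50, maf_range = c(0.5, 0.5),
    seed = 3
  )
  geno <- simulate_genotypes(cfg)
  expect_true(all(geno$dosage %in% c(0L, 1L, 2L)))
  # HWE mean dosage is 2p = 1 at p = 0.5
  expect_equal(mean(colMeans(geno$dosage)), 1, tolerance = 0.02)
  expect_equal(
    mean(apply(geno$dosage, 2, var)), 0.5,
    tolerance = 0.05
  )
})

test_that("released founder allele frequencies respect the MAF window", {
  cfg <- sim_config(
    m_unrelated = 120, n_snps = 800, maf_range = c(0.2, 0.4),
    seed = 5
  )
  geno <- simulate_genotypes(cfg)
  f <- colMeans(geno$dosage[seq_len(120), ]) / 2
  maf <- pmin(f, 1 - f)
  expect_true(all(maf >= 0.2 - 1e-12 & maf <= 0.4 + 1e-12))
})

test_that("GRM off-diagonals among founders have the closed-form noise scale", {
  # for unlinked standardized loci, the mean product over n loci has
  # mean 0 and standard deviation ~ 1/sqrt(n)
  cfg <- sim_config(m_unrelated = 200, n_snps = 10000, seed = 8)
  geno <- simulate_genotypes(cfg)
  grm <- compute_grm(geno)
  off <- grm$matrix[upper.tri(grm$matrix)]
  expect_lt(abs(mean(off)), 0.006)
  expect_equal(sd(off), 1 / sqrt(10000), tolerance = 0.1)
})

test_that("sib pairs share parents: empirical relatedness centers at 0.5", {
  cfg <- sim_config(m_unrelated = 50, n_families = 220, n_snps = 5000, seed = 12)
  geno <- simulate_genotypes(cfg)
  grm <- compute_grm(geno)
  fam <- geno$families
  vals <- grm$matrix[cbind(
    match(fam$sib1, grm$subject_ids),
    match(fam$sib2, grm$subject_ids)
  )]
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("phenotype generation matches the configured covariance structure", {
  # no genetic component: trait covariance reduces to R_true
  R <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  cfg <- sim_config(
    m_unrelated = 1500, n_snps = 300, t_traits = 2,
    G_true = matrix(0, 2, 2), R_true = R, seed = 21
  )
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  S <- cov(as.matrix(sim$phenotypes[, c("trait1", "trait2")]))
  expect_equal(unname(S), R, tolerance = 0.12)

  # retained genetic values realize the target genetic correlation
  G <- matrix(c(1, 0.7, 0.7, 1), 2)
  cfg2 <- sim_config(
    m_unrelated = 800, n_snps = 2000, t_traits = 2,
    G_true = G, R_true = diag(0.5, 2), seed = 22
  )
  geno2 <- simulate_genotypes(cfg2)
  sim2 <- simulate_phenotypes(geno2, cfg2)
  expect_equal(cor(sim2$genetic_values)[1, 2], 0.7, tolerance = 0.05)
})

test_that("trait variance decomposes into genetic, residual, and fixed parts", {
  fe <- matrix(c(0.5, 0.4), 1, 2) # age-like and sex effects for one trait
  cfg <- sim_config(
    m_unrelated = 2000, n_snps = 500, t_traits = 1,
    G_true = matrix(0.4), R_true = matrix(0.6),
    fixed_effects = fe, seed = 30
  )
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  expected <- 0.4 + 0.6 + 0.5^2 + 0.4^2 * 0.25 # var(sex) = 1/4
  mc_se <- expected * sqrt(2 / 2000)
  expect_lt(abs(var(sim$phenotypes$trait1) - expected), 3 * mc_se)
})

test_that("identical seeds give bit-identical data", {
  cfg <- sim_config(
    m_unrelated = 40, n_families = 10, n_snps = 200,
    t_traits = 2, G_true = diag(0.5, 2), R_true = diag(0.5, 2),
    missing_rate = 0.05, seed = 77
  )
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  s1 <- simulate_phenotypes(g1, cfg)
  s2 <- simulate_phenotypes(g2, cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$genetic_values, s2$genetic_values)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, n_snps = 5, maf_range = c(0.4, 0.2)), "interval")
  expect_error(sim_config(10, n_snps = 5, maf_range = c(0.01, 0.5)), "0.05")
  expect_error(
    sim_config(10,
      n_snps = 5, t_traits = 2,
      G_true = matrix(c(1, 2, 2, 1), 2), R_true = diag(2)
    ),
    "semidefinite"
  )
  expect_error(
    sim_config(10,
      n_snps = 5, t_traits = 2,
      G_true = diag(2), R_true = matrix(0, 2, 2)
    ),
    "positive definite"
  )
})

test_that("truth files round-trip the simulated components", {
  cfg <- sim_config(
    m_unrelated = 30, n_snps = 100, t_traits = 2,
    G_true = matrix(c(0.5, 0.2, 0.2, 0.5), 2), R_true = diag(0.5, 2),
    seed = 14
  )
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  prefix <- file.path(tempdir(), "simtruth")
  write_truth(sim, prefix)
  covs <- read.delim(paste0(prefix, ".truth_cov.tsv"))
  expect_equal(covs$cov_g[covs$i == "trait1" & covs$j == "trait2"], 0.2)
  gv <- read.delim(paste0(prefix, ".truth_genetic_values.tsv"))
  expect_equal(nrow(gv), 30)
})
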