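test_that("phenotypic correlation equals the product-moment coefficient", {
  set.seed(1)
  ph <- tibble::tibble(
    IID = sprintf("s%d", 1:400),
    a = rnorm(400)
  )
  ph$b <- 0.6 * ph$a + rnorm(400)
  out <- phenotypic_correlation(ph, "a", "b")
  expect_equal(out$estimate, cor(ph$a, ph$b), tolerance = 1e-12)

  # y identical to x: r = 1 exactly
  ph$c <- ph$a
  expect_equal(
    suppressWarnings(phenotypic_correlation(ph, "a", "c")$estimate),
    1,
    tolerance = 1e-12
  )

  # independent traits at large m stay within the noise band
  set.seed(2)
  ph2 <- tibble::tibble(IID = sprintf("s%d", 1:5000), a = rnorm(5000), b = rnorm(5000))
  out2 <- phenotypic_correlation(ph2, "a", "b")
  expect_lt(abs(out2$estimate), 3 * out2$se)

  expect_error(
    phenotypic_correlation(tibble::tibble(a = rep(1, 5), b = rnorm(5)), "a", "b"),
    "Zero-variance"
  )
})

test_that("Fisher-transform significance reproduces printed decisions", {
  n_tests <- 21
  # strongly correlated pair with moderate error: significant
  expect_true(fisher_significance(0.91, 0.18, n_tests)$significant)
  # same size of estimate but bigger error: not significant
  expect_false(fisher_significance(0.57, 0.24, n_tests)$significant)
  # negative estimate with small error: significant
  expect_true(fisher_significance(-0.57, 0.19, n_tests)$significant)
  # zero correlation: p = 1 regardless of the error
  out <- fisher_significance(0, 0.3, n_tests)
  expect_equal(out$p, 1)
  expect_false(out$significant)

  # the arctan variant is less sensitive and flips the borderline case
  expect_false(
    fisher_significance(-0.57, 0.19, n_tests, transform = "arctan")$significant
  )

  expect_error(fisher_significance(1, 0.1), "r")
  expect_error(fisher_significance(0.5, 1.2), "errors")
})

test_that("significance recovers every flag of the published tables", {
  tb <- mets_tables()
  for (nm in c(
    "genetic_related", "residual_related",
    "genetic_unrelated", "residual_unrelated",
    "phenotypic_related", "phenotypic_unrelated"
  )) {
    fs <- fisher_significance(tb[[nm]]$r, tb[[nm]]$se, n_tests = 21)
    expect_identical(fs$significant, tb[[nm]]$significant)
  }
})

test_that("Monte-Carlo proportionality collapses correctly without noise", {
  x <- c(0.2, 0.5, 0.8)
  y <- c(0.4, 1.0, 1.6)
  fit <- suppressWarnings(mc_proportionality(x, y, 0, 0, n_draws = 500, seed = 1))
  expect_equal(fit$slope_mean, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_equal(fit$slope_sd, 0)
  expect_equal(fit$slope_mean, 2)

  single <- mc_proportionality(1, 2, 0, 0, n_draws = 10, seed = 1)
  expect_equal(single$slope_mean, 2)
})

test_that("proportionality slopes are seed-reproducible and attenuated by x-noise", {
  tb <- mets_tables()
  x <- tb$genetic_related$r
  y <- tb$genetic_unrelated$r
  sx <- tb$genetic_related$se
  sy <- tb$genetic_unrelated$se
  f1 <- mc_proportionality(x, y, sx, sy, n_draws = 2000, seed = 42)
  f2 <- mc_proportionality(x, y, sx, sy, n_draws = 2000, seed = 42)
  expect_identical(f1$draws, f2$draws)
  # sampling noise on the abscissa shrinks the slope towards zero
  expect_lt(f1$slope_mean, f1$slope_point)
})

test_that("Haseman-Elston regression recovers construction-level heritability", {
  # phenotype equal to the true genetic values (plus negligible noise)
  ds <- sim_dataset(60, 120, 3000,
    G = matrix(1), R = matrix(0.01), seed = 35
  )
  y <- setNames(
    ds$sim$genetic_values[, 1] + rnorm(nrow(ds$Y), 0, 0.1),
    rownames(ds$Y)
  )
  he <- haseman_elston(y, ds$grm)
  expect_lt(abs(he$h2 - 1), 2 * he$se + 0.1)

  # permuted phenotypes carry no signal
  set.seed(3)
  he0 <- haseman_elston(sample(unname(y)), ds$grm)
  expect_lt(abs(he0$h2), 2 * he0$se)

  expect_error(
    haseman_elston(c(s01 = 1, s02 = 2), as_grm(diag(2))),
    "3 subject pairs"
  )
})

test_that("Haseman-Elston and REML agree on shared synthetic data", {
  ds <- sim_dataset(150, 60, 800, G = matrix(0.5), R = matrix(0.5), seed = 9)
  y <- setNames(ds$Y[, 1], rownames(ds$Y))
  he <- haseman_elston(y, ds$grm)
  fit <- reml_fit(reml_model(ds$Y, grm = ds$grm), "direct", max_iter = 20000)
  h <- heritability(fit)
  expect_lt(abs(he$h2 - h$h2), 2 * sqrt(he$se^2 + h$se^2))
})

test_that("the SNP-count scan reproduces the full fit at the largest grid point", {
  ds <- sim_dataset(250, 0, 4000, G = matrix(0.5), R = matrix(0.5), seed = 40)
  prepared <- prepare_traits(ds$sim$phenotypes, "trait1")
  th <- selection_thresholds(unrelated_max = 0.12)
  scan <- hg2_snp_scan(
    ds$geno, prepared, "trait1",
    grid = c(1000, 2000, 4000), order = "all",
    thresholds = th, max_iter = 10000
  )
  expect_equal(nrow(scan), 3)
  # largest prefix in panel order is the full panel
  grm_full <- compute_grm(ds$geno)
  unrel <- select_unrelated(grm_full, th)
  ph <- subset_prepared(prepared, unrel)
  fit_full <- reml_fit(
    reml_model(ph, "trait1", grm = subset_grm(grm_full, unrel)),
    max_iter = 10000
  )
  h_full <- heritability(fit_full)
  expect_equal(scan$h2[scan$n_snps == 4000], h_full$h2, tolerance = 1e-8)
  # the error grows with the number of markers (relatedness variance falls)
  expect_gt(scan$se[scan$n_snps == 4000], scan$se[scan$n_snps == 1000])

  expect_error(
    hg2_snp_scan(ds$geno, prepared, "trait1", grid = 5000),
    "exceeds"
  )
})
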