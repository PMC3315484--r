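test_that("restricted log-likelihood matches the identity-GRM closed form", {
  set.seed(1)
  y <- matrix(rnorm(6), ncol = 1, dimnames = list(NULL, "y"))
  model <- reml_model(y, grm = diag(6))
  sg <- 0.5
  se <- 0.8
  v <- sg + se
  S <- sum((y - mean(y))^2)
  closed <- -0.5 * (6 * log(v) + log(6 / v) + S / v)
  expect_equal(
    restricted_loglik(model, variance_components(sg, se))$loglik,
    closed,
    tolerance = 1e-10
  )
})

test_that("the restricted likelihood is invariant to fixed-effect translations", {
  set.seed(2)
  y <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "y"))
  A <- toy_sib_grm(5, 10)
  comps <- variance_components(0.4, 0.6)
  l1 <- restricted_loglik(reml_model(y, grm = A), comps)$loglik
  l2 <- restricted_loglik(reml_model(y + 7.3, grm = A), comps)$loglik
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("likelihood and gradient agree with a dense-matrix oracle", {
  set.seed(7)
  m <- 12
  A <- crossprod(matrix(rnorm(m * m), m)) / m
  A <- A / mean(diag(A))
  X <- cbind(1, rnorm(m))
  Y <- matrix(rnorm(m * 2), m, 2, dimnames = list(NULL, c("a", "b")))
  G <- matrix(c(0.5, 0.2, 0.2, 0.8), 2)
  R <- matrix(c(0.7, -0.1, -0.1, 0.6), 2)
  model <- reml_model(Y, grm = A, design = X)
  comps <- variance_components(G, R)

  rl <- restricted_loglik(model, comps)
  expect_equal(rl$loglik, dense_reml_loglik(A, X, Y, G, R), tolerance = 1e-8)

  # analytic gradient vs central differences of the likelihood
  gr <- reml_gradient(model, comps, rl$proj)
  px <- snpherit:::param_index(2)
  h <- 1e-5
  for (a in seq_len(nrow(px))) {
    pert <- function(s) {
      G2 <- G
      R2 <- R
      M <- if (px$block[a] == "g") G2 else R2
      M[px$i[a], px$j[a]] <- M[px$i[a], px$j[a]] + s * h
      M[px$j[a], px$i[a]] <- M[px$i[a], px$j[a]]
      if (px$block[a] == "g") {
        restricted_loglik(model, variance_components(M, R2))$loglik
      } else {
        restricted_loglik(model, variance_components(G2, M))$loglik
      }
    }
    fd <- (pert(1) - pert(-1)) / (2 * h)
    expect_equal(gr[[a]], fd, tolerance = 1e-4)
  }
})

test_that("EM fixed point coincides with the brute-force likelihood grid maximum", {
  A <- toy_sib_grm(4)
  set.seed(7)
  L <- chol(0.6 * A + 0.4 * diag(8))
  y <- matrix(drop(crossprod(L, rnorm(8))), ncol = 1, dimnames = list(NULL, "y"))
  model <- reml_model(y, grm = A)

  grid <- seq(0.02, 3, length.out = 100)
  ll <- outer(grid, grid, Vectorize(function(sg, se) {
    restricted_loglik(model, variance_components(sg, se))$loglik
  }))
  idx <- which(ll == max(ll), arr.ind = TRUE)
  grid_opt <- c(grid[idx[1]], grid[idx[2]])

  fit <- reml_fit(model, "direct",
    tol_loglik = 1e-12, tol_param = 1e-16,
    max_iter = 100000
  )
  resolution <- diff(grid)[1]
  expect_lt(abs(fit$components$G[1, 1] - grid_opt[1]), resolution)
  expect_lt(abs(fit$components$R[1, 1] - grid_opt[2]), resolution)

  # at the optimum the gradient vanishes and the EM update is a fixed point
  expect_lt(max(abs(reml_gradient(model, fit$components))), 1e-6)
  upd <- em_step_univariate(model, fit$components)
  expect_lt(abs(upd$G - fit$components$G), 1e-6)
  expect_lt(abs(upd$R - fit$components$R), 1e-6)
})

test_that("EM never decreases the restricted likelihood", {
  ds <- sim_dataset(80, 30, 600,
    t_traits = 2,
    G = matrix(c(0.5, 0.25, 0.25, 0.5), 2),
    R = matrix(c(0.5, 0.1, 0.1, 0.5), 2), seed = 5
  )
  model <- reml_model(ds$Y, grm = ds$grm)
  for (alg in c("direct", "canonical")) {
    fit <- reml_fit(model, alg, max_iter = 3000)
    expect_true(fit$converged)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("the multivariate EM step reduces exactly to the univariate step", {
  ds <- sim_dataset(60, 20, 300, seed = 16)
  model <- reml_model(ds$Y, grm = ds$grm)
  comps <- variance_components(0.45, 0.55)
  for (k in 1:5) {
    u1 <- em_step_univariate(model, comps)
    u2 <- em_step_multivariate(model, comps)
    expect_equal(u1$G[1, 1], u2$G[1, 1], tolerance = 1e-10)
    expect_equal(u1$R[1, 1], u2$R[1, 1], tolerance = 1e-10)
    comps <- u1
  }
})

test_that("independent traits keep near-zero covariance estimates", {
  ds <- sim_dataset(150, 60, 1200,
    t_traits = 2,
    G = diag(0.5, 2), R = diag(0.5, 2), seed = 18
  )
  fit <- reml_fit(reml_model(ds$Y, grm = ds$grm), "direct", max_iter = 5000)
  covg <- fit$components$G[1, 2]
  se_covg <- fit$se[["cov_g(trait1,trait2)"]]
  expect_lt(abs(covg), 3 * se_covg)
})

test_that("canonical transform whitens R and diagonalizes G", {
  # scalar case: Q = 1/sqrt(R), D = G/R
  ct <- canonical_transform(variance_components(0.3, 0.6))
  expect_equal(ct$Q[1, 1], 1 / sqrt(0.6), tolerance = 1e-12)
  expect_equal(ct$D, 0.3 / 0.6, tolerance = 1e-12)

  set.seed(20)
  for (i in 1:100) {
    t <- 5
    B <- matrix(rnorm(t * t), t)
    G <- crossprod(B) * 0.5
    Rm <- crossprod(matrix(rnorm(t * t), t)) + diag(t) * 0.1
    ct <- canonical_transform(variance_components(G, Rm))
    expect_lt(max(abs(ct$Q %*% Rm %*% t(ct$Q) - diag(t))), 1e-8)
    QGQ <- ct$Q %*% G %*% t(ct$Q)
    expect_lt(max(abs(QGQ - diag(diag(QGQ)))), 1e-8)
    expect_equal(ct$Qinv %*% diag(ct$D) %*% t(ct$Qinv), G, tolerance = 1e-8)
  }
  expect_error(
    canonical_transform(variance_components(diag(2), matrix(0, 2, 2))),
    "positive definite"
  )
})

test_that("direct and canonical EM agree component-wise", {
  ds <- sim_dataset(200, 50, 1000,
    t_traits = 2,
    G = matrix(c(0.4, 0.25, 0.25, 0.5), 2),
    R = matrix(c(0.6, 0.1, 0.1, 0.5), 2), seed = 11
  )
  model <- reml_model(ds$Y, grm = ds$grm)
  fd <- reml_fit(model, "direct",
    tol_loglik = 1e-9, tol_param = 1e-13, max_iter = 50000
  )
  fc <- reml_fit(model, "canonical", tol_grad = 1e-6, max_iter = 50000)
  expect_true(fd$converged && fc$converged)
  expect_lt(
    max(
      abs(fd$components$G - fc$components$G),
      abs(fd$components$R - fc$components$R)
    ),
    1e-3
  )
})

test_that("a null genetic model estimates heritability near zero", {
  ds <- sim_dataset(120, 60, 2000,
    G = matrix(1e-12), R = matrix(1), seed = 24
  )
  fit <- suppressWarnings(
    reml_fit(reml_model(ds$Y, grm = ds$grm), "direct", max_iter = 5000)
  )
  h <- heritability(fit)
  expect_lt(h$h2, 2 * max(h$se, 0.05))
})

test_that("observed Fisher information matches the finite-difference Hessian", {
  ds <- sim_dataset(80, 30, 600,
    t_traits = 2,
    G = matrix(c(0.5, 0.25, 0.25, 0.5), 2),
    R = matrix(c(0.5, 0.1, 0.1, 0.5), 2), seed = 5
  )
  model <- reml_model(ds$Y, grm = ds$grm)
  fit <- reml_fit(model, "direct",
    tol_loglik = 1e-9, tol_param = 1e-13,
    max_iter = 50000
  )
  comps <- fit$components
  px <- snpherit:::param_index(2)
  np <- nrow(px)
  h <- 2e-4
  bump <- function(G2, R2, k, s) {
    if (px$block[k] == "g") {
      G2[px$i[k], px$j[k]] <- G2[px$i[k], px$j[k]] + s * h
      G2[px$j[k], px$i[k]] <- G2[px$i[k], px$j[k]]
    } else {
      R2[px$i[k], px$j[k]] <- R2[px$i[k], px$j[k]] + s * h
      R2[px$j[k], px$i[k]] <- R2[px$i[k], px$j[k]]
    }
    list(G2, R2)
  }
  ll_at <- function(a, sa, b, sb) {
    x <- bump(comps$G, comps$R, a, sa)
    x <- bump(x[[1]], x[[2]], b, sb)
    restricted_loglik(model, variance_components(x[[1]], x[[2]]))$loglik
  }
  H <- matrix(0, np, np)
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      H[a, b] <- (ll_at(a, 1, b, 1) - ll_at(a, 1, b, -1) -
        ll_at(a, -1, b, 1) + ll_at(a, -1, b, -1)) / (4 * h^2)
    }
  }
  fo <- fisher_information(model, comps, type = "observed")
  expect_lt(max(abs(H + fo$F) / (abs(fo$F) + 1e-6)), 1e-3)
  expect_equal(fo$F, t(fo$F))
  expect_gt(min(eigen(fo$F, symmetric = TRUE, only.values = TRUE)$values), 0)

  # expected information is symmetric PSD and close to the observed one
  fe <- fisher_information(model, comps, type = "expected")
  expect_equal(fe$F, t(fe$F))
  expect_gt(min(eigen(fe$F, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_lt(max(abs(fo$F - fe$F) / (abs(fe$F) + 1e-6)), 0.3)
})

test_that("identity-GRM information recovers the i.i.d. variance closed form", {
  set.seed(26)
  m <- 40
  y <- matrix(rnorm(m), ncol = 1, dimnames = list(NULL, "y"))
  model <- reml_model(y, grm = diag(m))
  fit <- suppressWarnings(
    reml_fit(model, "direct",
      tol_loglik = 1e-12, tol_param = 1e-16,
      max_iter = 5000
    )
  )
  v_hat <- fit$components$G[1, 1] + fit$components$R[1, 1]
  expect_equal(v_hat, sum((y - mean(y))^2) / (m - 1), tolerance = 1e-6)
  # with A = I only the sum is identified: every F entry equals the
  # information of the variance of i.i.d. normals, (m - 1) / (2 v^2)
  fo <- suppressWarnings(fisher_information(model, fit$components))
  expect_equal(
    unname(fo$F),
    matrix((m - 1) / (2 * v_hat^2), 2, 2),
    tolerance = 1e-4
  )
})

test_that("delta-method errors agree with Monte-Carlo propagation", {
  ds <- sim_dataset(200, 80, 1500,
    t_traits = 2,
    G = matrix(c(0.5, 0.3, 0.3, 0.5), 2),
    R = matrix(c(0.5, 0.1, 0.1, 0.5), 2), seed = 28
  )
  fit <- reml_fit(reml_model(ds$Y, grm = ds$grm), "direct",
    tol_loglik = 1e-8, tol_param = 1e-12, max_iter = 20000
  )
  est <- fit$estimates
  Sig <- fit$vcov
  set.seed(1)
  draws <- MASS::mvrnorm(1e5, est, Sig)
  h2_draws <- draws[, 1] / (draws[, 1] + draws[, 4])
  h2 <- heritability(fit, "trait1")
  expect_lt(abs(sd(h2_draws) - h2$se), 0.05 * h2$se + 0.01)

  rg_draws <- draws[, 2] / sqrt(pmax(draws[, 1] * draws[, 3], 1e-12))
  rg_draws <- rg_draws[draws[, 1] > 0.05 & draws[, 3] > 0.05]
  rg <- genetic_correlation(fit, "trait1", "trait2")
  expect_lt(abs(sd(rg_draws) - rg$se), 0.10 * rg$se + 0.02)
})

test_that("heritability and correlation formulas give the defined ratios", {
  fake <- structure(
    list(
      components = variance_components(
        matrix(c(0.24, 0.1, 0.1, 0.5), 2),
        matrix(c(0.76, 0.05, 0.05, 0.5), 2)
      ),
      vcov = matrix(0, 6, 6, dimnames = list(
        snpherit:::param_names(2, c("a", "b")),
        snpherit:::param_names(2, c("a", "b"))
      )),
      estimates = setNames(numeric(6), snpherit:::param_names(2, c("a", "b"))),
      se = setNames(numeric(6), snpherit:::param_names(2, c("a", "b"))),
      traits = c("a", "b")
    ),
    class = "reml_fit"
  )
  h <- heritability(fake, "a")
  expect_equal(h$h2, 0.24)
  expect_equal(h$se, 0) # zero parameter variance propagates to zero
  rg <- genetic_correlation(fake, "a", "b")
  expect_equal(rg$estimate, 0.1 / sqrt(0.24 * 0.5))
  expect_equal(rg$se, 0)

  # boundary: cov_g at the geometric mean gives r_g = 1
  fake$components <- variance_components(
    matrix(c(0.4, sqrt(0.4 * 0.9), sqrt(0.4 * 0.9), 0.9), 2),
    diag(0.5, 2)
  )
  expect_equal(genetic_correlation(fake, "a", "b")$estimate, 1)

  # a non-positive genetic variance leaves the correlation undefined
  fake$components <- variance_components(
    matrix(c(0, 0.1, 0.1, 0.5), 2), diag(0.5, 2)
  )
  expect_warning(out <- genetic_correlation(fake, "a", "b"), "undefined")
  expect_true(is.na(out$estimate))
})

test_that("permuting phenotypes destroys the heritability signal", {
  ds <- sim_dataset(100, 60, 2000, G = matrix(0.6), R = matrix(0.4), seed = 31)
  Yp <- ds$Y
  set.seed(99)
  Yp[, 1] <- sample(Yp[, 1])
  fit <- suppressWarnings(
    reml_fit(reml_model(Yp, grm = ds$grm), "direct", max_iter = 5000)
  )
  h <- heritability(fit)
  expect_lt(h$h2, 2 * max(h$se, 0.05))
})

test_that("tidy, glance, and autoplot summarize a fit", {
  ds <- sim_dataset(60, 20, 300, seed = 16)
  fit <- reml_fit(reml_model(ds$Y, grm = ds$grm), "direct", max_iter = 2000)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_subjects, 100)
  expect_s3_class(autoplot(fit), "ggplot")
})
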