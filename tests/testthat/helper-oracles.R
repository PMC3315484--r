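# Independent oracles used across test files. These deliberately use naive
# dense linear algebra or direct enumeration, not the package's internals.

# dense-matrix restricted log-likelihood of the multi-trait mixed model
dense_reml_loglik <- function(A, X, Y, G, R) {
  m <- nrow(Y)
  t <- ncol(Y)
  if (is.null(dim(G))) G <- matrix(G, 1, 1)
  if (is.null(dim(R))) R <- matrix(R, 1, 1)
  V <- kronecker(G, A) + kronecker(R, diag(m))
  Xf <- kronecker(diag(t), X)
  Vi <- solve(V)
  C0 <- t(Xf) %*% Vi %*% Xf
  P <- Vi - Vi %*% Xf %*% solve(C0, t(Xf) %*% Vi)
  yv <- as.vector(Y)
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(C0)$modulus +
      t(yv) %*% P %*% yv)
  )
}

# Hardy-Weinberg exact p-value by direct enumeration of the conditional
# distribution of the heterozygote count (probabilities from the explicit
# combinatorial formula, not a recurrence)
hwe_oracle <- function(het, hom1, hom2, midp = TRUE) {
  n <- het + hom1 + hom2
  rare <- 2 * min(hom1, hom2) + het
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), 2)
  pr <- exp(sapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2)
  }))
  pr <- pr / sum(pr)
  p0 <- pr[hets == het]
  p <- sum(pr[pr <= p0 * (1 + 1e-9)])
  if (midp) p <- p - 0.5 * p0
  min(1, p)
}

# sib-pair block relationship matrix: n_pairs pairs at relatedness r plus
# n_single unrelated singletons
toy_sib_grm <- function(n_pairs, n_single = 0, r = 0.5) {
  m <- 2 * n_pairs + n_single
  A <- diag(m)
  for (k in seq_len(n_pairs)) {
    A[2 * k - 1, 2 * k] <- A[2 * k, 2 * k - 1] <- r
  }
  ids <- sprintf("s%02d", seq_len(m))
  dimnames(A) <- list(ids, ids)
  A
}

# wrap a plain relationship matrix as a grm object
as_grm <- function(A, n_snps = 1000L) {
  ids <- rownames(A)
  if (is.null(ids)) {
    ids <- sprintf("s%02d", seq_len(nrow(A)))
    dimnames(A) <- list(ids, ids)
  }
  snpherit:::new_grm(A, ids, n_snps)
}

# simulate a small genotype + phenotype set and return model-ready pieces
sim_dataset <- function(m_unrelated, n_families, n_snps, t_traits = 1,
                        G = matrix(0.5), R = matrix(0.5), seed = 1,
                        fixed_effects = NULL, missing_rate = 0) {
  cfg <- sim_config(
    m_unrelated = m_unrelated, n_families = n_families, n_snps = n_snps,
    t_traits = t_traits, G_true = G, R_true = R, seed = seed,
    fixed_effects = fixed_effects, missing_rate = missing_rate
  )
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  grm <- compute_grm(geno)
  traits <- sprintf("trait%d", seq_len(t_traits))
  Y <- as.matrix(sim$phenotypes[, traits, drop = FALSE])
  rownames(Y) <- sim$phenotypes$IID
  list(cfg = cfg, geno = geno, sim = sim, grm = grm, Y = Y, traits = traits)
}
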