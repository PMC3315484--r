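#' Phenotypic correlation by regression of standardized traits
#'
#' The correlation is estimated as the least-squares slope of the
#' standardized `trait_y` on the standardized `trait_x` (identical to the
#' Pearson product-moment correlation), and its standard error is the
#' regression slope standard error.
#'
#' @param prepared A prepared phenotype tibble (see [prepare_traits()]).
#' @param trait_x,trait_y Trait column names.
#' @return One-row tibble with `trait_x`, `trait_y`, `kind`, `estimate`,
#'   `se`.
#' @export
phenotypic_correlation <- function(prepared, trait_x, trait_y) {
  x <- prepared[[trait_x]]
  y <- prepared[[trait_y]]
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance trait.")
  x <- (x - mean(x)) / sd(x)
  y <- (y - mean(y)) / sd(y)
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  tibble(
    trait_x = trait_x, trait_y = trait_y, kind = "phenotypic",
    estimate = sm["x", "Estimate"], se = sm["x", "Std. Error"]
  )
}

#' Significance of correlation estimates via the Fisher transform
#'
#' Standardizes each correlation as `z = atanh(r) / atanh(se)` and computes
#' a two-tailed p-value from the standard normal, declaring significance at
#' a Bonferroni-corrected level `alpha / n_tests`. The variance-stabilizing
#' transform defaults to `atanh` (the Fisher z-transform); `"arctan"` is
#' available as a configuration switch.
#'
#' @param r Correlation estimates (vectorized), `|r| < 1`.
#' @param se Their standard errors, in `(0, 1)`.
#' @param n_tests Number of hypotheses for the Bonferroni correction; for
#'   all pairs of `t` traits this is `t (t - 1) / 2`.
#' @param alpha Family-wise significance level.
#' @param transform `"atanh"` or `"arctan"`.
#' @return Tibble with `r`, `se`, `z`, `p`, `significant`.
#' @export
fisher_significance <- function(r, se, n_tests = 1, alpha = 0.05,
                                transform = c("atanh", "arctan")) {
  transform <- match.arg(transform)
  if (any(abs(r) >= 1)) abort("Need |r| < 1.")
  if (any(se <= 0 | se >= 1)) abort("Need standard errors in (0, 1).")
  f <- if (transform == "atanh") atanh else atan
  z <- f(r) / f(se)
  p <- 2 * pnorm(-abs(z))
  tibble(r = r, se = se, z = z, p = p, significant = p < alpha / n_tests)
}

#' Monte-Carlo proportionality fit through the origin
#'
#' Estimates the proportionality constant between two sets of correlation
#' estimates by sampling both axes from normal distributions centered at
#' the estimates with their standard errors as spread (independently per
#' draw and per pair), fitting ordinary least squares through the origin in
#' each draw (`slope = sum(x y) / sum(x^2)`), and summarizing the slope
#' over draws by its mean and standard deviation. A preliminary
#' free-intercept fit on the point estimates confirms the intercept is
#' compatible with zero before the origin constraint is applied. Slope
#' significance uses the standardized coefficient against a t-distribution
#' with `n_pairs - 1` degrees of freedom.
#'
#' @param x,y Point estimates (equal length).
#' @param sx,sy Standard errors (scalars recycled).
#' @param n_draws Monte-Carlo draws (>= 1000 recommended; default 10000).
#' @param seed Integer seed for reproducibility.
#' @return Object of class `proportionality_fit`: `slope_mean`,
#'   `slope_sd`, `slope_point` (zero-noise slope), `slope_p`,
#'   `intercept_estimate`, `intercept_p`, `df`, `n_pairs`, `n_draws`,
#'   `draws`, and the inputs.
#' @export
mc_proportionality <- function(x, y, sx, sy, n_draws = 10000L, seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  sx <- rep_len(sx, n)
  sy <- rep_len(sy, n)
  if (all(x == 0)) abort("All x estimates are zero; slope undefined.")
  if (!is.null(seed)) set.seed(seed)

  intercept_estimate <- NA_real_
  intercept_p <- NA_real_
  if (n >= 3) {
    free <- summary(lm(y ~ x))$coefficients
    intercept_estimate <- free["(Intercept)", "Estimate"]
    intercept_p <- free["(Intercept)", "Pr(>|t|)"]
    if (intercept_p < 0.05) {
      warn(paste(
        "Free-intercept pre-test rejects a zero intercept;",
        "the origin-constrained slope may be inappropriate."
      ))
    }
  }

  slope_point <- sum(x * y) / sum(x^2)
  draws <- vapply(seq_len(n_draws), function(i) {
    xt <- rnorm(n, x, sx)
    yt <- rnorm(n, y, sy)
    sum(xt * yt) / sum(xt^2)
  }, numeric(1))
  slope_mean <- mean(draws)
  slope_sd <- sd(draws)
  df <- n - 1
  slope_p <- if (slope_sd > 0) {
    2 * pt(-abs(slope_mean / slope_sd), df = df)
  } else {
    NA_real_
  }

  structure(
    list(
      slope_mean = slope_mean, slope_sd = slope_sd,
      slope_point = slope_point, slope_p = slope_p,
      intercept_estimate = intercept_estimate, intercept_p = intercept_p,
      df = df, n_pairs = n, n_draws = n_draws, draws = draws,
      x = x, y = y, sx = sx, sy = sy, seed = seed
    ),
    class = "proportionality_fit"
  )
}

#' @export
print.proportionality_fit <- function(x, ...) {
  cat(sprintf(
    "<proportionality_fit> slope %.3f (s.d. %.3f) over %d draws, %d pairs; p = %.2g (t, %d d.f.)\n",
    x$slope_mean, x$slope_sd, x$n_draws, x$n_pairs, x$slope_p, x$df
  ))
  invisible(x)
}

#' Haseman-Elston regression estimate of heritability
#'
#' Regresses the squared pairwise differences of a standardized trait on
#' the pairwise genomic relatedness over all subject pairs; the
#' heritability estimate is minus half the slope, with the standard error
#' propagated from the regression slope standard error. The trait is
#' standardized internally, so the estimate is on the phenotypic-variance
#' scale.
#'
#' @param y Trait values, named by subject id or aligned with the GRM.
#' @param grm A `grm`.
#' @param subset Optional subject ids restricting the pairs.
#' @return One-row tibble with `h2`, `se`, `slope`, `n_pairs`.
#' @export
haseman_elston <- function(y, grm, subset = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (!is.null(subset)) grm <- subset_grm(grm, subset)
  ids <- grm$subject_ids
  if (!is.null(names(y))) {
    y <- y[ids]
    if (anyNA(y)) abort("Missing trait value for a GRM subject.")
  }
  if (length(y) != length(ids)) abort("Trait and GRM dimensions differ.")
  m <- length(y)
  if (m * (m - 1) / 2 < 3) abort("Need at least 3 subject pairs.")
  y <- (y - mean(y)) / sd(y)

  lt <- lower.tri(grm$matrix)
  a <- grm$matrix[lt]
  d <- (outer(y, y, "-")^2)[lt]
  n_pairs <- length(a)
  abar <- mean(a)
  slope <- sum((a - abar) * d) / sum((a - abar)^2)
  resid <- d - mean(d) - slope * (a - abar)
  se_slope <- sqrt(sum(resid^2) / (n_pairs - 2) / sum((a - abar)^2))
  tibble(
    h2 = -slope / 2, se = se_slope / 2, slope = slope,
    n_pairs = n_pairs
  )
}

#' Heritability versus SNP count
#'
#' For each prefix of the SNP list (ordered by allele frequency, ascending
#' or descending, or left in panel order), rebuilds the GRM, reselects the
#' unrelated cohort, and refits the univariate REML model, tracing how the
#' SNP-heritability estimate and its standard error depend on the number of
#' markers used.
#'
#' @param geno A QC'd `genotype_matrix`.
#' @param prepared Prepared phenotype tibble containing `trait`.
#' @param trait Trait column name.
#' @param grid Increasing SNP counts to evaluate (each at most the panel
#'   size).
#' @param order `"all"` (panel order), `"maf_ascending"`, or
#'   `"maf_descending"`.
#' @param thresholds [selection_thresholds()] for the unrelated cohort.
#' @param ... Passed to [reml_fit()].
#' @return Tibble with `n_snps`, `m_subjects`, `h2`, `se`.
#' @export
hg2_snp_scan <- function(geno, prepared, trait, grid,
                         order = c("all", "maf_ascending", "maf_descending"),
                         thresholds = selection_thresholds(), ...) {
  stopifnot(inherits(geno, "genotype_matrix"))
  order <- match.arg(order)
  if (max(grid) > length(geno$snp_ids)) {
    abort("Grid point exceeds the number of available SNPs.")
  }
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  ord <- switch(order,
    all = seq_along(maf),
    maf_ascending = base::order(maf),
    maf_descending = base::order(maf, decreasing = TRUE)
  )
  purrr::map_dfr(sort(grid), function(nk) {
    sub <- subset_genotypes(geno, snps = geno$snp_ids[ord[seq_len(nk)]])
    grm_k <- compute_grm(sub)
    unrel <- select_unrelated(grm_k, thresholds)
    ph <- subset_prepared(prepared, unrel)
    model <- reml_model(ph, traits = trait, grm = subset_grm(grm_k, unrel))
    fit <- reml_fit(model, ...)
    h <- heritability(fit, trait)
    tibble(
      n_snps = nk, m_subjects = length(unrel),
      h2 = h$h2, se = h$se
    )
  })
}
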