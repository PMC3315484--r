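#' Transform, adjust, and standardize traits
#'
#' Listed traits are natural-log transformed first. In `"pre_adjust"` mode
#' (the default) each trait is replaced by its least-squares residuals on an
#' intercept plus the listed covariates and then standardized to mean 0 and
#' variance 1; the fixed-effect design handed to REML is then intercept-only.
#' In `"in_model"` mode traits are standardized (after log transforms) and
#' the covariate design matrix is attached for use as REML fixed effects.
#' Rows with missing values in any used trait or covariate are dropped
#' first, so downstream stages see complete cases only.
#'
#' @param pheno Data frame with an `IID` column, trait columns, and
#'   covariate columns.
#' @param traits Character vector of trait column names.
#' @param log_transform Traits to natural-log transform (must be strictly
#'   positive).
#' @param covariates Covariate column names (may be empty).
#' @param mode `"pre_adjust"` or `"in_model"`.
#' @return A tibble with `IID`, covariates, and the prepared traits, with
#'   attributes `design` (REML fixed-effect design matrix), `mode`,
#'   `log_transformed`, and `standardized`.
#' @export
prepare_traits <- function(pheno, traits,
                           log_transform = character(),
                           covariates = character(),
                           mode = c("pre_adjust", "in_model")) {
  mode <- match.arg(mode)
  pheno <- as_tibble(pheno)
  missing_cols <- setdiff(c(traits, covariates), names(pheno))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(pheno[, c(traits, covariates), drop = FALSE])
  pheno <- pheno[keep, , drop = FALSE]

  for (tr in intersect(log_transform, traits)) {
    if (any(pheno[[tr]] <= 0)) {
      abort(sprintf("Trait '%s' has non-positive values; cannot log-transform.", tr))
    }
    pheno[[tr]] <- log(pheno[[tr]])
  }

  X <- if (length(covariates) > 0) {
    model.matrix(
      stats::reformulate(covariates),
      data = pheno[, covariates, drop = FALSE]
    )
  } else {
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }

  standardize <- function(v) (v - mean(v)) / sd(v)
  for (tr in traits) {
    v <- pheno[[tr]]
    if (mode == "pre_adjust" && ncol(X) > 1) {
      v <- lm.fit(X, v)$residuals
    }
    pheno[[tr]] <- standardize(v)
  }

  design <- if (mode == "in_model") X else
    matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  attr(pheno, "design") <- design
  attr(pheno, "mode") <- mode
  attr(pheno, "log_transformed") <- intersect(log_transform, traits)
  attr(pheno, "standardized") <- TRUE
  pheno
}

#' Subset a prepared phenotype table by subject, keeping the design
#'
#' Row subsetting with `[` does not carry the `"design"` attribute along;
#' this helper subsets both consistently.
#'
#' @param prepared A tibble from [prepare_traits()].
#' @param ids Subject ids to keep, in the desired order.
#' @return The subsetted tibble with a matching `design` attribute.
#' @export
subset_prepared <- function(prepared, ids) {
  idx <- match(ids, prepared$IID)
  if (anyNA(idx)) abort("Unknown subject id in `ids`.")
  out <- prepared[idx, , drop = FALSE]
  design <- attr(prepared, "design")
  if (!is.null(design)) {
    attr(out, "design") <- design[idx, , drop = FALSE]
  }
  attr(out, "mode") <- attr(prepared, "mode")
  attr(out, "standardized") <- attr(prepared, "standardized")
  out
}

#' Principal-component covariates from a (pruned) GRM
#'
#' Eigendecomposes a genomic relationship matrix built from an LD-pruned
#' SNP subset and returns the eigenvectors whose eigenvalue share of the
#' trace exceeds `variance_threshold`, ordered by decreasing eigenvalue.
#' These serve as fixed-effect covariates against population
#' stratification.
#'
#' @param grm A `grm` (or symmetric matrix), ideally from [ld_prune()]d
#'   SNPs.
#' @param variance_threshold Minimum eigenvalue share of the trace
#'   (default 0.001, i.e. 0.1 percent).
#' @return A tibble with `IID` and one `PC<k>` column per retained
#'   component; attribute `"share"` holds all eigenvalue shares.
#' @export
pca_covariates <- function(grm, variance_threshold = 0.001) {
  if (inherits(grm, "grm")) {
    A <- grm$matrix
    ids <- grm$subject_ids
    es <- grm_eigen(grm)
  } else {
    A <- grm
    if (max(abs(A - t(A))) > 1e-8) abort("GRM must be symmetric.")
    ids <- rownames(A)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(A)))
    es <- eigen(A, symmetric = TRUE)
  }
  share <- es$values / sum(es$values)
  keep <- which(share > variance_threshold)
  out <- tibble(IID = ids)
  for (k in seq_along(keep)) {
    out[[sprintf("PC%d", k)]] <- es$vectors[, keep[k]]
  }
  attr(out, "share") <- share
  out
}

#' LD-prune SNPs by pairwise r-squared in a sliding window
#'
#' Standard windowed pruning: within each window of `window` SNPs
#' (advanced by `step`), for every pair with squared genotype correlation
#' above `r2_max` the later SNP is dropped.
#'
#' @param geno A `genotype_matrix`.
#' @param window Window size in SNPs.
#' @param step Step size in SNPs.
#' @param r2_max Pairwise r-squared threshold.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(geno, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$dosage
  n <- ncol(x)
  keep <- rep(TRUE, n)
  starts <- seq(1, max(1, n - 1), by = step)
  for (s in starts) {
    idx <- seq(s, min(s + window - 1, n))
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r <- suppressWarnings(stats::cor(x[, idx, drop = FALSE],
      use = "pairwise.complete.obs"
    ))
    r[is.na(r)] <- 0
    r2 <- r^2
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      hits <- which(r2[a, ] > r2_max)
      hits <- hits[hits > a & keep[idx[hits]]]
      keep[idx[hits]] <- FALSE
    }
  }
  geno$snp_ids[keep]
}

#' Subset a genotype matrix by SNPs and/or subjects
#'
#' @param geno A `genotype_matrix`.
#' @param snps SNP ids to keep (default all).
#' @param subjects Subject ids to keep (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, snps = NULL, subjects = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  si <- if (is.null(snps)) seq_along(geno$snp_ids) else match(snps, geno$snp_ids)
  ui <- if (is.null(subjects)) {
    seq_along(geno$subject_ids)
  } else {
    match(subjects, geno$subject_ids)
  }
  if (anyNA(si) || anyNA(ui)) abort("Unknown SNP or subject id.")
  new_genotype_matrix(
    dosage = geno$dosage[ui, si, drop = FALSE],
    map = geno$map[si, , drop = FALSE],
    p_true = geno$p_true[si],
    families = geno$families
  )
}
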