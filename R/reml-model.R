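#' Variance components of the multi-trait mixed model
#'
#' Container for the `t x t` genetic covariance matrix `G` (entries
#' `cov_g(i,j)`) and the `t x t` residual covariance matrix `R` (entries
#' `cov_e(i,j)`) of the linear mixed-effects model.
#'
#' @param G Genetic covariance matrix (scalar allowed for one trait).
#' @param R Residual covariance matrix.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(G, R) {
  if (is.null(dim(G))) G <- matrix(G, 1, 1)
  if (is.null(dim(R))) R <- matrix(R, 1, 1)
  G <- as.matrix(G)
  R <- as.matrix(R)
  t <- nrow(G)
  if (!all(dim(G) == c(t, t)) || !all(dim(R) == c(t, t))) {
    abort("G and R must be square matrices of the same size.")
  }
  if (max(abs(G - t(G))) > 1e-8 || max(abs(R - t(R))) > 1e-8) {
    abort("G and R must be symmetric.")
  }
  structure(list(G = (G + t(G)) / 2, R = (R + t(R)) / 2, t = t),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\nG:\n")
  print(round(x$G, 4))
  cat("R:\n")
  print(round(x$R, 4))
  invisible(x)
}

#' Specify a multi-trait REML model
#'
#' Assembles phenotypes, the fixed-effect design, and the genomic
#' relationship matrix into a model specification for [reml_fit()]. All
#' traits must be observed on the same subjects (complete data) and share
#' one fixed-effect design. The GRM is eigendecomposed once here; every
#' subsequent likelihood, gradient, and EM computation works in the rotated
#' basis where the relationship matrix is diagonal.
#'
#' @param pheno Either a data frame with an `IID` column and trait columns
#'   (e.g. from [prepare_traits()]), or a numeric matrix of trait values
#'   (subjects x traits).
#' @param traits Trait column names (ignored when `pheno` is a matrix).
#' @param grm A `grm` object, or a symmetric relationship matrix.
#' @param design Optional fixed-effect design matrix (m x s, shared across
#'   traits). Defaults to the `"design"` attribute of `pheno` if present,
#'   else an intercept column.
#' @return An object of class `reml_model`.
#' @export
reml_model <- function(pheno, traits = NULL, grm, design = NULL) {
  if (is.matrix(pheno)) {
    Y <- pheno
    if (is.null(colnames(Y))) {
      colnames(Y) <- sprintf("trait%d", seq_len(ncol(Y)))
    }
    ids <- rownames(Y)
  } else {
    pheno <- as_tibble(pheno)
    if (is.null(traits)) abort("`traits` is required for data-frame input.")
    Y <- as.matrix(pheno[, traits, drop = FALSE])
    ids <- pheno$IID
    if (is.null(design)) design <- attr(pheno, "design")
  }
  if (anyNA(Y)) abort("Complete trait data required (no missing values).")

  if (inherits(grm, "grm")) {
    if (!is.null(ids)) {
      if (!all(ids %in% grm$subject_ids)) {
        abort("Some phenotyped subjects are missing from the GRM.")
      }
      if (!identical(ids, grm$subject_ids)) grm <- subset_grm(grm, ids)
    }
    es <- grm_eigen(grm)
    A_ids <- grm$subject_ids
  } else {
    if (max(abs(grm - t(grm))) > 1e-8) abort("Relationship matrix must be symmetric.")
    es <- eigen(grm, symmetric = TRUE)
    A_ids <- ids
  }
  m <- nrow(Y)
  if (nrow(es$vectors) != m) abort("GRM and phenotype dimensions differ.")

  if (is.null(design)) {
    design <- matrix(1, m, 1, dimnames = list(NULL, "(Intercept)"))
  }
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) {
    abort("Fixed-effect design must have full column rank.")
  }

  U <- es$vectors
  structure(
    list(
      Y = Y, X = design,
      traits = colnames(Y),
      subject_ids = A_ids,
      lambda = es$values,
      Ytil = crossprod(U, Y),
      Xtil = crossprod(U, design),
      m = m, t = ncol(Y), s = ncol(design)
    ),
    class = "reml_model"
  )
}

#' @export
print.reml_model <- function(x, ...) {
  cat(sprintf(
    "<reml_model> %d subjects, %d trait(s) [%s], %d fixed effect(s)\n",
    x$m, x$t, paste(x$traits, collapse = ", "), x$s
  ))
  invisible(x)
}

# parameter ordering: genetic block then residual block, pairs (i, j) with
# i <= j in lexicographic order; fixed for Fisher-matrix indexing
param_index <- function(t) {
  ij <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  tibble(
    block = rep(c("g", "r"), each = nrow(ij)),
    i = rep(ij[, 1], 2),
    j = rep(ij[, 2], 2)
  )
}

param_names <- function(t, traits = NULL) {
  px <- param_index(t)
  if (is.null(traits)) traits <- sprintf("trait%d", seq_len(t))
  blk <- ifelse(px$block == "g", "g", "e")
  ifelse(
    px$i == px$j,
    sprintf("var_%s(%s)", blk, traits[px$i]),
    sprintf("cov_%s(%s,%s)", blk, traits[px$i], traits[px$j])
  )
}

default_init <- function(model) {
  # half the phenotypic (co)variance to each component, computed from the
  # residuals of the fixed-effect fit
  res <- lm.fit(model$X, model$Y)$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  S <- cov(res)
  variance_components(S / 2, S / 2)
}
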