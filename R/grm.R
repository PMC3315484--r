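#' Relatedness cutoffs for cohort selection
#'
#' Defaults follow the GREML convention: the "related" cohort keeps subjects
#' with at least one empirical relatedness in `[0.35, 0.65]` (full sibs and
#' parent-offspring), and the "unrelated" cohort keeps subjects whose
#' maximum pairwise genomic correlation is below 0.025 (less than the
#' expected relatedness of second cousins).
#'
#' @param related_low,related_high Window of relatedness defining a related
#'   pair.
#' @param unrelated_max Strict upper bound on pairwise relatedness in the
#'   unrelated cohort.
#' @param seed Seed for the randomized related-cohort pruning order.
#' @return An object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(related_low = 0.35,
                                 related_high = 0.65,
                                 unrelated_max = 0.025,
                                 seed = 1L) {
  if (!(0 < unrelated_max && unrelated_max < related_low &&
    related_low < related_high)) {
    abort("Need 0 < unrelated_max < related_low < related_high.")
  }
  structure(
    list(
      related_low = related_low, related_high = related_high,
      unrelated_max = unrelated_max, seed = as.integer(seed)
    ),
    class = "selection_thresholds"
  )
}

#' Genomic relationship matrix with modified diagonal
#'
#' Off-diagonal entries are average products of standardized genotypes,
#' `A_jk = (1/n) sum_i z_ij z_ik`. Diagonal entries use the modified
#' formula computed from the raw dosages `x` and allele frequencies `p`,
#' `A_jj = 1 + (1/n) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i))`, which has expectation 1 under Hardy-Weinberg
#' equilibrium and lower sampling variance than the plain average of
#' squared standardized genotypes. Missing genotypes contribute zero to
#' both forms (mean imputation).
#'
#' @param geno A `genotype_matrix` (QC'd; no monomorphic loci).
#' @param p Optional allele frequencies; computed from the data when `NULL`.
#' @return An object of class `grm`: list with `matrix` (symmetric subjects
#'   x subjects), `subject_ids`, and `n_snps`.
#' @export
compute_grm <- function(geno, p = NULL) {
  x <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  Z <- standardize_genotypes(x, p)
  p <- attr(Z, "p")
  n <- ncol(Z)
  A <- tcrossprod(Z) / n

  denom <- 2 * p * (1 - p)
  num <- x^2 - sweep(x, 2, 1 + 2 * p, "*")
  num <- sweep(num, 2, 2 * p^2, "+")
  num <- sweep(num, 2, denom, "/")
  num[is.na(num)] <- 0
  diag(A) <- 1 + rowSums(num) / n

  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(x)))
  dimnames(A) <- list(ids, ids)
  new_grm(A, ids, n)
}

new_grm <- function(A, subject_ids, n_snps) {
  structure(
    list(
      matrix = A, subject_ids = subject_ids, n_snps = as.integer(n_snps),
      cache = new.env(parent = emptyenv())
    ),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "<grm> %d subjects, %d SNPs; mean diagonal %.3f, off-diagonal range [%.3f, %.3f]\n",
    length(x$subject_ids), x$n_snps, mean(diag(x$matrix)),
    min(off), max(off)
  ))
  invisible(x)
}

#' Subset a GRM to a set of subjects
#'
#' @param grm A `grm`.
#' @param ids Subject identifiers to keep (order preserved as given).
#' @return A new `grm` over the requested subjects.
#' @export
subset_grm <- function(grm, ids) {
  stopifnot(inherits(grm, "grm"))
  idx <- match(ids, grm$subject_ids)
  if (anyNA(idx)) abort("Unknown subject id in `ids`.")
  new_grm(grm$matrix[idx, idx, drop = FALSE], ids, grm$n_snps)
}

# cached eigendecomposition of the GRM (used by the REML core)
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(grm$cache$eigen)) {
    grm$cache$eigen <- eigen(grm$matrix, symmetric = TRUE)
  }
  grm$cache$eigen
}

#' Select the related analysis cohort
#'
#' Retains subjects that have at least one partner with empirical
#' relatedness inside `[related_low, related_high]` among the retained
#' subjects. The pruning loop repeatedly picks a uniformly random currently
#' violating row (a subject with no in-window partner) and removes it,
#' iterating to a fixed point; the retained set is therefore seed-dependent
#' when several pruning orders are possible.
#'
#' @param grm A `grm`.
#' @param thresholds A [selection_thresholds()].
#' @param seed Overrides `thresholds$seed` when given.
#' @return Character vector of retained subject ids (possibly empty).
#' @export
select_related <- function(grm, thresholds = selection_thresholds(),
                           seed = NULL) {
  stopifnot(inherits(grm, "grm"))
  set.seed(if (is.null(seed)) thresholds$seed else seed)
  A <- grm$matrix
  diag(A) <- NA
  inwin <- !is.na(A) & A >= thresholds$related_low & A <= thresholds$related_high
  keep <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(inwin[, keep, drop = FALSE]) * keep
    violating <- which(keep & deg == 0)
    if (length(violating) == 0) break
    drop <- if (length(violating) == 1) violating else sample(violating, 1)
    keep[drop] <- FALSE
  }
  grm$subject_ids[keep]
}

#' Select the unrelated analysis cohort
#'
#' Removes subjects until every remaining pairwise relatedness is strictly
#' below `unrelated_max`. A greedy rule removes, at each step, the subject
#' incident to the largest number of offending pairs, breaking ties by the
#' lower subject index; the procedure is deterministic.
#'
#' @inheritParams select_related
#' @return Character vector of retained subject ids.
#' @export
select_unrelated <- function(grm, thresholds = selection_thresholds()) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$matrix
  diag(A) <- NA
  offend <- !is.na(A) & A >= thresholds$unrelated_max
  keep <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(offend[, keep, drop = FALSE]) * keep
    if (all(deg[keep] == 0)) break
    drop <- which.max(deg) # ties -> lowest index
    keep[drop] <- FALSE
  }
  grm$subject_ids[keep]
}

#' Export a GRM as text or binary
#'
#' Two dialects: `"text"` writes the whitespace-delimited lower triangle
#' (`index_j index_k n_snps value`, 1-based indices, diagonal included)
#' plus an `.id` sidecar; `"binary"` writes the lower triangle as
#' little-endian doubles (the GCTA `.grm.bin` layout) plus the `.id`
#' sidecar.
#'
#' @param grm A `grm`.
#' @param prefix Output path prefix.
#' @param format `"text"` or `"binary"`.
#' @return The data file path, invisibly.
#' @export
write_grm <- function(grm, prefix, format = c("text", "binary")) {
  stopifnot(inherits(grm, "grm"))
  format <- match.arg(format)
  m <- length(grm$subject_ids)
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- grm$matrix[idx]
  id_path <- paste0(prefix, ".grm.id")
  utils::write.table(
    data.frame(FID = grm$subject_ids, IID = grm$subject_ids),
    id_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  if (format == "text") {
    path <- paste0(prefix, ".grm.txt")
    utils::write.table(
      data.frame(j = idx[, 1], k = idx[, 2], n = grm$n_snps, a = vals),
      path,
      sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  } else {
    path <- paste0(prefix, ".grm.bin")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}
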