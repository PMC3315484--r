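#' Quality-control thresholds for SNPs and subjects
#'
#' Default values retain biallelic autosomal SNPs with per-SNP missingness
#' below 0.05, minor allele frequency above 0.05, and a Hardy-Weinberg exact
#' test p-value of at least 1e-6, and retain subjects with missingness of at
#' most 0.05.
#'
#' @param snp_missingness_max Remove SNPs with missingness at or above this.
#' @param maf_min Remove SNPs with minor allele frequency at or below this.
#' @param hwe_p_min Remove SNPs with Hardy-Weinberg exact p-value below this.
#' @param subject_missingness_max Remove subjects with missingness above this.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_missingness_max = 0.05,
                          maf_min = 0.05,
                          hwe_p_min = 1e-6,
                          subject_missingness_max = 0.05) {
  vals <- c(snp_missingness_max, maf_min, hwe_p_min, subject_missingness_max)
  if (any(vals < 0) || any(vals > 1)) {
    abort("All QC thresholds must lie in [0, 1].")
  }
  structure(
    list(
      snp_missingness_max = snp_missingness_max,
      maf_min = maf_min,
      hwe_p_min = hwe_p_min,
      subject_missingness_max = subject_missingness_max
    ),
    class = "qc_thresholds"
  )
}

#' Per-SNP allele frequencies from non-missing calls
#'
#' @param geno A `genotype_matrix` or dosage matrix (minor-allele counts).
#' @return Numeric vector of allele-1 frequencies.
#' @export
allele_freq <- function(geno) {
  x <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  colMeans(x, na.rm = TRUE) / 2
}

#' Hardy-Weinberg exact test (mid-p)
#'
#' Exact test of Hardy-Weinberg equilibrium from genotype counts, following
#' the conditional distribution of the heterozygote count given the allele
#' counts. The mid-p variant (half weight on the observed outcome) is the
#' PLINK convention and the default.
#'
#' @param n_het Heterozygote counts (vectorized).
#' @param n_hom1 Counts of one homozygote class.
#' @param n_hom2 Counts of the other homozygote class.
#' @param midp Use the mid-p correction.
#' @return Vector of p-values.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2, midp = TRUE) {
  mapply(function(het, hom1, hom2) {
    n <- het + hom1 + hom2
    if (n == 0) return(NA_real_)
    rare <- 2 * min(hom1, hom2) + het
    # log-probabilities of all heterozygote counts with the same parity
    hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
    homr <- (rare - hets) / 2
    homc <- n - hets - homr
    logp <- hets * log(2) - lfactorial(homr) - lfactorial(hets) -
      lfactorial(homc)
    logp <- logp - max(logp)
    prob <- exp(logp)
    prob <- prob / sum(prob)
    p_obs <- prob[hets == het]
    extreme <- prob <= p_obs * (1 + 1e-9)
    p <- sum(prob[extreme])
    if (midp) p <- p - 0.5 * p_obs
    min(1, p)
  }, n_het, n_hom1, n_hom2)
}

#' Filter SNPs and subjects by missingness, frequency, and HWE
#'
#' Subjects are filtered first (on missingness across all SNPs); SNP
#' statistics are then recomputed on the retained subjects before applying
#' the SNP filters: missingness, minor allele frequency, and the
#' Hardy-Weinberg exact test.
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `genotype` (the filtered `genotype_matrix`) and
#'   `report` (tibble of per-criterion removal counts; criteria are counted
#'   independently, so one SNP can appear under several).
#' @export
qc_genotypes <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  th <- thresholds
  x <- geno$dosage

  subj_miss <- rowMeans(is.na(x))
  keep_subj <- subj_miss <= th$subject_missingness_max
  x <- x[keep_subj, , drop = FALSE]

  snp_miss <- colMeans(is.na(x))
  p <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  n_het <- colSums(x == 1, na.rm = TRUE)
  n_hom1 <- colSums(x == 2, na.rm = TRUE)
  n_hom2 <- colSums(x == 0, na.rm = TRUE)
  hwe_p <- hwe_exact_test(n_het, n_hom1, n_hom2)

  fail_miss <- snp_miss >= th$snp_missingness_max
  fail_maf <- maf <= th$maf_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < th$hwe_p_min
  keep_snp <- !(fail_miss | fail_maf | fail_hwe)

  report <- tibble(
    criterion = c(
      "subject_missingness", "snp_missingness", "snp_maf", "snp_hwe",
      "snps_retained", "subjects_retained"
    ),
    removed = c(
      sum(!keep_subj), sum(fail_miss), sum(fail_maf), sum(fail_hwe),
      NA_integer_, NA_integer_
    ),
    retained = c(
      NA_integer_, NA_integer_, NA_integer_, NA_integer_,
      sum(keep_snp), sum(keep_subj)
    )
  )
  if (sum(keep_snp) == 0 || sum(keep_subj) == 0) {
    warn("QC removed all SNPs or all subjects; the result is empty.")
  }

  out <- new_genotype_matrix(
    dosage = x[, keep_snp, drop = FALSE],
    map = geno$map[keep_snp, , drop = FALSE],
    p_true = geno$p_true[keep_snp],
    families = geno$families
  )
  list(genotype = out, report = report)
}

#' Standardize genotypes to zero mean and unit variance under HWE
#'
#' Each dosage `x` at a locus with allele frequency `p` (computed from the
#' non-missing calls) becomes `(x - 2 p) / sqrt(2 p (1 - p))`; missing
#' entries become exactly 0 (mean imputation after centering), so they
#' contribute nothing to genomic relatedness.
#'
#' @param geno A `genotype_matrix` or dosage matrix.
#' @param p Optional allele frequencies; computed from the data when `NULL`.
#' @return Matrix `Z` of standardized genotypes with attribute `"p"`.
#' @export
standardize_genotypes <- function(geno, p = NULL) {
  x <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  if (is.null(p)) p <- colMeans(x, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    abort(paste(
      "Monomorphic locus (allele frequency 0 or 1) cannot be standardized;",
      "run `qc_genotypes()` first."
    ))
  }
  Z <- scale_dosage(x, p)
  attr(Z, "p") <- p
  Z
}
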