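#' Published ARIC metabolic-syndrome summary estimates
#'
#' Transcribed summary statistics for seven metabolic syndrome (MetS)
#' traits in the ARIC (Atherosclerosis Risk in Communities) GWAS cohort, as
#' printed in the published mixed-model analysis: univariate heritability
#' estimates from the related (`h2`) and unrelated (`hg2`, common-SNP)
#' cohorts, and the 21 pairwise genetic, residual, and phenotypic
#' correlations with their standard errors and printed significance flags
#' (Bonferroni-corrected at 0.05 over 21 hypotheses). These printed tables
#' are the inputs to the proportionality and significance-pattern analyses;
#' the underlying genotype data are access-restricted and are not part of
#' this package.
#'
#' Traits: body-mass index (BMI), waist-to-hip ratio (WHR), fasting glucose
#' (GLU), fasting insulin (INS), fasting triglycerides (TG), fasting HDL
#' cholesterol (HDL), and systolic blood pressure (SBP). Pair tables are in
#' upper-triangle row-major order over that trait ordering.
#'
#' @return A named list of tibbles: `h2` (per-trait `h2`, `h2_se`, `hg2`,
#'   `hg2_se`), and pair tables `genetic_related`, `residual_related`,
#'   `genetic_unrelated`, `residual_unrelated`, `phenotypic_related`,
#'   `phenotypic_unrelated`, each with `trait_x`, `trait_y`, `r`, `se`,
#'   `significant`.
#' @export
mets_tables <- function() {
  traits <- c("BMI", "WHR", "GLU", "INS", "TG", "HDL", "SBP")
  pairs <- utils::combn(traits, 2)
  pair_tbl <- function(r, se, sig) {
    tibble(
      trait_x = pairs[1, ], trait_y = pairs[2, ],
      r = r, se = se, significant = as.logical(sig)
    )
  }

  h2 <- tibble(
    trait = traits,
    h2 = c(0.34, 0.28, 0.33, 0.23, 0.47, 0.48, 0.30),
    h2_se = c(0.12, 0.12, 0.12, 0.12, 0.11, 0.11, 0.12),
    hg2 = c(0.14, 0.13, 0.10, 0.09, 0.16, 0.12, 0.24),
    hg2_se = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
  )

  # pair order: BMI-WHR, BMI-GLU, BMI-INS, BMI-TG, BMI-HDL, BMI-SBP,
  # WHR-GLU, WHR-INS, WHR-TG, WHR-HDL, WHR-SBP, GLU-INS, GLU-TG, GLU-HDL,
  # GLU-SBP, INS-TG, INS-HDL, INS-SBP, TG-HDL, TG-SBP, HDL-SBP
  genetic_related <- pair_tbl(
    r = c(
      0.75, 0.23, 0.17, 0.19, -0.12, 0.55,
      0.35, 0.67, 0.10, -0.12, 0.37,
      0.69, 0.21, -0.07, 0.13,
      0.76, -0.33, 0.29,
      -0.59, 0.21,
      -0.06
    ),
    se = c(
      0.16, 0.24, 0.27, 0.20, 0.21, 0.24,
      0.26, 0.26, 0.22, 0.22, 0.26,
      0.25, 0.21, 0.21, 0.27,
      0.21, 0.23, 0.29,
      0.13, 0.22,
      0.23
    ),
    sig = c(
      1, 0, 0, 0, 0, 0,
      0, 1, 0, 0, 0,
      1, 0, 0, 0,
      1, 0, 0,
      1, 0,
      0
    )
  )

  residual_related <- pair_tbl(
    r = c(
      0.52, 0.19, 0.64, 0.29, -0.38, 0.11,
      0.14, 0.35, 0.34, -0.34, 0.18,
      0.22, 0.21, -0.22, 0.05,
      0.27, -0.39, 0.24,
      -0.45, 0.10,
      -0.02
    ),
    se = c(
      0.08, 0.12, 0.08, 0.12, 0.12, 0.12,
      0.12, 0.09, 0.12, 0.12, 0.11,
      0.11, 0.13, 0.13, 0.12,
      0.11, 0.11, 0.11,
      0.11, 0.13,
      0.13
    ),
    sig = c(
      1, 0, 1, 0, 1, 0,
      0, 1, 0, 0, 0,
      0, 0, 0, 0,
      0, 1, 0,
      1, 0,
      0
    )
  )

  genetic_unrelated <- pair_tbl(
    r = c(
      0.91, 0.01, 0.57, 0.20, -0.15, 0.16,
      0.09, 0.33, 0.32, -0.06, 0.17,
      0.05, 0.07, -0.16, 0.11,
      0.22, -0.20, 0.20,
      -0.57, 0.002,
      -0.03
    ),
    se = c(
      0.18, 0.32, 0.24, 0.24, 0.28, 0.20,
      0.32, 0.31, 0.23, 0.30, 0.21,
      0.40, 0.30, 0.34, 0.24,
      0.29, 0.36, 0.25,
      0.19, 0.19,
      0.22
    ),
    sig = c(
      1, 0, 0, 0, 0, 0,
      0, 0, 0, 0, 0,
      0, 0, 0, 0,
      0, 0, 0,
      1, 0,
      0
    )
  )

  residual_unrelated <- pair_tbl(
    r = c(
      0.44, 0.27, 0.51, 0.31, -0.34, 0.25,
      0.18, 0.40, 0.33, -0.33, 0.18,
      0.39, 0.20, -0.16, 0.17,
      0.43, -0.39, 0.22,
      -0.51, 0.21,
      -0.04
    ),
    se = c(
      0.03, 0.04, 0.03, 0.04, 0.04, 0.05,
      0.04, 0.04, 0.04, 0.04, 0.05,
      0.04, 0.04, 0.04, 0.05,
      0.04, 0.04, 0.04,
      0.03, 0.05,
      0.05
    ),
    sig = c(
      1, 1, 1, 1, 1, 1,
      1, 1, 1, 1, 1,
      1, 1, 1, 1,
      1, 1, 1,
      1, 1,
      0
    )
  )

  phenotypic_related <- pair_tbl(
    r = c(
      0.59, 0.20, 0.49, 0.24, -0.26, 0.25,
      0.21, 0.43, 0.23, -0.24, 0.23,
      0.34, 0.21, -0.15, 0.07,
      0.42, -0.35, 0.25,
      -0.52, 0.14,
      -0.04
    ),
    se = rep(0.04, 21),
    sig = c(
      1, 1, 1, 1, 1, 1,
      1, 1, 1, 1, 1,
      1, 1, 1, 0,
      1, 1, 1,
      1, 1,
      0
    )
  )

  phenotypic_unrelated <- pair_tbl(
    r = c(
      0.51, 0.24, 0.52, 0.30, -0.32, 0.23,
      0.17, 0.39, 0.33, -0.30, 0.18,
      0.35, 0.19, -0.15, 0.15,
      0.40, -0.37, 0.21,
      -0.52, 0.16,
      -0.04
    ),
    se = rep(0.01, 21),
    sig = rep(1, 21)
  )

  list(
    h2 = h2,
    genetic_related = genetic_related,
    residual_related = residual_related,
    genetic_unrelated = genetic_unrelated,
    residual_unrelated = residual_unrelated,
    phenotypic_related = phenotypic_related,
    phenotypic_unrelated = phenotypic_unrelated
  )
}
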