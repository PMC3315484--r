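Package: snpherit
Title: SNP-Based Heritability and Genetic Correlations via EM-REML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of narrow-sense heritability and genetic, residual,
    and phenotypic correlations from genome-wide SNP data using univariate and
    multivariate linear mixed-effects models fit by restricted maximum
    likelihood (REML) with an expectation-maximisation algorithm. Includes
    construction of the genomic relationship matrix (GRM) from standardized
    genotypes with a modified diagonal, relatedness-based selection of related
    and unrelated analysis cohorts, canonical-transformation acceleration of
    the multivariate fit, Fisher-information standard errors with delta-method
    propagation to heritabilities and correlations, Haseman-Elston regression,
    Monte-Carlo proportionality fits between correlation sets, significance
    testing of correlation estimates, a PLINK bed/bim/fam reader and writer,
    and a synthetic GWAS generator with Hardy-Weinberg genotypes, sib-pair
    families, and multi-trait polygenic phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
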