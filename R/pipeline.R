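#' Configuration for the end-to-end analysis pipeline
#'
#' Declarative bundle of every stage's parameters. All stochastic stages
#' (related-cohort pruning, Monte-Carlo summaries) derive their seeds from
#' the single global `seed`.
#'
#' @param traits Trait column names to analyze.
#' @param log_transform Traits to natural-log transform.
#' @param covariates Covariate column names.
#' @param covariate_mode `"pre_adjust"` or `"in_model"`.
#' @param qc A [qc_thresholds()].
#' @param selection A [selection_thresholds()].
#' @param algorithm REML algorithm, `"direct"` or `"canonical"`.
#' @param tol_loglik,tol_param,tol_grad,max_iter REML tolerances (see
#'   [reml_fit()]).
#' @param multivariate Also fit the all-trait simultaneous model.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traits,
                            log_transform = character(),
                            covariates = c("age", "sex"),
                            covariate_mode = "pre_adjust",
                            qc = qc_thresholds(),
                            selection = selection_thresholds(),
                            algorithm = "direct",
                            tol_loglik = 1e-4,
                            tol_param = 1e-8,
                            tol_grad = 1e-4,
                            max_iter = 2000L,
                            multivariate = FALSE,
                            seed = 1L) {
  structure(
    list(
      traits = traits, log_transform = log_transform,
      covariates = covariates, covariate_mode = covariate_mode,
      qc = qc, selection = selection, algorithm = algorithm,
      tol_loglik = tol_loglik, tol_param = tol_param, tol_grad = tol_grad,
      max_iter = max_iter, multivariate = multivariate,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full heritability / genetic-correlation pipeline
#'
#' Sequences the analysis stages: genotype QC, genotype standardization and
#' GRM construction, selection of the related and unrelated cohorts,
#' phenotype preparation, univariate REML per trait on both cohorts,
#' bivariate REML per trait pair on the unrelated cohort, optionally the
#' all-trait multivariate fit, and the post-hoc correlation and
#' significance summaries. When a cohort is empty (for example, no pair
#' falls inside the relatedness window) its estimates are marked
#' unavailable and the remaining stages still run.
#'
#' @param geno A `genotype_matrix` (e.g. from [read_plink()] or
#'   [simulate_genotypes()]).
#' @param pheno Phenotype/covariate data frame with `IID`, trait, and
#'   covariate columns.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, result tables are
#'   written there as tab-delimited text.
#' @return A named list: `qc_report`, `cohorts` (ids and sizes with ordered
#'   and unordered pair counts), `univariate` (per trait x cohort tibble of
#'   variance components and h2), `bivariate` (per pair correlations),
#'   `multivariate` (all-trait fit or `NULL`), `phenotypic` (phenotypic
#'   correlations per cohort), and `log` (stage records).
#' @export
run_pipeline <- function(geno, pheno, config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(stage = stage, sprintf(...))
  }

  qc <- qc_genotypes(geno, config$qc)
  note("qc", "retained %d SNPs, %d subjects", ncol(qc$genotype$dosage),
    nrow(qc$genotype$dosage))

  grm <- compute_grm(qc$genotype)
  note("grm", "GRM over %d SNPs", grm$n_snps)

  sel <- config$selection
  sel$seed <- config$seed
  related <- select_related(grm, sel)
  unrelated <- select_unrelated(grm, sel)
  pair_counts <- function(m) c(
    unordered = m * (m - 1) / 2,
    ordered = m * (m - 1)
  )
  cohorts <- list(
    related = related, unrelated = unrelated,
    n_related = length(related), n_unrelated = length(unrelated),
    pairs_related = pair_counts(length(related)),
    pairs_unrelated = pair_counts(length(unrelated))
  )
  note(
    "select", "related cohort %d subjects (%d pairs); unrelated %d (%d pairs)",
    length(related), cohorts$pairs_related["unordered"],
    length(unrelated), cohorts$pairs_unrelated["unordered"]
  )

  prepared <- prepare_traits(
    pheno, config$traits,
    log_transform = config$log_transform,
    covariates = intersect(config$covariates, names(pheno)),
    mode = config$covariate_mode
  )
  # keep genotyped subjects only
  prepared <- prepared[prepared$IID %in% grm$subject_ids, , drop = FALSE]

  fit_cohort <- function(ids, label) {
    ids <- intersect(ids, prepared$IID)
    if (length(ids) < 10) {
      note("reml", "%s cohort too small (%d); estimates unavailable", label,
        length(ids))
      return(NULL)
    }
    ph <- subset_prepared(prepared, ids)
    g <- subset_grm(grm, ids)
    purrr::map_dfr(config$traits, function(tr) {
      fit <- reml_fit(
        reml_model(ph, traits = tr, grm = g),
        algorithm = config$algorithm,
        tol_loglik = config$tol_loglik, tol_param = config$tol_param,
        tol_grad = config$tol_grad, max_iter = config$max_iter
      )
      dplyr::mutate(heritability(fit),
        cohort = label, n_subjects = length(ids),
        converged = fit$converged, .before = 1
      )
    })
  }
  univariate <- dplyr::bind_rows(
    fit_cohort(related, "related"),
    fit_cohort(unrelated, "unrelated")
  )

  bivariate <- NULL
  if (length(config$traits) >= 2) {
    ids <- intersect(unrelated, prepared$IID)
    if (length(ids) >= 10) {
      ph <- subset_prepared(prepared, ids)
      g <- subset_grm(grm, ids)
      prs <- utils::combn(config$traits, 2, simplify = FALSE)
      bivariate <- purrr::map_dfr(prs, function(pr) {
        fit <- reml_fit(
          reml_model(ph, traits = pr, grm = g),
          algorithm = config$algorithm,
          tol_loglik = config$tol_loglik, tol_param = config$tol_param,
          tol_grad = config$tol_grad, max_iter = config$max_iter
        )
        dplyr::mutate(correlations(fit),
          cohort = "unrelated",
          converged = fit$converged, .before = 1
        )
      })
    }
  }

  multivariate <- NULL
  if (isTRUE(config$multivariate) && length(config$traits) >= 3) {
    ids <- intersect(unrelated, prepared$IID)
    if (length(ids) >= 10) {
      ph <- subset_prepared(prepared, ids)
      fit <- reml_fit(
        reml_model(ph, traits = config$traits, grm = subset_grm(grm, ids)),
        algorithm = config$algorithm,
        tol_loglik = config$tol_loglik, tol_param = config$tol_param,
        tol_grad = 1e-3, max_iter = config$max_iter
      )
      multivariate <- fit
    }
  }

  phenotypic <- purrr::map_dfr(
    list(related = related, unrelated = unrelated)[
      vapply(list(related, unrelated), function(x) length(x) >= 10, TRUE)
    ],
    function(ids) {
      ph <- subset_prepared(prepared, intersect(ids, prepared$IID))
      if (length(config$traits) < 2) return(NULL)
      prs <- utils::combn(config$traits, 2, simplify = FALSE)
      purrr::map_dfr(prs, function(pr) {
        phenotypic_correlation(ph, pr[1], pr[2])
      })
    },
    .id = "cohort"
  )

  results <- list(
    qc_report = qc$report, cohorts = cohorts, univariate = univariate,
    bivariate = bivariate, multivariate = multivariate,
    phenotypic = phenotypic, log = log, config = config
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.table(df, file.path(output_dir, paste0(name, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
    }
    wr(qc$report, "qc_report")
    wr(univariate, "univariate")
    wr(bivariate, "bivariate")
    wr(phenotypic, "phenotypic")
  }
  results
}
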