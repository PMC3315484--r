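#' Fit the mixed model by EM-REML
#'
#' Maximizes the restricted likelihood over the genetic and residual
#' covariance matrices using expectation-maximization. Two algorithms are
#' available: `"direct"` iterates the full multivariate EM update
#' ([em_step_multivariate()]; [em_step_univariate()] for one trait) until
#' the log-likelihood change drops below `tol_loglik` and the summed
#' squared parameter change drops below `tol_param`; `"canonical"` recodes
#' the current components so the residual covariance is the identity and
#' the genetic covariance diagonal (see [canonical_transform()]), takes one
#' univariate EM step per transformed trait for the diagonal components
#' plus the implied cross-moment updates for the covariances (cheap in this
#' basis, where the projection is block-diagonal), and transforms back,
#' until the largest gradient component is below `tol_grad`. Both converge
#' to the same optimum. The restricted log-likelihood is non-decreasing
#' across iterations for either algorithm.
#'
#' Initialization halves the phenotypic (co)variances: genetic and residual
#' components each start at half the phenotypic covariance matrix, so
#' initial genetic correlations equal the phenotypic correlations.
#' Parameters are unconstrained during iteration; a final positive-
#' semidefiniteness check is reported in the fit, not enforced.
#'
#' @param model A [reml_model()].
#' @param algorithm `"direct"` or `"canonical"`.
#' @param init Optional starting [variance_components()].
#' @param tol_loglik Convergence threshold on the log-likelihood change
#'   (direct algorithm).
#' @param tol_param Convergence threshold on the summed squared parameter
#'   change (direct algorithm).
#' @param tol_grad Convergence threshold on the maximum absolute gradient
#'   component (canonical algorithm).
#' @param max_iter Iteration cap; hitting it returns a non-converged fit
#'   with partial results.
#' @param fisher_type Passed to [fisher_information()].
#' @return An object of class `reml_fit`: converged components, per-
#'   iteration log-likelihood trace, final gradient, Fisher information
#'   with parameter covariance and standard errors, and bookkeeping.
#' @export
reml_fit <- function(model,
                     algorithm = c("direct", "canonical"),
                     init = NULL,
                     tol_loglik = 1e-4,
                     tol_param = 1e-8,
                     tol_grad = 1e-4,
                     max_iter = 2000L,
                     fisher_type = "observed") {
  stopifnot(inherits(model, "reml_model"))
  algorithm <- match.arg(algorithm)
  comps <- if (is.null(init)) default_init(model) else init
  stopifnot(inherits(comps, "variance_components"))
  t <- model$t
  floor_vals <- 1e-8 * apply(model$Y, 2, var)

  trace <- numeric(0)
  converged <- FALSE
  criterion <- NA_character_
  iter <- 0L

  if (algorithm == "direct") {
    proj <- reml_project(model, comps)
    trace <- proj$loglik
    for (iter in seq_len(max_iter)) {
      new_comps <- if (t == 1) {
        em_step_univariate(model, comps, proj)
      } else {
        em_step_multivariate(model, comps, proj)
      }
      dtheta <- sum((new_comps$G - comps$G)^2) + sum((new_comps$R - comps$R)^2)
      comps <- new_comps
      proj <- reml_project(model, comps)
      trace <- c(trace, proj$loglik)
      dll <- trace[length(trace)] - trace[length(trace) - 1]
      if (abs(dll) < tol_loglik && dtheta < tol_param) {
        converged <- TRUE
        criterion <- sprintf(
          "|dL| = %.3g < %g and sum(dtheta^2) = %.3g < %g",
          abs(dll), tol_loglik, dtheta, tol_param
        )
        break
      }
    }
  } else {
    for (iter in seq_len(max_iter)) {
      step <- canonical_em_step(model, comps)
      trace <- c(trace, step$loglik)
      g <- reml_gradient(model, comps, step$proj)
      comps <- step$comps
      if (max(abs(g)) < tol_grad) {
        converged <- TRUE
        criterion <- sprintf("max|grad| = %.3g < %g", max(abs(g)), tol_grad)
        break
      }
    }
    trace <- c(trace, reml_project(model, comps)$loglik)
  }
  if (!converged) {
    warn(sprintf("EM did not converge within %d iterations.", max_iter))
  }

  proj <- reml_project(model, comps)
  grad <- reml_gradient(model, comps, proj)
  fish <- fisher_information(model, comps, proj, type = fisher_type)
  nm <- param_names(t, model$traits)
  px <- param_index(t)
  est <- param_values(comps, px)

  psd_ok <- min(eigen(comps$G, symmetric = TRUE, only.values = TRUE)$values) >=
    -1e-8 * max(1, max(abs(comps$G)))

  structure(
    list(
      components = comps,
      loglik = proj$loglik,
      loglik_trace = trace,
      gradient = grad,
      fisher = fish$F,
      vcov = fish$vcov,
      se = setNames(fish$se, nm),
      estimates = setNames(est, nm),
      converged = converged,
      criterion = criterion,
      n_iter = iter,
      algorithm = algorithm,
      traits = model$traits,
      m = model$m, t = t, s = model$s,
      psd_ok = psd_ok
    ),
    class = "reml_fit"
  )
}

param_values <- function(comps, px) {
  vapply(seq_len(nrow(px)), function(a) {
    M <- if (px$block[a] == "g") comps$G else comps$R
    M[px$i[a], px$j[a]]
  }, numeric(1))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> %s EM, %d trait(s), m = %d; logLik = %.4f; %s after %d iterations\n",
    x$algorithm, x$t, x$m, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  print(tidy(x), n = Inf)
  invisible(x)
}

# covariance of a set of parameters from the fit, by term name
vcov_of <- function(fit, terms) {
  idx <- match(terms, names(fit$estimates))
  if (anyNA(idx)) abort("Unknown parameter term.")
  fit$vcov[idx, idx, drop = FALSE]
}

#' SNP (or pedigree) heritability of each trait
#'
#' `h2 = var_g / (var_g + var_e)` per trait, with the standard error
#' propagated from the inverse Fisher information by a first-order Taylor
#' expansion:
#' `var(h2) = (b^2 var(a) + a^2 var(b) - 2 a b cov(a, b)) / (a + b)^4`
#' for `a = var_g`, `b = var_e`.
#'
#' @param fit A [reml_fit()].
#' @param traits Traits to report (default all).
#' @return Tibble with `trait`, `var_g`, `var_e`, `h2`, `se`.
#' @export
heritability <- function(fit, traits = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(traits)) traits <- fit$traits
  purrr::map_dfr(traits, function(tr) {
    a <- fit$components$G[match(tr, fit$traits), match(tr, fit$traits)]
    b <- fit$components$R[match(tr, fit$traits), match(tr, fit$traits)]
    if (a + b <= 0) abort(sprintf("Non-positive phenotypic variance for '%s'.", tr))
    terms <- c(sprintf("var_g(%s)", tr), sprintf("var_e(%s)", tr))
    Vc <- vcov_of(fit, terms)
    h2 <- a / (a + b)
    v <- (b^2 * Vc[1, 1] + a^2 * Vc[2, 2] - 2 * a * b * Vc[1, 2]) / (a + b)^4
    tibble(trait = tr, var_g = a, var_e = b, h2 = h2, se = sqrt(max(v, 0)))
  })
}

correlation_one <- function(fit, ti, tj, block) {
  i <- match(ti, fit$traits)
  j <- match(tj, fit$traits)
  if (anyNA(c(i, j))) abort("Unknown trait name.")
  M <- if (block == "g") fit$components$G else fit$components$R
  v1 <- M[i, i]
  v2 <- M[j, j]
  cc <- M[i, j]
  kind <- if (block == "g") "genetic" else "residual"
  if (v1 <= 0 || v2 <= 0) {
    warn(sprintf(
      "Zero or negative %s variance; %s correlation undefined.", kind, kind
    ))
    return(tibble(
      trait_x = ti, trait_y = tj, kind = kind,
      estimate = NA_real_, se = NA_real_
    ))
  }
  r <- cc / sqrt(v1 * v2)
  lab <- if (block == "g") "var_g(%s)" else "var_e(%s)"
  lab_c <- if (block == "g") "cov_g(%s,%s)" else "cov_e(%s,%s)"
  ii <- min(i, j)
  jj <- max(i, j)
  terms <- c(
    sprintf(lab, fit$traits[i]),
    sprintf(lab, fit$traits[j]),
    sprintf(lab_c, fit$traits[ii], fit$traits[jj])
  )
  Vc <- vcov_of(fit, terms)
  gvec <- c(-r / (2 * v1), -r / (2 * v2), 1 / sqrt(v1 * v2))
  se <- sqrt(max(as.numeric(t(gvec) %*% Vc %*% gvec), 0))
  tibble(trait_x = ti, trait_y = tj, kind = kind, estimate = r, se = se)
}

#' Genetic correlation between two traits
#'
#' `r_g = cov_g(i, j) / sqrt(var_g(i) var_g(j))`, the genetic covariance
#' normalized by the geometric mean of the trait genetic variances, with a
#' delta-method standard error over the joint parameter covariance from the
#' inverse Fisher information. A non-positive genetic variance leaves the
#' correlation undefined (reported as `NA`, not 0).
#'
#' @param fit A [reml_fit()] of at least the two traits.
#' @param trait_x,trait_y Trait names.
#' @return One-row tibble with `trait_x`, `trait_y`, `kind`, `estimate`,
#'   `se`.
#' @export
genetic_correlation <- function(fit, trait_x, trait_y) {
  correlation_one(fit, trait_x, trait_y, "g")
}

#' Residual correlation between two traits
#'
#' Analog of [genetic_correlation()] for the residual components.
#' @inheritParams genetic_correlation
#' @return One-row tibble.
#' @export
residual_correlation <- function(fit, trait_x, trait_y) {
  correlation_one(fit, trait_x, trait_y, "r")
}

#' All pairwise genetic and residual correlations of a fit
#'
#' @param fit A [reml_fit()].
#' @return Tibble with one row per trait pair and kind.
#' @export
correlations <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  pairs <- utils::combn(fit$traits, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    dplyr::bind_rows(
      genetic_correlation(fit, pr[1], pr[2]),
      residual_correlation(fit, pr[1], pr[2])
    )
  })
}
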