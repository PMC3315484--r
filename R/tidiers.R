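#' Tidy a REML fit into a parameter table
#'
#' @param x A [reml_fit()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se)
  )
}

#' One-row summary of a REML fit
#'
#' @inheritParams tidy.reml_fit
#' @return Tibble with `logLik`, `n_iter`, `converged`, `algorithm`,
#'   `n_subjects`, `n_traits`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    algorithm = x$algorithm, n_subjects = x$m, n_traits = x$t
  )
}

#' Tidy a Monte-Carlo proportionality fit
#'
#' @param x A [mc_proportionality()] result.
#' @param ... Unused.
#' @return One-row tibble with the slope summary.
#' @export
tidy.proportionality_fit <- function(x, ...) {
  tibble(
    term = "slope",
    estimate = x$slope_mean,
    std.error = x$slope_sd,
    p.value = x$slope_p,
    point.estimate = x$slope_point,
    intercept.p = x$intercept_p,
    n_pairs = x$n_pairs,
    n_draws = x$n_draws
  )
}

#' Plot the log-likelihood trace of a REML fit
#'
#' @param object A [reml_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reml_fit <- function(object, ...) {
  df <- tibble(
    iteration = seq_along(object$loglik_trace) - 1,
    loglik = object$loglik_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "EM iteration", y = "restricted log-likelihood",
      title = sprintf("%s EM-REML (%d traits)", object$algorithm, object$t)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo proportionality fit
#'
#' Scatter of the point estimates with error bars on both axes and the
#' origin-constrained Monte-Carlo slope.
#'
#' @param object A [mc_proportionality()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proportionality_fit <- function(object, ...) {
  df <- tibble(
    x = object$x, y = object$y, sx = object$sx, sy = object$sy
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sy, ymax = .data$y + .data$sy),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$x - .data$sx, xmax = .data$x + .data$sx),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = 0, slope = object$slope_mean, linetype = "dashed"
    ) +
    ggplot2::labs(
      title = sprintf(
        "Origin-constrained slope %.2f (s.d. %.2f)",
        object$slope_mean, object$slope_sd
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a heritability-versus-SNP-count scan
#'
#' @param scan Tibble from [hg2_snp_scan()].
#' @return A ggplot with the estimate and a +/- 1 s.e. ribbon.
#' @export
plot_snp_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$n_snps, y = .data$h2)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$h2 - .data$se, ymax = .data$h2 + .data$se),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of SNPs", y = expression(h[g]^2)) +
    ggplot2::theme_minimal()
}
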