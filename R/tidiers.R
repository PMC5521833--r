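#' Tidy a fitted path model
#'
#' One row per free parameter with raw and standardized estimates,
#' Hessian-based standard errors, Wald statistics and p-values.
#'
#' @param x A `path_model_fit`.
#' @param conf.int Add normal-theory confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `from`, `to`, `estimate`,
#'   `std_estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy path_model_fit
#' @export
tidy.path_model_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble(
    term = x$parameters$label, type = x$parameters$type,
    from = x$parameters$from, to = x$parameters$to,
    estimate = x$parameters$estimate,
    std_estimate = x$parameters$std_estimate,
    std.error = x$parameters$se,
    statistic = x$parameters$statistic,
    p.value = x$parameters$p_value
  )
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a fitted path model
#'
#' @param x A `path_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_par`, `f_min`, `chi2`, `df`, `p_chi2`,
#'   `cfi`, `rmsea`, `converged`, `iterations`.
#' @method glance path_model_fit
#' @export
glance.path_model_fit <- function(x, ...) {
  fi <- suppressWarnings(fit_indices(x))
  tibble(
    n = x$n, n_par = length(x$theta), f_min = x$f_min,
    chi2 = x$chi2, df = x$df, p_chi2 = fi$p_chi2, cfi = fi$cfi,
    rmsea = fi$rmsea, converged = x$converged, iterations = x$iterations
  )
}

#' @method tidy genotype_summary
#' @export
tidy.genotype_summary <- function(x, ...) {
  tibble(
    genotype = c("0", "1", "2"),
    n = as.integer(x$counts),
    expected = as.numeric(x$expected),
    maf = x$maf, hwe_chi2 = x$hwe_chi2, hwe_p = x$hwe_p,
    hwe_exact_p = x$hwe_exact_p
  )
}

#' @method tidy fdr_family
#' @export
tidy.fdr_family <- function(x, ...) x$table
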