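#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with sorted p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, find \eqn{k^* = \max\{k : p_{(k)} \le k\,q/m\}} and reject every
#' hypothesis with \eqn{p \le p_{(k^*)}}. The reported `alpha_adj` is the
#' largest rejected p-value — the family-specific adjusted significance level
#' as quoted in applied result tables — or 0 when nothing is rejected.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]. Names, if present,
#'   label the hypotheses.
#' @param q Target FDR level (default 0.05).
#' @return A list of class `fdr_family`: `table` (tibble with `label`, `p`,
#'   `rank`, `critical`, `rejected`), `q`, `alpha_adj`, `n_rejected`.
#' @examples
#' bh_fdr(c(a = 0.001, b = 0.01, c = 0.02, d = 0.9))
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    abort("empty p-value vector", class = "pathmed_spec_error")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "pathmed_spec_error")
  }
  m <- length(p_values)
  labels <- names(p_values) %||% as.character(seq_len(m))
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  critical <- seq_len(m) * q / m
  below <- which(p_sorted <= critical)
  k_star <- if (length(below) > 0) max(below) else 0L
  alpha_adj <- if (k_star > 0) p_sorted[[k_star]] else 0
  rejected_sorted <- seq_len(m) <= k_star

  tab <- tibble(
    label = labels[ord], p = as.numeric(p_sorted),
    rank = seq_len(m), critical = critical, rejected = rejected_sorted
  )
  structure(
    list(table = tab, q = q, alpha_adj = as.numeric(alpha_adj),
         n_rejected = as.integer(k_star)),
    class = "fdr_family"
  )
}

#' @export
print.fdr_family <- function(x, ...) {
  cat(sprintf("<fdr_family> m = %d, q = %g, rejected = %d, alpha_adj = %g\n",
              nrow(x$table), x$q, x$n_rejected, x$alpha_adj))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}
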