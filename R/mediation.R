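#' Enumerate all directed paths between two variables
#'
#' Exhaustively lists every directed path from `source` to `target` in an
#' acyclic path model. The length-1 path (if the direct edge exists) carries
#' the direct effect; every longer path is a mediated path.
#'
#' @param x A [path_model()], a [fit_path_model()] result, or a data frame of
#'   edges with columns `from` and `to`.
#' @param source,target Variable names.
#' @return A list of character vectors, each a variable chain from `source`
#'   to `target`; empty list if the pair is disconnected.
#' @export
enumerate_paths <- function(x, source, target) {
  edges <- effect_edges(x)
  vars <- unique(c(edges$from, edges$to, source, target))
  if (inherits(x, "path_model")) vars <- x$variables
  if (inherits(x, "path_model_fit")) vars <- x$model$variables
  for (v in c(source, target)) {
    if (!v %in% vars) {
      abort(sprintf("unknown variable `%s`", v), class = "pathmed_spec_error")
    }
  }
  topological_order(vars, edges)  # guards against cyclic edge tables
  adj <- split(edges$to, edges$from)
  paths <- list()
  walk <- function(chain) {
    head_v <- chain[length(chain)]
    if (head_v == target) {
      paths[[length(paths) + 1L]] <<- chain
      return(invisible())
    }
    for (nxt in adj[[head_v]]) walk(c(chain, nxt))
  }
  walk(source)
  paths
}

effect_edges <- function(x) {
  if (inherits(x, "path_model_fit")) {
    pt <- x$parameters[x$parameters$type == "edge", ]
    tibble(from = pt$from, to = pt$to, estimate = pt$std_estimate)
  } else if (inherits(x, "path_model")) {
    tibble(from = x$edges$from, to = x$edges$to, estimate = NA_real_)
  } else {
    e <- check_edge_frame(as.data.frame(x))
    if (!"estimate" %in% names(e)) e$estimate <- NA_real_
    as_tibble(e[c("from", "to", "estimate")])
  }
}

path_label <- function(chain) paste(chain, collapse = " -> ")

#' Decompose the effect of one variable on another
#'
#' Product-of-coefficients mediation decomposition: the direct effect is the
#' coefficient on the `source -> target` edge (0 if that edge is absent from
#' the model); each mediated path contributes the product of the standardized
#' coefficients along it; the total indirect effect is the sum of those
#' products and the total effect is direct plus total indirect — an exact
#' identity by construction.
#'
#' Accepts either a fitted model (standardized solution is used) or a plain
#' coefficient table (`from`, `to`, `estimate`), which allows decomposition
#' of published path coefficients.
#'
#' @param x A [fit_path_model()] result or a coefficient data frame.
#' @param source,target Variable names.
#' @param se `"none"` (default), `"delta"` or `"bootstrap"`: inference for
#'   the direct, per-path, total-indirect and total effects. Requires a
#'   fitted model.
#' @param B,seed Bootstrap replicates (>= 100) and seed, when
#'   `se = "bootstrap"`.
#' @return A tibble of class `effect_decomposition` with columns `source`,
#'   `target`, `effect_type` (`direct`, `indirect_path`, `indirect_total`,
#'   `total`), `path`, `estimate`, and (with inference) `se`, `statistic`,
#'   `p_value`, `method`.
#' @examples
#' printed <- data.frame(
#'   from = c("snp", "snp", "ara", "ara", "bmi", "snp"),
#'   to = c("ara", "bmi", "bmi", "sbp", "sbp", "sbp"),
#'   estimate = c(-0.237, -0.058, 0.076, 0.149, 0.282, 0.077)
#' )
#' decompose_effects(printed, "snp", "sbp")
#' @export
decompose_effects <- function(x, source, target,
                              se = c("none", "delta", "bootstrap"),
                              B = 1000, seed = NULL) {
  se <- match.arg(se)
  edges <- effect_edges(x)
  paths <- enumerate_paths(x, source, target)
  if (length(paths) > 0 && anyNA(edges$estimate)) {
    miss <- edges[is.na(edges$estimate), ]
    abort(sprintf("missing coefficient for edge %s -> %s",
                  miss$from[1], miss$to[1]),
          class = "pathmed_spec_error")
  }
  edge_coef <- setNames(edges$estimate, paste(edges$from, edges$to, sep = "\r"))
  chain_product <- function(chain) {
    keys <- paste(chain[-length(chain)], chain[-1], sep = "\r")
    prod(edge_coef[keys])
  }
  is_direct <- lengths(paths) == 2L
  direct <- if (any(is_direct)) chain_product(paths[is_direct][[1]]) else 0
  mediated <- paths[!is_direct]
  products <- vapply(mediated, chain_product, numeric(1))
  total_indirect <- sum(products)

  out <- dplyr::bind_rows(
    tibble(effect_type = "direct",
           path = if (any(is_direct)) path_label(c(source, target)) else NA_character_,
           estimate = direct),
    if (length(mediated) > 0) {
      tibble(effect_type = "indirect_path",
             path = vapply(mediated, path_label, character(1)),
             estimate = products)
    },
    tibble(effect_type = "indirect_total", path = NA_character_,
           estimate = total_indirect),
    tibble(effect_type = "total", path = NA_character_,
           estimate = direct + total_indirect)
  )
  out <- dplyr::mutate(out, source = source, target = target,
                       .before = 1)

  if (se != "none") {
    if (!inherits(x, "path_model_fit")) {
      abort("inference requires a fitted model", class = "pathmed_spec_error")
    }
    path_sets <- c(
      list(if (any(is_direct)) paths[is_direct] else list()),
      lapply(mediated, list),
      list(mediated),
      list(paths)
    )
    inf <- purrr::map_dfr(path_sets, function(ps) {
      if (length(ps) == 0) {
        return(tibble(se = NA_real_, statistic = NA_real_, p_value = NA_real_))
      }
      indirect_se(x, ps, method = se, B = B, seed = seed)[
        c("se", "statistic", "p_value")]
    })
    out <- dplyr::bind_cols(out, inf)
    out$method <- se
  }
  class(out) <- c("effect_decomposition", class(out))
  out
}

#' Standard error and p-value for a (sum of) path product(s)
#'
#' The effect is \eqn{g(\theta) = \sum_k \prod_{e \in k} \beta^{std}_e} over
#' the supplied path set. `method = "delta"` propagates the Hessian-based
#' parameter covariance through the numeric gradient of `g` (for a single
#' two-edge path with independent estimates this reduces to the Sobel
#' formula). `method = "bootstrap"` refits the model on `B` nonparametric
#' resamples and reports the bootstrap SE, a percentile interval, and a
#' symmetric normal-approximation p-value.
#'
#' @param fitted A converged [fit_path_model()] result.
#' @param paths A single path (character vector of variable names) or a list
#'   of such paths.
#' @param method `"delta"` or `"bootstrap"`.
#' @param B Number of bootstrap resamples; values below 100 are refused.
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level for the percentile interval.
#' @return One-row tibble with `estimate`, `se`, `statistic`, `p_value`,
#'   `method` (and `conf_low`/`conf_high` for the bootstrap).
#' @export
indirect_se <- function(fitted, paths, method = c("delta", "bootstrap"),
                        B = 1000, seed = NULL, level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(fitted, "path_model_fit"))
  if (is.character(paths)) paths <- list(paths)
  model <- fitted$model
  edge_key <- paste(model$parameters$col, model$parameters$row, sep = "\r")
  effect_fun <- function(theta) {
    std <- standardize_theta(model, theta)
    coefs <- setNames(std, edge_key)
    sum(vapply(paths, function(chain) {
      keys <- paste(chain[-length(chain)], chain[-1], sep = "\r")
      prod(coefs[keys])
    }, numeric(1)))
  }
  est <- effect_fun(fitted$theta)

  if (method == "delta") {
    if (is.null(fitted$vcov)) {
      abort("fitted model has no parameter covariance (refit with se = TRUE)",
            class = "pathmed_spec_error")
    }
    g <- numDeriv::grad(effect_fun, fitted$theta)
    v <- drop(t(g) %*% fitted$vcov %*% g)
    se_val <- sqrt(max(v, 0))
    z <- if (se_val > 0) est / se_val else 0
    return(tibble(estimate = est, se = se_val, statistic = z,
                  p_value = 2 * pnorm(-abs(z)), method = "delta"))
  }

  if (B < 100) {
    abort("bootstrap requires B >= 100 resamples", class = "pathmed_spec_error")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- as.data.frame(fitted$data)
  n <- nrow(X)
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(fit_path_model(X[idx, , drop = FALSE], model, se = FALSE),
                   error = function(e) NULL)
    if (is.null(bf)) return(NA_real_)
    effect_fun(bf$theta)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  se_val <- sd(boot)
  z <- if (se_val > 0) est / se_val else 0
  alpha <- (1 - level) / 2
  tibble(estimate = est, se = se_val, statistic = z,
         p_value = 2 * pnorm(-abs(z)),
         conf_low = quantile(boot, alpha, names = FALSE),
         conf_high = quantile(boot, 1 - alpha, names = FALSE),
         method = "bootstrap")
}
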