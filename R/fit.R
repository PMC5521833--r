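# Covariance-structure machinery. The model is written in reduced RAM form
# for observed variables only: A holds the directed-edge slopes (A[i, j] is
# the slope of variable j in the equation for variable i), S the variances
# and covariances of exogenous variables and residuals. The model-implied
# covariance is Sigma = (I - A)^-1 S (I - A)^-T.

build_matrices <- function(model, theta) {
  p <- length(model$variables)
  A <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  S <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  pt <- model$parameters
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]
    if (pt$type[k] == "edge") {
      A[i, j] <- theta[k]
    } else {
      S[i, j] <- theta[k]
      S[j, i] <- theta[k]
    }
  }
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Computes \eqn{\Sigma(\theta) = (I-A)^{-1} S (I-A)^{-\top}} for a recursive
#' path model, where `A` collects the directed-edge slopes and `S` the
#' exogenous/residual variances and covariances.
#'
#' @param model A [path_model()].
#' @param theta Numeric vector of free-parameter values, in the order of
#'   `model$parameters`.
#' @return A symmetric covariance matrix over `model$variables`.
#' @export
implied_covariance <- function(model, theta) {
  stopifnot(inherits(model, "path_model"))
  if (length(theta) != nrow(model$parameters)) {
    abort("`theta` must have one value per free parameter",
          class = "pathmed_spec_error")
  }
  m <- build_matrices(model, theta)
  p <- length(model$variables)
  B <- solve(diag(p) - m$A)
  sigma <- B %*% m$S %*% t(B)
  dimnames(sigma) <- list(model$variables, model$variables)
  (sigma + t(sigma)) / 2
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The ML fit function for covariance structures,
#' \eqn{F = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p}, which is
#' non-negative and zero iff \eqn{\Sigma = S}.
#'
#' @param implied Model-implied covariance matrix \eqn{\Sigma}.
#' @param observed Sample covariance matrix \eqn{S}.
#' @return The scalar discrepancy \eqn{F \ge 0}.
#' @export
ml_discrepancy <- function(implied, observed) {
  p <- nrow(observed)
  stopifnot(nrow(implied) == p, ncol(implied) == p, ncol(observed) == p)
  ld_i <- determinant(implied, logarithm = TRUE)
  ld_o <- determinant(observed, logarithm = TRUE)
  if (ld_i$sign <= 0 || ld_o$sign <= 0) {
    abort("covariance matrices must be positive definite",
          class = "pathmed_numeric_error")
  }
  as.numeric(ld_i$modulus) + sum(diag(observed %*% solve(implied))) -
    as.numeric(ld_o$modulus) - p
}

# F and its analytic gradient for optim(); C is the sample covariance.
ml_objective <- function(model, C) {
  p <- length(model$variables)
  pt <- model$parameters
  ridx <- match(pt$row, model$variables)
  cidx <- match(pt$col, model$variables)
  is_edge <- pt$type == "edge"
  is_diag <- ridx == cidx
  ld_C <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  I_p <- diag(p)

  fn <- function(theta) {
    m <- build_matrices(model, theta)
    B <- solve(I_p - m$A)
    sigma <- B %*% m$S %*% t(B)
    ld <- determinant(sigma, logarithm = TRUE)
    if (ld$sign <= 0) return(.Machine$double.xmax / 1e10)
    as.numeric(ld$modulus) + sum(diag(C %*% solve(sigma))) - ld_C - p
  }
  gr <- function(theta) {
    m <- build_matrices(model, theta)
    B <- solve(I_p - m$A)
    sigma <- B %*% m$S %*% t(B)
    sigma_inv <- solve(sigma)
    W <- sigma_inv %*% (sigma - C) %*% sigma_inv
    SWB <- sigma %*% W %*% B   # for edge slots: dF = 2 * SWB[j, i]
    BWB <- t(B) %*% W %*% B    # for S slots
    g <- numeric(length(theta))
    g[is_edge] <- 2 * SWB[cbind(cidx[is_edge], ridx[is_edge])]
    sdiag <- !is_edge & is_diag
    g[sdiag] <- BWB[cbind(ridx[sdiag], ridx[sdiag])]
    soff <- !is_edge & !is_diag
    g[soff] <- 2 * BWB[cbind(ridx[soff], cidx[soff])]
    g
  }
  list(fn = fn, gr = gr)
}

# OLS start values: per-equation regression slopes computed from the sample
# covariance, residual variances from the OLS fit, sample moments for the
# exogenous block. Free residual covariances start at zero.
ols_start <- function(model, C) {
  pt <- model$parameters
  theta <- numeric(nrow(pt))
  endo <- model$variables[model$roles == "endogenous"]
  slopes <- list()
  for (v in endo) {
    parents <- model$edges$from[model$edges$to == v]
    b <- solve(C[parents, parents, drop = FALSE], C[parents, v])
    slopes[[v]] <- setNames(as.numeric(b), parents)
  }
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]
    theta[k] <- switch(
      pt$type[k],
      edge = slopes[[i]][[j]],
      variance = if (i %in% endo) {
        parents <- names(slopes[[i]])
        max(C[i, i] - sum(slopes[[i]] * C[parents, i]), 1e-8)
      } else C[i, i],
      covariance = if (i %in% endo || j %in% endo) 0 else C[i, j]
    )
  }
  theta
}

#' Fit a recursive path model by maximum likelihood
#'
#' Minimizes the ML covariance-structure discrepancy over the free parameters
#' with quasi-Newton (BFGS) iterations started from per-equation OLS
#' estimates. Data are centered internally (no mean structure). Standard
#' errors come from the observed information, i.e. the inverse Hessian of
#' \eqn{\frac{n-1}{2} F_{ML}} at the optimum. The standardized solution
#' rescales every parameter by the model-implied standard deviations.
#'
#' @param data Data frame containing (at least) the model variables; rows
#'   with any missing model variable are dropped (listwise deletion).
#' @param model A [path_model()].
#' @param max_iter Iteration cap for the quasi-Newton optimizer.
#' @param grad_tol Convergence criterion: infinity norm of the gradient of
#'   \eqn{F_{ML}} at the solution.
#' @param se Logical; compute the Hessian-based parameter covariance.
#' @return An object of class `path_model_fit` with the parameter tibble
#'   (raw and standardized estimates, SEs, z and p), `implied`, `sample`
#'   covariance matrices, `n`, `f_min`, `chi2`, `df`, `converged`,
#'   `iterations`, and `vcov`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$m <- 0.5 * d$x + rnorm(200)
#' d$y <- 0.4 * d$m + 0.2 * d$x + rnorm(200)
#' fit <- fit_path_model(d, path_model(data.frame(
#'   from = c("x", "m", "x"), to = c("m", "y", "y"))))
#' tidy(fit)
#' @export
fit_path_model <- function(data, model, max_iter = 500, grad_tol = 1e-8,
                           se = TRUE) {
  stopifnot(inherits(model, "path_model"))
  missing_vars <- setdiff(model$variables, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("model variables not in data: ",
                 paste(missing_vars, collapse = ", ")),
          class = "pathmed_spec_error")
  }
  X <- as.matrix(as.data.frame(data)[model$variables])
  storage.mode(X) <- "double"
  keep <- complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort(sprintf("need more observations (%d) than variables (%d)", n, p),
          class = "pathmed_data_error")
  }
  C <- cov(X)
  if (determinant(C, logarithm = TRUE)$sign <= 0 || any(diag(C) <= 0)) {
    abort("sample covariance matrix is not positive definite",
          class = "pathmed_numeric_error")
  }

  obj <- ml_objective(model, C)
  theta0 <- ols_start(model, C)
  opt <- optim(theta0, obj$fn, obj$gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-14))
  g_norm <- max(abs(obj$gr(opt$par)))
  if (g_norm > grad_tol) {
    opt2 <- optim(opt$par, obj$fn, obj$gr, method = "BFGS",
                  control = list(maxit = max_iter, reltol = 1e-15))
    if (opt2$value <= opt$value) opt <- opt2
    g_norm <- max(abs(obj$gr(opt$par)))
  }
  theta_hat <- opt$par
  f_min <- obj$fn(theta_hat)
  converged <- g_norm <= grad_tol
  if (!converged) {
    warn(sprintf("optimizer did not reach gradient tolerance (|g| = %.2e)",
                 g_norm))
  }

  n_free <- length(theta_hat)
  df <- p * (p + 1) / 2 - n_free
  vcov_theta <- NULL
  se_theta <- rep(NA_real_, n_free)
  if (se) {
    H <- optimHess(theta_hat,
                   function(t) 0.5 * (n - 1) * obj$fn(t),
                   function(t) 0.5 * (n - 1) * obj$gr(t))
    vcov_theta <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      dv <- diag(vcov_theta)
      se_theta <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
    }
  }

  sigma <- implied_covariance(model, theta_hat)
  std <- standardize_theta(model, theta_hat)
  pt <- model$parameters
  est_tbl <- tibble(
    label = pt$label, type = pt$type, to = pt$row, from = pt$col,
    estimate = theta_hat, std_estimate = std,
    se = se_theta, statistic = theta_hat / se_theta,
    p_value = 2 * pnorm(-abs(theta_hat / se_theta))
  )

  structure(
    list(
      model = model, parameters = est_tbl, theta = theta_hat,
      implied = sigma, sample = C, n = n, f_min = f_min,
      chi2 = (n - 1) * f_min, df = df, converged = converged,
      iterations = opt$counts[["function"]], grad_norm = g_norm,
      vcov = vcov_theta, data = X
    ),
    class = "path_model_fit"
  )
}

# standardized solution as a function of theta (used by the delta method):
# edges are scaled by sd(from)/sd(to), variances become proportions of the
# target's implied variance, covariances become correlations.
standardize_theta <- function(model, theta) {
  sigma <- implied_covariance(model, theta)
  sds <- sqrt(diag(sigma))
  pt <- model$parameters
  out <- numeric(length(theta))
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]
    out[k] <- switch(pt$type[k],
      edge = theta[k] * sds[[j]] / sds[[i]],
      variance = theta[k] / sigma[i, i],
      covariance = theta[k] / (sds[[i]] * sds[[j]])
    )
  }
  out
}

#' @export
print.path_model_fit <- function(x, digits = 3, ...) {
  cat("<path_model_fit> n = ", x$n, ", free parameters = ",
      length(x$theta), "\n", sep = "")
  cat(sprintf("F_ML = %.6g, chi2(%d) = %.4g, converged: %s\n",
              x$f_min, x$df, x$chi2, x$converged))
  print(as.data.frame(x$parameters[x$parameters$type == "edge",
                                   c("label", "estimate", "std_estimate",
                                     "se", "p_value")]),
        digits = digits, row.names = FALSE)
  invisible(x)
}
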