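test_that("implied covariance reproduces closed forms", {
  # A = 0: Sigma equals S
  m <- path_model(data.frame(from = "x", to = "y"))
  idx_edge <- which(m$parameters$type == "edge")
  theta <- numeric(nrow(m$parameters))
  theta[m$parameters$type == "variance"] <- c(1.5, 2.5)[
    match(m$parameters$row[m$parameters$type == "variance"], c("x", "y"))]
  sigma0 <- implied_covariance(m, theta)
  expect_equal(sigma0["x", "x"], 1.5)
  expect_equal(sigma0["y", "y"], 2.5)
  expect_equal(sigma0["x", "y"], 0)

  # x -> y with slope b, Var(x) = 1, residual Var = 1:
  # Var(y) = 1 + b^2, Cov(x, y) = b
  b <- 0.7
  theta[idx_edge] <- b
  theta[m$parameters$type == "variance"] <- 1
  sigma <- implied_covariance(m, theta)
  expect_equal(sigma["y", "y"], 1 + b^2)
  expect_equal(sigma["x", "y"], b)
})

test_that("implied covariance matches brute-force simulation", {
  set.seed(101)
  paths <- random_recursive_paths(5, p_edge = 0.6, coef_max = 0.6)
  m <- path_model(paths[c("from", "to")])
  theta <- numeric(nrow(m$parameters))
  for (k in seq_len(nrow(m$parameters))) {
    pr <- m$parameters[k, ]
    theta[k] <- switch(pr$type,
      edge = paths$coef[paths$from == pr$col & paths$to == pr$row],
      variance = 1,
      covariance = 0)
  }
  sigma <- implied_covariance(m, theta)
  n_mc <- 1e6
  X <- as.matrix(simulate_recursive(paths, n_mc))[, m$variables]
  C <- cov(X)
  # MC standard error of each covariance entry
  se <- sqrt((outer(diag(sigma), diag(sigma)) + sigma^2) / n_mc)
  expect_true(all(abs(C - sigma) < 3.5 * se))
})

test_that("ML discrepancy satisfies its scalar formula and properties", {
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), log(2) + 1 / 2 - 1)
  s <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(s, s), 0)
  expect_error(ml_discrepancy(matrix(-1), matrix(1)),
               class = "pathmed_numeric_error")
  # F >= 0 over random PD pairs
  set.seed(7)
  for (i in 1:200) {
    p <- sample(2:4, 1)
    A1 <- matrix(rnorm(p * p), p); A2 <- matrix(rnorm(p * p), p)
    s1 <- crossprod(A1) + diag(p) * 0.1
    s2 <- crossprod(A2) + diag(p) * 0.1
    expect_gte(ml_discrepancy(s1, s2), -1e-10)
  }
})

test_that("saturated models fit perfectly with zero discrepancy", {
  set.seed(3)
  d <- simulate_recursive(
    data.frame(from = c("v1", "v2"), to = c("v2", "v3"),
               coef = c(0.5, 0.4)), 300)
  m <- path_model(data.frame(from = c("v1", "v1", "v2"),
                             to = c("v2", "v3", "v3")))
  fit <- fit_path_model(d, m)
  expect_true(fit$converged)
  expect_equal(fit$df, 0)
  expect_lt(abs(fit$f_min), 1e-10)
  expect_equal(unname(fit$implied), unname(fit$sample), tolerance = 1e-6)
})

test_that("ML estimates equal per-equation OLS for recursive models", {
  # known equivalence for recursive systems with uncorrelated residuals;
  # lm() on the raw data is the independent oracle
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    paths <- random_recursive_paths(k)
    d <- simulate_recursive(paths, 150)
    m <- path_model(paths[c("from", "to")])
    fit <- fit_path_model(d, m)
    expect_true(fit$converged)
    for (v in unique(paths$to)) {
      parents <- paths$from[paths$to == v]
      ols <- stats::lm(stats::reformulate(parents, v), data = d)
      got <- fit$parameters[fit$parameters$type == "edge" &
                              fit$parameters$to == v, ]
      expect_equal(setNames(got$estimate, got$from),
                   coef(ols)[got$from], tolerance = 1e-6)
    }
  }
})

test_that("estimates are invariant to variable order and affine rescaling", {
  set.seed(9)
  paths <- data.frame(from = c("x", "x", "m"), to = c("m", "y", "y"),
                      coef = c(0.5, 0.2, 0.4))
  d <- simulate_recursive(paths, 400)
  m1 <- path_model(paths[c("from", "to")], variables = c("x", "m", "y"))
  m2 <- path_model(paths[3:1, c("from", "to")], variables = c("y", "m", "x"))
  f1 <- fit_path_model(d, m1)
  f2 <- fit_path_model(d, m2)
  expect_equal(f1$f_min, f2$f_min, tolerance = 1e-9)

  # affine rescaling of observed variables leaves the standardized solution
  d_resc <- transform(d, x = 3 * x - 2, y = y / 10 + 5)
  f3 <- fit_path_model(d_resc, m1)
  key <- function(f) {
    e <- f$parameters[f$parameters$type == "edge", ]
    setNames(e$std_estimate, e$label)
  }
  expect_equal(key(f3), key(f1), tolerance = 1e-6)
})

test_that("degenerate inputs are refused with informative errors", {
  m <- path_model(data.frame(from = "x", to = "y"))
  tiny <- data.frame(x = rnorm(2), y = rnorm(2))
  expect_error(fit_path_model(tiny, m), class = "pathmed_data_error")
  const <- data.frame(x = rep(1, 50), y = rnorm(50))
  expect_error(fit_path_model(const, m), class = "pathmed_numeric_error")
  expect_error(fit_path_model(data.frame(x = rnorm(50)), m),
               regexp = "not in data")
})

test_that("delta-method SEs in a two-edge chain match the Sobel formula", {
  set.seed(21)
  d <- simulate_recursive(
    data.frame(from = c("x", "m"), to = c("m", "y"), coef = c(0.5, 0.4)),
    800)
  fit <- fit_path_model(d, path_model(data.frame(from = c("x", "m"),
                                                 to = c("m", "y"))))
  res <- indirect_se(fit, c("x", "m", "y"), method = "delta")
  e <- tidy(fit)
  a <- e[e$term == "x->m", ]; b <- e[e$term == "m->y", ]
  # raw-scale Sobel with independent a, b as an order-of-magnitude oracle
  sobel <- sqrt(a$estimate^2 * b$std.error^2 + b$estimate^2 * a$std.error^2)
  expect_equal(res$se, sobel, tolerance = 0.15)
  expect_gt(res$se, 0)
})
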