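test_that("the core mediation graph has the expected path inventory", {
  m <- bp_model("ara", "sbp_z")
  paths <- enumerate_paths(m, "snp", "sbp_z")
  expect_length(paths, 4)  # 1 direct + 3 mediated
  expect_setequal(
    canonical_path_set(paths),
    c("snp>sbp_z", "snp>ara>sbp_z", "snp>bmi_z>sbp_z",
      "snp>ara>bmi_z>sbp_z"))
  # disconnected pair
  m2 <- path_model(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_length(enumerate_paths(m2, "a", "d"), 0)
  expect_error(enumerate_paths(m2, "a", "nope"), regexp = "unknown variable")
})

test_that("path enumeration matches a DFS oracle on random DAGs", {
  set.seed(314)
  for (r in 1:1000) {
    k <- sample(3:8, 1)
    edges <- random_dag(k, p_edge = runif(1, 0.2, 0.6))
    vars <- paste0("v", seq_len(k))
    pick <- sample(vars, 2)
    got <- enumerate_paths(
      path_model(edges, variables = vars), pick[1], pick[2])
    want <- oracle_paths(edges, pick[1], pick[2])
    expect_identical(canonical_path_set(got), canonical_path_set(want))
  }
})

test_that("decomposition reproduces published-coefficient worked examples", {
  printed <- published_path_coefficients("2a")[c("from", "to", "estimate")]
  dec <- decompose_effects(printed, "snp", "sbp_z")
  expect_equal(
    round(dec$estimate[dec$effect_type == "indirect_total"], 3), -0.057)
  expect_equal(round(dec$estimate[dec$effect_type == "total"], 3), 0.020)
  # single-edge model: total indirect 0, total = direct
  one <- data.frame(from = "x", to = "y", estimate = 0.3)
  d1 <- decompose_effects(one, "x", "y")
  expect_equal(d1$estimate[d1$effect_type == "indirect_total"], 0)
  expect_equal(d1$estimate[d1$effect_type == "total"], 0.3)
})

test_that("total = direct + sum of path products, machine-exact", {
  set.seed(88)
  for (r in 1:50) {
    paths <- random_recursive_paths(sample(4:7, 1), p_edge = 0.5)
    tbl <- data.frame(from = paths$from, to = paths$to,
                      estimate = paths$coef)
    vars <- unique(c(paths$from, paths$to))
    pick <- sample(vars, 2)
    dec <- decompose_effects(tbl, pick[1], pick[2])
    direct <- dec$estimate[dec$effect_type == "direct"]
    products <- dec$estimate[dec$effect_type == "indirect_path"]
    expect_identical(dec$estimate[dec$effect_type == "indirect_total"],
                     sum(products))
    expect_identical(dec$estimate[dec$effect_type == "total"],
                     direct + sum(products))
  }
})

test_that("missing edge coefficients raise an error naming the edge", {
  tbl <- data.frame(from = c("x", "m"), to = c("m", "y"),
                    estimate = c(0.5, NA))
  expect_error(decompose_effects(tbl, "x", "y"), regexp = "m -> y")
})

test_that("delta-method p-values do not depend on path summation order", {
  set.seed(31)
  paths <- data.frame(from = c("x", "x", "m1", "m2", "x"),
                      to = c("m1", "m2", "y", "y", "y"),
                      coef = c(0.5, 0.4, 0.3, 0.25, 0.1))
  d <- simulate_recursive(paths, 600)
  fit <- fit_path_model(d, path_model(paths[c("from", "to")]))
  p1 <- list(c("x", "m1", "y"), c("x", "m2", "y"))
  p2 <- rev(p1)
  r1 <- indirect_se(fit, p1, method = "delta")
  r2 <- indirect_se(fit, p2, method = "delta")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-12)
})

test_that("a null first leg drives the delta statistic toward zero", {
  set.seed(77)
  d <- data.frame(x = rnorm(500))
  d$m <- rnorm(500)               # a = 0 exactly in truth
  d$y <- 0.5 * d$m + rnorm(500)
  fit <- fit_path_model(d, path_model(data.frame(from = c("x", "m"),
                                                 to = c("m", "y"))))
  res <- indirect_se(fit, c("x", "m", "y"), method = "delta")
  expect_lt(abs(res$statistic), 2.5)
  expect_gt(res$p_value, 0.01)
})

test_that("delta and bootstrap SEs agree for a mediated effect", {
  set.seed(55)
  d <- simulate_recursive(
    data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"),
               coef = c(0.5, 0.4, 0.2)), 10000)
  fit <- fit_path_model(d, path_model(data.frame(
    from = c("x", "m", "x"), to = c("m", "y", "y"))))
  delta <- indirect_se(fit, c("x", "m", "y"), method = "delta")
  boot <- indirect_se(fit, c("x", "m", "y"), method = "bootstrap",
                      B = 400, seed = 99)
  expect_lt(abs(delta$se - boot$se) / delta$se, 0.15)
  expect_error(indirect_se(fit, c("x", "m", "y"), method = "bootstrap",
                           B = 50), regexp = "B >= 100")
})

test_that("decompose_effects on a fitted model carries inference columns", {
  set.seed(13)
  d <- simulate_recursive(
    data.frame(from = c("x", "m", "x"), to = c("m", "y", "y"),
               coef = c(0.5, 0.4, 0.2)), 500)
  fit <- fit_path_model(d, path_model(data.frame(
    from = c("x", "m", "x"), to = c("m", "y", "y"))))
  dec <- decompose_effects(fit, "x", "y", se = "delta")
  expect_true(all(c("se", "statistic", "p_value") %in% names(dec)))
  expect_true(all(dec$se[!is.na(dec$se)] > 0))
  tot <- dec[dec$effect_type == "total", ]
  expect_equal(tot$estimate,
               sum(dec$estimate[dec$effect_type %in%
                                  c("direct", "indirect_path")]))
})
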