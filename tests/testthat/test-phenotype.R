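test_that("additive coding counts minor alleles, order-insensitively", {
  expect_identical(encode_additive(c("CC", "CT", "TT")), c(0L, 1L, 2L))
  expect_identical(encode_additive("TC"), 1L)
  expect_identical(encode_additive(c("CC", NA, "")), c(0L, NA, NA))
  expect_error(encode_additive("CA"), class = "pathmed_parse_error")
  expect_error(encode_additive("C"), class = "pathmed_parse_error")
})

test_that("call-rate filter retains strictly above threshold", {
  g <- matrix("CC", nrow = 3, ncol = 100,
              dimnames = list(c("s97", "s99", "s100"), NULL))
  g[1, 1:3] <- NA   # 97/100 calls: excluded (0.97 <= 0.98)
  g[2, 1] <- NA     # 99/100 calls: retained (0.99 > 0.98)
  res <- call_rate_filter(g)
  expect_identical(res$retained, c(FALSE, TRUE, TRUE))
  expect_error(call_rate_filter(matrix(nrow = 0, ncol = 0)),
               class = "pathmed_data_error")
})

test_that("genotype summary reproduces reported sample arithmetic", {
  gs <- genotype_summary(rep(c(0L, 1L, 2L), c(266, 206, 48)))
  expect_equal(gs$maf, 0.2904, tolerance = 1e-4)
  expect_equal(round(100 * gs$maf), 29)
  # hand evaluation of the chi-square on expected counts 261.85/214.30/43.85
  expect_equal(unname(gs$expected), c(261.85, 214.30, 43.85),
               tolerance = 1e-3)
  expect_equal(gs$hwe_chi2, 0.780, tolerance = 0.005)
  expect_equal(gs$hwe_p, 0.377, tolerance = 0.005)
  # the reported p = 0.395 comes from the exact test
  expect_equal(gs$hwe_exact_p, 0.395, tolerance = 0.005)
})

test_that("genotype summary invariants hold", {
  set.seed(10)
  codes <- generate_genotypes(400, 0.3)
  gs1 <- genotype_summary(codes)
  gs2 <- genotype_summary(sample(codes))
  expect_identical(gs1$maf, gs2$maf)           # order-invariant
  # exact HWE proportions: chi2 = 0, p = 1
  exact <- rep(c(0L, 1L, 2L), c(49, 42, 9))    # p = 0.3, n = 100
  gs3 <- genotype_summary(exact)
  expect_equal(gs3$hwe_chi2, 0, tolerance = 1e-10)
  expect_equal(gs3$hwe_p, 1)
  expect_error(genotype_summary(c(NA_integer_, NA_integer_)),
               class = "pathmed_data_error")
  expect_error(genotype_summary(c(0L, 3L)), class = "pathmed_parse_error")
})

test_that("blood-pressure consolidation follows the smallest-pair rule", {
  expect_equal(consolidate_bp(100, 104), 102)        # 4% <= 5%
  expect_true(is.na(consolidate_bp(100, 106)))       # 6% > 5%, no third
  expect_equal(consolidate_bp(100, 106, 105), 105.5) # closest pair wins
  expect_true(is.na(consolidate_bp(100)))            # single reading
  expect_error(consolidate_bp(-5, 100), class = "pathmed_data_error")
})

test_that("three-reading consolidation is permutation-invariant", {
  set.seed(12)
  for (r in 1:200) {
    readings <- round(runif(3, 80, 130), 1)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    vals <- vapply(perms, function(p) {
      consolidate_bp(readings[p[1]], readings[p[2]], readings[p[3]])
    }, numeric(1))
    expect_equal(max(vals) - min(vals), 0)
  }
})

test_that("blood-pressure classification is monotone in percentiles", {
  expect_identical(as.character(classify_bp(c(50, 92, 96), c(50, 50, 50))),
                   c("normal", "prehypertension", "hypertension"))
  # driven by the worse of the two readings
  expect_identical(as.character(classify_bp(50, 97)), "hypertension")
  expect_true(is.na(classify_bp(NA, NA)))
  set.seed(3)
  for (r in 1:100) {
    s <- runif(1, 1, 99); d <- runif(1, 1, 99)
    base <- classify_bp(s, d)
    up <- classify_bp(min(s + runif(1, 0, 30), 99.9), d)
    expect_gte(as.integer(up), as.integer(base))
  }
  expect_error(classify_bp(101, 50), class = "pathmed_data_error")
})

test_that("desaturase index and BMI formulas", {
  expect_equal(d5d_index(7.0, 1.4), 5.0)
  expect_equal(d5d_index(3.3, 3.3), 1.0)
  # ratio of the reported mean FA levels; distinct from the reported mean
  # D5D (6.32), which averages per-subject ratios
  expect_equal(d5d_index(7.53, 1.22), 6.172, tolerance = 1e-3)
  expect_error(d5d_index(7, 0), class = "pathmed_data_error")
  expect_equal(bmi(16, 1.0), 16.0)
  expect_equal(bmi(20, 1.25), 12.8)
  expect_error(bmi(0, 1.2), class = "pathmed_data_error")
})
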