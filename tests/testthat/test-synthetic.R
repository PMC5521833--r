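test_that("genotype generator respects HWE and the configured MAF", {
  g <- generate_genotypes(520, 0.29, seed = 1)
  expect_true(all(g %in% 0:2))
  maf_hat <- mean(g) / 2
  # binomial sampling error of the allele frequency at n = 520
  se <- sqrt(0.29 * 0.71 / (2 * 520))
  expect_lt(abs(maf_hat - 0.29), 3 * se)

  big <- generate_genotypes(1e5, 0.5, seed = 2)
  freq <- as.numeric(table(factor(big, levels = 0:2))) / 1e5
  se3 <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se3))

  expect_error(generate_genotypes(10, 0), class = "pathmed_invalid_parameter")
  expect_error(generate_genotypes(10, 1), class = "pathmed_invalid_parameter")
})

test_that("generated genotypes pass the HWE test across seeds", {
  # calibration: HWE holds by construction, so rejections at alpha = 0.001
  # should be about 1 per 1000; require >= 99/100 seeds passing
  pass <- vapply(1:100, function(s) {
    g <- generate_genotypes(520, 0.29, seed = s)
    genotype_summary(g)$hwe_p > 0.001
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(maf = 1.2), class = "pathmed_invalid_parameter")
  cyc <- data.frame(from = c("a", "b"), to = c("b", "a"), coef = c(1, 1))
  expect_error(synthetic_config(std_paths = cyc), class = "pathmed_cycle_error")
  big <- data.frame(from = c("a", "b"), to = c("y", "y"), coef = c(0.9, 0.9))
  expect_error(synthetic_config(std_paths = big),
               class = "pathmed_invalid_parameter")
})

test_that("standardized generation hits unit variances and the configured
           single-parent slope", {
  cfg <- synthetic_config(n_subjects = 1e5, seed = 77)
  out <- generate_cohort(cfg)
  z <- out$cohort[paste0(c("ara", "bmi_z", "sbp_z"), "_std")]
  mc_se <- sqrt(2 / 1e5)  # SE of a unit-normal sample variance
  for (v in names(z)) {
    expect_lt(abs(var(z[[v]]) - 1), 3 * mc_se)
  }
  # ARA has the SNP as its only parent: the correlation equals the
  # configured standardized coefficient (-0.237) up to MC error
  r <- cor(out$cohort$snp_std, out$cohort$ara_std)
  expect_lt(abs(r - (-0.237)), 3 / sqrt(1e5))
  # slope of the standardized regression equals the coefficient
  b <- coef(lm(ara_std ~ snp_std, data = out$cohort))[["snp_std"]]
  expect_lt(abs(b - (-0.237)), 3 / sqrt(1e5))
})

test_that("empty path set gives mutually independent variables", {
  cfg <- synthetic_config(
    n_subjects = 2e4,
    std_paths = data.frame(from = character(), to = character(),
                           coef = numeric()),
    seed = 5)
  out <- generate_cohort(cfg)
  z <- as.matrix(out$cohort[paste0(c("dgla", "ara", "epa", "bmi_z"), "_std")])
  cc <- cor(z)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3.5 / sqrt(2e4)))
})

test_that("marginal rescaling reproduces the configured means and SDs", {
  cfg <- synthetic_config(n_subjects = 5e4, seed = 8)
  out <- generate_cohort(cfg)
  marg <- default_marginals()
  for (k in seq_len(nrow(marg))) {
    v <- marg$variable[k]
    expect_lt(abs(mean(out$cohort[[v]]) - marg$mean[k]),
              4 * marg$sd[k] / sqrt(5e4))
    expect_lt(abs(sd(out$cohort[[v]]) - marg$sd[k]), 0.02 * marg$sd[k])
  }
})

test_that("ledger totals satisfy total = direct + sum(indirect) exactly", {
  led <- ground_truth_ledger(default_std_paths("2a"))
  for (k in seq_len(nrow(led$total))) {
    row <- led$total[k, ]
    prods <- led$indirect$product[led$indirect$source == row$source &
                                    led$indirect$target == row$target]
    expect_identical(row$total, row$direct + sum(prods))
  }
  # the SNP -> SBP entry decomposes into 1 direct + 3 mediated paths
  snp_sbp <- led$indirect[led$indirect$source == "snp" &
                            led$indirect$target == "sbp_z", ]
  expect_equal(nrow(snp_sbp), 3)
})

test_that("ledgers survive the JSON round trip", {
  led <- ground_truth_ledger(default_std_paths("1a"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_equal(as.data.frame(back$total), as.data.frame(led$total))
  expect_equal(as.data.frame(back$indirect), as.data.frame(led$indirect))
})

test_that("cohorts are bit-reproducible under a fixed seed and round-trip
           through the delimited format", {
  cfg <- synthetic_config(n_subjects = 200, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$snp, a$cohort$snp)
  expect_equal(back$ara, a$cohort$ara, tolerance = 1e-12)
})

test_that("stratified generation reproduces stratum-specific slopes", {
  cfg <- stratified_epa_config(seed = 33)
  out <- generate_stratified_cohort(cfg, n_per_stratum = c(316, 204) * 50)
  coh <- out$cohort
  for (s in c(0, 1)) {
    sub <- coh[coh$weight_status == s, ]
    b <- coef(lm(bmi_z_std ~ epa_std + snp_std, data = sub))[["epa_std"]]
    truth <- if (s == 0) -0.206 else 0.535
    expect_lt(abs(b - truth), 0.03)
    expect_equal(sign(b), sign(truth))
  }
  expect_identical(sort(unique(coh$weight_status)), c(0L, 1L))
  # per-stratum ledgers carry the stratum-specific EPA -> BMI truth
  l0 <- out$ledgers[["0"]]$direct
  l1 <- out$ledgers[["1"]]$direct
  expect_equal(l0$coef[l0$from == "epa" & l0$to == "bmi_z"], -0.206)
  expect_equal(l1$coef[l1$from == "epa" & l1$to == "bmi_z"], 0.535)
})

test_that("stratified generation guards its preconditions", {
  cfg <- synthetic_config(seed = 2)          # no stratum block
  expect_error(generate_stratified_cohort(cfg),
               class = "pathmed_invalid_parameter")
  cfg2 <- stratified_epa_config(seed = 2)
  expect_error(generate_stratified_cohort(cfg2, n_per_stratum = c(0, 100)),
               class = "pathmed_invalid_parameter")
  bad <- cfg2
  bad$stratum$paths <- bad$stratum$paths["0"]
  expect_error(
    synthetic_config(stratum = list(paths = bad$stratum$paths)),
    class = "pathmed_invalid_parameter")
})

test_that("identical stratum coefficients leave the pooled fit unbiased", {
  cfg <- stratified_epa_config(seed = 19, n_subjects = 4e4)
  same <- default_stratum_paths("sbp_z")
  same[["1"]] <- same[["0"]]
  cfg$stratum$paths <- same
  out <- generate_stratified_cohort(cfg)
  b <- coef(lm(bmi_z_std ~ epa_std + snp_std, data = out$cohort))[["epa_std"]]
  expect_lt(abs(b - (-0.206)), 0.03)
})
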