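#' Additive genotype coding
#'
#' Encodes biallelic genotype calls as the number of minor-allele copies
#' (0, 1 or 2). Order-insensitive ("CT" and "TC" both code 1); missing calls
#' (`NA` or `""`) propagate as `NA`.
#'
#' @param calls Character vector of two-letter genotype calls.
#' @param minor,major Single-character allele symbols (defaults T minor /
#'   C major, the rs174546 convention).
#' @return Integer vector of codes in `{0, 1, 2}` with `NA` for missing.
#' @examples
#' encode_additive(c("CC", "CT", "TC", "TT", NA))
#' @export
encode_additive <- function(calls, minor = "T", major = "C") {
  calls <- as.character(calls)
  out <- rep(NA_integer_, length(calls))
  present <- !is.na(calls) & nzchar(calls)
  alleles <- strsplit(toupper(calls[present]), "")
  bad <- vapply(alleles, function(a) {
    length(a) != 2 || !all(a %in% c(minor, major))
  }, logical(1))
  if (any(bad)) {
    abort(sprintf("invalid genotype call `%s`: alleles must be in {%s, %s}",
                  calls[present][bad][1], major, minor),
          class = "pathmed_parse_error")
  }
  out[present] <- vapply(alleles, function(a) sum(a == minor), integer(1))
  out
}

#' Sample call-rate filter
#'
#' Retains subjects whose fraction of non-missing genotype calls is strictly
#' greater than `threshold` (subjects at or below the threshold are
#' excluded, mirroring an "excluded for call rate <= 0.98" rule).
#'
#' @param genotypes Matrix or data frame, subjects in rows and markers in
#'   columns; `NA` marks a missing call.
#' @param threshold Minimum call-rate fraction (exclusive), default 0.98.
#' @return A tibble with `subject`, `n_called`, `n_markers`, `call_rate`,
#'   `retained`.
#' @export
call_rate_filter <- function(genotypes, threshold = 0.98) {
  g <- as.matrix(genotypes)
  if (nrow(g) == 0 || ncol(g) == 0) {
    abort("genotype matrix is empty", class = "pathmed_data_error")
  }
  called <- unname(rowSums(!is.na(g) & g != ""))
  rate <- called / ncol(g)
  tibble(
    subject = rownames(g) %||% as.character(seq_len(nrow(g))),
    n_called = as.integer(called),
    n_markers = ncol(g),
    call_rate = rate,
    retained = rate > threshold
  )
}

# Exact Hardy-Weinberg test (Wigginton, Cutler & Abecasis style): enumerate
# all heterozygote counts compatible with the observed allele counts, and sum
# the probabilities of configurations no more likely than the observed one.
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  rare <- 2L * n_hom_rare + n_het
  if (rare > n) { # make "rare" the actual minor allele count
    rare <- 2L * n - rare
  }
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # unnormalized log-probabilities of each possible het count
  lp <- vapply(hets, function(h) {
    ra <- (rare - h) %/% 2L
    co <- n - h - ra
    lgamma(n + 1) - lgamma(h + 1) - lgamma(ra + 1) - lgamma(co + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- min(n_het, rare)
  p_obs <- pr[match(obs, hets)]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

#' Genotype summary: counts, minor allele frequency, Hardy-Weinberg tests
#'
#' From additive genotype codes computes the genotype counts, the frequency
#' of the coded (minor) allele, and a test of Hardy-Weinberg equilibrium: by
#' default the 1-df chi-square test against the HWE-expected counts
#' \eqn{(q^2 N, 2pqN, p^2 N)}; an exact-test p-value is always reported
#' alongside.
#'
#' @param codes Integer vector of additive codes in `{0, 1, 2}` (`NA`
#'   allowed).
#' @return A list of class `genotype_summary`: `counts` (named 0/1/2),
#'   `n`, `maf`, `major_freq`, `hwe_chi2`, `hwe_p` (chi-square),
#'   `hwe_exact_p`.
#' @examples
#' genotype_summary(rep(c(0L, 1L, 2L), c(266, 206, 48)))
#' @export
genotype_summary <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    abort("no non-missing genotype codes", class = "pathmed_data_error")
  }
  if (!all(codes %in% 0:2)) {
    abort("genotype codes must be 0, 1 or 2", class = "pathmed_parse_error")
  }
  counts <- c(`0` = sum(codes == 0), `1` = sum(codes == 1),
              `2` = sum(codes == 2))
  n <- sum(counts)
  p <- (counts[["1"]] + 2 * counts[["2"]]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (p == 0 || p == 1) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(
    list(
      counts = counts, n = as.integer(n), maf = as.numeric(p),
      major_freq = as.numeric(1 - p),
      expected = setNames(expected, names(counts)),
      hwe_chi2 = as.numeric(chi2),
      hwe_p = pchisq(chi2, df = 1, lower.tail = FALSE),
      hwe_exact_p = hwe_exact_p(counts[["1"]], counts[["2"]], counts[["0"]])
    ),
    class = "genotype_summary"
  )
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf(
    "<genotype_summary> N = %d; counts 0/1/2 = %d/%d/%d; MAF = %.4f\n",
    x$n, x$counts[["0"]], x$counts[["1"]], x$counts[["2"]], x$maf))
  cat(sprintf("HWE chi2(1) = %.3f, p = %.3f (exact p = %.3f)\n",
              x$hwe_chi2, x$hwe_p, x$hwe_exact_p))
  invisible(x)
}

#' Consolidate repeated blood-pressure readings
#'
#' With three readings, returns the mean of the pair with the smallest
#' absolute difference (ties broken toward the pair with the smaller mean,
#' which makes the rule permutation-invariant). With two readings, returns
#' their mean if they agree within `tol` (relative to the first reading),
#' otherwise missing — the "third measurement would have been needed" case.
#' A single reading is never used: missing.
#'
#' @param r1,r2,r3 Numeric vectors of readings in mmHg (`NA` = not taken).
#' @param tol Maximum relative deviation between two readings, default 0.05.
#' @return Numeric vector of consolidated pressures (mmHg), `NA` where the
#'   rule yields missing.
#' @examples
#' consolidate_bp(c(100, 100, 100), c(104, 106, 106), c(NA, NA, 105))
#' @export
consolidate_bp <- function(r1, r2 = NULL, r3 = NULL, tol = 0.05) {
  n <- length(r1)
  r2 <- r2 %||% rep(NA_real_, n)
  r3 <- r3 %||% rep(NA_real_, n)
  stopifnot(length(r2) == n, length(r3) == n)
  readings <- cbind(r1, r2, r3)
  if (any(readings <= 0, na.rm = TRUE)) {
    abort("blood-pressure readings must be positive",
          class = "pathmed_data_error")
  }
  apply(readings, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) <= 1) return(NA_real_)
    if (length(r) == 2) {
      return(if (abs(r[1] - r[2]) / r[1] <= tol) mean(r) else NA_real_)
    }
    pairs <- utils::combn(3, 2)
    diffs <- abs(r[pairs[1, ]] - r[pairs[2, ]])
    means <- (r[pairs[1, ]] + r[pairs[2, ]]) / 2
    best <- which(diffs == min(diffs))
    mean_val <- min(means[best])
    mean_val
  })
}

#' Classify blood pressure from percentiles
#'
#' Pediatric scheme on reference percentiles: the category is driven by the
#' worse of the systolic and diastolic percentiles — at or above the upper
#' cutpoint (default 95th) hypertension, at or above the lower cutpoint
#' (default 90th) prehypertension, otherwise normal. Both percentiles
#' missing gives a missing category.
#'
#' @param sbp_pct,dbp_pct Percentiles in (0, 100); `NA` allowed.
#' @param cutpoints Length-2 numeric, lower and upper percentile cutpoints.
#' @return Ordered factor with levels `normal < prehypertension <
#'   hypertension`.
#' @examples
#' classify_bp(c(50, 92, 96), c(50, 50, 50))
#' @export
classify_bp <- function(sbp_pct, dbp_pct, cutpoints = c(90, 95)) {
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2])
  ok <- function(x) is.na(x) | (x > 0 & x < 100)
  if (!all(ok(sbp_pct)) || !all(ok(dbp_pct))) {
    abort("percentiles must lie in (0, 100)", class = "pathmed_data_error")
  }
  worst <- pmax(sbp_pct, dbp_pct, na.rm = TRUE)
  worst[is.na(sbp_pct) & is.na(dbp_pct)] <- NA_real_
  cat_chr <- dplyr::case_when(
    is.na(worst) ~ NA_character_,
    worst >= cutpoints[2] ~ "hypertension",
    worst >= cutpoints[1] ~ "prehypertension",
    TRUE ~ "normal"
  )
  factor(cat_chr, levels = c("normal", "prehypertension", "hypertension"),
         ordered = TRUE)
}

#' Delta-5 desaturase activity index
#'
#' Product-precursor ratio of arachidonic acid (20:4n-6) to
#' dihomo-gamma-linolenic acid (20:3n-6), both as weight percentages of all
#' fatty acids detected. A proxy for delta-5 desaturase enzyme activity.
#'
#' @param ara,dgla Numeric vectors of fatty-acid weight percentages.
#' @return `ara / dgla`.
#' @examples
#' d5d_index(7.0, 1.4)
#' @export
d5d_index <- function(ara, dgla) {
  if (any(dgla <= 0, na.rm = TRUE)) {
    abort("DGLA must be positive", class = "pathmed_data_error")
  }
  ara / dgla
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in m.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(20, 1.25)
#' @export
bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    abort("weight and height must be positive", class = "pathmed_data_error")
  }
  weight / height^2
}
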