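#' Configuration for the synthetic cohort generator
#'
#' The generator works on the standardized scale: every endogenous variable
#' is built recursively as \eqn{z_i = \sum_j \beta_{ij} z_j + \varepsilon_i}
#' with residual SD \eqn{\sqrt{1 - R_i^2}} chosen analytically so that
#' \eqn{Var(z_i) = 1}, which makes the configured standardized coefficients
#' the exact generating truth. The genotype is drawn as binomial(2, maf) —
#' Hardy-Weinberg by construction — and standardized by its binomial moments
#' \eqn{(G - 2p)/\sqrt{2p(1-p)}}. Standardized variables are then rescaled to
#' the configured raw-scale marginals.
#'
#' @param n_subjects Cohort size (default 520, the analysis-sample size the
#'   defaults are calibrated to).
#' @param maf Minor allele frequency in (0, 1); default 0.29.
#' @param std_paths Data frame (`from`, `to`, `coef`) of generating
#'   standardized coefficients; default: the published ARA/systolic model
#'   (see [published_path_coefficients()]).
#' @param marginals Data frame (`variable`, `mean`, `sd`) of raw-scale
#'   marginals; defaults to [default_marginals()]. Variables without a
#'   marginal stay standardized. The genotype column is emitted raw (0/1/2).
#' @param covariates Optional list of covariate specs, each a list with
#'   `name`, `kind` (`"binary"`, `"categorical"`, `"continuous"`) and
#'   parameters (`prevalence`; `levels` + `probs`; `mean` + `sd`).
#'   Covariates are generated independently with zero structural effect
#'   unless they appear in `std_paths`.
#' @param stratum Optional stratification spec: list with `var` (label
#'   column name), `prevalence` (probability of stratum 1; default 204/520),
#'   and `paths`, a named list of two data frames (`"0"`, `"1"`) of
#'   stratum-specific coefficient overrides.
#' @param genotype_var Name of the genotype variable (default `"snp"`).
#' @param seed Single integer seed; all draws flow from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 520, maf = 0.29,
                             std_paths = default_std_paths(),
                             marginals = default_marginals(),
                             covariates = NULL, stratum = NULL,
                             genotype_var = "snp", seed = 1) {
  if (!(maf > 0 && maf < 1)) {
    abort("`maf` must lie strictly in (0, 1)", class = "pathmed_invalid_parameter")
  }
  if (n_subjects < 1) {
    abort("`n_subjects` must be positive", class = "pathmed_invalid_parameter")
  }
  std_paths <- check_path_frame(std_paths)
  vars <- unique(c(std_paths$from, std_paths$to, genotype_var,
                   marginals$variable))
  topological_order(vars, std_paths)        # recursive check
  implied_std_covariance(vars, std_paths)   # residual-variance check (R^2 < 1)
  if (!is.null(stratum)) {
    if (is.null(stratum$paths) || !all(c("0", "1") %in% names(stratum$paths))) {
      abort("`stratum$paths` must name both strata \"0\" and \"1\"",
            class = "pathmed_invalid_parameter")
    }
    stratum$prevalence <- stratum$prevalence %||% (204 / 520)
    stratum$paths <- lapply(stratum$paths, check_path_frame)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), maf = maf,
         std_paths = std_paths, marginals = as_tibble(marginals),
         covariates = covariates, stratum = stratum,
         genotype_var = genotype_var, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

check_path_frame <- function(std_paths) {
  std_paths <- check_edge_frame(std_paths, "std_paths")
  if (!"coef" %in% names(std_paths)) {
    abort("`std_paths` needs a `coef` column", class = "pathmed_invalid_parameter")
  }
  as_tibble(std_paths[c("from", "to", "coef")])
}

# Analytic covariance of the standardized system assuming unit-variance,
# mutually uncorrelated exogenous variables. Errors if any implied R^2 >= 1.
implied_std_covariance <- function(vars, std_paths) {
  ord <- topological_order(vars, std_paths)
  sigma <- diag(length(vars))
  dimnames(sigma) <- list(vars, vars)
  resid <- setNames(rep(1, length(vars)), vars)
  for (v in ord) {
    parents <- std_paths$from[std_paths$to == v]
    if (length(parents) == 0) next
    b <- std_paths$coef[std_paths$to == v]
    r2 <- drop(t(b) %*% sigma[parents, parents, drop = FALSE] %*% b)
    if (r2 >= 1) {
      abort(sprintf("implied R^2 for `%s` is %.3f >= 1: residual variance not positive",
                    v, r2), class = "pathmed_invalid_parameter")
    }
    resid[[v]] <- 1 - r2
    cv <- drop(sigma[, parents, drop = FALSE] %*% b)
    sigma[, v] <- cv
    sigma[v, ] <- cv
    sigma[v, v] <- 1
  }
  list(sigma = sigma, resid = resid, order = ord)
}

#' Draw additive genotype codes under Hardy-Weinberg equilibrium
#'
#' Each subject's code is binomial(2, maf): the number of minor-allele
#' copies, so genotype frequencies are in HWE proportions by construction.
#'
#' @param n Number of subjects.
#' @param maf Minor allele frequency in (0, 1).
#' @param seed Optional seed.
#' @return Integer vector of codes in `{0, 1, 2}`.
#' @examples
#' table(generate_genotypes(1000, 0.29, seed = 7))
#' @export
generate_genotypes <- function(n, maf, seed = NULL) {
  if (!(maf > 0 && maf < 1)) {
    abort("`maf` must lie strictly in (0, 1)", class = "pathmed_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 2L, maf)
}

#' Generate a synthetic cohort with a ground-truth effect ledger
#'
#' Simulates a cohort under the structural model in `config$std_paths` (see
#' [synthetic_config()] for the construction) and returns both the cohort
#' table and a ledger of the generating direct effects, every implied
#' mediated path product, and their totals — the totals satisfy
#' `total = direct + sum(indirect)` exactly, by construction.
#'
#' @param config A [synthetic_config()].
#' @param std_paths_override Internal: replaces `config$std_paths` (used for
#'   stratified generation).
#' @param n_override,seed_override Internal: per-stratum size and seed.
#' @return A list with `cohort` (tibble: `subject`, genotype code column,
#'   raw-scale variables, `<var>_std` standardized columns, covariates) and
#'   `ledger` (see [ground_truth_ledger()]).
#' @export
generate_cohort <- function(config, std_paths_override = NULL,
                            n_override = NULL, seed_override = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  std_paths <- std_paths_override %||% config$std_paths
  n <- n_override %||% config$n_subjects
  set.seed(seed_override %||% config$seed)

  gvar <- config$genotype_var
  vars <- unique(c(std_paths$from, std_paths$to, gvar,
                   config$marginals$variable))
  impl <- implied_std_covariance(vars, std_paths)

  z <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  geno <- generate_genotypes(n, config$maf)
  p <- config$maf
  for (v in impl$order) {
    parents <- std_paths$from[std_paths$to == v]
    if (v == gvar) {
      if (length(parents) > 0) {
        abort("the genotype must be exogenous", class = "pathmed_invalid_parameter")
      }
      z[, v] <- (geno - 2 * p) / sqrt(2 * p * (1 - p))
    } else if (length(parents) == 0) {
      z[, v] <- rnorm(n)
    } else {
      b <- std_paths$coef[std_paths$to == v]
      z[, v] <- drop(z[, parents, drop = FALSE] %*% b) +
        rnorm(n, sd = sqrt(impl$resid[[v]]))
    }
  }

  cohort <- tibble(subject = sprintf("S%05d", seq_len(n)))
  cohort[[gvar]] <- as.integer(geno)
  for (v in setdiff(vars, gvar)) {
    m <- config$marginals[config$marginals$variable == v, ]
    cohort[[v]] <- if (nrow(m) == 1) m$mean + m$sd * z[, v] else z[, v]
  }
  for (v in vars) cohort[[paste0(v, "_std")]] <- z[, v]

  for (cv in config$covariates) {
    cohort[[cv$name]] <- switch(
      cv$kind,
      binary = rbinom(n, 1L, cv$prevalence),
      categorical = sample(cv$levels, n, replace = TRUE,
                           prob = cv$probs %||% NULL),
      continuous = rnorm(n, cv$mean %||% 0, cv$sd %||% 1),
      abort(sprintf("unknown covariate kind `%s`", cv$kind),
            class = "pathmed_invalid_parameter")
    )
  }

  list(cohort = cohort, ledger = ground_truth_ledger(std_paths))
}

#' Ground-truth effect ledger for a generating path configuration
#'
#' For every ordered variable pair connected in the generating graph,
#' records the direct coefficient, each mediated path and its coefficient
#' product, the total indirect effect and the total effect. The identity
#' `total = direct + sum of path products` holds exactly.
#'
#' @param std_paths Data frame (`from`, `to`, `coef`).
#' @return A list of class `ground_truth_ledger` with tibbles `direct`,
#'   `indirect` (one row per mediated path) and `total`.
#' @export
ground_truth_ledger <- function(std_paths) {
  std_paths <- check_path_frame(std_paths)
  coef_tbl <- tibble(from = std_paths$from, to = std_paths$to,
                     estimate = std_paths$coef)
  vars <- unique(c(std_paths$from, std_paths$to))
  indirect <- list()
  total <- list()
  for (s in vars) {
    for (t in setdiff(vars, s)) {
      paths <- enumerate_paths(coef_tbl, s, t)
      if (length(paths) == 0) next
      dec <- decompose_effects(coef_tbl, s, t)
      med <- dec[dec$effect_type == "indirect_path", ]
      if (nrow(med) > 0) {
        indirect[[length(indirect) + 1L]] <-
          tibble(source = s, target = t, path = med$path,
                 product = med$estimate)
      }
      total[[length(total) + 1L]] <- tibble(
        source = s, target = t,
        direct = dec$estimate[dec$effect_type == "direct"],
        total_indirect = dec$estimate[dec$effect_type == "indirect_total"],
        total = dec$estimate[dec$effect_type == "total"]
      )
    }
  }
  structure(
    list(direct = tibble(from = std_paths$from, to = std_paths$to,
                         coef = std_paths$coef),
         indirect = dplyr::bind_rows(indirect),
         total = dplyr::bind_rows(total)),
    class = "ground_truth_ledger"
  )
}

#' Generate a two-stratum cohort with stratum-specific coefficients
#'
#' The stratum label (e.g. weight status: thin/normal = 0 vs
#' overweight/obese = 1) is generated first, Bernoulli with the configured
#' prevalence; each stratum's variables are then generated under its own
#' coefficient set (`config$stratum$paths`, overriding the base
#' `std_paths` edge-wise). Used to emulate effect modification such as a
#' stratum-dependent EPA to BMI coefficient.
#'
#' @param config A [synthetic_config()] with a `stratum` entry.
#' @param stratum_var Name for the label column; defaults to
#'   `config$stratum$var` or `"weight_status"`.
#' @param n_per_stratum Optional length-2 vector of exact stratum sizes
#'   (names/order: stratum 0, stratum 1); by default sizes are Bernoulli.
#' @return A list with `cohort` (stratum label column included) and
#'   `ledgers`, a named list of per-stratum [ground_truth_ledger()]s.
#' @export
generate_stratified_cohort <- function(config, stratum_var = NULL,
                                       n_per_stratum = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$stratum)) {
    abort("config has no `stratum` specification", class = "pathmed_invalid_parameter")
  }
  stratum_var <- stratum_var %||% config$stratum$var %||% "weight_status"
  set.seed(config$seed)
  if (is.null(n_per_stratum)) {
    labels <- rbinom(config$n_subjects, 1L, config$stratum$prevalence)
    n_per_stratum <- c(sum(labels == 0), sum(labels == 1))
  }
  if (any(n_per_stratum == 0)) {
    abort("both strata must be non-empty", class = "pathmed_invalid_parameter")
  }
  parts <- list()
  ledgers <- list()
  for (s in c("0", "1")) {
    n_s <- n_per_stratum[[as.integer(s) + 1L]]
    paths_s <- override_paths(config$std_paths, config$stratum$paths[[s]])
    out <- generate_cohort(config, std_paths_override = paths_s,
                           n_override = n_s,
                           seed_override = derive_seed(config$seed, as.integer(s) + 1L))
    out$cohort[[stratum_var]] <- as.integer(s)
    out$cohort$subject <- paste0(out$cohort$subject, "_", s)
    parts[[s]] <- out$cohort
    ledgers[[s]] <- out$ledger
  }
  list(cohort = dplyr::bind_rows(parts), ledgers = ledgers)
}

override_paths <- function(base, override) {
  key <- function(d) paste(d$from, d$to, sep = "\r")
  keep <- base[!key(base) %in% key(override), , drop = FALSE]
  dplyr::bind_rows(keep, override)
}

#' Generate a toy reference table fixture
#'
#' Builds a seeded stand-in for licensed growth / pediatric blood-pressure
#' references, in the [read_reference_table()] format: ages 2-10 y in
#' one-year bins, both sexes, and (for `mean_sd`) 20-cm height bands from 60
#' to 200 cm. Medians increase monotonically in age; all scale parameters
#' are positive.
#'
#' @param kind `"lms"` (L, M, S rows, e.g. a BMI reference) or `"mean_sd"`
#'   (mu, sigma rows with height bands, e.g. a blood-pressure reference).
#' @param seed Seed for the small jitter on the smooth age trends.
#' @param base Median at the youngest age (defaults: 15.5 kg/m^2 for `lms`,
#'   95 mmHg for `mean_sd`).
#' @param age_slope Median increase per year of age.
#' @param height_slope (`mean_sd` only) median increase per cm above 120 cm.
#' @param spread S (for `lms`) or sigma (for `mean_sd`).
#' @return A `reference_table` tibble with `cutpoints` attribute `c(90, 95)`.
#' @export
generate_reference_table <- function(kind = c("lms", "mean_sd"), seed = 1,
                                     base = NULL, age_slope = NULL,
                                     height_slope = 0.1, spread = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  ages <- as.numeric(2:9)
  sexes <- c("f", "m")
  if (kind == "lms") {
    base <- base %||% 15.5
    age_slope <- age_slope %||% 0.2
    spread <- spread %||% 0.1
    rows <- tidyr::expand_grid(sex = sexes, age_lo = ages)
    # monotone medians: positive jitter increments accumulated over age
    rows <- dplyr::group_by(rows, .data$sex)
    rows <- dplyr::mutate(
      rows,
      M = base + (.data$sex == "m") * 0.3 +
        cumsum(age_slope + runif(dplyr::n(), 0, 0.05)),
      L = -1.5, S = spread,
      age_hi = .data$age_lo + 1,
      height_lo = NA_real_, height_hi = NA_real_,
      mu = NA_real_, sigma = NA_real_
    )
    rows <- dplyr::ungroup(rows)
  } else {
    base <- base %||% 95
    age_slope <- age_slope %||% 1.2
    spread <- spread %||% 10
    rows <- tidyr::expand_grid(sex = sexes, age_lo = ages,
                               height_lo = seq(60, 180, by = 20))
    rows <- dplyr::group_by(rows, .data$sex, .data$height_lo)
    rows <- dplyr::mutate(
      rows,
      mu = base + (.data$sex == "m") * 1 +
        height_slope * (.data$height_lo + 10 - 120) +
        cumsum(age_slope + runif(dplyr::n(), 0, 0.1)),
      sigma = spread,
      age_hi = .data$age_lo + 1,
      height_hi = .data$height_lo + 20,
      L = NA_real_, M = NA_real_, S = NA_real_
    )
    rows <- dplyr::ungroup(rows)
  }
  tab <- dplyr::select(dplyr::mutate(rows, kind = kind),
                       "kind", "sex", "age_lo", "age_hi",
                       "height_lo", "height_hi", "L", "M", "S", "mu", "sigma")
  tab <- dplyr::arrange(tab, .data$sex, .data$age_lo, .data$height_lo)
  attr(tab, "cutpoints") <- c(90, 95)
  class(tab) <- c("reference_table", class(tab))
  tab
}
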