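#' Build the core genotype - fatty acid - BMI - blood pressure path model
#'
#' The six structural edges of the mediation graph: SNP to fatty acid, SNP
#' to BMI, SNP to BP, fatty acid to BMI, fatty acid to BP, BMI to BP, plus
#' optional covariate edges into each endogenous variable.
#'
#' @param exposure Fatty-acid variable name (e.g. `"ara"`).
#' @param outcome Blood-pressure z-score variable name (e.g. `"sbp_z"`).
#' @param genotype Genotype variable name (default `"snp"`).
#' @param bmi_var BMI z-score variable name (default `"bmi_z"`).
#' @param covariates Character vector of exogenous covariates with edges
#'   into the fatty acid, BMI and BP equations.
#' @param fixed_zero Passed to [path_model()].
#' @return A [path_model()].
#' @export
bp_model <- function(exposure, outcome, genotype = "snp", bmi_var = "bmi_z",
                     covariates = NULL, fixed_zero = NULL) {
  edges <- tibble(
    from = c(genotype, genotype, genotype, exposure, exposure, bmi_var),
    to = c(exposure, bmi_var, outcome, bmi_var, outcome, outcome)
  )
  if (length(covariates) > 0) {
    edges <- dplyr::bind_rows(edges, tidyr::expand_grid(
      from = covariates, to = c(exposure, bmi_var, outcome)))
  }
  path_model(edges, fixed_zero = fixed_zero)
}

#' Define the eight-model analysis plan
#'
#' Two blood-pressure outcomes (systolic, diastolic z-scores) crossed with
#' four fatty-acid exposures (DGLA, ARA, EPA, D5D index) give models
#' `1a`-`4a` (systolic) and `1b`-`4b` (diastolic). A fish-consumption
#' covariate, when named, enters exactly the EPA models.
#'
#' @param exposures,outcomes Variable names in the cohort.
#' @param covariates Covariates entering every model.
#' @param fish_covariate Covariate added only to EPA models (`NULL` to
#'   disable).
#' @param q FDR level for the per-outcome effect families.
#' @param stratum_var Binary column used by [run_stratified()].
#' @return A list of class `analysis_plan` with a `models` tibble.
#' @export
analysis_plan <- function(exposures = c("dgla", "ara", "epa", "d5d"),
                          outcomes = c("sbp_z", "dbp_z"),
                          covariates = NULL, fish_covariate = NULL,
                          q = 0.05, stratum_var = "weight_status") {
  models <- tidyr::expand_grid(outcome = outcomes, exposure = exposures)
  suffix <- setNames(c("a", "b"), outcomes)
  number <- setNames(seq_along(exposures), exposures)
  models$model <- paste0(number[models$exposure], suffix[models$outcome])
  structure(
    list(models = models[c("model", "exposure", "outcome")],
         covariates = covariates, fish_covariate = fish_covariate,
         q = q, stratum_var = stratum_var),
    class = "analysis_plan"
  )
}

#' Run the full analysis plan on a cohort
#'
#' For every model in the plan: fit the path model by ML, compute fit
#' indices with pass flags, and decompose the SNP-on-BP, SNP-on-BMI and
#' exposure-on-BP effects (direct, per-path indirect, total indirect,
#' total) with delta-method inference. Indirect and direct effect p-values
#' are then FDR-controlled per outcome family (Benjamini-Hochberg at
#' `plan$q`). A non-converged model does not stop the run: it is flagged
#' and the report's `exit_status` becomes nonzero.
#'
#' @param cohort Cohort data frame containing all plan variables.
#' @param plan An [analysis_plan()].
#' @param se Inference method for effect decompositions (`"delta"` or
#'   `"none"`).
#' @return A list of class `plan_report`: `models` (per-model fit summary),
#'   `effects` (tidy effect table with `fdr_significant` and `alpha_adj`),
#'   `fdr` (per-outcome `fdr_family`), `fits` (named list of
#'   `path_model_fit`), `exit_status`.
#' @export
run_plan <- function(cohort, plan, se = "delta") {
  stopifnot(inherits(plan, "analysis_plan"))
  cohort <- as_tibble(cohort)
  needed <- unique(c(plan$models$exposure, plan$models$outcome, "snp",
                     "bmi_z", plan$covariates, plan$fish_covariate))
  missing_cols <- setdiff(needed, c(names(cohort), NA))
  missing_cols <- missing_cols[!is.na(missing_cols)]
  if (length(missing_cols) > 0) {
    abort(paste("plan variables absent from cohort:",
                paste(missing_cols, collapse = ", ")),
          class = "pathmed_spec_error")
  }

  fits <- list()
  model_rows <- list()
  effect_rows <- list()
  for (k in seq_len(nrow(plan$models))) {
    mrow <- plan$models[k, ]
    covs <- plan$covariates
    if (identical(mrow$exposure, "epa") && !is.null(plan$fish_covariate)) {
      covs <- c(covs, plan$fish_covariate)
    }
    spec <- bp_model(mrow$exposure, mrow$outcome, covariates = covs)
    fit <- fit_path_model(cohort, spec)
    fits[[mrow$model]] <- fit
    fi <- fit_indices(fit)
    model_rows[[k]] <- dplyr::bind_cols(
      mrow, tibble(n = fit$n, converged = fit$converged,
                   f_min = fit$f_min),
      fi[c("chi2", "df", "p_chi2", "cfi", "rmsea",
           "pass_chi2", "pass_cfi", "pass_rmsea")]
    )
    pairs <- list(c("snp", mrow$outcome), c("snp", "bmi_z"),
                  c(mrow$exposure, mrow$outcome))
    dec <- purrr::map_dfr(pairs, function(pr) {
      decompose_effects(fit, pr[1], pr[2], se = se)
    })
    dec$model <- mrow$model
    dec$outcome <- mrow$outcome
    effect_rows[[k]] <- dec
  }
  effects <- dplyr::bind_rows(effect_rows)

  fdr <- list()
  effects$fdr_significant <- NA
  effects$alpha_adj <- NA_real_
  if (se != "none") {
    for (oc in unique(plan$models$outcome)) {
      fam_idx <- which(effects$outcome == oc &
                         effects$effect_type %in% c("direct", "indirect_total") &
                         !is.na(effects$p_value))
      ps <- setNames(effects$p_value[fam_idx],
                     paste(effects$model[fam_idx], effects$source[fam_idx],
                           effects$target[fam_idx],
                           effects$effect_type[fam_idx], sep = ":"))
      fam <- bh_fdr(ps, q = plan$q)
      fdr[[oc]] <- fam
      rej <- fam$table$label[fam$table$rejected]
      effects$fdr_significant[fam_idx] <- names(ps) %in% rej
      effects$alpha_adj[fam_idx] <- fam$alpha_adj
    }
  }

  models_tbl <- dplyr::bind_rows(model_rows)
  structure(
    list(models = models_tbl, effects = effects, fdr = fdr, fits = fits,
         exit_status = as.integer(any(!models_tbl$converged))),
    class = "plan_report"
  )
}

#' @export
print.plan_report <- function(x, digits = 3, ...) {
  cat("<plan_report> ", nrow(x$models), " models, exit status ",
      x$exit_status, "\n", sep = "")
  print(as.data.frame(x$models[c("model", "n", "converged", "chi2", "df",
                                 "p_chi2", "cfi", "rmsea")]),
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Weight-status-stratified exposure analysis
#'
#' Effect modification of the exposure-to-BMI(-to-BP) pathway by a binary
#' stratum (weight status). `method = "two_group"` fits the core path model
#' separately in each stratum and reports the per-stratum standardized
#' direct effects (exposure on BMI, exposure on BP) and the mediated
#' exposure-BMI-BP effect. `method = "interaction"` fits one pooled model
#' with a centered-exposure-by-stratum product term and reports its (raw)
#' coefficient, from which the stratum-specific raw slopes differ.
#'
#' @param cohort Cohort data frame.
#' @param exposure,outcome Variable names (defaults: EPA on systolic).
#' @param stratum Name of the binary stratum column (0/1).
#' @param method `"two_group"` (default) or `"interaction"`.
#' @param min_n Strata smaller than this are flagged in the output.
#' @param se Passed to [decompose_effects()].
#' @return For `"two_group"`: list of class `stratified_report` with
#'   `effects` (per-stratum tibble) and `fits`. For `"interaction"`: the
#'   pooled fit plus the interaction row.
#' @export
run_stratified <- function(cohort, exposure = "epa", outcome = "sbp_z",
                           stratum = "weight_status",
                           method = c("two_group", "interaction"),
                           min_n = 30, se = "delta") {
  method <- match.arg(method)
  cohort <- as_tibble(cohort)
  if (!stratum %in% names(cohort)) {
    abort(sprintf("stratum column `%s` not found", stratum),
          class = "pathmed_spec_error")
  }
  lv <- sort(unique(stats::na.omit(cohort[[stratum]])))
  if (length(lv) < 2) {
    abort("stratum column has fewer than two levels", class = "pathmed_data_error")
  }
  if (length(lv) > 2) {
    abort("stratum column must be binary", class = "pathmed_data_error")
  }

  if (method == "interaction") {
    d <- cohort
    d$.exposure_c <- d[[exposure]] - mean(d[[exposure]], na.rm = TRUE)
    d$.stratum <- as.numeric(d[[stratum]] == lv[2])
    d$.interaction <- d$.exposure_c * d$.stratum
    spec <- path_model(tibble(
      from = c("snp", "snp", ".exposure_c", ".stratum", ".interaction",
               ".exposure_c", "bmi_z", ".stratum", ".interaction"),
      to = c(".exposure_c", "bmi_z", "bmi_z", "bmi_z", "bmi_z",
             outcome, outcome, outcome, outcome)
    ))
    fit <- fit_path_model(d, spec)
    pt <- fit$parameters
    int_row <- pt[pt$type == "edge" & pt$from == ".interaction" &
                    pt$to == "bmi_z", ]
    base_row <- pt[pt$type == "edge" & pt$from == ".exposure_c" &
                     pt$to == "bmi_z", ]
    return(structure(
      list(fit = fit, interaction = int_row,
           slopes = tibble(
             stratum = lv,
             raw_slope = c(base_row$estimate,
                           base_row$estimate + int_row$estimate)),
           method = "interaction"),
      class = "stratified_report"
    ))
  }

  fits <- list()
  rows <- list()
  for (s in lv) {
    sub <- cohort[!is.na(cohort[[stratum]]) & cohort[[stratum]] == s, ]
    spec <- bp_model(exposure, outcome)
    fit <- fit_path_model(sub, spec)
    fits[[as.character(s)]] <- fit
    dec <- decompose_effects(fit, exposure, outcome, se = se)
    pt <- fit$parameters
    ebmi <- pt[pt$type == "edge" & pt$from == exposure & pt$to == "bmi_z", ]
    rows[[as.character(s)]] <- tibble(
      stratum = s, n = fit$n, flagged_small = fit$n < min_n,
      converged = fit$converged,
      effect_type = c("direct_on_bmi", "direct_on_bp", "indirect_via_bmi"),
      estimate = c(ebmi$std_estimate,
                   dec$estimate[dec$effect_type == "direct"],
                   dec$estimate[dec$effect_type == "indirect_total"]),
      p_value = c(ebmi$p_value,
                  dec$p_value[dec$effect_type == "direct"],
                  dec$p_value[dec$effect_type == "indirect_total"])
    )
  }
  structure(
    list(effects = dplyr::bind_rows(rows), fits = fits,
         method = "two_group", exposure = exposure, outcome = outcome),
    class = "stratified_report"
  )
}

#' @export
print.stratified_report <- function(x, digits = 3, ...) {
  cat("<stratified_report> method:", x$method, "\n")
  if (x$method == "two_group") {
    print(as.data.frame(x$effects), digits = digits, row.names = FALSE)
  } else {
    print(as.data.frame(x$slopes), digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Cohort quality-control and exclusion report
#'
#' Applies the analysis-group exclusion rules in their fixed order —
#' non-fasting blood draw, missing blood pressure, missing covariates,
#' missing genotype — counting exclusions per rule, and summarizes the
#' genotype distribution (MAF, Hardy-Weinberg) of the retained subjects.
#' The per-rule counts always sum to input minus analyzed.
#'
#' @param cohort Cohort data frame.
#' @param genotype_col Genotype code column (default `"snp"`).
#' @param bp_cols Columns that must all be non-missing for blood pressure.
#' @param covariate_cols Columns that must all be non-missing (listwise).
#' @param fasting_col Optional logical/0-1 column; `FALSE`/0 rows are
#'   excluded first. Ignored when absent.
#' @return A list of class `qc_report`: `exclusions` tibble (`rule`,
#'   `n_excluded`, `n_remaining`), `n_input`, `n_analyzed`, `genotype`
#'   ([genotype_summary()] of retained subjects), `retained` (logical
#'   index).
#' @export
qc_report <- function(cohort, genotype_col = "snp",
                      bp_cols = c("sbp_z", "dbp_z"), covariate_cols = NULL,
                      fasting_col = "fasting") {
  cohort <- as_tibble(cohort)
  n_input <- nrow(cohort)
  keep <- rep(TRUE, n_input)
  steps <- list()
  drop_step <- function(rule, bad) {
    newly <- keep & bad
    keep <<- keep & !bad
    steps[[length(steps) + 1L]] <<- tibble(
      rule = rule, n_excluded = sum(newly), n_remaining = sum(keep))
  }
  if (fasting_col %in% names(cohort)) {
    drop_step("non_fasting", !is.na(cohort[[fasting_col]]) &
                !as.logical(cohort[[fasting_col]]))
  } else {
    drop_step("non_fasting", rep(FALSE, n_input))
  }
  bp_cols <- intersect(bp_cols, names(cohort))
  bad_bp <- if (length(bp_cols) > 0) {
    !complete.cases(cohort[bp_cols])
  } else rep(FALSE, n_input)
  drop_step("missing_bp", bad_bp)
  covariate_cols <- intersect(covariate_cols %||% character(0), names(cohort))
  bad_cov <- if (length(covariate_cols) > 0) {
    !complete.cases(cohort[covariate_cols])
  } else rep(FALSE, n_input)
  drop_step("missing_covariates", bad_cov)
  bad_geno <- if (genotype_col %in% names(cohort)) {
    is.na(cohort[[genotype_col]])
  } else rep(TRUE, n_input)
  drop_step("missing_genotype", bad_geno)

  geno <- if (genotype_col %in% names(cohort) && any(keep)) {
    genotype_summary(cohort[[genotype_col]][keep])
  } else NULL
  structure(
    list(exclusions = dplyr::bind_rows(steps), n_input = n_input,
         n_analyzed = sum(keep), genotype = geno, retained = keep),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> input n = %d, analyzed n = %d\n",
              x$n_input, x$n_analyzed))
  print(as.data.frame(x$exclusions), row.names = FALSE)
  if (!is.null(x$genotype)) print(x$genotype)
  invisible(x)
}
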