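#' Published standardized path coefficients
#'
#' The standardized direct effects reported by the motivating pediatric
#' cohort analysis of the *FADS1* rs174546 variant, whole-blood fatty acids
#' (DGLA, ARA, EPA, D5D index), BMI z-score and blood-pressure z-scores.
#' Eight models: `1a`-`4a` (systolic outcome, exposures DGLA/ARA/EPA/D5D)
#' and `1b`-`4b` (diastolic). These printed coefficients are inputs: they
#' calibrate the synthetic-cohort generator and anchor the path-product
#' identity checks. Reported p-values of "< .0001" are stored as 0.0001.
#'
#' @param model Optional model id (e.g. `"2a"`) to filter on.
#' @return A tibble with columns `model`, `exposure`, `outcome`, `from`,
#'   `to`, `estimate`, `p_value`.
#' @examples
#' published_path_coefficients("2a")
#' @export
published_path_coefficients <- function(model = NULL) {
  tab <- as_tibble(read.csv(
    system.file("extdata", "published-direct-effects.csv",
                package = "pathmed", mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = c(model = "character")
  ))
  if (!is.null(model)) {
    if (!model %in% tab$model) {
      abort(sprintf("unknown model `%s`", model), class = "pathmed_spec_error")
    }
    tab <- tab[tab$model == model, ]
  }
  tab
}

#' @rdname published_path_coefficients
#' @description `published_indirect_effects()` returns the printed indirect
#'   cells (the via-fatty-acid effect of the SNP on BMI, the total indirect
#'   effect of the SNP on blood pressure, and the via-BMI effect of the
#'   fatty acid on blood pressure), used as oracle values for the
#'   path-product identity suite.
#' @export
published_indirect_effects <- function(model = NULL) {
  tab <- as_tibble(read.csv(
    system.file("extdata", "published-indirect-effects.csv",
                package = "pathmed", mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = c(model = "character")
  ))
  if (!is.null(model)) tab <- tab[tab$model == model, ]
  tab
}

#' @rdname published_path_coefficients
#' @description `published_stratified_effects()` returns the
#'   weight-status-stratified EPA effects (thin/normal, n = 316, versus
#'   overweight/obese, n = 204).
#' @export
published_stratified_effects <- function() {
  as_tibble(read.csv(
    system.file("extdata", "published-stratified-effects.csv",
                package = "pathmed", mustWork = TRUE),
    stringsAsFactors = FALSE
  ))
}

#' @rdname published_path_coefficients
#' @description `published_genotype_counts()` returns the reported rs174546
#'   genotype counts (CC/CT/TT) of the analysis sample.
#' @export
published_genotype_counts <- function() {
  c(`0` = 266L, `1` = 206L, `2` = 48L)
}

#' Default generating coefficients and marginals for the synthetic cohort
#'
#' `default_std_paths()` returns the generating standardized coefficients
#' for one published model (default `"2a"`: ARA exposure, systolic outcome)
#' as a `(from, to, coef)` table. `default_marginals()` returns the
#' raw-scale means and SDs the standardized variables are rescaled to,
#' calibrated to the study population's descriptive statistics (DGLA 1.22
#' (0.25), ARA 7.53 (1.34), EPA 0.27 (0.11), D5D 6.32 (1.29) % wt/wt or
#' ratio; BMI z 0.88 (1.27); SBP z 0.41 (0.78); DBP z 0.63 (0.59)).
#'
#' @param model Model id, one of `"1a"`-`"4b"`.
#' @return A tibble (`from`, `to`, `coef`) or (`variable`, `mean`, `sd`).
#' @export
default_std_paths <- function(model = "2a") {
  pc <- published_path_coefficients(model)
  tibble(from = pc$from, to = pc$to, coef = pc$estimate)
}

#' @rdname default_std_paths
#' @export
default_marginals <- function() {
  tibble(
    variable = c("dgla", "ara", "epa", "d5d", "bmi_z", "sbp_z", "dbp_z"),
    mean = c(1.22, 7.53, 0.27, 6.32, 0.88, 0.41, 0.63),
    sd = c(0.25, 1.34, 0.11, 1.29, 1.27, 0.78, 0.59)
  )
}

#' @rdname default_std_paths
#' @description `stratified_epa_config()` assembles a full
#'   [synthetic_config()] for the weight-status effect-modification
#'   analysis: the EPA model's published coefficients as the base graph
#'   (with the BMI-to-BP slope set to the value implied by the published
#'   stratified indirect effects, about 0.14 for systolic), overridden per
#'   stratum by `default_stratum_paths()`. Default prevalence of the
#'   overweight/obese stratum is 204/520.
#' @param n_subjects,seed Passed to [synthetic_config()].
#' @export
stratified_epa_config <- function(outcome = "sbp_z", n_subjects = 520,
                                  seed = 1) {
  stopifnot(outcome %in% c("sbp_z", "dbp_z"))
  bmi_bp <- if (outcome == "sbp_z") 0.140 else 0.010
  base <- tibble(
    from = c("snp", "snp", "epa", "epa", "bmi_z"),
    to = c("epa", "bmi_z", "bmi_z", outcome, outcome),
    coef = c(-0.092, -0.061, 0.147, 0.027, bmi_bp)
  )
  synthetic_config(
    n_subjects = n_subjects, maf = 0.29, std_paths = base,
    stratum = list(var = "weight_status", prevalence = 204 / 520,
                   paths = default_stratum_paths(outcome)),
    seed = seed
  )
}

#' @rdname default_std_paths
#' @description `default_stratum_paths()` returns the stratum-specific
#'   coefficient overrides for the weight-status effect-modification
#'   analysis of EPA (stratum 0 = thin/normal weight, 1 =
#'   overweight/obese), for a given outcome.
#' @param outcome `"sbp_z"` or `"dbp_z"`.
#' @export
default_stratum_paths <- function(outcome = "sbp_z") {
  stopifnot(outcome %in% c("sbp_z", "dbp_z"))
  st <- published_stratified_effects()
  st <- st[st$outcome == outcome & st$effect_type == "direct", ]
  per <- function(label) {
    rows <- st[st$stratum == label, ]
    tibble(from = rows$from, to = rows$to, coef = rows$estimate)
  }
  list(`0` = per("thin_normal"), `1` = per("overweight_obese"))
}
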