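---
title: "Path-model mediation for genotype, fatty acids, BMI and blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-model mediation for genotype, fatty acids, BMI and blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmed)
library(dplyr)
```

## The scientific question

Common variants of the *FADS1* gene alter the activity of the delta-5
desaturase (D5D) enzyme, which converts dihomo-gamma-linolenic acid (DGLA,
20:3n-6) to arachidonic acid (ARA, 20:4n-6) and similarly acts in the n-3
series toward eicosapentaenoic acid (EPA, 20:5n-3). Because long-chain
polyunsaturated fatty acids and adiposity both influence blood pressure
(BP), a variant such as rs174546 may affect a child's BP *indirectly* —
through its effect on fatty-acid levels and through BMI — even when its
*direct* association with BP is weak. Separating these channels is a
mediation question, and the natural statistical machinery is path
analysis: a recursive system of linear equations over observed variables,
estimated simultaneously.

`pathmed` implements that machinery end to end: a covariance-structure
maximum-likelihood (ML) engine for recursive path models, standardized
effect decomposition with product-of-coefficients mediation, delta-method
and bootstrap inference, fit indices, Benjamini-Hochberg FDR control,
genotype QC, the derived-phenotype rules used in pediatric BP studies, and
a seeded synthetic-cohort generator whose ground truth makes every stage
testable without access to individual-level data.

## The model

Each cohort variable is a node; a directed edge $j \to i$ contributes a
linear term to the equation of $i$. With slopes collected in a matrix $A$
(with $A_{ij}$ the slope of $j$ in the equation for $i$) and exogenous /
residual variances and covariances in a symmetric matrix $S$, the implied
covariance of the observed vector is

$$\Sigma(\theta) = (I - A)^{-1}\, S\, (I - A)^{-\top}.$$

Because the edge graph is acyclic (a *recursive* model), $I - A$ is always
invertible. Estimation minimizes the ML discrepancy between $\Sigma(\theta)$
and the sample covariance $S_{\mathrm{obs}}$,

$$F_{ML}(\theta) = \log|\Sigma| + \mathrm{tr}(S_{\mathrm{obs}}\Sigma^{-1})
  - \log|S_{\mathrm{obs}}| - p,$$

by quasi-Newton (BFGS) iteration with the analytic gradient
$\partial F = \mathrm{tr}\!\left[\Sigma^{-1}(\Sigma - S_{\mathrm{obs}})
\Sigma^{-1}\, \partial\Sigma\right]$. Start values are per-equation OLS
estimates; for recursive models with uncorrelated residuals these are
already the ML optimum (a classical identity we exploit as an independent
test oracle), so convergence is essentially immediate and deterministic.
There is no mean structure — data are centered internally — and no latent
variables: the models in scope are path models over observed variables.

Standard errors come from the observed information, the inverse Hessian of
$\tfrac{n-1}{2}F_{ML}$ at the optimum. The standardized solution rescales
each slope by the ratio of *model-implied* standard deviations
($\hat\beta^{std} = \hat\beta\, \hat\sigma_{from}/\hat\sigma_{to}$), making
coefficients comparable across variables and cohorts.

Model fit is summarized by $\chi^2 = (n-1)F_{ML}$ on
$df = p(p+1)/2 - \#\text{free}$, the Comparative Fit Index against the
independence baseline, and RMSEA, with the conventional very-good-fit
thresholds ($P_{\chi^2} > 0.05$, $\mathrm{CFI} \ge 0.97$,
$\mathrm{RMSEA} \le 0.03$) reported as pass flags. A saturated model
($df = 0$) reports $\chi^2 = 0$, CFI = 1 and RMSEA = 0 with a saturation
flag rather than an undefined value.

## Effect decomposition

For a source-target pair, `decompose_effects()` enumerates every directed
path, multiplies the standardized coefficients along each mediated path,
and reports

* the **direct** effect (the source→target edge, 0 if absent),
* one row per **mediated path** with its coefficient product,
* the **total indirect** effect (sum of products), and
* the **total** effect (direct + total indirect — an exact identity).

In the core graph (SNP → FA, SNP → BMI, SNP → BP, FA → BMI, FA → BP,
BMI → BP) the SNP reaches BP through three mediated channels:

```{r decompose}
printed <- published_path_coefficients("2a")
decompose_effects(printed[c("from", "to", "estimate")], "snp", "sbp_z")
```

Run on the published ARA-model coefficients, the total indirect effect is
$-0.057$ and the total effect $0.077 - 0.057 = 0.020$, reproducing the
published values to the printed precision. The same identity holds for
every published indirect cell across all eight models, which is the core
of the acceptance suite.

Inference for products of coefficients uses the multivariate delta method
on the standardized solution by default (for a single two-edge path with
independent estimates this is the Sobel formula); a nonparametric
bootstrap (refitting on resampled rows) is available and preferable in
small samples, where product distributions are skewed. Both are labelled
in the output; neither is treated as exact.

## Multiple testing

Families of effect p-values (one family per outcome, following the
analysis plan) are controlled by the Benjamini-Hochberg step-up rule at
$q = 0.05$. Besides the rejection set, `bh_fdr()` reports `alpha_adj`, the
largest rejected p-value — the "adjusted significance level" convention
used in applied result tables. Since the underlying per-family p-value
lists of the motivating analysis are not published, the package makes no
claim to reproduce its specific `alpha_adj` values.

## Genotype QC and derived phenotypes

* **Additive coding**: `encode_additive()` counts minor-allele copies
  (CC/CT/TT → 0/1/2), order-insensitively, with missing calls propagating.
* **Call rate**: subjects are retained when their non-missing call
  fraction is *strictly above* the threshold (default 0.98), so 97/100
  calls is excluded and 99/100 retained.
* **Hardy-Weinberg**: the default test is the 1-df $\chi^2$ against
  HWE-expected counts; an exact (Wigginton-style enumeration) p-value is
  always reported alongside. On the reported genotype counts
  (266/206/48), MAF is 0.2904 (29%), the $\chi^2$ test gives 0.780
  ($p = 0.377$) while the exact test gives $p = 0.395$ — matching the
  published HWE p-value, which identifies the published test as an exact
  variant.
* **BP consolidation**: with three readings, the mean of the pair with the
  smallest absolute difference; with two readings, their mean if they
  agree within 5%, else missing; one reading is never used. Two choices
  the source protocol leaves open are fixed here: the 5% rule is evaluated
  relative to the *first* reading, and a tie between pairs (possible with
  three readings) resolves to the pair with the smaller mean, which makes
  the rule permutation-invariant.
* **z-scores**: reference tables are pluggable delimited files — LMS rows
  ($z = ((x/M)^L - 1)/(LS)$, with the $L \to 0$ log limit) for growth
  references, mean-SD rows for BP references keyed additionally by height
  band. The licensed published references (pediatric BP percentiles;
  IOTF-style BMI cutoffs) are deliberately *not* shipped; any table in
  the documented format plugs in, and `generate_reference_table()` builds
  seeded toy stand-ins used throughout the tests. There is no
  extrapolation outside a table's coverage — that is an error.
* **Classification**: the BP category is driven by the worse of the
  systolic and diastolic percentiles against cutpoints stored in the
  reference file (default 90th/95th → prehypertension/hypertension).
* **Missingness**: missing inputs propagate; the pipeline applies listwise
  deletion, with `qc_report()` counting exclusions in a fixed order
  (non-fasting → missing BP → missing covariates → missing genotype).

## The synthetic-cohort generator

`generate_cohort()` is first-class, tested code, not a test fixture. It
generates on the standardized scale: in topological order, each endogenous
variable is $z_i = \sum_j \beta_{ij} z_j + \varepsilon_i$ with residual SD
$\sqrt{1 - R_i^2}$ computed *analytically* from the implied covariance of
its parents, so every variance is 1 and the configured standardized
coefficients are the exact generating truth. The genotype is drawn
binomial(2, MAF) — HWE by construction — and standardized by its binomial
moments $(G - 2p)/\sqrt{2p(1-p)}$ rather than empirically, so generating
coefficients are exact (at the cost that the SNP column's *sample*
variance is only approximately 1 at finite $n$; the recovery tolerances
absorb this). Standardized variables are then rescaled to configured
raw-scale marginals.

Defaults state the emulated world: $n = 520$ children, MAF 0.29,
generating coefficients from the published ARA/systolic model, marginals
from the published descriptive statistics (e.g. ARA 7.53 (1.34) % wt/wt,
BMI z 0.88 (1.27)), overweight/obese stratum prevalence 204/520. Every
cohort comes with a `ground_truth_ledger()` whose totals satisfy
`total = direct + sum(indirect)` exactly.

For the weight-status effect-modification analysis, the stratum label is
generated first (Bernoulli), then each stratum is generated under its own
coefficient set — by default the published stratum-specific EPA → BMI
effects ($-0.206$ thin/normal, $0.535$ overweight/obese). The published
stratified analysis does not print its BMI → BP coefficient; we back it
out from the published per-stratum indirect effects
($-0.029/-0.206 \approx 0.075/0.535 \approx 0.14$ for systolic,
$\approx 0.01$ for diastolic) and fix it there — a one-time calibration
stated here, not tuned against tests.

What the generator does *not* emulate: fatty-acid cross-correlations
beyond those induced by the modelled edges, the oversampling of
overweight children in the source fatty-acid subsample (stratum prevalence
is a knob, the sampling design is not modelled), covariate effects beyond
the core graph (covariates default to independent noise with zero
structural effect, since the published covariate coefficients are not
numerically reported), measurement error, and longitudinal structure.
A green recovery test therefore establishes that the estimator recovers
the stated generating structure — not that the published cohort estimates
themselves would be reproduced from raw data, which are not available.

## Numerical choices

* Convergence: BFGS with relative tolerance $10^{-14}$, iteration cap 500,
  declared converged when the gradient infinity-norm is below $10^{-8}$;
  both the gradient norm and iteration count are reported, and
  non-convergence is flagged, never silent.
* The optimizer restarts once from its endpoint if the gradient criterion
  is not met on the first pass.
* Sample covariances use the $n-1$ denominator; $\chi^2 = (n-1) f_{min}$.
* Non-positive-definite sample covariance matrices are an error, not a
  warning.
* Exogenous covariances are free by default; `fixed_zero` entries express
  the zeroed-covariance model modifications (e.g. among country indicators
  and sex) used in the motivating analysis. Residual covariances are fixed
  at zero unless explicitly freed, which preserves the OLS equivalence
  that anchors the test suite.
* Categorical covariates are expanded to reference-coded indicators
  (6 countries → 5 indicators, 3 parental-education levels → 2).
* The interaction route to effect modification (centered exposure ×
  stratum product term) reports raw-scale slopes; the two-group route is
  the primary, standardized analysis.

## Known limitations

* Observed variables only: no latent measurement models, no FIML for
  missing data (listwise deletion only), no polychoric/ordinal machinery.
* The delta method linearizes products of coefficients; its p-values are
  asymptotic. Bootstrap inference is recommended below a few hundred
  subjects.
* The exact covariate sets per endogenous equation used after the source
  analysis's model modification are not fully published; shipped model
  builders expose covariates as arguments rather than hard-coding a
  particular post-modification configuration.
* No causal-identification diagnostics: the decomposition is an algebraic
  property of the fitted linear system, and its causal reading rests on
  the model's assumptions, not on anything the software verifies.
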