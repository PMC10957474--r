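---
title: "Methods: longitudinal logistic-normal modeling of microbiome compositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal logistic-normal modeling of microbiome compositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmdyn)
```

## Scope and model

`lnmdyn` analyzes longitudinal relative-abundance profiles (species-level
genome bins or pathways) from immunotherapy cohorts. The core model treats
each sample's composition through its additive log-ratio (alr) coordinates
`η = alr(x)` and fits the multivariate linear model

$$\eta_j \sim N(\Lambda X_j, \Sigma), \qquad
  \Lambda \sim MN(\Theta, \Sigma, \Gamma), \qquad
  \Sigma \sim W^{-1}(\Xi, \nu),$$

the logistic-normal branch of the Bayesian multinomial logistic-normal
family. We deliberately fit only this branch: when profilers report
proportions without usable totals, the count layer carries no extra
information, and with `η` observed the posterior is conjugate
(matrix-normal inverse-Wishart), so posterior draws are **exact** — the
package never runs MCMC for inference. The count layer exists only in the
synthetic generator, as an optional multinomial observation step.

Assumptions worth stating plainly:

- **Linearity in visit.** Each feature's trajectory per outcome group and
  context is a line in visit index. Nonlinear time trends are out of scope;
  the separate days-since-first-infusion covariate absorbs calendar-time
  variation around the 3–4 week cycle.
- **Homogeneous residual covariance** `Σ` across samples and visits.
- **Compositional coherence.** All reported effects are differences of
  log-ratio coordinates; converting coefficient draws to centered log-ratio
  (clr) coordinates makes summaries independent of the alr reference (a
  property the test suite checks both algebraically and through the fit).

## Transforms and zero handling

Zero replacement is mandatory plumbing before any log-ratio transform. We
use multiplicative replacement: zeros become `epsilon` (default `1e-6` of
the sample total) and nonzero parts rescale so ratios among them are
untouched. The default is small enough to sit below any realistic detection
limit for shotgun profiles while keeping log-ratios finite; it is
configurable everywhere it appears. Presence for the prevalence filter is
defined as strictly positive abundance — relative abundances carry no
detection-limit semantics that would justify a nonzero threshold — and both
filter thresholds (20% of baseline samples, 10% of post-baseline samples)
are inclusive.

The alr reference defaults to the last feature row; since all inference is
reported in clr coordinates this choice is cosmetic, which the
reference-invariance tests confirm to `1e-8` on the posterior mean.

## Design matrix

The focal block expands `visit (X) × PFS12 (Z) × W` for the three moderators
(combination therapy, colitis, PPI use) into 16 terms. Visit is coded as the
integer 0–3: the intercept is then the baseline, and slopes are per-visit
changes. All peripheral categorical covariates use **weighted-sum coding**:
level `j` of a `k`-level factor gets 1 in column `j`, the reference level
gets `−n_j/n_k`. Every coding column has observation-weighted mean zero, so
the model intercept is the observation-weighted grand mean and the marginal
case–control contrasts depend only on the 16 focal coefficients. Continuous
covariates (age, BMI, days since first infusion) are mean-centered for the
same reason.

The patient identifier enters as a weighted-sum-coded **fixed** factor to
absorb repeated-measures correlation. This is exactly reproducible and
avoids inventing a random-effects structure the model family does not
define. The cost is deliberate rank deficiency: patient-constant variables
(PFS12, colitis, PPI) are linear combinations of the patient columns. The
Bayesian ridge prior `Γ = I` keeps the posterior proper; `build_design()`
reports the numerical rank. A consequence — visible in the synthetic
studies — is that *baseline* (intercept) group differences are partially
absorbed by the patient block and shrink toward zero, while *slope*
differences (interactions with visit) are within-patient quantities and are
recovered cleanly. This is why the generator plants its effects on the
visit-by-outcome interaction.

## Priors

The defaults are weakly informative on the alr scale: `Θ = 0`, `Γ = I_Q`,
`ν = D + 2`, `Ξ = (ν − D)·I`, which centers the prior for `Σ` at the
identity. These follow the convention of the conjugate multinomial
logistic-normal literature; exact hyperparameters used in any particular
published analysis are rarely recoverable, so all four are configurable and
recorded in the pipeline manifest. Inverse-Wishart draws use the Bartlett
construction (via `stats::rWishart` on the inverted scale), and all draws
flow from a single root seed.

## Contrasts, BCL, and dynamics

Seven post hoc contrasts are built in (`lnm_contrasts()`), each defined by
fixing some of `(Z, W1, W2, W3)` per arm and averaging the rest. Averaging
uses observed sample frequencies (proportional weighting), consistent with
the weighted-sum/mean-centering logic; equal weighting is available as an
option. Because the model is linear in the moderators, frequency-averaging
a marginal mean equals substituting the frequency into the focal expansion,
and the product weights of two jointly averaged moderators treat them as
independent — the same convention reference-grid tools like `emmeans` use
with proportional weights.

Per posterior draw, the case–control difference at visit `t` is
`Δ(t) = Δ_intercept + t·Δ_slope`, `t ∈ {0,1,2,3}`. Significance at Bayesian
confidence level `p` means the equal-tailed `p`-level credible interval
(linear-interpolation quantiles, type 7; the full range at `p = 1`)
excludes zero. BCL is not a frequentist error rate and no multiplicity
adjustment is applied, matching practice for this model family; the null
calibration study below quantifies what the 90% rule does under a true
null. Flagged-feature counts are non-increasing in the level by
construction, which the suite asserts on every run.

The dynamics classifier assigns `stable-difference`, `baseline-only`,
`emergent`, `crossing`, `case-flat`, `control-flat` or `none`, in that
precedence order, from the per-visit interval signs and the per-arm slope
intervals at 90% BCL. Published trajectory taxonomies of this kind are
typically shown graphically rather than defined; our rule set captures the
four canonically exemplified patterns plus the two one-armed variants and
should be read as a documented approximation, not a reimplementation of any
specific figure's labels.

## Balances and prediction

A balance is `B = mean(log x_i, i∈I⁺) − mean(log x_j, j∈I⁻)` — the log
ratio of geometric means, with the `sqrt(k⁺k⁻/(k⁺+k⁻))` normalization
dropped as a harmless monotone rescaling. Balances are invariant to
renormalization and to subcompositions containing their members.

Predictive evaluation uses 100-times repeated 5-fold cross-validation of a
univariate logistic regression of the outcome on the balance. Folds are
stratified by class (the original procedure's stratification is typically
unstated; stratification is the conservative choice that keeps folds
estimable), and degenerate splits are re-drawn within the repeat with a
message. Held-out linear predictors are pooled across folds into one
rank-AUC per repeat (midrank tie convention); we report mean ± SD over
repeats. External-cohort evaluation fits on all samples and reports the
training AUC, with member features missing from the cohort optionally
dropped from their geometric mean — mirroring how independent validation
cohorts lack some taxa.

Median stratification labels scores strictly above the median `High`; ties
and the median element go `Low`. With an odd sample count this puts the
median patient in the larger (`Low`) stratum.

## Survival

Kaplan–Meier estimation, Cox proportional-hazards regression and the
Schoenfeld-residual trend test delegate to the `survival` package behind
thin, contract-tested wrappers. Ties use the Efron correction — follow-up
recorded in months ties heavily, and Efron is the less biased convention
when the method is unstated. The median survival time is the earliest time
at which the estimate reaches 0.5 or below, `NA` when never reached. Both
stratified (High/Low) and continuous-score Cox analyses are exposed.

## The synthetic generator

`simulate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every stage is testable without external data and
parameter recovery can be scored against known truth:

- 175 patients; per-visit sampling probabilities calibrated by moment
  matching to per-visit sample counts of 62/77/38/30 (PFS ≥ 12, 83
  patients) and 74/69/34/24 (PFS < 12, 92 patients) — about 408 samples in
  expectation. Visits are sampled independently per patient (baseline
  included: the calibrating counts have more visit-1 than visit-0 samples,
  so baseline cannot be guaranteed), and patients drawing no visits are
  re-drawn.
- Covariate frequencies: combination therapy 58/175, colitis 33/175, PPI
  47/175, antibiotics 25/175, prior targeted therapy 41/175, PFS12 83/175,
  female 75/175, five centers at 54/74/17/19/11. The other-irAE rate is set
  to 0.55, a value consistent with a 61% any-irAE rate of which colitis is
  a subset. Age ~ N(62, 14²) truncated to 19–94; BMI ~ N(26, 4.5²).
- Effects are planted on the **clr scale** (so truth is coordinate-free)
  on the visit-by-PFS12 interaction: `+δ` for half the planted features,
  `−δ` for the other half, columns re-centered to sum zero; default
  `δ = 0.8` clr units/visit, `D = 60` features as the desk-scale stand-in
  for the several hundred retained by prevalence filtering at full scale
  (a full-scale `D` is one argument away). Peripheral coefficients are
  small random draws, `Σ* = σ²I` with `σ = 1`.
- The default observation layer is the exact logistic-normal (zero
  inflation 0, no count resampling), keeping planted truth well defined
  for recovery scoring; multinomial depth and structural zeros are
  available switches for robustness experiments.
- Survival times are exponential with a planted log hazard ratio between
  strata, administratively censored at 84 months, baseline median 34
  months.

What the generator does **not** emulate: phylogenetic correlation between
features, strain-level structure, realistic zero patterns (microbiome
tables are far sparser than a logistic-normal draw), batch effects between
centers beyond a coded covariate, and informative dropout. Passing
recovery tests therefore demonstrates the estimator's correctness under
its own assumptions — not robustness to the full mess of real data.

## Numerical choices and problem sizes

All linear algebra goes through Cholesky factorizations (`chol`,
`chol2inv`); posterior covariance matrices are re-symmetrized after
inversion to suppress drift. The softmax guards against overflow by
subtracting the column maximum. Equal-tailed quantiles are type 7; ranking
ties break lexicographically by feature ID. Degenerate inputs error early
with the offending sample or feature named: all-zero compositions,
all-zero sample columns after filtering, missing metadata fields,
single-class folds, zero-margin 2×2 tables.

The test and acceptance studies run at: full-scale cohorts (~408 samples,
`D = 60`, `S = 2000` draws) for recovery and null calibration; a
`D = 3, Q = 2, N = 8` instance for the brute-force Metropolis oracle that
cross-checks the conjugate posterior (120k iterations on a
log-Cholesky parameterization with the matching Jacobian); `n = 200` for
null cross-validation; 500 patients for hazard-ratio recovery. These sizes
give Monte Carlo error comfortably below the asserted tolerances while a
full run of everything stays in the minutes range on one core.

## Known limitations

- Trajectories are linear in visit; saturating or non-monotone dynamics
  get averaged into a slope.
- The fixed-effect patient factor leaves baseline group differences only
  weakly identified (see above); analyses that need sharp baseline
  contrasts should drop the patient factor (`include_patient = FALSE`) and
  accept the exchangeability cost, or use contrast (1) at later visits
  where slope information accumulates.
- BCL significance is a posterior-mass statement under this prior, not a
  calibrated error rate; the null study bounds its practical false-flag
  behavior (≤ 15% per visit at 90% BCL is the asserted loose bound).
- The multinomial count layer is generative only; fitting it (and thus
  modeling depth-dependent noise) is out of scope.
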