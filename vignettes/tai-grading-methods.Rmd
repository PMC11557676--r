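---
title: "Grading traumatic axonal injury on MRI and modelling TBI outcome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading traumatic axonal injury on MRI and modelling TBI outcome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taigrade)
```

## Scope

`taigrade` implements an analysis chain for early-MRI studies of traumatic
brain injury (TBI): anatomical grading of traumatic axonal injury (TAI),
construction of the 6-month Glasgow Outcome Scale Extended (GOSE) endpoint,
adjusted ordinal and binary logistic outcome models, elastic-net penalised
ordinal regression with bootstrap stability selection, and cross-validated
model comparison. Because patient-level data of this kind are not publicly
deposited, the package also ships a calibrated synthetic cohort generator;
every empirical statement in this vignette is something the test suite or the
acceptance script computes.

## The cohort model and location ontology

Lesion annotations are rows of (patient, location, side, MRI sequence,
presence, count, volume). Locations come from a packaged ontology of 58
laterality-resolved entries: three midline corpus-callosum segments (genu,
truncus, splenium), the midline cerebellar vermis, and 27 paired structures
in both hemispheres. Each code maps to exactly one of ten region groups
(hemispheric white matter, cerebellum, corpus callosum, basal ganglia,
thalamus, posterior limb of the internal capsule, mesencephalon, pons,
medulla, cerebellar peduncles), and the region group — not the individual
code — is what grading rules and models consume. The ontology is a CSV
resource: substituting a different location list is a configuration edit, not
a code change. Whether a published count of "58 locations including
laterality" counts sided entries separately is ambiguous; this package
resolves it by counting sided entries, and a midline lesion extending into
both halves of a paired structure is annotated as two sided rows.

Volumes (cm³) exist only for FLAIR and DWI, where lesions were segmented;
T2\*GRE/SWI contributes lesion counts only. Validation enforces these
invariants together with range checks (GCS 3–15, GOSE 1–8, non-negative
volumes and days) and referential integrity, and `read_cohort()` /
`write_cohort()` round-trip the cohort exactly through plain CSV (UTF-8,
comma separator, empty cell = missing).

## Region features and the grading rule engine

`extract_features()` reduces annotations to per-patient flags and totals. A
region group is *present* on a side if any of its locations carries a lesion
on **any** of the three sequences; *bilateral* requires left and right
presence (the sequences may differ between sides — a left pontine FLAIR
lesion plus a right pontine SWI microbleed counts as bilateral pons). The
rationale is that presence was registered per location across sequences, and
grading is defined anatomically, not per sequence. *Unilateral* means
presence on exactly one side, so a structure is never both unilateral and
bilateral; since every bilateral tier outranks the corresponding unilateral
tier in every shipped rule set, grades remain monotone under added lesions (a
property test verifies this).

Grading systems are data, not code: YAML files mapping grades to predicate
expressions over the named feature flags, evaluated by a small rule engine
that returns the highest satisfied grade, or the rule set's no-TAI grade.
Four rule sets ship:

* **standard** (three tiers): hemispheres/cerebellum < corpus callosum <
  brainstem (including cerebellar peduncles); no TAI is grade 0.
* **trondheim** (five tiers): grade 1 hemispheres/cerebellum; grade 2 corpus
  callosum (not subdivided); grade 3 unilateral thalamus or brainstem
  (including peduncles) or any basal-ganglia TAI; grade 4 bilateral
  mesencephalon or thalami; grade 5 bilateral pons; no TAI is grade 0.
* **stockholm** (approximate): reconstructed only from what the comparison
  study states — thalamic TAI incorporated, bilateral pons the worst grade,
  broader grade-2/3 tiers, and no TAI *not* distinguished from hemispheric
  TAI (both grade 1).
* **gcs_based** (approximate): bilateral brainstem-or-thalami as the worst
  grade over a standard-like base.

The Stockholm-style and GCS-based files are clearly marked approximations:
their original tier definitions are published elsewhere and should be checked
before any comparative claim. Two edge cases the five-tier system does not
address are decided here and are editable in the rule files: bilateral
medulla maps to the bilateral non-pons tier (grade 4), and cerebellar
peduncles count toward unilateral-brainstem grade 3 but never trigger grades
4–5 without parenchymal mesencephalic or pontine involvement. Posterior-limb
internal-capsule lesions default to grade-1 territory in the Trondheim rules
(they are named only by the deep tiers of the other systems).

The engine is tested against a brute-force oracle that evaluates every
predicate independently and takes the maximum over random corners of the
boolean feature lattice, for all four rule sets.

## Outcome construction

The analysis endpoint is the 6-month GOSE. When GOSE was assessed at 3 and
12 months instead, the 6-month value is the weighted mean corresponding to
linear interpolation in time, (2·GOSE₃ + GOSE₁₂)/3, rounded half-up and
clipped to [1, 8]; the 2/3–1/3 weighting is configurable since the exact
weights used in the source analysis are not published. Patients assessed only
at 3 months (the mild-TBI convention) contribute that score. Remaining
missing values are imputed once by an expectation–maximisation algorithm
under a joint multivariate-normal model over (GOSE₆, age, GCS,
Marshall-as-integer, Trondheim grade, log1p total FLAIR TAI volume) — a
reconstruction, as the original imputation's variable set is in an
unavailable supplement. log1p replaces ln for the volume covariate because
zero volumes occur. The E-step uses the conditional normal mean and variance,
the M-step updates the mean and covariance (with a tiny relative ridge,
1e-8 of the mean diagonal, so collinear covariates keep the model proper);
the observed-data log-likelihood is asserted non-decreasing and iteration
stops at a 1e-6 change or errors at 500 iterations. Imputed values are
rounded half-up and clipped to [1, 8]. Models use the inverted score
(9 − GOSE) as the ordinal response; dichotomisations are poor outcome
(GOSE ≤ 4) and disability (GOSE ≤ 6).

## Unpenalised outcome models

The proportional-odds model P(Y ≤ j | x) = logistic(θⱼ − xᵀβ) is fitted by
BFGS on the unconstrained reparameterisation (θ₁, log-increments), with
analytic gradients, starting from the intercepts-only closed form (thresholds
at the cumulative-frequency logits). Standard errors come from the observed
information at the optimum; Wald 95% CIs and p-values match the OR (95% CI)
presentation, with significance flagged at p < 0.01 (the source analyses'
pragmatic multiplicity guard). Rank-deficient designs error naming the
collinear columns, and coefficient magnitudes above 25 on the logit scale are
treated as separation. Binary logistic models are maximum-likelihood binomial
GLMs reported with the same metric fields (McFadden pseudo-R² against the
intercepts-only model, AIC = −2ℓ + 2k, BIC = −2ℓ + k·ln n). In the
two-category case the ordinal fitter reproduces the binary GLM to 1e-6,
and it matches `MASS::polr` and a generic-optimiser oracle on small
instances.

Modelling conventions: volumes enter as (presence, ln volume) pairs — ln 0
does not exist, so volume 0 maps to (0, 0); rescaling a volume's units moves
only the presence/threshold structure, leaving the log-volume slope invariant
(tested). Adjustment sets are per-stratum presets: severe and all-TBI models
use age, GCS, pupils (two dummies) and the Marshall CT score; moderate TBI
with GCS 9–12 uses age, GCS, Marshall; GCS 13 uses age, Marshall; mild uses
age and sex, with one MRI variable per model throughout. The Marshall score
is collapsed to ordered categories {1, 2, 3–4, 5–6} (plus no-CT where it
occurs) — the exact coding used in the source is unstated, so the collapsed
coding mirrors how the cohort table bands it, with reference category 1.
Association tables suppress exposures carried by fewer than 10 patients.

## The penalised ordinal model

The elastic-net objective is the negative **mean** cumulative-logit
log-likelihood plus λ[αΣ|βⱼ| + (1−α)/2Σβⱼ²] over the penalised columns; core
variables and the Marshall term are never penalised. The solver is a
monotone accelerated proximal-gradient method (FISTA with adaptive restart
and backtracking line search): the smooth part (likelihood + ridge) is
differentiated analytically in the unconstrained threshold
parameterisation, the ℓ1 part is handled by soft-thresholding, so penalised
coefficients are exactly zero at rest. The objective trace is asserted
non-increasing; convergence requires a 1e-8 relative objective change and a
1e-6 parameter change, with non-convergence an error carrying the trace.
Solutions are verified against the KKT subgradient conditions
(|∂ℓ/∂βⱼ| ≤ λα for zeroed columns), against the unpenalised fitter at λ = 0,
and against `glmnet` in the two-category lasso and ridge limits.

Columns are standardised internally to full-sample mean 0 / SD 1 and
coefficients reported on the original scale. Tuning is chosen by 5-fold
cross-validation, stratified by response category, maximising the mean
out-of-fold log-likelihood; ties break toward the larger λ (sparser model).
The default grid — 50 log-spaced λ from λ_max (the smallest value zeroing all
penalised columns) down to 10⁻³·λ_max, α ∈ {0.1, 0.25, 0.5, 0.75, 1} — is a
package choice, as no grid is published. Stability selection refits the model
on 500 case resamples at tuning **fixed from the full data** (re-tuning per
resample is not the default: the source procedure is unstated, holding tuning
fixed is common stability-selection practice and far cheaper), reusing the
full-sample standardisation, and reports the percentage of resamples in which
each variable kept a nonzero coefficient; unpenalised variables report 100%
by construction. Resamples with fewer than two response categories are
redrawn and counted. Two packaged variable lists mirror the two published
models: *clinical* (presence/laterality flags only) and *quantitative*
(adding lesion counts and log-volume pairs).

## Evaluation

Discrimination is summarised as AUC computed by the midrank (tie-corrected
Mann–Whitney) statistic, which equals the brute-force all-pairs proportion
exactly (tested on random instances, ties included). `cv_auc()` uses
stratified 10-fold splits, predicts the model-implied event probability on
the held-out fold (ordinal models: P(inverted response ≥ cut); binary:
fitted probability), pools the out-of-fold pairs, and attaches a percentile
CI from 2000 case bootstrap resamples of those pairs. Pooling and
no-refit bootstrap are the defaults — chosen for stability at the stratum
sizes involved (55–176 patients) and because the published procedure is
unstated; per-fold averaging and full-refit bootstrap are available behind
flags. Strata with fewer than 10 events or 10 non-events refuse the analysis
(the mild stratum typically cannot support it). `comparison_table()` enters
each grading as a single integer-scored covariate (0–5) added to the
stratum's baseline — dummy coding is a flag, integer scoring being the
parsimonious default at these sample sizes — and the volumetric models as
log-volume pairs.

The Jonckheere–Terpstra trend test sums pairwise Mann–Whitney counts across
ordered group pairs; p-values use the tie-corrected normal approximation with
a 0.5 continuity correction, or full permutation enumeration for total
n ≤ 12. On untied data the corrected approximation sits within 0.02 of the
exact p at n ≤ 12; heavy ties degrade it to roughly 0.05, which is a known
property of the variance-only tie correction.

## The synthetic cohort generator

The generator emulates the *statistical structure the analyses assume*, not
any patient: stratum sizes 176/74/55/158 (severe, moderate GCS 9–12, GCS 13,
mild); per-stratum covariate distributions matched to the published
demographics (age medians, sex ratios, GCS, pupil and Marshall frequencies,
days to MRI); and a hierarchical lesion model. Each patient draws a latent
severity tier (the intended maximum anatomical grade, 0–5) from per-stratum
probabilities — e.g. severe TBI: 5% no TAI and 7% bilateral pons, matching
the printed prevalences — then conditional draws fill in the pattern:
hemispheric lesions almost always accompany higher tiers, cerebellar TAI
occurs only alongside hemispheric TAI (as observed in the source cohort),
callosal lesions accompany deep tiers with high probability, and deep
bilateral lesions occur only at their tier. The hierarchy is used because the
published composite rows imply strong nesting of deep lesions; the
co-occurrence strengths themselves are unpublished and are stated
assumptions, all visible in `preset_paper()`. Volumes are log-normal
per-patient totals (tier-shifted location parameter; severe-stratum total
FLAIR TAI volume median ≈ 1.3 cm³) split over lesion sites, and T2\*GRE/SWI
counts are negative-binomial per site.

GOSE is drawn from a proportional-odds model on the realised features and
covariates. The preset's location log-ORs are the natural logarithms of the
published severe-stratum adjusted odds ratios (bilateral pons ln 10.7,
bilateral thalami ln 8.24, bilateral mesencephalon ln 3.82 from the composite
row, bilateral basal ganglia ln 5.42, and so on), volume effects ln 1.78 per
unit log FLAIR TAI volume and ln 1.36 per unit log contusion volume, and
covariate effects are package choices of plausible sign and size (e.g.
−0.25 per GCS point, +0.8/+1.6 for unilateral/bilateral pupil dilation).
Bilateral medulla is never reported separately in the source, so it takes the
bilateral-brainstem composite effect (ln 6.01) at a realistically rare ~1%
tier frequency. The seven thresholds were calibrated **once**, by
deterministic search (uniroot on the marginal cumulative probabilities
against a large fixed-seed simulation of the linear predictor), so that the
marginal GOSE distribution approximates the published severity-stratified
bands; the calibrated values are stored in the preset and never re-fitted.

Two things the generator deliberately does not emulate: real lesion
co-occurrence correlations beyond the tier hierarchy, and any scanner/site
effects or annotation noise. Passing tests therefore show that the
*pipeline* is correct and well-calibrated under the assumed structure — not
that the effect sizes would replicate in new patients.

### Parameter recovery as the acceptance harness

`recovery_experiment()` generates cohorts in which the outcome depends on
the covariates plus a **single** target exposure at a known log-OR, fits the
stratum's adjusted model per replicate, and summarises the fitted ORs. The
single-effect design is deliberate: the published association table reports
marginal one-exposure-at-a-time estimates, so a joint multi-effect generator
would make the single-exposure fit mis-specified and the printed OR would no
longer be the estimand. With the well-specified design, the median fitted OR
over 50 cohorts of n = 3000 recovers the generating value (bilateral pons OR
10.7 in severe TBI within 10%; log FLAIR TAI volume OR 1.78 across all
severities within 5%), which is what `scripts/acceptance.R` recomputes.

## Numerical choices, degenerate inputs, and problem sizes

* Optimiser tolerances: 1e-14 relative (BFGS) with a gradient-norm guard for
  the unpenalised fits; 1e-8 relative objective / 1e-6 parameter change for
  the penalised solver; EM tolerance 1e-6 on the log-likelihood.
* Deterministic starts everywhere (null-model thresholds, zero slopes); CV
  fold assignment, bootstrap resampling, and the generator all require
  explicit seeds, and repeated runs are byte-identical.
* Empty response categories are dropped before unpenalised fits; penalised
  CV keeps the global category set so folds remain comparable. Degenerate
  resamples are redrawn and counted. Zero-variance exposures are dropped
  with a warning; all-missing columns, infeasible configurations, and empty
  strata are errors naming the offender.
* Rounding is half-up for weighted and imputed GOSE, then clipped to [1, 8].
* Test problem sizes are chosen to make the suite complete in minutes on one
  CPU: oracle equivalences run at n ≤ 400, the stability-selection check at
  the published n = 305 with the full 500 resamples, and the recovery
  experiments at 50 replicates of n = 3000.

## Known limitations

* The Stockholm-style and GCS-based rule sets are reconstructions from
  secondary statements; comparative conclusions about those systems require
  the original definitions.
* The EM imputation model and the 3-/12-month weighting reconstruct
  procedures whose specifics are unpublished.
* The generator's co-occurrence hierarchy and covariate effect sizes are
  assumptions; headline fit statistics from the source cohort (pseudo-R²,
  AUCs) depend on unavailable patient data and are not reproduction targets.
* No proportionality-assumption tests, random effects, multiple imputation,
  group penalties, or DeLong CIs: none of these appear in the source
  analyses.
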