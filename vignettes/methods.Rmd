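---
title: "Methods: linking blood biomarkers to multimorbidity measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking blood biomarkers to multimorbidity measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`multimorbid` implements a pipeline for relating a baseline panel of blood
biomarkers to three operationalizations of multimorbidity in ageing cohorts:
the baseline count of chronic diseases, latent-class multimorbidity patterns,
and the longitudinal rate of disease accumulation. This vignette is the
package's account of the statistical machinery, the choices that were
genuinely open, and what the test suite does and does not establish.

## Data model

A cohort is two tables. The wide baseline table has one row per participant:
an identifier, baseline age, binary sex and education codes, a continuous
biomarker panel ($B$ columns, assay units), and binary indicators for $D$
chronic-disease categories. The long follow-up table records repeated visits
(participant, years since baseline, chronic-disease count). Validity rules
are enforced at construction: indicators are strictly 0/1, a time-0 visit
must equal the baseline row sum, visit times increase strictly within
participant.

Preprocessing follows the panel conventions of population studies of ageing:

* **Complete-case rule.** Participants with any missing biomarker are
  excluded at load time and counted. Visits with a missing count are dropped
  per record, not per participant, because the exclusion criterion concerns
  the baseline panel only.
* **Detection limits.** Measurements flagged below an assay's limit of
  detection are replaced by exactly zero (single-value, not-missing-at-random
  imputation) *before* standardization. Whether imputation precedes or
  follows z-scoring was an open choice; imputing first keeps the imputed
  value on the assay scale, where "no detectable analyte" is a meaningful
  zero.
* **Standardization.** Each biomarker is z-scored with the cohort's own mean
  and sample ($n-1$) standard deviation, so penalized coefficients are per
  s.d. of the analyzed cohort. In external validation each cohort is
  standardized internally (a documented knob): transferring a model across
  cohorts then asks whether *relative* biomarker positions predict, which is
  the transportable quantity when assay platforms differ.
* **Correlation structure.** Descriptive biomarker interdependence is
  summarized by Spearman rank correlations; the age-adjusted variant is a
  partial rank correlation (rank-transform, residualize on rank-transformed
  age, correlate residuals). The estimator for "age-adjusted" was not fixed
  externally; rank-residualization keeps the adjusted and unadjusted
  matrices on the same scale.

## Latent class model

Multimorbidity patterns are latent classes of a conditional-independence
binary mixture. With mixing proportions $\pi_k$ and item-response
probabilities $\rho_{kj}$,

$$P(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{D}
  \rho_{kj}^{y_{ij}} (1-\rho_{kj})^{1-y_{ij}},$$

fitted by EM. The fitter is authored in the package: the E-step computes
Bayes posteriors in log space, the M-step takes posterior-weighted means,
and the best of `n_starts` random initializations (item probabilities drawn
by perturbing observed prevalences, defaults: 10 starts, relative tolerance
1e-8, 5,000 iterations) is kept. $\hat\rho$ is smoothed into
$[10^{-6}, 1-10^{-6}]$ so log-likelihoods stay finite; classes are re-ordered
by descending $\hat\pi$ so labels are stable across refits. The model is fit
on the multimorbid subset only (participants with $\ge 2$ diseases, after a
$\ge 2\%$ prevalence eligibility filter); the 0–1-disease stratum is held out
as the no-multimorbidity reference group.

The number of classes minimizes the sample-size-adjusted BIC,
$-2\ell + p\,\log((n+2)/24)$ with $p = K-1+KD$ — the Sclove $n^* = (n+2)/24$
correction that is the standard "adjusted BIC" in LCA practice (the
adjustment variant was not externally specified and is fixed here). The
selection report also carries BIC, relative entropy
$1 - \sum_{ik} (-p_{ik}\log p_{ik})/(n \log K)$, and a five-fold
cross-validated assignment accuracy: fold models are matched to the
full-data model by exhaustive permutation search minimizing total-variation
distance between item-probability rows (exact for $K \le 8$), and held-out
modal assignments are compared with the full-model assignments.

Pattern labelling uses hard modal assignments (exact posterior ties broken
toward the larger class and reported). For disease $j$ in class $k$, the
observed/expected ratio is the within-class prevalence over the
multimorbid-population prevalence, and exclusivity is the share of all
multimorbid cases of $j$ falling in $k$. A disease is *overexpressed* when
O/E $\ge 2$ and exclusivity $\ge 25\%$, both inclusive; a pattern with no
overexpressed disease is labelled "Unspecific". Whether labelling should use
modal or posterior-weighted counts was open; modal is the default and
posterior-weighted soft counts are available through the `posterior`
argument for sensitivity analysis. Two identities are enforced by
construction and asserted in tests: exclusivities sum to 1 across classes
for every observed disease, and the class-size-weighted mean O/E is 1.

## Classification-uncertainty-aware selection

Hard class assignment understates classification uncertainty, so every
regression on pattern membership is repeated over pseudo-class draws: each
participant's label is sampled from their posterior membership, 1,000 times
by default (the no-multimorbidity stratum stays fixed). Per draw, a
multinomial LASSO of the resulting group variable on the biomarkers is fit
with age, sex and education forced in unpenalized (`penalty_factor = 0`;
adjustment covariates are never candidates for exclusion). The penalty is
chosen per draw by K-fold cross-validation on deviance with the
one-standard-error rule — the largest penalty within one standard error of
the minimum, i.e. the most regularized near-optimal model. Folds are
re-randomized per draw from the draw's child seed.

The multinomial model is fit symmetrically (ungrouped per-class L1) and then
re-expressed against the no-multimorbidity reference by subtracting the
reference-class coefficient vector, which reproduces reference-coded
log-odds while keeping the software's symmetric parameterization. A
biomarker is *retained* for a pattern when its reference-coded coefficient
is nonzero in at least 70% of usable draws (inclusive); its pooled
coefficient is the mean of the nonzero per-draw coefficients, 0 if never
selected. Draws missing an entire group are skipped with a warning and
excluded from the denominator. For inference-style pooling (distal-outcome
logistic models per draw), estimates and variances combine by Rubin's rule,
$\bar{Q} = m^{-1}\sum Q_d$, $T = \bar{W} + (1+1/m)B$.

One stated design input was internally inconsistent — a fold count of 200
described as 10% of a ~2,000-person sample. The fold count is therefore a
configuration knob (default 10; 200 available), and no result in this
package depends on that choice beyond ordinary CV noise.

The Gaussian LASSO on the baseline disease count uses the full sample
(including the 0–1-disease stratum) with the same covariate handling and
1-se rule. Biomarker z-scores are computed once on the full cohort and held
fixed across draws (recomputing within draws was the alternative; fixed-once
keeps coefficients comparable across draws).

## Disease-accumulation slopes

The longitudinal measure is the participant-specific slope of a linear
mixed model fitted by REML to the visit table:

$$\text{count}_{it} = \beta_0 + \beta_t t + \beta_a \text{age}_i +
  \beta_s \text{sex}_i + \beta_e \text{edu}_i + u_{0i} + u_{1i} t +
  \varepsilon_{it},$$

with correlated (unstructured) random intercept and slope. The
per-participant slope is the empirical-Bayes prediction
$\hat\beta_t + \hat u_{1i}$ — the shrinkage estimate, not a two-stage OLS
slope; with many visits and small residual noise the two coincide, which the
tests exploit as an oracle. These slopes are then the outcome of a single
Gaussian LASSO (1-se penalty, covariates unpenalized); biomarkers with
nonzero coefficients at the chosen penalty are the slope-associated set.

External validation transfers coefficients rather than refitting: (1) the
validation cohort's own slopes are estimated with the same mixed model;
(2) an age-adjusted OLS of those slopes on the retained biomarkers is
reported as a diagnostic — it never enters the prediction; (3) the frozen
training coefficient vector (intercept, covariates, biomarkers) is applied
to the validation design matrix; (4) the MSE between predicted and observed
slopes is reported next to the training MSE. Freezing the *full* linear
predictor (not only the retained biomarkers) is required for step 3 to
produce slopes on the right scale. By construction, validating a model on
its own training cohort reproduces the training MSE exactly, which the
suite asserts as an identity.

## PCA subprofiles

Within each multimorbidity measure, the retained biomarkers are submitted
to a correlation-matrix PCA (inputs are z-scores, so correlation rather
than covariance PCA is the natural choice). The first four components are
reported with a flag for whether their cumulative explained variance
reaches 40%. Variable contributions are $\cos^2$ values — squared
correlations between variable and component, computed as
$(\text{loading} \times \text{component s.d.})^2$; across all $p$
components they sum to 1 per variable. Component signs are canonicalized so
each component's largest-loading variable loads positively. Whether the
per-measure PCA should use all participants or only the pattern's members
was open; the default uses the full analytic sample restricted to the
measure's retained biomarkers, since retained coefficients are defined
against the whole-cohort contrast.

## Synthetic cohorts and what the tests show

The generator plants known structure so every stage is testable by
parameter recovery: latent classes with class-conditional Bernoulli
diseases; an optional low-disease stratum emulating the no-multimorbidity
group; a correlated Gaussian biomarker panel (AR(1) correlation 0.3 by
default) with class-specific mean shifts in s.d. units — directly
comparable to standardized LASSO coefficients; left-censoring of the bottom
2% of each biomarker at its empirical detection limit; and trajectories
$\text{count}_{it} = \text{count}_{i0} + a_i 1(t>0) + b_i t +
\varepsilon_{it}$ with $b_i = \gamma^\top z_i + N(0, \sigma_b)$, rounded to
non-negative integers and monotonized (chronic diseases accumulate). The
rounding/monotonization keeps counts valid while staying close to the
linear model the analysis fits.

Three scenarios ship with the package. `well_separated` (n = 2,000, K = 3,
D = 20, B = 15) uses an item-probability gap of 0.55, class shifts of
0.8 s.d. on two markers per class, and slope effects of 0.10/0.08/−0.06
diseases/year per s.d. on three markers disjoint from the class markers —
effect sizes at which recovery should be essentially certain, so failures
indicate defects rather than noise. `null_effects` (n = 800) zeroes all
biomarker effects and narrows the class gap so posteriors retain real
uncertainty; it calibrates false retention. `study_scale` (n = 2,000, K = 5
plus a 15% low-disease stratum, D = 30, B = 20, visits every 3 years to 15
years) mirrors the scale of the motivating study design, with a shared
five-marker signature across classes plus class-specific markers.

Scale choices for the heavier suites: latent-class recovery runs once at
n = 2,000 over K = 1–5; stability selection uses 200 pseudo-class draws
with 5-fold CV across five generator seeds plus one null run; the slope
pipeline runs 20 seeds. One caveat is recorded for the recovery bound: with
~425–680 members in the smallest class, the maximum item-probability error
over 60 cells has sampling noise of the same order as the 0.05 recovery
bound, so at some generator seeds that bound can be exceeded by noise alone;
the suite pins the shipped scenario seed.

What passing does **not** show about real data: the generator draws
diseases independently given class (real comorbidity has residual
dependence), biomarker effects are linear and additive on the latent scale,
trajectories are linear in time with Gaussian noise, and there is no
dropout, mortality or informative visit schedule. Recovery under these
conditions demonstrates correctness of the machinery, not robustness to
misspecification.

## Numerical choices and degenerate inputs

* EM log-likelihood is asserted non-decreasing (1e-9 slack) when a trace is
  requested; convergence is relative log-likelihood change below 1e-8.
* Item probabilities are clamped to $[10^{-6}, 1-10^{-6}]$; posterior ties
  in modal assignment break toward the larger class and are reported.
* Constant biomarker columns, constant outcomes, single-visit-only cohorts,
  non-positive-definite correlation inputs, and empty classes all raise
  informative errors rather than producing silent numbers.
* O/E and exclusivity for a never-observed disease are flagged undefined
  (`NA`), never coerced to a sentinel value.
* Penalized fits refit the path exactly (threshold 1e-12) when coefficients
  are requested at off-path penalties, so the small-penalty limit agrees
  with ordinary least squares to 1e-4 in the tests.
* All randomness flows from a single master seed through deterministic
  child seeds (recorded in the run manifest), so reruns are bit-identical.

## Interfaces

`run_full_analysis()` executes the seven stages — simulate/load, preprocess,
latent classes, labelling, selection, longitudinal, PCA — writing each
artifact as delimited text or JSON plus a manifest (config hash, seeds,
timings). Stage functions are exported individually and consume each
other's artifacts, so the pipeline is resumable per stage;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper over the same
entry point.
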