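---
title: "Prognostic-stratum matching and policy trees for treatment assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic-stratum matching and policy trees for treatment assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratarx)
```

## The problem

Observational cohorts record which patients received a treatment and what
happened to them, but treatment was assigned by clinicians, not by a coin:
sicker patients are more likely to be treated. A naive arm comparison then
shows the *treated* doing worse even when the therapy works — the classic
confounding inversion. Matching on observed covariates removes part of the
bias, but any factor that influenced both prescribing and outcome without
being recorded (an *unobserved confounder*) survives matching, and the
usual "unconfoundedness" assumption simply declares it absent.

`stratarx` implements a workflow that (1) equalizes arms within strata of
predicted baseline risk, (2) *measures* the residual bias that matching
could not remove and cancels its mean effect with a cost-sensitive weight,
and (3) turns the corrected counterfactual predictions into an
interpretable, axis-aligned policy tree whose leaves are patient subgroups
with a concrete treat / don't-treat recommendation. Recommendations are
validated on an external cohort of untreated patients with sensitivity,
specificity and NPV — recommendation-level metrics a clinician can act on.

## The model, step by step

**Baseline risk.** A probabilistic classifier $g_\theta$ is fit on the
*untreated*, training-eligible patients to predict the binary outcome at a
fixed horizon (e.g. recurrence within 7 years, 84 months). Applied to the
treated patients, $w_i = g_\theta(x_i)$ is a counterfactual: their risk
had they not been treated. Patients are then banded into $m$ contiguous
risk buckets covering $[0,1]$. Censored-before-horizon records have no
defined label; they are excluded from every model fit but retained for
policy application.

**Within-stratum matching.** Inside each bucket, the minority arm is
matched 1:1 to the majority arm by solving the assignment program that
minimizes the total squared Euclidean distance over normalized continuous
covariates, each minority patient matched exactly once, each majority
patient at most once. The constraint matrix is totally unimodular, so a
shortest-augmenting-path solver (compiled, `src/assignment.cpp`) returns
the exact binary optimum — no integer-programming dependency. Only matched
patients are retained, so both arms are equally large in every stratum and
the empirical within-stratum treatment probability is exactly 0.5,
emulating stratified randomization.

**Measuring and cancelling residual confounding.** Two counterfactual
models are fit on the matched cohort: $h_{t=0}$ on the untreated arm and
$h_{t=1}$ on the treated arm. If unobserved confounding remains, the
treated arm carries extra risk its covariates cannot explain, so the mean
gap $\hat w_{t=1} - \hat w_{t=0} > 0$ is a *lower bound* on that bias.
The remedy is cost-sensitive: records of treated patients who stayed
event-free are given loss weight $\rho \ge 1$, which pulls the treated
model's predictions down; the smallest grid weight with gap $\le 0$ is
the minimum correction. For integer $\rho$ this weighting is exactly
equivalent to duplicating the up-weighted records $\rho$ times (proved in
the tests with a weighted-logistic exact-loss learner). The untreated
model never depends on $\rho$ and is fit once per scan. A mode flag swaps
the roles for the mirror-image bias where the treated arm is spuriously
*favoured*.

**Policy tree.** Given per-patient rewards $(h_0(x_i), h_1(x_i, \rho))$,
the tree minimizes the total assigned risk
$\sum_i \mathbf 1[\tau(x_i)=0]\,h_0(x_i) + \mathbf 1[\tau(x_i)=1]\,h_1(x_i)$
by greedy recursive partitioning: every covariate and every candidate cut
(midpoints of consecutive distinct values; category subsets for factors
with at most 8 levels) is scored, recursion stops at `max_depth`,
`minbucket`, or when no split improves the objective. Numeric routing is
strict: values below the threshold go left, boundary values go right — so
a printed rule reads "mitotic count equal or greater than 10.5". Leaf
ties assign no treatment: at equal predicted risk the treatment buys
nothing, and sparing patients unnecessary therapy is the safer default.
An exhaustive depth-$\le 2$ oracle (`brute_force_policy_tree`) bounds the
greedy search in the test-suite; depth-1 greedy and oracle coincide by
construction since they score the same candidate set.

**Validation.** On an external cohort of *untreated* patients (their
baseline risk is unmodified), sensitivity is the fraction of patients with
the event whom the policy would have treated; specificity is the fraction
of event-free patients it spares. Both are prevalence-free. NPV — the
probability that a patient left untreated stays event-free — uses the
validation prevalence, and the confusion-count computation agrees with the
Bayes identity
$\mathrm{NPV} = \mathrm{spec}(1-\pi) / [(1-\mathrm{sens})\pi + \mathrm{spec}(1-\pi)]$
to machine precision. Intervals are Wilson score intervals (the method the
source tables' unstated CIs are closest to, and the standard choice for
binomial proportions at these sample sizes). The weight $\rho$ doubles as
a tunable hyperparameter: higher weights make the tree treat more people,
raising sensitivity and lowering specificity; `tune_weight` returns the
whole trade-off table and a default `max_youden` selection, because the
judgment call between marginal sensitivity gains and disproportionate
specificity losses cannot be fully automated.

**Randomized cohorts.** A trial cohort needs no weight correction
(`rct` mode refuses a weight grid). Its failure mode is different: small
trials can have sparse high-risk strata, e.g. when clinicians steer
high-risk patients away from the no-treatment arm before randomization.
`stratify` merges sparse bands top-down (sparsity concentrates at high
risk) and `oversample_strata` resamples the depleted arm with replacement
up to the per-arm target (default: the median arm size of unflagged
buckets), with duplicate records carrying their source id.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `horizon` (months) | 84 | 7-year outcome window typical for recurrence endpoints |
| buckets `m` | 6 observational, 5 RCT, 3 for n < 300 | small cohorts cannot support fine strata |
| `min_per_arm` | 5 | below this a stratum cannot be matched stably |
| `ratio_threshold` | 2 | arm imbalance beyond 2:1 (or an empty arm) flags a bucket |
| weight grid | 1.0–3.5 by 0.05 | brackets reported correcting weights with a fine step |
| `minbucket` | max(15, 3% of cohort) | 15 matches the source setting at n≈164 (~9%); the 3% rule keeps leaves meaningful in larger cohorts |
| `max_depth` | 4 | deep enough for 3-covariate interaction rules, shallow enough to read |
| forest `ntree` | 400 | prediction-mean noise must be well below the ~0.01 gap resolution |
| forest `min_node` | 5 (rewards), 25 (baseline) | reward surfaces need sharp subgroup boundaries; the baseline model needs a stable ranking |
| forest `mtry` | all features | with 3–4 clinical covariates, feature subsampling starves interaction detection |

## The synthetic world

Real registry data of this kind are available only on request, so the
package ships a generator whose defaults *are* the stated world of the
tests. The GIST-like preset draws tumor size (log-normal, median 4.5 cm),
mitotic count (over-dispersed negative binomial, median ≈ 3) and site
(27% non-gastric); the outcome logit uses these with intercept −2.0,
giving an event rate near 18.6% and a ~27% treated fraction. A single
latent standard-normal confounder $U$ enters the outcome logit with
coefficient $\gamma_y = 1$ and the treatment logit with $\gamma_t = 2$;
treatment multiplies outcome odds by $e^{-1.9}$ inside the planted
subgroup (mitoses ≥ 10, or size ≥ 5 cm and non-gastric) — an effect size
consistent with the adjuvant-trial risk reductions for high-risk disease.
$\gamma_t$ was deliberately set larger than $\gamma_y$: selection strength
is what makes the residual confounding gap clearly positive at $\rho = 1$,
while outcome-side noise is what blurs subgroup recovery. Under these
defaults the raw arm comparison inverts (treated fare worse despite the
benefit) in 20/20 seeds, the measured gap at $\rho=1$ is positive in
10/10 seeds, and the minimum correcting weight lands around 1.5–3.

The genetic-like preset adds a resistance mutation (12% prevalence) that
nullifies benefit; the sarcoma-like RCT preset assigns treatment by fair
coin and removes 85% of the untreated candidates above the 80th risk
percentile, leaving flagged sparse strata holding roughly 10% of the
cohort. RCT analyses stratify by `nomogram_risk()`, a deterministic
covariate-only risk — the analogue of using a published nomogram rather
than refitting a model on a depleted arm.

What a green test does **not** establish: the generator has uniform
administrative censoring only, no missing data, no measurement error, a
single latent confounder acting linearly on both logits, and exact binary
compliance. Real cohorts violate all of these; the tests establish that
the machinery recovers a planted truth under its own assumptions, not
that any particular clinical recommendation is correct.

## Numerical choices and degenerate inputs

* Matching ties are broken toward low patient indices via an epsilon
  secondary objective; the reported cost is recomputed from unperturbed
  distances, so optimality is exact.
* Covariate normalization uses the population (n-denominator) standard
  deviation, computed once over all matchable strata; zero-variance
  covariates are an error, not silently dropped.
* Missing covariate values are rejected everywhere — imputation would
  contaminate matching distances and is never described in this workflow.
* `find_minimum_weight` scans the grid in order and stops at the first
  closing weight; exhaustion raises an error carrying the full trace.
* Forest randomness is drawn from R's RNG, so `set.seed` makes every fit,
  match and pipeline artifact reproducible byte-for-byte.
* Buckets with an empty arm are dropped with a warning in observational
  mode (they cannot be matched) and flagged for oversampling in RCT mode;
  an all-degenerate stratification is a pipeline error.

## Known limitations

* The weight cancels the *mean* confounding gap; covariate-dependent
  confounding leaves local distortions the tree can mistake for subgroup
  structure.
* The greedy tree is exact at depth 1 and bounded by the exhaustive
  oracle in tests at depth 2, but carries no global-optimality guarantee
  at depth ≥ 2.
* Two-arm, binary-outcome, fixed-horizon problems only; no competing
  risks, no time-varying treatment.
* Validation requires an untreated external cohort; sensitivity reads
  "would have benefited" into every observed event, which presumes the
  treatment is effective for those patients.
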