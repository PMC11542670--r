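---
title: "Models and methods in gazeimpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gazeimpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeimpress)
```

# The problem

When people judge a stranger's face — how agreeable, conscientious,
extraverted, neurotic or open it looks — the judgment depends not only on
the face but on the observer. Observers differ in personality, and
personality shapes *where* they look: some dwell on the eyes, others on
the nose or mouth. `gazeimpress` implements a complete analysis chain for
studies of this kind: eye-tracking data recorded while observers view
standardized face photographs and then rate one impression per face on a
7-point scale, together with the observers' Big Five scores (TIPI,
1–7 scale, traits ordered agr, con, ext, neu, ope throughout).

The package covers four stages:

1. **Preprocessing** raw gaze streams into per-area gaze weights.
2. **A joint hierarchical Bayesian model**: a zero-inflated beta (ZIB)
   regression of gaze weights on traits, and an ordered-logistic
   regression of ratings on gaze and traits, estimated simultaneously.
3. **Posterior reporting**: split R-hat, 95% highest-density intervals
   (HDI), significance tables, random-effect significance proportions,
   predictive trait-response curves.
4. **A synthetic-study generator** with known ground truth, used for
   parameter-recovery and null-calibration studies, so every stage is
   testable without any human data.

# Gaze preprocessing

A trial yields roughly 3 s of samples at the tracker's native rate
(~120 Hz) in display coordinates (1024 × 768 px), each flagged valid or
invalid. The pipeline (`preprocess_gaze()`):

* **Sampling-rate exclusion.** The sampling rate is the valid fraction of
  samples. Sessions with a rate *below* 60% are excluded (exactly 60% is
  retained). The rate can be assessed per trial or pooled per
  subject × task session (the default, which removes a participant's whole
  task block, mirroring per-task participant counts in studies of this
  design); both modes are available because the published descriptions of
  such pipelines are ambiguous on this point.
* **Coordinate mapping.** The 412 × 558 px stimulus is assumed centered on
  the display; valid samples are translated into stimulus coordinates and
  off-canvas samples are dropped (they still count toward the sampling
  rate).
* **Kernel density.** Each sample contributes an isotropic Gaussian kernel
  (sd 10 px), a standard smoothing that acknowledges parafoveal uptake.
  For speed the kernel is truncated at 4 sd and renormalized to unit mass,
  so the total map mass equals the number of samples exactly; the
  truncation changes individual weights by less than 1e-4.
* **Masking and normalization.** Hand-drawn (or synthetic) masks label the
  eye, nose and mouth areas. The map mass inside each area is divided by
  the area's pixel count, giving a per-pixel density that corrects for
  area size. The three densities are then normalized to relative shares
  `G = (G_eye, G_nose, G_mouth)`, each in `[0, 1)`; a share of exactly 1
  (all density in one area) is clipped to `1 - 1e-6`. The share
  normalization is one admissible reading of "weight divided by area
  size": the beta likelihood below requires its support to be inside the
  unit interval, and relative shares preserve the size correction while
  guaranteeing that. Scale invariance (multiplying the map by any positive
  constant leaves `G` unchanged) follows by construction.

# The joint model

For observer $i$, face $j$ and area $k \in \{\text{eye}, \text{nose},
\text{mouth}\}$, the gaze weight $G_{ijk}$ is zero-inflated beta:

$$G_{ijk} \sim \mathrm{ZIB}(q_{ijk}, a_{ijk}, b_{ijk}), \qquad
\mathrm{ZIB}(g) = \begin{cases}
1 - q_{ijk} & g = 0\\
q_{ijk}\,\mathrm{Beta}(g \mid a_{ijk}, b_{ijk}) & g > 0
\end{cases}$$

The Bernoulli part ($q$, "was the area looked at at all") and the beta
part ($\mu$, "how much, given it was looked at") are both logistic
regressions on the observer's five trait scores $p_{il}$ with subject and
face random intercepts:

$$\operatorname{logit} q_{ijk} = \alpha^Z_k + \sum_{l=1}^5 \beta^Z_{kl}
p_{il} + r^Z_{ik} + r^Z_{jk}, \qquad
\operatorname{logit} \mu_{ijk} = \alpha^B_k + \sum_{l=1}^5 \beta^B_{kl}
p_{il} + r^B_{ik} + r^B_{jk},$$

with the mean–precision parameterization $a = \phi_k \mu$,
$b = \phi_k (1 - \mu)$. The 7-point rating $Y_{ij}$ is ordered-logistic
with cutpoints $c_1 < \dots < c_6$:

$$Y_{ij} \sim \mathrm{OrderedLogistic}(\eta_{ij}, c), \qquad
\eta_{ij} = \sum_{g} \beta^{RG}_g x_{ijg} + \sum_{l} \beta^{RP}_l p_{il}
+ r^R_i + r^R_j,$$

where the gaze design $x_{ij}$ holds the three observed gaze weights,
their three pairwise products and the triple product. Using the observed
weights (rather than their model-implied expectations) as covariates is
the reproducible default; `predict_rating_curve(gaze = "model")` exposes
the model-implied alternative. All blocks are estimated simultaneously in
one posterior (`fit_joint()`), one joint model per impression task. The
subject and face random intercepts of the ZIB and rating blocks are
independent — the model lists them as separate effects, and sharing them
is a modelling choice we deliberately avoid.

For gaze-manipulation designs (between-subject Free/Eye/Nose/Mouth
conditions), `fit_condition_model()` replaces the predictors with
reference-coded condition effects ($\beta_{\text{Free}} \equiv 0$), so
each posterior contrast against Free is the condition effect itself.

## Priors

* Fixed effects (intercepts, trait, gaze, condition coefficients):
  Normal(0, sd 10), i.e. variance 100 — weakly informative on the logit
  scale.
* Random-effect scales: $\sigma \sim \mathrm{Gamma}(10, 10)$ (mean 1,
  sd ≈ 0.32), with effects $r \sim \mathrm{Normal}(0, \sigma)$. A gamma
  prior cannot sit on the signed effects themselves; placing it on the
  scales is the standard reading and keeps the hierarchy away from the
  degenerate $\sigma = 0$ funnel.
* Beta precisions: half-Normal(0, 10), positive and weakly informative.
* Cutpoints: Normal(0, sd 10) on each, subject to strict ordering —
  effectively flat over the plausible range while keeping the posterior
  proper and the sampler stable.

## Sampler

The joint posterior is smooth in all parameters once positives are
log-transformed and the cutpoints are rewritten as a first cutpoint plus
log-increments, so the package uses Hamiltonian Monte Carlo with analytic
gradients, implemented in C++:

* dual-averaging step-size adaptation toward an 0.8 acceptance rate, with
  a diagonal mass matrix estimated from the middle warmup window;
* jittered leapfrog trajectories of fixed integration time (±20%), capped
  at 64 steps;
* trait and gaze covariates are mean-centered internally for conditioning
  and every draw is transformed back to the raw 1–7 covariate scale, a
  pure reparameterization;
* interior leapfrog steps evaluate only the gradient (the `lgamma` terms
  of the beta likelihood cancel from it), and the gradient uses a fast
  series `digamma`; the accept/reject step always uses the exact log
  posterior, so the invariant distribution is untouched.

The compiled log posterior is verified in the test suite against a pure-R
reference (`joint_log_posterior()`) to 1e-10 and its gradient against
central finite differences; the whole sampler is cross-checked against an
independent Gibbs implementation (JAGS) on a reduced dataset.

Default sampling follows the reference configuration of such studies:
4 chains, 2000 iterations each with 1000 warmup, thin 1 — 4000 retained
draws. Convergence is declared when every parameter's split R-hat is
below 1.1; a fit violating the rule is flagged with a warning and in
`glance()`, never silently accepted.

## Summaries

An effect is "significant" when its 95% HDI — the shortest contiguous
interval holding 95% of the draws, assuming unimodality, which holds for
these regression posteriors — excludes 0. `significance_table()` reports
significant fixed effects in the conventional layout (component,
impression, area, predictor, mean, HDI bounds, rounded to 3 decimals with
flags computed before rounding); `ranef_significance_props()` reports the
percentage of subject, face, and pooled subject-or-face random intercepts
whose HDI excludes 0 (the pooled denominator is the union of both sets).
`predict_gaze_curve()` and `predict_rating_curve()` sweep one trait over
1–7 with the others fixed at their sample means and random effects at 0;
the point estimate is the highest-posterior retained draw (the MAP draw;
a posterior-mean variant is available), and because "gaze weight" can
mean the beta mean or the unconditional expectation, both `mu` and
`q * mu` are emitted, labelled.

# The synthetic-study generator

`sim_study()` draws a complete study from known parameters: trait
profiles, per-task face sets (each face appears in exactly one impression
task, 10 faces per task by default), ZIB gaze weights and
ordered-logistic ratings with fresh Normal(0, σ) random effects per
subject and face. `sim_gaze_stream()` additionally renders raw tracker
streams (uniform placement within the attended area plus 5 px Gaussian
jitter at 120 Hz for 3 s, with a configurable validity rate), and
`sim_masks()` builds elliptical stand-ins for hand-drawn masks.

Choices a reader should know about:

* **Trait distribution.** Truncated normal on [1, 7], mean 4, sd 1.2 per
  trait, independent across traits. Published work of this kind does not
  report the observed trait distribution or inter-trait correlations, so
  these defaults are a scientist's-choice calibration to typical TIPI
  samples, not to any particular study sample.
* **Ground-truth effects.** The default `default_true_params()` places an
  extraversion effect of +0.8 on looking at the eyes and an agreeableness
  effect of −0.3 on the nose gaze weight — the magnitudes such studies
  report for their clearest effects — an agreeableness effect of +0.4 on
  ratings, and a +0.5 Eye-condition effect in the contrast model;
  everything else is 0. Intercepts are set so looking probabilities and
  mean weights are moderate (≈ 0.6–0.75 and 0.25–0.4) at the trait-scale
  midpoint; precisions φ = 8 give the right-skewed weight distributions
  seen in real data.
* **What it does not emulate.** Fixation sequences and saccade structure
  (only area-level mass matters downstream), pupilometry, photoreal
  faces, correlated traits, or one-inflation. Passing recovery tests
  therefore demonstrates the estimator is consistent with its own
  generative assumptions — not that those assumptions exhaust real data.

# Verification by simulation

The acceptance layer (`tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) re-derives, from scratch:

* density normalization of the ZIB mixture (quadrature, 1e-8) and the
  ordinal pmf (1e-12, against CDF differencing);
* kernel-map mass conservation (1e-6), hand-computed toy-map weights, and
  the exact 60% exclusion boundary;
* HDI calibration on 1e5 standard-normal draws (endpoints within ±0.05 of
  ±1.96) and equality with a brute-force shortest-window search;
* **parameter recovery**: 20 replicate studies of 34 subjects × 10 faces
  (the scale of the motivating experiments), fitted with a reduced
  configuration (2 chains, 500 warmup + 500 kept) chosen so the full
  study runs at desk scale; ≥ 90% of the 48 true fixed effects must fall
  inside their 95% HDIs and the two planted gaze effects must keep their
  signs in ≥ 18/20 replicates;
* **null calibration**: with all fixed effects zero, the HDI-excludes-0
  rate per fixed effect across the same design must stay ≤ 10%. With 20
  replicates an individual effect's rate has 5% granularity and ~5%
  binomial sd, so the claim is assessed on the rate across the 48 null
  effects (observed: well under the nominal 5%), with a per-effect guard
  three binomial standard errors above 10% against gross miscalibration;
* **condition-contrast recovery**: the planted Eye effect must be
  detected, and the null Nose contrast not flagged, in ≥ 18/20
  replicates. At the stated effect size (0.5) and the design's group
  sizes, the contrast posterior sd is ≈ 0.17, putting per-replicate
  detection power near 0.85 — so this bar sits at the edge of what the
  design affords, and runs landing at 17/20 reflect datasets whose
  sampled effect was genuinely small, not estimator failures.

Under the reduced configuration a few random-intercept parameters can
show split R-hat slightly above 1.1 (the global intercept and the face
intercepts form a weakly identified ridge that mixes slowly); fits are
flagged accordingly, and the recovery criteria are computed on the flagged
fits as they stand. The full default configuration mixes cleanly.

# Known limitations

* One joint model per impression task; no sharing of information across
  tasks.
* Logit links only; no probit variant, no one-inflation, no covariance
  between a subject's random effects across sub-models.
* The HDI routine assumes unimodal marginals.
* The sampler is purpose-built for these two model shapes; it is not a
  general-purpose probabilistic-programming backend.
* Time-resolved analyses (fixation order, dwell dynamics) are out of
  scope; the area-weight representation discards them by design.
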