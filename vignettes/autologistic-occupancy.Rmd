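---
title: "Autologistic multi-season occupancy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autologistic multi-season occupancy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aloccu)
```

## The model

Multi-season occupancy models describe a species' presence at monitored
sites over years when detection is imperfect. Let `z[i,k]` be the latent
occupancy state of site `i` in year `k` and `y[i,j,k]` the 0/1 outcome of
sampling occasion `j` (here, a block of 5 consecutive trap-days collapsed to
one detection/nondetection value). The model has two coupled parts.

**Occurrence.** Occupancy in the first year depends on its own intercept and
the site covariates; from year 2 on, the intercept shifts by `alpha1`
whenever the site was occupied the previous year:

```
logit(psi[i,1]) = alpha2 + alphaS*SNARES[i,1] + alphaE*ELEV[i] + alphaE2*ELEV2[i]
logit(psi[i,k]) = alpha0 + alpha1*z[i,k-1] + alphaS*SNARES[i,k]
                  + alphaE*ELEV[i] + alphaE2*ELEV2[i] + alphaB*BAN[k]
z[i,k] ~ Bernoulli(psi[i,k])
```

This autologistic form trades the separate colonization and extinction
submodels of the classical dynamic parameterization for a single occurrence
equation: `plogis(alpha0)` is the colonization probability of an unoccupied
site, `plogis(alpha0 + alpha1)` the persistence probability of an occupied
one, and every covariate effect acts on occurrence itself. That is the
natural choice when the scientific questions are about occupancy (does
hunting pressure depress it? did a management ban raise it?), not about
colonization or extinction separately. The full
colonization/extinction model with its own covariates on each component is
deliberately out of scope.

**Detection.** Given presence, each sampled occasion detects the species
with a site-specific probability constant over occasions and years:

```
y[i,j,k] ~ Bernoulli(p[i] * z[i,k]),    logit(p[i]) = beta0 + betaB*BORDER[i]
```

Distance to the protected-area border enters detection, not occurrence:
animals near the edge are expected to be more elusive (denser understory,
more disturbance), so `betaB > 0` means detection improves away from the
border. Because the detection equation carries no occasion or year terms, an
occasion-varying `p` is not supported; users who need one must pre-aggregate
or extend the model.

## Covariates and their preparation

| term | unit | varies over | standardization |
|------|------|-------------|-----------------|
| ELEV | m a.s.l. | sites | over sites (mean 0, sample variance 1) |
| ELEV2 | — | sites | square of standardized ELEV, left as is |
| BORDER | distance | sites | over sites |
| SNARES | count | site-years | one mean/sd over all site-year cells |
| BAN | 0/1 | years | none |

Two conventions deserve a note, because either could plausibly be done
differently:

* **Snares are standardized jointly over all site-year cells**, not year by
  year. A per-year transform would erase exactly the between-year decline in
  snaring the model is supposed to relate to occupancy; with a single
  transform, a given snare count means the same thing in every year.
* **ELEV2 is the square of standardized elevation** and is itself left
  unstandardized. Squaring after centering keeps the quadratic term small
  near the middle of the gradient and roughly orthogonal to the linear term,
  which helps the sampler; squaring raw meters first and then standardizing
  would give a nearly collinear pair.

Standardization uses the sample standard deviation (denominator n − 1), so
standardized columns have unit sample variance exactly; `standardize()`
returns the transform parameters so new data can be mapped through the same
transform, and `destandardize()` inverts it.

`pearson_r()` screens covariate pairs and warns at |r| ≥ 0.7 (configurable).
Collinear covariates are tolerable when they sit in different model parts —
elevation (occurrence) and border distance (detection) being the canonical
example — which is why the screen warns rather than errors.

## Occasion aggregation

Daily camera records (an operating flag and a detection flag per day) are
collapsed into occasions of `occasion_length_days` (default 5) calendar
days: an occasion is 1 if any operating day in the block recorded a
detection, 0 if operating days recorded none, and missing if no day in the
block was operating. Trailing partial occasions are kept: deployments of
30–35 days would otherwise silently lose up to 4 days (about an occasion's
worth) of effort per site-year. A detection on a non-operating day is an
error, never coerced — it indicates corrupted upstream data. Missingness is
binary per occasion; there is no partial-effort offset because the detection
model has no effort term.

## Exact marginal likelihood

The package never data-augments `z` during fitting. Each site's likelihood
is computed by a two-state forward recursion along its year chain: start
from mass `(psi[i,1], 1 − psi[i,1])`, multiply per year by the emission
probability of that year's occasion history (a product of Bernoulli terms
over sampled occasions; missing occasions contribute 1; a detection makes
the unoccupied branch impossible), and propagate through the 2×2 transition
matrix built from the autologistic equation. Because `p[i]` is constant
within a site, the emission depends on the history only through the number
of sampled occasions `J` and detection-positive occasions `d`, which is
precomputed once per dataset — a likelihood evaluation at 60 sites × 8 years
costs ~0.2 ms, which is what makes plain-R MCMC practical here.

Years with zero effort advance the chain with unit emission instead of
collapsing adjacent years, preserving the meaning of "previous year" in the
autologistic term. Per-year renormalization of the forward mass prevents
underflow on long series. The recursion is verified in the test suite
against brute-force enumeration of all `2^K` latent sequences (tolerance
1e-10) and against closed forms for single-season histories.

## Inference

**Priors.** Independent Normal(0, sd = 10) on every free logit-scale
parameter, the conventional "uninformative" choice for this model family.
The sd is exposed (`model_spec(prior_sd = )`) because flat-ish logit-scale
priors are not innocuous: on the probability scale sd = 10 piles mass near 0
and 1, and analyses sensitive to that should try sd ∈ {2.5, 5, 10}.

**Sampler.** Adaptive random-walk Metropolis on the joint vector of free
parameters. During burn-in the proposal covariance is adapted to the running
empirical posterior covariance (scaled by 2.38²/d) with a Robbins–Monro
scale adjustment toward 23% acceptance; adaptation freezes at the end of
burn-in, so the retained draws come from a fixed, valid Markov kernel. With
9 parameters and the marginalized likelihood this mixes well: the reduced
protocol (3 chains × 5,000 iterations, 1,000 burn-in, thin 5 → 2,400
retained draws) reaches Rhat < 1.05 on the reference scenario in a few
seconds. The survey-scale default protocol (3 × 100,000, burn-in 5,000,
thin 20) matches long-run field practice for these models and is available
through `mcmc_config()` defaults.

**Initialization.** Occurrence intercepts start at the logit of the naive
occupancy proportion (fraction of site-years with ≥ 1 detection), the
detection intercept at the logit of the naive per-occasion detection
frequency, covariate effects at 0, each chain jittered independently; a
non-finite posterior after 100 jitter redraws is an initialization error.

**Convergence.** `gelman_rubin()` implements the plain potential scale
reduction factor: with `m` chains of length `n`, within-chain variance `W`
and between-chain mean variance `B/n`, `Rhat = sqrt(((n−1)/n · W + B/n) /
W)`, floored at 1 because the finite-sample factor can push the ratio
marginally below 1 for perfectly agreeing chains and sub-1 values carry no
diagnostic content. The usual 1.1 threshold gates the strict mode of the
command-line `fit`.

**Maximum likelihood.** `fit_mle()` maximizes the same marginal likelihood
(BFGS, multiple jittered starts) and flags degenerate fits — a species never
detected, or estimates running to the logit boundary. It doubles as an
independent cross-check of the sampler: with prior sd 10⁶ the posterior mean
must sit within half a posterior SD of the MLE, which the suite verifies on
a 150-site simulation.

## Derived quantities

Colonization `plogis(alpha0)` and persistence `plogis(alpha0 + alpha1)` are
transformed draw by draw, then summarized by the posterior mean and
equal-tailed 95% credible interval; because the transform is monotone, the
interval endpoints commute with it. A `distinct` flag records whether the
two intervals fail to overlap — the conventional mark for a clear
colonization/persistence difference. Effects are "significant" when their
95% interval excludes zero.

**Yearly mean occupancy** is, by default, the finite-sample average of the
latent states over the monitored sites, `(1/N) Σ_i z[i,k]`, with `z` drawn
from its exact conditional distribution given the data and the parameter
draw by forward-filtering backward-sampling. This conditions on what was
actually observed: a site with a detection in year `k` contributes `z = 1`
with probability one. The alternative — averaging model-expected smoothed
probabilities instead of sampled states — is available via
`type = "expected"`; it removes the finite-sample Bernoulli noise and is the
better choice when the target is the underlying occupancy probability rather
than the realized fraction of occupied sites. Which of the two a published
trajectory shows is often ambiguous; both are first-class here, finite-sample
being the default because it matches the autologistic model's conditioning
on realized states.

## Goodness of fit

The posterior-predictive check uses a Pearson chi-square-type discrepancy at
the site-year level. Marginalizing over the latent state, the detection
count `d` of a site-year is a mixture of Binomial(J, p) (weight psi) and a
point mass at 0, so

```
E[d]   = psi·J·p
Var[d] = psi·J·p·(1−p) + psi·(1−psi)·(J·p)²
D      = Σ (d − E[d])² / (Var[d] + 1e-6)
```

summed over sampled site-years, with `psi` the chain-implied marginal
occupancy of the cell. For each retained draw a replicate survey is
simulated under the drawn parameters on exactly the observed effort mask,
and the Bayesian p-value is the fraction of draws whose replicated
discrepancy exceeds the observed one, ties counted one half (unbiased under
exchangeability). Values outside (0.05, 0.95) flag inadequacy. Site-year
aggregation (rather than per-occasion cells) keeps the variance closed-form
and is the standard occupancy choice; alternative discrepancies
(Freeman–Tukey, deviance) are not implemented beyond this hook. On surveys
simulated from the model the p-value centers somewhat below 0.5 (≈ 0.35 in a
16-replicate calibration sweep) — the familiar behaviour of this statistic,
whose observed term is evaluated at posterior draws rather than the truth —
and the deliberate-misfit harness in the test suite (histories overwritten
to all-detections at half the sites) drives it to 0.

## The synthetic survey generator

`scenario()`/`preset()`/`simulate_dataset()` generate surveys with the
structure the model assumes, for testing, calibration and power analysis:

* 60 sites × 8 years by default; deployments of 30–35 days (uniform), cut
  into 5-day occasions with the trailing partial occasion kept; 2% of
  occasions lost to camera failure (each site-year keeps at least one).
* Elevation uniform on 290–2,300 m; border distance (0–6 km) generated via a
  Gaussian copula targeting a 0.7 Pearson correlation with elevation, the
  realized correlation accepted within ±0.1 (else redrawn, up to 50 times).
* Snare counts negative binomial (size 5 — field counts are clumped), yearly
  means declining linearly from 8 to ~0 per deployment, accepted when the
  pooled count-year correlation is within ±0.1 of −0.7.
* The ban switches on at year 4 and stays on: `(0,0,0,1,1,1,1,1)`.
* The latent chain and detections are drawn by a forward run of the model's
  own generative equations, so the generator shares its parameter semantics
  with the likelihood but none of its code path.

The correlation targets are descriptive bands, not exact constraints,
because that is how such field correlations are reported. Presets encode
species archetypes on the logit scale: `"harvey"` (common antelope:
colonization 0.71, persistence 0.88, snare effect −0.49, detection ≈ 0.5
rising away from the border), `"suni"` (scarce edge species with a
mid-elevation peak and a +0.49 ban effect), `"sengi"` (high-elevation
specialist; the snare covariate structurally excluded from its model spec),
and `"null"` (all effects zero, colonization = persistence = 0.5).
Archetype values not tied to a reported estimate (first-year intercepts, the
elevation slopes, detection intercepts) were fixed once at field-plausible
magnitudes and are documented in `preset()`.

What the generator does **not** emulate: spatial autocorrelation between
sites, animal movement and home ranges, photo-event dependence within
occasions, observer/camera heterogeneity in detection, and year effects on
detection. Passing tests therefore demonstrate that the pipeline recovers
the model's own truth under the model's assumptions — not that those
assumptions hold for any particular field system.

## Problem sizes and numerical choices

The test suite and the acceptance script run the reference scenario at its
natural size (60 sites, 8 years) with the reduced MCMC protocol; the
parameter-recovery experiment uses 20 replicate surveys and the MLE
consistency checks use 150–200 sites. These sizes give stable Monte-Carlo
behaviour (coverage assessed over 180 intervals; recovery within 3 posterior
SDs) while a full check runs in about two minutes.

Other numerical decisions, collected: `inv_logit()` switches its lower tail
to `exp(x)` below −30 so extreme logits underflow gracefully rather than to
an exact 0; the forward recursion renormalizes every year; the discrepancy
denominator carries ε = 1e-6; equal-tailed intervals use R's default
(type-7) quantiles; GOF ties count one half; constant covariates are a hard
error for standardization except the all-zero snare matrix, which encodes
"no snare covariate" and maps to a structurally zero effect.

## Known limitations

* Detection is constant per site; no occasion, year or behavioural effects.
* One species per fit; no community/hierarchical sharing of parameters.
* No model selection machinery (WAIC/DIC) — compare fits by design, not
  automatically.
* Snare counts recorded per array of cameras must be apportioned to sites by
  the user before loading; the package takes site-level values as given.
* The sampler is tuned for the model's ~9 parameters; much larger covariate
  sets would warrant gradient-based samplers.
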