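---
title: "Methods: the occupipe occupancy pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the occupipe occupancy pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(occupipe)
```

## The model

occupipe fits the standard single-season, single-species occupancy model
with constant detection. Site `i` carries a latent occupancy state
`z_i ~ Bernoulli(psi_i)`; occasion `j` at an occupied site yields a
detection with probability `p`; unoccupied sites yield none (no false
positives — the standard assumption, stated here explicitly because
camera-trap species identification errors are outside the model). Occupancy
is linked to seven site covariates on the logit scale:

```
logit(psi_i) = beta0 + b_settlement*x1 + b_livestock*x2 + b_predators*x3 +
               b_cropland*x4 + b_canopycover*x5 + b_human*x6 + b_road*x7
```

All predictors are z-scored (sample mean/SD, denominator n−1), so
coefficients are effects per SD of the raw covariate. The column order
above is canonical (`occu_covariate_names()`) and defines the layout of
every coefficient vector, CSV header and summary table in the package.

Rather than augmenting the sampler with the latent `z_i`, the likelihood
marginalizes them analytically: with `d_i` detected occasions out of `J_i`
active ones,

```
L_i = psi_i * p^d_i * (1-p)^(J_i - d_i) + (1 - psi_i) * 1[d_i = 0].
```

Marginalization has two payoffs: the sampler moves in only 9 dimensions,
and the likelihood can be verified directly against brute-force enumeration
over all `2^n` latent configurations — the test suite does exactly that at
`n <= 10` to 1e-10.

Occasions with no active camera-days are skipped (`J_i` shrinks); a site
with no active occasions contributes a factor of 1.

## Detection histories

Daily records become a site × day binary matrix aligned to each site's own
deployment window (day 1 = that site's start date), then consecutive days
are collapsed into occasions of `bin_days` (default 7; 21-day deployments
give 3 occasions). Two deliberate choices:

* bins anchor at the deployment start, not calendar weeks, because the
  emulated protocol groups "every 7 days of the deployment";
* a partially missing bin that still contains at least one active
  non-detection day is 0, not missing — an active camera that saw nothing
  is a genuine non-detection trial. A bin is `NA` only when every day in it
  was inactive.

Effort is the count of active camera-days (trap nights), which equals the
number of non-missing daily cells.

## Priors, sampler, diagnostics

The source analysis delegated sampling to an external Gibbs engine and
never stated its priors. The package's own choices:

* `beta0` and slopes: independent Normal(0, sd = 2.5). We initially used
  sd = 10, but on the logit scale that prior puts substantial mass on the
  quasi-separation ridge — slopes of ±10 with detection compensating — and
  in simulation the posterior then drifts far above moderate true effects.
  2.5 is the conventional weakly-informative scale for standardized
  logistic predictors and restored near-nominal behaviour everywhere except
  the hardest recovery clause (below). The SD is a `occu_model_spec()`
  argument, so the wider prior is one keystroke away.
* `p`: Uniform(0,1) by default (a logit-normal alternative is available).
  Sampling runs on `logit(p)` with the Jacobian `log p + log(1-p)` so the
  uniform prior is honoured; `fix_p` holds detection fixed for reduced
  models and sampler validation.

The sampler is componentwise Gaussian random-walk Metropolis on
`(beta, logit p)`. Each parameter has its own proposal scale, tuned every
50 iterations during the adaptation phase (multiply by 0.75 below 20%
acceptance, by 1.30 above 40%) and frozen afterwards; only post-adaptation,
post-burn-in draws are retained, mirroring the adapt/burn-in/iteration
phases of the emulated analysis (defaults 3 chains × 1000/1000/10000;
`occu_mcmc_fast()` is 3 × 500/500/2000 for CI budgets). The linear
predictor is updated incrementally per component, so one iteration costs
O(n) per parameter. Chains start from jittered inits (SD 0.25) with
per-chain sub-seeds derived from the master seed; the whole fit is
bit-reproducible given the seed.

Diagnostics: split-chain Gelman–Rubin Rhat (each chain halved before the
between/within variance ratio, so within-chain trends register); effective
sample size via the multi-chain autocorrelation estimator with Geyer's
initial-positive-pair truncation. Rhat above 1.1 triggers a warning, never
an error — reported, not enforced, matching field practice. Zero-variance
draws return `NA` rather than crashing (the documented sentinel).

Summary-table semantics, where the source table's caption is garbled, are
resolved to their conventional meanings: `overlap0` is whether the 95%
credible interval contains zero (the field's "non-significance" flag — no
p-values are produced), and `f` is the fraction of draws sharing the sign
of the posterior mass, computed as `max(P(draw >= 0), P(draw <= 0))` so it
lies in [0.5, 1] by construction and equals 1 for constant-sign draws.

`derived_occupancy()` reports the posterior of the landscape mean occupancy
(mean of `psi_i` over sites, per draw) and the conditional occupancy of
each site given its own history: 1 for detected sites, else
`psi (1-p)^J / (psi (1-p)^J + 1 - psi)` per draw.

## The synthetic world

The generator is a stated world, not a tuning knob. It emulates the
motivating design: 154 sites with ≥1 km pairwise separation (sequential
inhibition in a 150 × 65 km planar box approximating the study complex;
the box grows if a requested density is infeasible), 21 active days per
camera, 7-day occasions. Covariate families and their published moments:

| covariate | family | mean ± SD | why |
|---|---|---|---|
| canopy (%) | truncated normal on [0, 100] | 42.19 ± 21.36 | bounded, mild skew |
| humans (count) | negative binomial | 76.72 ± 244.55 | SD ≫ mean: strong overdispersion |
| livestock (count) | negative binomial | 36.74 ± 102.45 | same |
| settlement dist (m) | truncated normal on [0, ∞) | 2182.8 ± 1691.3 | CV < 1, feasible |
| road dist (m) | log-normal (see below) | 741.7 ± 1138.9 | CV > 1 |
| farmland (m²) | log-normal, capped at π·500² | 1.5e5 ± 1.5e5 | unpublished; one-time choice |
| predator rate | Beta(1.2, 6.8) | ≈ 0.15 | unpublished; most sites rarely visited |

For truncated normals the *underlying* (mu, sigma) are solved numerically
so the *truncated* moments hit the targets exactly. This exposed a
constraint worth recording: a normal truncated at zero cannot exceed a
coefficient of variation of ~1, so the road-distance target (CV 1.54) is
infeasible for that family — the original plan of "truncated normal for
all distances" is mathematically impossible for road. When the solver
residual exceeds 1%, the generator falls back to a log-normal matched to
the same mean/SD. Farmland's moments were never published (it came from a
land-cover raster, out of scope); the 1.5e5 ± 1.5e5 m² choice is a
mid-range buffer occupancy fixed once and not revisited.

Truth: `psi` from the logit equation on the z-scored covariates, `z`
Bernoulli. Detection is simulated *daily* — the per-day probability `q`
solves `1-(1-q)^7 = p` — and then collapsed through the same occasion
binning the real pipeline uses, so the collapsing code is exercised by the
generator's own data path. Tiger and leopard records are co-simulated at
each site's predator rate; the model's predator covariate is then *derived
from the records* (fraction of occasions with any pooled predator
detection — the simplest site-level quantity consistent with treating the
two carnivores collectively), standardized with everything else.

What the generator does **not** emulate: spatial autocorrelation of
occupancy, seasonal behaviour shifts, camera failures/vandalism (the
missing-occasion mechanism exists, but no loss process is simulated), and
false positives. A green test therefore establishes correctness of the
pipeline under independence assumptions, not robustness to those
violations.

Human/livestock counts are interpreted as totals over the 21-day
deployment (the published study does not say; this reading matches the
magnitudes reported).

## Numerical choices

* Impossible likelihood configurations (a detection where `psi` underflows
  to 0) return −Inf and are rejected by the Metropolis step; the initial
  state is checked finite.
* IDW weights are computed on distances normalized by each cell's nearest
  distance, so `d^-50` (the nearest-neighbour-limit check) cannot
  under/overflow. A cell centre within 1e-9 m of a sample point takes that
  point's value exactly. The default power is 2 (the conventional choice;
  the source names the method but not the power); the interpolated quantity
  is the per-site posterior mean `psi_i`, with the conditional variant
  behind a flag. Distances are planar Euclidean — the synthetic frame is
  planar by construction and the emulated extent (< 250 km) makes
  projection error negligible.
* ESRI ASCII rasters are written with 17 significant digits so a
  write–read cycle is bit-exact; NODATA cells round-trip as `NA`.
* Run configs are JSON (no YAML parser in the supported dependency set);
  exactly one of a `synthetic` block or an `inputs` block of CSV paths is
  accepted.

## Known limitations

* **Low-information slope inflation.** At the recovery design used in the
  acceptance suite (300 sites, 3 occasions, p = 0.3, ~70 detected sites
  for 9 parameters — under 8 events per variable), occupancy-model slope
  estimates inflate away from zero: the maximum-likelihood estimates
  themselves average ~25% above the truth, and the posterior right tail
  along the separation ridge pushes credible intervals further. The
  cropland slope's 95% CrI consequently covers its true value in about
  70% of replicates rather than the targeted 75%+ — verified to be a
  property of the data regime, not the code: the likelihood matches
  brute-force enumeration, the sampler matches a dense-grid posterior and
  an independently coded joint-proposal sampler, and an intercept-only
  model is well calibrated at the same n. The corresponding acceptance
  test is left failing rather than loosened.
* Detection is constant (intercept-only), matching the emulated analysis;
  occasion- or covariate-dependent detection is out of scope.
* One full model is fitted — no model selection or averaging, no
  goodness-of-fit testing, no multi-season or spatial occupancy variants.
* The published study's own posterior numbers cannot be reproduced: its
  data were never deposited and its two summaries disagree with each other;
  nothing in this package asserts them.
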