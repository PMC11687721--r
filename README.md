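# occupipe

Camera-trap occupancy analysis as a single tested pipeline: from daily
detection records to a Bayesian single-season occupancy model with
covariates, convergence diagnostics, and an inverse-distance-weighted
occupancy surface.

## The problem

Camera-trap surveys of elusive wildlife (the motivating case is a nocturnal
burrowing rodent in a human-dominated lowland landscape in Nepal) almost
never detect a species everywhere it occurs. The *single-season,
single-species occupancy model* separates the probability that a site is
occupied from the probability of detecting the species given presence. With
sites `i = 1..N` surveyed over `J` sampling occasions:

```
z_i ~ Bernoulli(psi_i)                    latent occupancy
y_ij | z_i ~ Bernoulli(z_i * p)           detection, constant p
logit(psi_i) = beta0 + beta' x_i          seven standardized covariates
```

The covariates (in the canonical order used everywhere in the package) are
distance to settlement, livestock activity, large-predator (tiger + leopard)
activity, farmland area within 500 m, canopy cover, human activity, and
distance to road. The latent `z_i` are marginalized analytically, so each
site contributes

```
psi_i * p^d_i * (1-p)^(J_i - d_i) + (1 - psi_i) * 1[d_i = 0]
```

to the likelihood (`d_i` = occasions with detections, `J_i` = active
occasions). Inference is by an adaptive componentwise random-walk Metropolis
sampler with Normal(0, 2.5) priors on the logit-scale coefficients and
Uniform(0,1) on `p`; summaries report posterior mean, SD, 95% credible
interval, split-chain Rhat, effective sample size, `overlap0` and the `f`
statistic — the conventional occupancy summary table. Per-site posterior
mean occupancy is interpolated onto a regular grid by inverse distance
weighting (IDW) and written as an ESRI ASCII raster.

Because the motivating study's field data were never deposited, the package
ships a first-class synthetic-data module that emulates the study design —
154 sites at least 1 km apart, 21 active days each (3234 trap nights),
7-day occasions (3 per site) — and the reported covariate moments (canopy
42.19 ± 21.36 %, humans 76.72 ± 244.55, livestock 36.74 ± 102.45, road
741.69 ± 1138.91 m, settlement 2182.80 ± 1691.33 m).

## Worked example

```r
library(occupipe)

sim   <- simulate_survey(n_sites = 154, n_days = 21, bin_days = 7, seed = 42)
daily <- build_daily_matrix(sim$records, sim$deployments, "porcupine")
occ   <- collapse_occasions(daily, bin_days = 7)
effort(sim$deployments)            # 3234 trap nights
naive_occupancy(occ)               # 36 of 154 sites = 0.234

covs <- prepare_covariates(sim$sites, sim$records, sim$deployments)
correlation_screen(covs, 0.7)      # empty: no |r| > 0.7, keep all predictors

fit <- run_mcmc(occ, covs, spec = occu_model_spec(),
                config = occu_mcmc_fast(seed = 42))
summarize_posterior(fit)
```

```
         parameter    mean     sd     LCI    UCI Rhat n.eff overlap0     f
1            beta0 -0.0419 0.6873 -1.1716  1.580 1.00   290     TRUE 0.573
2  beta_settlement -0.7644 0.5206 -1.9039  0.171 1.01   499     TRUE 0.945
3   beta_livestock  0.5473 0.7040 -0.6427  2.149 1.00  1001     TRUE 0.784
4   beta_predators  0.9605 0.6687 -0.0947  2.451 1.01   380     TRUE 0.956
5    beta_cropland  2.8139 0.7959  1.4394  4.649 1.01   635    FALSE 1.000
6 beta_canopycover -1.9948 0.7500 -3.7042 -0.735 1.01   528    FALSE 1.000
7       beta_human -1.0197 1.1763 -3.5382  1.161 1.00  1035     TRUE 0.839
8        beta_road -0.0923 0.5656 -1.2407  0.944 1.00   874     TRUE 0.559
9                p  0.2270 0.0423  0.1511  0.316 1.00   300    FALSE 1.000
```

The simulation truth behind these data has a positive farmland effect
(+1.5), a negative canopy effect (−1.0) and zero for the rest: the fitted
`overlap0 = FALSE` rows single out exactly those two covariates, with the
correct signs (`f = 1`: every posterior draw agrees on the sign). `Rhat`
near 1 says the three chains mixed; `LCI`/`UCI` are the 2.5%/97.5%
posterior quantiles.

```r
d <- derived_occupancy(fit, covs)
# mean occupancy 0.453 +/- 0.064 (posterior SD); detection p 0.227

surf <- idw_interpolate(
  data.frame(x = sim$sites$x, y = sim$sites$y, value = d$psi_site),
  n_cols = 40, margin = 1000)
write_surface(surf, "surface.asc")   # ESRI ASCII grid, values in [0, 1]
```

The whole chain — simulate (or read CSVs), build matrix, screen covariates,
fit, summarize, interpolate — also runs as one call or from the shell:

```r
run_pipeline(list(synthetic = list(), seed = 42, fast = TRUE,
                  output_dir = "run"))
```

```sh
inst/cli/occupipe run-all --config config.json --seed 42 --fast
```

`config.json` holds either a `synthetic` design block or an `inputs` block
of CSV paths (exactly one of the two), plus optional `model`, `mcmc` and
`idw` settings; see `?occu_run_config`.

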