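---
title: "Modelling thermal-abundance distributions with thermoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal-abundance distributions with thermoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

How does a species' local abundance vary across the temperature gradient it
occupies? The abundant-centre hypothesis predicts a peak at the centre of
the realised niche with declines toward both thermal edges, but wild
abundance data are noisy, zero-inflated, and confounded by habitat,
depth, human pressure and survey effort, and many species' gradients are
truncated by geography (there is no water warmer than the warmest sea).
`thermoniche` implements a complete pipeline for quantifying the *shape* of
thermal-abundance distributions from site-level community survey tables:

1. **Survey preparation** — absences inferred within a 10-degree
   (latitude/longitude, planar) buffer around occupied sites, species
   filters (at least 30 presence records spanning at least 3 °C), and
   balancing of absences against presences.
2. **Two-stage residualization** — a per-species PCA of environmental
   covariates (axes explaining more than 10% of variance retained) feeds a
   zero-inflated Poisson (ZIP) regression together with depth and
   protection; response residuals `y - (1 - pi) * lambda` carry the
   abundance variation not attributable to those covariates.
3. **Quantile-spline peak estimation** — an 80th-quantile cubic regression
   spline (basis dimension 4) of residual abundance against temperature,
   refit over 25 random absence subsets; the realised thermal optimum
   `T_opt` is the argmax of the pointwise-mean curve.
4. **Shape classification** — the four-way rule based on whether the curve
   at the cool/warm thermal edges falls below 75% (and, as a sensitivity
   check, 50%) of the curve maximum: no-trend, abundant-centre,
   warm-skewed, cool-skewed.
5. **Niche geometry** — thermal edges as the 2.5th/97.5th presence
   temperature quantiles; split-Gaussian scales
   `sigma_min = |T_opt - T_min| / 1.96`, `sigma_max = |T_max - T_opt| / 1.96`;
   skew `T_skew = sigma_max - sigma_min` (negative = warm-skewed).
6. **Pooled split-Gaussian model** — all species standardized onto common
   axes and the performance model fitted by MCMC, per thermal guild.
7. **Skew regression** — `T_skew ~ T_opt + habitat associations` with
   nested taxonomic random intercepts (order/family/genus).

## The split-Gaussian performance model

On standardized axes (temperature centred on the optimum and scaled by the
mean of the two sigmas; abundance scaled by the species maximum), the
pooled model for binned 99th-percentile maxima is

$$
\mathrm{Performance}(T) = c \, e^{-\left(\frac{T - T_{opt}}{\sigma}\right)^2},
\qquad
\sigma = \begin{cases}\sigma_{T_{min}} & T < T_{opt}\\
\sigma_{T_{max}} & T \ge T_{opt}\end{cases}
$$

Note the exponent carries no factor of ½: the model is implemented exactly
in this printed form, so the sigmas are *not* standard deviations of a
conventional Gaussian (they are larger by a factor of √2). The 1.96 z-score
used to derive the sigmas from the 95% occupancy interval treats the edges
as normal-distribution percentiles; the mismatch between that convention
and the missing ½ is a documented idiosyncrasy of the model family, kept
as-is rather than silently corrected. Similarly, the printed formula
`sigma_Tmin = (T_min - T_opt)/1.96` is negative whenever the cool edge lies
below the optimum, yet a centred optimum must give zero skew and a
warm-edge optimum negative skew; magnitudes are therefore used.

The observation model is Gaussian on the binned maxima with an estimated
`error_sd` (the likelihood is not specified by the model family itself;
binned 99th percentiles are approximately continuous and homoscedastic on
the standardized scale). Priors are weakly informative: `c ~ Uniform(0, 2)`,
`topt_std ~ Normal(0, 1)`, sigmas half-Normal(0, 5), `error_sd`
half-Normal(0, 0.5). Recovery tests show the data sizes used overwhelm
these priors.

### Sampler and diagnostics

The posterior is sampled with an adaptive random-walk Metropolis sampler
(positive parameters on the log scale with the Jacobian; proposal scale
adapted toward 23.4% acceptance and proposal covariance taken from the
accumulated burn-in history, frozen at the end of burn-in so the retained
draws come from a fixed kernel). Defaults mirror the reporting convention
of the field: 4 chains × 10 000 iterations, burn-in 2 500, thinning 5 —
exactly `floor((10000 - 2500)/5) = 1500` retained draws per chain. The
Gelman-Rubin statistic `sqrt(((n-1)/n·W + B/n)/W)` must fall below 1.01 for
every parameter; otherwise the iteration count is doubled once and the fit
flagged if still unconverged. Sampler correctness is enforced in the test
suite by comparison against a brute-force grid-search maximum-likelihood
oracle (with the scale `c` profiled out in closed form), not by trust in
the sampler's identity.

## The quantile spline

The 80th-quantile curve minimizes the *mean* pinball loss
$\rho_\tau(r) = r(\tau - \mathbf{1}[r<0])$ over a cubic regression spline
basis (4 functions, knots at data quantiles) plus a second-derivative
roughness penalty. Using the mean rather than the sum makes the objective
invariant to uniform duplication of observations. The non-smooth loss is
softened as $\rho_\tau(r) \approx \tfrac12((2\tau-1)r + \sqrt{r^2+\epsilon^2})$
with ε set to 0.1% of the mean absolute deviation (itself
duplication-invariant), and minimized by BFGS from a penalized
least-squares warm start, with one polishing pass at ε/10. The smoothing
parameter is chosen by 5-fold cross-validated pinball loss over a fixed
log-spaced grid (ties to the smallest value). Within the 25-replicate
absence bootstrap the smoothing parameter is tuned on the first replicate
and reused: replicates share all presence rows and differ only in which
absences enter, so re-tuning adds cost rather than information. The
temperature-effect permutation test (199 permutations by default) compares
the pinball-loss reduction of the smooth fit over the constant-quantile fit
against the same statistic under permuted temperatures.

A structural property worth knowing: with only 4 basis functions the curve
cannot bend sharply. A strongly asymmetric niche whose short side drops
within a couple of degrees is smoothed into a curve that stays high at that
edge — such species are classified as skewed *by design resolution*, not by
error. The classification at threshold 0.50 is reported alongside 0.75 for
sensitivity.

## What the synthetic generator emulates — and what it does not

`generate_sites()` builds 10²–10³ sites along a 5–30 °C gradient with
latitude tied to temperature (≈2.4° latitude per °C, the large-scale ocean
average), eight environmental covariates rank-correlated with temperature
(Gaussian copula, default ρ ≈ 0.6, mirroring the observation that the first
PCA axis tracks temperature), and a sigmoidal coral-to-macroalgae
transition crossing at 23 °C with total cover bounded by habitat
availability. `generate_species()` draws split-Gaussian niches: base
sigma ~ Uniform(2.2, 3.6) °C — realised thermal ranges of roughly 9–14 °C,
typical of reef fishes — with skewed scenarios splitting the two sides
1.45 : 0.7 (skew magnitudes ≈ 1.6–2.7 °C, consistent with observed skew
distributions); peak expected counts are log-normal across species
(median 12 per survey area; the generative abundance distribution across
species is a configuration choice, not an empirical estimate), and
zero-inflation probabilities Uniform(0.15, 0.4). Warm-skew scenarios place
tropical optima near or beyond the warm end of the gradient so that edge
truncation — the mechanism behind realised warm-skew — actually occurs.
`simulate_surveys()` draws ZIP counts whose Poisson mean follows the
split-Gaussian curve times a bounded habitat multiplier
`exp(pref · (coral - macroalgae)/100)`.

Not emulated: coastline geometry and dispersal limits, temporal dynamics,
satellite-derived temperature error, transect-level structure (counts are
generated directly at site level), and detection covariates. Passing
recovery tests therefore demonstrate statistical correctness of the
machinery under the stated generative assumptions — not robustness to every
property of real survey data.

### Ground truth for recovery tests

`realised_truth()` defines what a perfect run of the pipeline should find
for a synthetic species: thermal edges from the occupancy-probability
weighted temperature distribution (so gradient truncation is part of the
truth), and the shape label and target optimum from the noiseless true
curve *projected onto the estimator's own 4-function spline basis* — the
population target of the procedure. Optimum-recovery error is nevertheless
judged against the raw generative optimum. Skew-sign agreement is assessed
on species whose realised |T_skew| is at least 0.5 °C; species whose skew
is erased by truncation have no recoverable sign, a limitation the
geographic arguments for warm-edge truncation make explicit.

## Numerical and design choices

* Quantile convention: linear interpolation between order statistics
  (type 7), used for thermal edges, binned maxima and every other quantile
  in the package.
* Binning: width 0.1 on the standardized axis, half-open `[left, right)`
  anchored at 0; boundary points join the right-hand bin.
* Argmax ties on the prediction grid (200 points over the sampled range)
  resolve to the lowest temperature.
* Shape classification shifts the curve so its minimum is zero before
  taking fractions of the maximum, because residual curves may be negative
  while the rule speaks of percentages of maximum abundance.
* Guild ties at exactly 23 °C go to tropical (only strict inequalities are
  defined by the convention).
* The ZIP inflation part is intercept-only (simplest identifiable choice);
  zero-variance or aliased design columns — including the within-species
  constant sampling intensity — are dropped automatically. Non-convergence
  routes the species to a plain Poisson fallback, flagged on the fit.
* Residuals are response residuals `y - (1 - pi_hat) lambda_hat`, keeping
  the 80th-quantile curve interpretable as a maximum-abundance anomaly.
* Absence balancing happens inside each bootstrap replicate, with child
  seeds derived from the master seed by fixed offsets.
* Mantel tests use 999 random permutations by default
  (`p = (1 + #{r* >= r})/(n_perm + 1)`), or exhaustive enumeration of all
  `n!` permutations for matrices up to 7 × 7.
* Model comparison: REML fits report coefficients; LRTs require ML fits of
  nested models (term-subset nesting is verified). AICc uses
  `-2l + 2k + 2k(k+1)/(n-k-1)`. A singular random-effects fit is refit
  with the collapsed taxonomic level removed and flagged.
* Problem sizes in the test-suite recovery studies (50 species × ~1500
  sites, 25 bootstrap replicates; 500/100 binned points for the pooled
  model) were chosen as the smallest sets at which the Monte-Carlo noise of
  the checks is comfortably below the tolerances being verified.

## Known limitations

* `T_opt` for species whose optimum lies at or beyond the sampled gradient
  end is clamped to the grid; its error is bounded by the truncation, not
  by the estimator.
* The spline's 4-function resolution biases peak placement away from the
  centre of wide, asymmetric data spans by up to ~1 °C for narrow niches;
  broad-niche mid-gradient species may be labelled no-trend at this
  resolution even when the underlying curve is peaked.
* The deviance explained by a quantile fit has no agreed definition and is
  not reported.
* The two-sample Wald contrast between guild slopes uses the simple
  `z = (b1 - b2)/sqrt(se1^2 + se2^2)` form; other SE conventions
  (e.g. interaction-term Wald tests) give somewhat different statistics.
* Taxonomic random intercepts proxy shared evolutionary history; no
  phylogenetic comparative methods are implemented.

## A minimal worked run

```{r, eval = FALSE}
library(thermoniche)

sites <- generate_sites(1500, seed = 101)
species <- generate_species(50, guild_mix = 0.5, skew_scenario = "mixed",
                            seed = 102)
records <- simulate_surveys(sites, species, seed = 103)

pipe <- run_thermal_pipeline(records, sites, n_boot = 25, seed = 104)
head(pipe$profiles)
table(pipe$profiles$shape, pipe$profiles$guild)

pooled <- pooled_shape_analysis(pipe, guild = "tropical", seed = 105)
pooled$posterior
pooled$r2

trop <- fit_skew_lmm(pipe$profiles, guild = "tropical")
temp <- fit_skew_lmm(pipe$profiles, guild = "temperate")
slope_difference_test(trop, temp)
```
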