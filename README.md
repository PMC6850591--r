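# thermoniche

Quantifying the shape of species' **thermal-abundance distributions** from
community survey data: where along a temperature gradient does each species
reach its realised optimum, how fast does abundance fall toward the cool
and warm edges of its range, and is the decline symmetric?

The package is aimed at macroecologists working with large standardized
survey tables (one row per species × site, with counts, coordinates,
temperature and environmental covariates — e.g. reef-fish visual census
data). It implements:

* **absence construction** within a 10° latitude/longitude buffer around
  occupied sites, species data filters (≥ 30 presence records spanning
  ≥ 3 °C) and presence/absence balancing;
* **two-stage residualization**: per-species PCA of environmental
  covariates (axes explaining > 10% variance retained) + zero-inflated
  Poisson regression, so temperature effects are assessed on covariate-free
  residual abundance; Mantel tests check residual spatial autocorrelation;
* **realised thermal optima** (`T_opt`) from 80th-quantile penalized cubic
  regression splines (basis dimension 4) of residual abundance vs
  temperature, bootstrapped over 25 random absence subsets;
* **shape classification** — *no-trend*, *abundant-centre*, *warm-skewed*,
  *cool-skewed* — by whether the curve at each thermal edge falls below 75%
  (sensitivity: 50%) of the curve maximum, with a chi-square test of the
  category proportions;
* **niche geometry**: thermal edges `T_min`/`T_max` (2.5th/97.5th presence
  temperature quantiles), split-Gaussian scales
  `sigma_min = |T_opt − T_min|/1.96`, `sigma_max = |T_max − T_opt|/1.96` and
  the skew statistic `T_skew = sigma_max − sigma_min` (negative =
  warm-skewed);
* the **pooled split-Gaussian performance model**

  `Performance(T) = c · exp(−((T − T_opt)/σ_side)²)`

  fitted by MCMC (4 × 10 000 iterations, burn-in 2 500, thinning 5,
  Gelman-Rubin R̂ < 1.01) to binned 99th-percentile standardized abundances,
  per thermal guild (temperate `T_opt` < 23 °C, tropical > 23 °C);
* **skew regression** across species:
  `T_skew ~ T_opt + coral + macroalgae associations` with nested taxonomic
  random intercepts (lme4), AICc/likelihood-ratio model comparison and a
  Wald contrast of guild slopes;
* a **synthetic survey generator** with known ground truth
  (split-Gaussian niches, zero-inflated counts, covariates collinear with
  temperature, a coral→macroalgae transition at 23 °C) so the entire
  pipeline is testable end-to-end without any external data.

## Worked example

```r
library(thermoniche)

sites   <- generate_sites(1200, seed = 11)
species <- generate_species(30, guild_mix = 0.5, skew_scenario = "mixed",
                            seed = 12)
records <- simulate_surveys(sites, species, seed = 13)

pipe <- run_thermal_pipeline(records, sites, n_boot = 10, seed = 14)
head(pipe$profiles[, c("species_id","topt","tmin","tmax","tskew","guild","shape")])
#>   species_id topt tmin tmax  tskew    guild           shape
#> 1     sp0001 24.9 19.5 28.9 -0.648 tropical abundant_centre
#> 2     sp0002 30.0 21.3 29.8 -4.373 tropical     warm_skewed
#> 3     sp0003 26.3 21.2 29.8 -0.798 tropical abundant_centre
#> 4     sp0004 24.5 18.1 29.7 -0.618 tropical abundant_centre
#> 5     sp0005 30.0 19.1 29.8 -5.486 tropical     warm_skewed
#> 6     sp0006 25.0 19.1 29.8 -0.519 tropical abundant_centre

table(pipe$profiles$shape, pipe$profiles$guild)
#>                   temperate tropical
#>   abundant_centre         2       10
#>   cool_skewed             6        0
#>   warm_skewed             7        5
```

Each row is one species' realised niche: its thermal optimum (°C), edges,
skew (°C; `sp0002` has its optimum jammed against the warm end of the
gradient, hence strongly negative skew and a warm-skewed class) and guild.
Tropical species near the gradient top come out warm-skewed, temperate ones
cool-skewed or abundant-centre — the truncation pattern the classification
is designed to expose.

```r
pooled <- pooled_shape_analysis(pipe, guild = "tropical", seed = 15)
pooled$posterior$summary[, c("parameter","mean","q2.5","q97.5","rhat")]
#>       parameter     mean    q2.5   q97.5   rhat
#> 1             c  0.80618  0.7836 0.82870 1.0011
#> 2      topt_std -0.08103 -0.1811 0.02039 0.9999
#> 3 sigma_min_std  1.68919  1.5535 1.82564 1.0000
#> 4 sigma_max_std  1.52127  1.3777 1.66619 1.0000
#> 5      error_sd  0.14596  0.1386 0.15381 1.0026
#> 6         tskew -0.16792 -0.4226 0.08122     NA

pooled$r2
#> $r2_points: 0.76   $r2_binned_means: 0.966
```

The pooled curve peaks at `c ≈ 0.81` of maximum abundance near the
standardized optimum; the fit explains far more variance in cross-species
bin means than in individual species' points, as expected when species
scatter around a common shape.

```r
profiles <- merge(pipe$profiles,
                  species[, c("species_id","order","family","genus")])
trop <- fit_skew_lmm(profiles, guild = "tropical")
temp <- fit_skew_lmm(profiles, guild = "temperate")
trop$fixed_effects
#>               term estimate     se      z        p
#> 1      (Intercept)   18.954 1.6611  11.41 3.70e-30
#> 2             topt   -0.778 0.0733 -10.63 2.23e-26
#> 3      coral_assoc    1.145 0.3251   3.52 4.28e-04
#> 4 macroalgae_assoc    1.151 0.3233   3.56 3.70e-04

slope_difference_test(trop, temp)
#> $z: -2.88   $p: 0.00396
```

Skew declines with the thermal optimum (warm-affinity species are more
warm-skewed), more steeply in the tropical guild.

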