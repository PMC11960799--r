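# arcwinter

Arctic winters are changing in ways that averages hide: brief mid-winter
thaws that melt the insulating snow cover (*extreme winter warming*), and
rain falling onto an existing snowpack that refreezes into ice crusts
(*rain-on-snow*, ROS). Both events are rare by definition — tail events of
local climatologies — yet they drive shoot mortality, herbivore die-offs
and reproductive failure in Arctic biota. `arcwinter` is an R package for
the two analyses this question needs:

1. **Event climatology** on daily gridded fields (daily maximum
   temperature, rainfall, snow depth): per-cell percentile baselines,
   run-based event detection, day-weighted intensity scores, Theil–Sen /
   Mann–Kendall trends, paired period comparisons, Mantel tests of spatial
   autocorrelation, and emergence maps.
2. **Evidence synthesis**: standardized mean differences with
   heteroscedastic variances (SMDH) from control/response group summaries,
   single-pass outlier filtering, and a multilevel random-effects
   meta-analysis with study, effect-size, species and *phylogenetic*
   random effects, I² decomposition, omnibus moderator tests (Q_M,
   marginal R²), and spatial projection of significant pooled effects.

It is written for quantitative ecologists and climate-impact researchers
who want the full pipeline — from gridded fields or effect-size tables to
pooled estimates and projections — with every stage testable offline
through seeded synthetic-data generators.

## The core model

A warming event is a maximal run of consecutive winter (Oct–Mar) days in
one grid cell whose daily maximum exceeds that cell's baseline 99th
percentile; its intensity is the day-weighted exceedance sum
`Σ_d (tmax_d − thr) · d`. A ROS day has ≥ 3 mm rain on ≥ 3 mm SWE of snow
with tmax > 1 °C, and an event must be followed by a 3-day mean maximum
below 0 °C (refreeze); its intensity is `Σ_d rain_d · d`.

Pooled effects come from the marginal model

    y ~ N(Xβ, σ²_study Z_s Z_sᵀ + σ²_es I + σ²_species Z_sp Z_spᵀ
             + σ²_phylo Z_sp A Z_spᵀ + diag(v_i))

fitted by REML, where `A` is the species correlation matrix from a
(seeded, bifurcated, ultrametric) phylogeny and `v_i` the SMDH sampling
variances. See `vignette("arcwinter-methods")` for formulas, conventions
and design choices.

## Worked example

Seventy years of synthetic daily fields, detection, a period comparison
and a trend:

```r
library(arcwinter)
cfg  <- climate_sim_config(lat_range = c(66, 70), lon_range = c(20, 24),
                           years = c(1950, 2020), seed = 1)
cube <- simulate_climate(cfg)
thr  <- compute_threshold(cube, baseline = c(1950, 1980))
warm <- detect_warming_events(cube, thr)
sm   <- annual_summaries(warm, cube)
paired_period_test(sm, c(1950, 1980), c(1990, 2020))
#> Paired period comparison (total): mean diff (B - A) = 8.065,
#>   t(15) = 7.947, p = 9.347e-07, 16 cells
agg <- aggregate(sm$total, by = list(season = sm$season), mean)
theil_sen(agg$season, agg$x)
#> Trend (theil-sen + mann-kendall): slope = 0.183676 per unit x,
#>   p = 5.225e-19 (n = 70)
```

The period comparison says mean annual cumulative warming exceedance per
cell rose by ~8.1 °C between the baseline and modern periods of this
simulation (its configured trend is 0.06 °C/yr); the Theil–Sen slope is
the median pairwise trend of the regional mean exceedance per season.

Meta-analysis on a synthetic effect-size table with known truth (overall
effect −0.9):

```r
sim  <- simulate_effect_sizes(meta_sim_config(seed = 2))
es   <- smdh(sim$records$n_c, sim$records$mean_c, sim$records$sd_c,
             sim$records$n_r, sim$records$mean_r, sim$records$sd_r)
d    <- cbind(sim$records, es)
keep <- remove_outliers(d$yi, d$vi)$keep   # 1 of 187 removed here
d    <- d[keep, ]
pc   <- tree_to_correlation(sim$tree, unique(d$species), seed = 1)
fit  <- meta_fit(yi ~ 1, vi = vi, data = d, study = study,
                 species = species, A = pc)
summary(fit)
#> Multilevel meta-analysis (REML), k = 186
#> Random components (sigma2): study = 0.1414, es = 0.6342,
#>   species = 0.137, phylo = 0.04537
#>             estimate     se       z      p   ci.lb  ci.ub
#> (Intercept)  -0.7107 0.2233 -3.1824 0.0015 -1.1484 -0.273
#> Total I2 = 85.7% (typical sampling variance 0.1599, weighted)
#>   study    12.6%
#>   es       56.7%
#>   species  12.3%
#>   phylo    4.1%
```

The pooled SMD is negative and significant (the generator's truth −0.9
lies inside the CI), and ~86 % of the variation in effects is
heterogeneity rather than sampling error, decomposed by level. Moderator
models (`moderator_test`), the authorship-group bias check
(`publication_bias_check`) and projection (`project_impacts`,
`coverage_gap`) build on the same objects, and `run_pipeline()` drives
everything end to end from one config.

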