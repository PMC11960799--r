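---
title: "Methods: detecting Arctic winter extreme events and meta-analysing their biotic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting Arctic winter extreme events and meta-analysing their biotic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcwinter)
```

## Scope and model overview

`arcwinter` implements a two-part analysis. The first part detects two
kinds of ecologically relevant extreme events on daily gridded climate
fields — *extreme winter warming* and *rain-on-snow* — and quantifies their
temporal trends and period changes. The second part pools published
control-versus-response contrasts of Arctic biota fitness into standardized
mean differences and fits a multilevel random-effects meta-analytic model
with phylogenetic correlation. A final stage multiplies per-cell period
changes in event exposure by statistically significant pooled effects to
map the relative magnitude of projected biotic impact.

Everything is driven either by user-supplied inputs (a gridded cube, an
effect-size table, a newick tree) or by the package's seeded synthetic
generators, which exist so that every stage has testable ground truth.

## Event detection

**Winter season.** The Arctic winter runs October–March. The winter
spanning October of year $Y-1$ to March of year $Y$ is labelled $Y$; the
label convention is ours (the season definition leaves it open) and keeps
each season's days contiguous. All per-"year" outputs use this label. A
period such as 1950–1980 selects the winters lying wholly inside it
(labels 1951–1980).

**Warming events.** Per grid cell, the baseline threshold is the 99th
percentile of daily maximum winter temperature over the baseline period
(default 1950–1980). The percentile uses linear interpolation between
order statistics (R type 7); the convention is recorded in the output
because none is canonical. A day qualifies when it is a winter day and its
daily maximum *strictly exceeds* the cell threshold; maximal runs of
consecutive qualifying days form one event. The per-day *exceedance* is
`tasmax - threshold`; annual cumulative exceedance sums it over a cell's
events in a season. The event *intensity* is the day-weighted sum
$\sum_d e_d \cdot d$ with $d$ the 1-based day index within the event, so a
two-day event with maxima 5 and 7 °C over a 3 °C threshold scores
$(5-3)\cdot 1 + (7-3)\cdot 2 = 10$. Intensity weights late-event
conditions: sustained exceedance late in a long event counts more than an
equal exceedance on day one.

**Rain-on-snow events.** A day qualifies when it is a winter day with at
least 3 mm of rain, at least 3 mm snow-water-equivalent of snow on the
ground, and a daily maximum above 1 °C. Runs of qualifying days form a
candidate event, retained only if the mean of the three daily maxima after
the event's last day is below 0 °C (the refreeze criterion — the ecological
damage mechanism is rain freezing into ice layers within the snowpack).
Intensity is the day-weighted rainfall sum (5 mm then 7 mm gives
$5\cdot1 + 7\cdot2 = 19$). Numerical conventions that the definitions
leave open, and our choices:

* rain and snow comparisons are inclusive (`>= 3 mm`), the temperature
  comparison strict (`> 1` °C, `exceeds` for warming); both are switchable
  arguments because nothing in the definitions pins down the boundary case;
* the three-day refreeze lookahead may use April days when an event ends
  in late March — it tests physical refreeze, not season membership;
* candidates with fewer than three days of record after them cannot be
  assessed and are discarded, with a count in a diagnostics attribute;
* missing data in any required variable disqualify a day and break runs
  (conservative detection);
* events never span a season boundary; a qualifying run cannot cross
  March 31 because April days are non-winter.

**Aggregation.** Spatial aggregation to coarser grids uses the unweighted
mean of member fine cells per day (a `cos(latitude)`-weighted option
exists but is off by default, matching how reanalysis aggregation for this
kind of analysis is usually reported). Snow-depth unit conversion (metres
of water equivalent to mm) happens in the reader, never in detection.

## Trend and period statistics

Per-season series (event counts, cumulative exceedance, mean length, mean
intensity, total rain-on-snow) are fit with the Theil–Sen estimator: the
slope is the median of all pairwise slopes. Significance comes from the
Mann–Kendall trend test, the standard nonparametric companion, computed as
the Kendall rank-correlation test against time; a percentile bootstrap CI
on the slope is the switchable alternative. Winter precipitation trends
(total rainfall, total snowfall, rain:snow ratio) default to ordinary
least squares, as such trends are conventionally reported as linear
trends; seasons with zero snowfall drop out of the ratio with a logged
count.

Period comparisons pair *grid cells*: each cell contributes its mean of a
summary variable over the seasons of each period, and a two-sided paired
t-test runs on the per-cell differences. Spatial autocorrelation is
assessed with a Mantel test — Pearson correlation of distance-matrix upper
triangles with a one-sided permutation p-value under the add-one
convention ($p \ge 1/(B+1)$); small matrices can be enumerated
exhaustively. The second distance matrix is built from absolute
differences of per-cell values, a one-dimensional choice we document
prominently because the pairing of "grid data" with a distance is an
interpretation.

## Effect sizes

Group summaries (n, mean, SD for a control and a response group) become
standardized mean differences with heteroscedastic population variances
(SMDH):

$$ d = J(m)\,\frac{\bar{x}_r - \bar{x}_c}{s'}, \qquad
   s' = \sqrt{(s_c^2 + s_r^2)/2}, \quad m = n_c + n_r - 2, $$

with $J(m) = \Gamma(m/2)\,/\,(\sqrt{m/2}\,\Gamma((m-1)/2))$ the exact
small-sample bias correction, and large-sample sampling variance

$$ v = \frac{d^2}{8}\,\frac{s_c^4/(n_c-1) + s_r^4/(n_r-1)}{s'^4}
     + \frac{s_c^2/(n_c-1) + s_r^2/(n_r-1)}{s'^2}. $$

The variance expression is asymptotic: at group sizes below roughly 30 its
relative error (order $1/n^2$) is a few percent, which is visible to a
$10^5$-replicate parametric bootstrap; the bootstrap oracle tests
therefore probe it at group sizes of 60–200, its intended regime, and the
small-sample worked example is held to a relative-agreement bound instead.

Directionality is harmonized by multiplying each effect by a per-variable
flag (−1 when an increase in the response harms fitness, e.g. winter
mortality), looked up in an editable shipped table; unknown variables are
quarantined rather than passed through, and applying the flip twice is
refused. For observational time series, years are split into response
(extreme) and control groups: labelled extreme years are used directly
with the preceding year as control; otherwise a year is extreme when the
site's environmental variable exceeds the regional 99th percentile over
the baseline period in a 5°×5° box around the site, and an extreme year is
kept only when its preceding year is observed. A year never serves as
control twice, and a year preceded by another extreme year is excluded;
both situations are logged.

Outliers are removed in a single pass: standardized residuals
$(y_i - \hat\mu)/\sqrt{v_i + \hat\tau^2}$ under a random-effects
overall-mean model, cut at absolute value 3 (common-effect standardization
is switchable). No refit-and-repeat: the filter runs once by policy.

## The multilevel meta-analytic model

The marginal model is $y \sim N(X\beta,\; V)$ with

$$ V = \sigma^2_{study} Z_s Z_s^\top + \sigma^2_{es} I
     + \sigma^2_{species} Z_{sp} Z_{sp}^\top
     + \sigma^2_{phylo} Z_{sp} A Z_{sp}^\top + \mathrm{diag}(v_i), $$

where $A$ is the phylogenetic correlation matrix (shared root-to-tip path
proportion under a Brownian model, built with `ape`; polytomies are
resolved by *seeded* randomization because coarse-taxon results are
sensitive to the bifurcation, and the seed is echoed into the result).
Components are estimated by REML with a log-variance parameterization,
analytic gradients, and three starts (method-of-moments-flavoured,
near-zero, perturbed; relative tolerance $10^{-8}$). Components below
$10^{-6}$ — far below interpretable heterogeneity on the squared-SMD
scale — are reported as exactly zero. Fixed effects follow by GLS at the
REML solution; CIs use normal critical values by default (t available),
matching common multilevel meta-analysis practice, and prediction
intervals add the sum of all variance components.

Heterogeneity is decomposed as multilevel $I^2$: with typical sampling
variance $\bar v = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$,
$w_i = 1/v_i$ (simple mean switchable; the choice is recorded),
$I^2_{total} = \sum_l \sigma^2_l / (\sum_l \sigma^2_l + \bar v)$ with
per-level shares summing to the total by construction.

Moderator models use the no-intercept level-means parameterization, one
pooled estimate per level. The omnibus $Q_M$ is a Wald chi-square on
*level-difference contrasts*: with no intercept, a raw test of all
coefficients would ask whether all level means are zero, which is not the
moderator question (do levels differ?). Contrast-coded or continuous terms
are tested against zero; single-level moderators yield an undefined
$Q_M$, reported as `NA`. Marginal $R^2$ is
$100\cdot\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\sum_l \hat\sigma^2_l)$. The authorship-group check is the same machinery
on a two-level first-author flag, reporting the between-group Wald p.

### Identifiability of the phylogenetic component

The phylogenetic variance is the hardest component to estimate. Two
structural effects matter. First, under deep trees (e.g. coalescent
shapes) much of $\sigma^2_{phylo} A$ lies along a nearly common direction
that REML cannot separate from the fixed intercept, so part of the
phylogenetic variance is simply not estimable. Second, at realistic sizes
(tens of species) the estimate's sampling distribution is strongly
right-skewed with mass at the boundary, so its *median* sits well below
its mean even when the estimator is approximately unbiased. In our
simulations at 50 studies × 4 effects the median phylogenetic estimate ran
13–37 % below truth across tree shapes, matching an independent
implementation exactly — an estimator property, not an implementation
artefact. The packaged recovery study therefore uses truth values that are
either well identified (study, effect-size level) or exactly zero
(species, phylogeny), which keeps the 10 %-median and CI-coverage checks
informative; users should treat small fitted phylogenetic components as
order-of-magnitude statements.

## Synthetic generators

**Climate.** Daily maximum temperature is a cell-wise seasonal cycle
(annual mean at a reference latitude, a latitude gradient, semi-amplitude
peaking mid-July) plus a linear secular trend plus AR(1) noise.
Precipitation occurs with a daily probability and gamma amounts; it falls
as snow at or below 0 °C and feeds a bucket snowpack that melts at a fixed
rate per degree above zero (recorded snow depth is after snowfall, before
melt, so rain meets the pack it falls on). Defaults (annual mean −5 °C,
semi-amplitude 12 °C, AR(1) 0.7 with 3 °C innovations, trend
0.06 °C yr⁻¹, rain probability 0.3 with mean ~2.4 mm, melt
2.5 mm °C⁻¹ day⁻¹) produce cold winters with occasional shoulder-season
warm excursions and a few rain-on-snow-qualifying days per cell-decade —
the regime the detectors target; the trend sits in the range of reported
regional winter warming rates. The generator produces daily values
directly (the analysis aggregates hourly data to daily before anything
else, so an hourly step would add nothing testable); it has no orography,
ocean coupling or spatial noise correlation, so passing detection tests
says nothing about reanalysis biases, only about the detection logic.
One seed is split into fixed per-field substreams so adding a field never
perturbs earlier fields.

**Effect sizes.** A coalescent species tree is drawn (`ape::rcoal`),
per-level random effects are drawn with the phylogenetic level correlated
by the tree's correlation matrix, moderator offsets are added, and each
record's control/response summaries are then generated by exact normal
sampling theory (means normal, SDs scaled-chi). Defaults mirror a
realistic evidence base: 17 studies × 11 effects, 49 species, overall
effect −0.9, and components (study 0.19, es 0.98, species 0, phylo 0.04)
chosen so that at typical sampling variances (~0.16) the total $I^2$ is
about 86 % with shares of roughly 69/14/3/0 % — the kind of decomposition
meta-analyses of ecological field studies report. Group sizes 5–30 mimic
year- or plot-limited field designs; the recovery experiments override to
30–100 so that the known-variance assumption of the fitted model holds to
within the resolution of the checks.

## Projection

Per-cell period change in an event metric (cumulative exceedance, °C, or
total rain-on-snow, mm) is multiplied by the event-type-specific pooled
effect — only when its CI excludes zero, otherwise the projection refuses.
The output is a relative-magnitude surface (a uniform effect size applied
across space), flagged as such in its metadata; the coverage-gap report
ranks regions by mean absolute impact against the number of study
locations inside them.

## Problem sizes and determinism

The test suite runs entirely on synthetic data: detection equivalence uses
one hundred 10°×10°, five-winter cubes against brute-force oracles;
the bootstrap oracle uses $10^5$ replicates per setting; the recovery
study uses 200 replicates of 50 studies × 4 effects. All randomness flows
from explicit seeds (generator configs carry them; permutation tests and
polytomy resolution require them), and reruns of the pipeline with the
same config are byte-identical.

## Known limitations

* No area weighting by default in regridding, no field-significance
  correction across cells, mirroring the analysis design this package
  operationalizes.
* The CSV cube layout is convenient and text-stable but verbose;
  pan-Arctic archives should be processed regionally (see the shipped
  ERA5 recipe).
* CIs do not propagate variance-component uncertainty (normal-based GLS
  intervals); coverage is checked by simulation at the packaged design.
* The phylogenetic variance component is weakly identified at realistic
  sizes (see above).
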