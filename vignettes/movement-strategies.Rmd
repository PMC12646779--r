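---
title: "Classifying partial-migration strategies and explaining them from resource variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying partial-migration strategies and explaining them from resource variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partmig)
```

## The problem

Temperate ungulate populations are often partially migratory: some
individuals are year-round residents, some shuttle between fixed summer and
winter ranges (dual-range migrants), and some migrate seasonally but switch
seasonal — especially winter — ranges from year to year (multi-range
migrants, sometimes called seasonal nomads). partmig implements a pipeline
that (i) classifies individuals into these strategies from multi-year GPS
trajectories, and (ii) asks what properties of the resource environment —
spatial heterogeneity, interannual (un)predictability, winter severity,
human footprint — predict the strategy an individual uses.

Because strategy classification and regression on landscape summaries are
both easy to get subtly wrong, every stage is paired with a synthetic-data
generator whose ground truth is known exactly. The package's tests are
built on that generator; this vignette records the modelling choices and
what the tests do and do not demonstrate.

## Occurrence distributions

Space use within a temporal window is summarized by an occurrence
distribution (OD): a probability-mass surface on a regular 150 m grid.
Two estimators are provided.

**Brownian bridge movement model (BBMM).** For frequent fixes (the pipeline
uses it when the window's median fix interval is at most 4 h), consecutive
fixes are joined by conditioned Brownian motion. A segment of duration $T$
contributes, at fraction $\alpha$ along it, an isotropic normal centred on
the linear interpolation of its endpoints with per-coordinate variance

$$\sigma^2(\alpha) = \alpha(1-\alpha)\,T\,\sigma^2_m
  + \left[(1-\alpha)^2 + \alpha^2\right]\delta^2,$$

where $\sigma^2_m$ (m²/h) is the Brownian motion variance and $\delta$ the
location-error SD. The bridge integral is discretized with `n_alpha = 10`
midpoint steps (doubling `n_alpha` moves the OD by < 0.02 total variation in
tests), segments are weighted by their duration, segments longer than
`max_lag = 8` h contribute nothing, and cell masses use the cell-centre
approximation with components narrower than half a cell deposited as point
masses. $\sigma^2_m$ is estimated once per animal by maximizing the
leave-one-out likelihood of every second fix under the bridge between its
neighbours, bracketed on a log scale.

**Kernel utilization distribution (KUD).** For sparse fixes and for the
year-round range, an isotropic Gaussian kernel density with the reference
bandwidth $h = \hat\sigma\, n^{-1/6}$,
$\hat\sigma = \sqrt{(\mathrm{var}_x + \mathrm{var}_y)/2}$. The bandwidth
rule and the BBMM settings are declared package defaults, not estimates of
what any particular field study used.

Each animal gets one grid covering its whole 21–23-month point cloud (with
a margin of three bridge/bandwidth SDs), snapped to a shared 150 m lattice
so that ODs of different windows — and, via mass-conserving re-binning,
different animals — can be compared cell by cell. A *volume isopleth* at
level $p$ is the smallest set of cells, in order of descending mass (ties
broken by cell index), reaching cumulative mass $p$.

## The four movement metrics

For each animal the pipeline estimates two summer ODs (1 Jun–31 Aug), two
winter ODs (1 Dec–28/29 Feb, winter of year $t$ spanning Dec $t$–Feb
$t{+}1$), and one OD per calendar month. Windows with fewer than
`min_fixes = 30` relocations are treated as absent; animals without two
usable summers and two usable winters are unclassifiable.

Overlap between ODs $p, q$ is the Bhattacharyya affinity
$\mathrm{BA}(p,q) = \sum_i \sqrt{p_i q_i}$, computed after restricting each
OD to its own 95% isopleth and renormalizing. The text this design follows
conditions the overlap index on the 95% ODs without saying whether mass is
renormalized after truncation; truncation-with-renormalization is the
default here and `truncate = FALSE` provides the full-support alternative
for sensitivity checks.

* **Metric 1, seasonal overlap** — mean of the year-1 and year-2
  summer-vs-winter affinities (each summer paired with the winter that
  follows it). High values ⇒ residency.
* **Metric 2, summer overlap** — affinity of the two summer ranges.
* **Metric 3, winter overlap** — affinity of the two winter ranges. Low
  metric 1 with high metric 3 ⇒ dual-range migration; low with low ⇒
  multi-range migration.
* **Metric 4, annual overlap** — mean affinity over all monthly OD pairs
  whose sequential month indices differ by at least two. Adjacent months
  are excluded to limit temporal autocorrelation; the sequential index runs
  over the whole record, so a July of year 1 *is* compared with the June of
  year 2 (21 pairs are excluded from the $\binom{22}{2}$ possible ones in a
  22-month record, leaving 210).

## Classification

Animals are clustered on metrics 1–3 (all on the common $[0,1]$ scale, so
no standardization) with $k$-means: Lloyd iterations, k-means++ seeding,
50 restarts, best within-cluster sum of squares kept, fixed seed. $k = 3$
is a design constant, matching the three strategies the metrics are built
to separate. Clusters are named by rule: highest metric-1 centroid ⇒
resident; of the remaining two, higher metric-3 centroid ⇒ dual-range
migrant, the other ⇒ multi-range migrant. An exact tie in the deciding
centroid raises an error asking for manual labels rather than guessing.

## The synthetic generator

Trajectories are discrete-time Ornstein–Uhlenbeck tracks,

$$x_{t+\Delta} = x_t + a\,(\mu(t) - x_t)\,\Delta
  + s\,\sqrt{\Delta}\,\varepsilon_t,$$

with attraction $a = 0.05$ h⁻¹, step scale $s = 300$ m·h^{-1/2} and fix
interval $\Delta = 2$ h (within the 1–4 h range typical of ungulate GPS
schedules; tests that only need window bookkeeping use 4 h to stay quick).
The centre $\mu(t)$ sits on the summer range in June–August and the winter
range in December–February, and interpolates linearly during the
transitions — any monotone schedule would do for recovery tests, linear is
the simplest. Dual-range migrants keep one winter centre (default 30 km
from the summer centre) across years; multi-range migrants redraw each
year's winter centre uniformly on the 30 km circle, so two winter ranges
coincide only with probability a few percent — those rare draws are left in
deliberately, as honestly ambiguous animals. The displacement and noise
scales are free parameters of the generator: the source material gives no
quantitative per-strategy scales, so they were chosen once to give a
stationary OU spread (~1 km SD) well below the 30 km seasonal displacement
and never revisited. In the noiseless limit $s = 0$ the track sits exactly
on $\mu(t)$.

Landscapes are Gaussian random fields: per covariate, white noise smoothed
with a Gaussian kernel of scale `corr_length` (kernel normalized to sum to
one, so smoother fields are also flatter — heterogeneity is controlled by
one knob), shifted and scaled to covariate-typical units (days of spring
length, lbs/acre of biomass, cm of snow, etc.). Annual covariates receive a
per-year scalar effect $e_y \sim N(0, \texttt{yty\_sd}^2)$ multiplied by a
smooth spatial modulation field with grid mean ~1, so the landscape-average
interannual SD equals `yty_sd` while different areas are more or less
temporally variable — without the modulation every animal would measure an
identical year-to-year SD and the regressions would be degenerate. Static
covariates (elevation, percent agriculture, distance to roads) have no year
effect; percent agriculture passes through a logistic map to stay in
$[0,1]$.

What the generator does *not* emulate: topography, resource-following
(step-selection) movement, social dynamics, collar failure patterns, true
nomadism, and any correlation between an individual's strategy and where it
settles. Passing recovery tests therefore demonstrates the *machinery* is
correct, not that real animals are this easy to classify.

## Resource variation and the regression stage

Per animal, over either availability domain:

* **Spatial variation** — each covariate is averaged across years cell by
  cell, the SD is taken over the masked cells (population convention,
  denominator $n$: the cells are a census of the range), and the
  per-covariate SDs are aggregated by PCA (columns centred and scaled; PC1
  scores, sign-oriented so the dominant loading is positive).
* **Year-to-year variation** — annual spatial means of spring length and
  biomass over the mask, then the SD across years (sample convention,
  denominator $n-1$: years are a sample).
* **Winter conditions** — mean snow depth over the mask and years;
  **relative winter severity** is its within-cohort z-score (the
  appendix-level severity index of the source material is not recoverable
  from its main text, so the package defines this transparent cohort
  z-score instead).
* **Anthropogenic indices** — masked-cell means of percent agriculture and
  distance to roads.

The *empirical* domain is the 95% KUD year-round range; the *standardized*
domain is a circle of species-standard area (3765 km² for pronghorn-like,
1647 km² for elk-like cohorts) centred on the winter-fix centroid. The
quoted "radius approximately equal to the 95% quantile of the areas"
conflates a length with an area; the area-equivalent-circle reading is
adopted (3765 km² ⇒ radius 34 619 m). Both domains run through one code
path that differs only in the mask, which is property-tested. The
standardized domain matters because empirical ranges confound strategy with
range size: migrants sweep larger areas and mechanically accumulate larger
spatial SDs, which is visible in the demo cohort as a strong
spatial-score–strategy association.

Strategies are then regressed on these summaries with beta regressions:
$y_i \sim \mathrm{Beta}(\mu_i \phi, (1-\mu_i)\phi)$,
$\mathrm{logit}(\mu_i) = x_i^\top\beta$, constant precision $\phi$ (the
standard first parameterization), fitted by BFGS on $(\beta, \log\phi)$
with analytic-free gradients, OLS-on-logit starting values and up to five
jittered restarts. Because observed overlaps include exact zeros, where the
beta likelihood is undefined, the response is compressed by
$y' = (y(n-1) + 0.5)/n$ before fitting. Standard errors come from the
inverse observed information, intervals are 95% Wald, and the pseudo-R² is
the squared correlation between $\mathrm{logit}(y')$ and the linear
predictor — the conventional beta-regression definition, declared here
because "ps–R²" is otherwise ambiguous. Model ranking uses
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting
coefficients plus precision.

Four subsets are analysed (all animals / dual vs multi / resident vs dual /
resident vs multi) with responses seasonal, winter, seasonal and annual
overlap respectively; predictors are centred and scaled within each subset.
Objective 2 compares spatial variation, year-to-year variation (spring
length + biomass) and an intercept-only model — spatial and year-to-year
variation never co-occur in a candidate because they are strongly
correlated. Objective 3 fits seven candidates: the subset's objective-2 top
model, intercept-only, climate (winter conditions + severity),
anthropogenic (agriculture + roads), and the top model combined with
climate, with anthropogenic, and with both; the three combination
candidates are a declared reading of "combinations" and are configurable in
code. Subsets smaller than 10 animals are refused.

## Numerical choices and degenerate inputs

* Isopleth ties are broken by cell index, so masks are deterministic.
* ODs are compared on the union grid of their (lattice-aligned) grids;
  off-lattice grids are re-binned by assigning each source cell's mass to
  the target cell containing its centre, which conserves mass exactly.
* `fit_bbmm_variance` returns 0 when the optimum sits on the lower bracket
  (stationary animals); it errors when no fix triplet is within `max_lag`.
* Zero-variance point sets need an explicit KUD bandwidth; single-cell
  masks refuse a spatial SD; zero-variance PCA columns are dropped with a
  warning; rank-deficient design matrices and subsets too small for their
  parameter count are errors, not silent fits.
* All simulators are deterministic functions of (parameters, seed); the
  demonstration pipeline writes byte-identical outputs on rerun.

## Problem sizes used in the tests

The test-suite and acceptance-script cohorts use 60 animals (20 per
strategy, 22 months at 2 h fixes) for classification recovery, 12-animal
cohorts at 4 h fixes for end-to-end determinism, 10 simulations for
Brownian-variance recovery, 200 simulated datasets (n = 500) for interval
coverage, and 50 replicates for the selection-consistency and
year-to-year-recovery checks. These sizes were chosen as the smallest
cohorts at which the recovery properties are stable.

## Known limitations

* The BBMM uses fixed $\sigma^2_m$ per animal and no behavioural-state
  segmentation (no dynamic BBMM), and the KUD uses a single reference
  bandwidth — both are the plainest members of their families.
* The cell-centre mass approximation degrades when the kernel SD is close
  to the cell size; components narrower than half a cell are point-deposited.
* k-means with $k = 3$ cannot discover additional strategies (e.g. true
  nomads); the cluster-naming rule presumes the three intended clusters
  exist in the data.
* The winter-severity index is a cohort z-score, not a physiological
  severity model, and is only comparable within the cohort it was computed
  in.
* Beta regressions assume independent observations; no spatial or
  individual random effects are offered.
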