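---
title: "Ensemble suitability modelling under aridity stress: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble suitability modelling under aridity stress: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aridsuit` implements a complete climate-suitability workflow for a single
crop species — here parameterized around olive (*Olea europaea* L.) — and
couples it with an aridity analysis: ensemble species distribution models
(SDMs) gated by discrimination skill, equal-interval suitability
classification with km² accounting, gain/loss/stable change maps between a
reference climate and SSP-style future forcings, Thornthwaite potential
evapotranspiration (PET) and the UNEP Aridity Index (AI), and a binomial
logistic regression attributing projected habitat loss to aridity. Because
the workflow is exercised on synthetic worlds with a known ground-truth
suitability surface, every stage can be tested against parameter recovery
rather than against irreproducible field data.

## The modelling pipeline

### Occurrence preparation

Presence records are spatially rarefied with a greedy thinning: points are
shuffled (seeded) and accepted one at a time iff at least `min_dist_km`
(default 5 km) from every accepted point. Distances are great-circle
(haversine, R = 6371.0088 km) on geographic grids and Euclidean on the
projected synthetic grids. Pseudo-absences are drawn uniformly from the
study mask, excluding a buffer (default 5 km) around presences, and then
thinned to a minimum spacing of 100 km — the side of a 10,000 km² square, so
at most one absence per coarse neighbourhood. The absence count defaults to
the presence count (prevalence 0.5 before thinning caps it), the standard
choice when discrimination metrics such as the True Skill Statistic are the
evaluation currency. Covariates are extracted by containing-cell lookup;
points on nodata are dropped and counted.

### Variable screening

Multicollinearity is screened with iterative variance-inflation-factor
pruning at threshold 5: `VIF_j = 1/(1 - R²_j)` from the OLS regression of
variable `j` on all others, dropping the single worst variable per round
(ties to the first column) until all VIFs comply; the Pearson correlation
matrix of the survivors is reported confirmatorily. VIF is computed on the
covariate table at the presence/absence points — the distribution the models
are fitted on — not on whole-raster values. Aspect, a circular variable, is
used as-is by default; nothing in the workflow requires its sin/cos
decomposition, and treating it linearly mirrors common SDM practice. One
consequence worth knowing: under the lapse-rate coupling (below), elevation
and the quarter temperatures (bio8/bio9) form a collinear group, and which
member gets pruned can differ between realizations — the survivors proxy the
dropped variable almost perfectly, which is exactly the situation VIF
screening is designed to produce.

### Algorithms, evaluation, gating, ensembles

Six algorithms are fitted per replicate: logistic regression on
standardized covariates (`glm`), random forest (300 trees), boosted
regression trees (xgboost, 150 rounds, learning rate 0.1, depth 3), an RBF
support vector machine with probability calibration, and two presence-only
models implemented from first principles — a percentile envelope (`bioclim`:
per variable `s_j = clip(1 - 2|F_j(x_j) - 0.5|, 0, 1)` with `F_j` the
mid-rank empirical CDF of presence training values, score `min_j s_j`) and a
Mahalanobis scorer (`D²` to the presence mean with presence covariance,
ridge-regularized `1e-6·trace/k` on the diagonal if singular, score
`P(χ²_k > D²)`). Ten replicates of a stratified 80/20 split are used by
default.

Evaluation uses the rank (Mann–Whitney) AUC with tie correction and the
maximum TSS over an exhaustive scan of all distinct test scores as
thresholds (prediction positive iff score ≥ t; TSS ties resolve to the
smallest threshold). Max-sens+spec thresholding is the convention of the
SDM toolchains this workflow emulates. Gating is at the algorithm level —
an algorithm is kept iff its mean AUC ≥ 0.9 and mean TSS ≥ 0.7 across
replicates — because published evaluations star whole algorithms, not
individual replicates. The ensemble is the unweighted per-cell mean of all
kept scorers (algorithm × replicate); a TSS-weighted mean
(`weight = max(0, tss)`) is available via
`modelling$ensemble_weighting = "tss"`. Variable importance is permutation
based: `max(0, 1 - cor(original scores, scores with column j permuted))`,
averaged over permutations and replicates of kept algorithms.

### Classification, areas, change

Ensemble probabilities are classified by equal intervals: unsuitable
(p < 0.25), low (0.25 ≤ p < 0.5), moderate (0.5 ≤ p < 0.75), high
(p ≥ 0.75); boundaries are inclusive upward. Areas use latitude-aware
spherical cell areas on geographic grids (`Δlon·π/180·R·cosφ ×
Δlat·π/180·R`) and `cellsize²` on projected synthetic grids; percentages
are half-up rounded to one decimal with the full mask area as denominator.
Change maps binarize "suitable" as class ≥ moderate by default and cross
the two periods into unsuitable-both / stable / gain / loss. The cutoff is
configurable (`"low"` counts low+moderate+high as suitable) because
published area tables do not always pin down which binarization was used;
the moderate+high pairing is the default since that is the habitat set the
aridity coupling analyses.

### Thornthwaite PET and the UNEP Aridity Index

Per cell and month: `Td = max(Tm, 0)`; annual heat index
`I = Σ (Td_m/5)^1.514`; exponent
`a = 6.75e-7·I³ − 7.71e-5·I² + 1.7912e-2·I + 0.49239`; monthly
`PET = 16 · AdjF · (10·Td/I)^a` mm with PET = 0 where `Td = 0` or `I = 0`.
`AdjF = (N/12)(d/30)` combines the month length `d` (non-leap calendar)
with the mean day length `N` at the month's middle day from the standard
solar-declination model (`δ = 0.4093·sin(2π(284+J)/365)`, sunset hour angle
clamped so day length stays within [0, 24] beyond the polar circles). Two
deliberate numerical choices:

* Some renderings of the exponent polynomial print a *negative* linear term
  (−1.792e-2·I). That variant yields nonphysical exponents for typical heat
  indices (a < 0 for I ≳ 30), so the canonical positive coefficient is the
  default; `thornthwaite$linear_term_sign = "as_printed"` switches to the
  strict-as-printed polynomial for comparison.
* Monthly mean temperature stands in for "average daily temperature"
  — at monthly-normal resolution they coincide.

The aridity index is `AI = P/PET` on annual totals, classified
lower-inclusive: hyper-arid [0, 0.05), arid [0.05, 0.2), semi-arid
[0.2, 0.5), dry sub-humid [0.5, 0.65), sub-humid [0.65, 1], humid > 1.
Published class tables often overlap at the boundaries (0.5 appears twice);
lower-inclusive resolution is used consistently, with sub-humid closed at
1.0 because "humid" is defined strictly above 1. Cells with PET = 0
(nothing but frozen months) are energy-limited: AI is undefined there, the
cells are flagged, and they classify as humid.

### Loss attribution

Cells coded *loss* in a change map become 1, every other masked cell 0, and
the standardized AI of the future period is the single predictor of a
maximum-likelihood binomial logistic regression. Because AI *decreases* as
aridity increases, the odds ratio per one-SD increase in **aridity** is
`exp(−β)`. The report carries the Wald p-value, McFadden pseudo-R² (×100)
— the variant whose typical magnitudes match published habitat-loss
regressions — and the in-sample AUC of fitted probabilities computed with
the same rank-AUC routine as the SDM evaluation. Standardization is the
default because the odds ratio is explicitly per-SD; the fit is invariant
to affine rescaling of raw AI. All mask cells enter the regression (no
subsampling), and spatial autocorrelation is deliberately ignored — the
inference mimics the published procedure, so p-values are anti-conservative
in the usual way; treat effect sizes, not significance, as the result.

The frequency coupling is area-weighted: the percent of suitable-habitat
area (moderate+high) in each aridity class, every class reported even when
empty. A future period can lose all suitable habitat, in which case the
pipeline emits an all-zero frequency table rather than failing.

## The synthetic world

`synthetic_world_spec()` defines a projected kilometre grid (default
100 × 160 cells of 10 km — a region of roughly Anatolian extent including
neighbouring land) carrying:

* twelve monthly temperature normals (default a Mediterranean-type seasonal
  cycle, 5–28 °C) and twelve monthly precipitation normals (winter-peaked,
  8–130 mm), each the stated mean plus a spatially correlated Gaussian
  field. Fields are white noise convolved (FFT, circular) with a Gaussian
  kernel of sd = `spatial_corr_length_cells` (default 6 cells) and
  standardized per realization, so every layer has exactly the stated mean
  and noise sd (defaults: 3 °C; 35% of the monthly precipitation mean,
  clipped at zero);
* terrain: a smooth random elevation surface (mean 700 m, sd 550 m, clipped
  at sea level, doubled correlation length), with slope and aspect by
  Horn's method — aspect is degrees clockwise from north of the *downslope*
  direction, flat cells get the sentinel −1;
* an optional lapse-rate coupling (default 6.5 °C/km, as an anomaly around
  the mean elevation) that cools high ground in every month. This is what
  ties the temperature-derived bioclim layers to terrain the way real
  mountain climates are tied, and it is enabled in the pipeline;
* scenario forcing as uniform warming ΔT plus a multiplicative
  precipitation factor. The four default scenarios (ΔT = 1.8/2.8/2.3/4.5 °C
  with precipitation factors 0.96/0.93/0.94/0.86) span the
  moderate-to-pessimistic range of mid- and end-century Mediterranean
  projections: a two-scenario × two-period design.

Six bioclim-style layers are derived from the normals: bio4
(100 × sd of monthly temperatures), bio8/bio9 (mean temperature of the
wettest/driest consecutive 3-month quarter, circular with
December–January–February wraparound, ties to the earliest start), bio14
(driest-month precipitation), bio19 (precipitation of the coldest quarter),
and bio3 (isothermality). Daily temperature extremes are not simulated, so
bio3 uses a fixed configurable diurnal range (default 10 °C) over the
annual range — this keeps the nine-variable covariate set (terrain + six
bioclim layers) intact without simulating sub-monthly weather.

### Ground truth and its calibration

The truth model is a logistic surface over named layers. The default is a
sharp niche on the two drivers such studies repeatedly find dominant —
elevation (−0.022 per m: frost and temperature limitation acting through
altitude) and coldest-quarter precipitation (+0.15 per mm: the winter-rain
requirement of Mediterranean tree crops) — with the intercept placed so
roughly 5% of the default world is suitable. Two properties of this design
matter:

* **The gate must be attainable.** With uniformly placed pseudo-absences,
  a fraction of absences inevitably falls on truly suitable cells, which
  caps the achievable AUC near `1 − s/2` for suitable fraction `s`. A
  soft, diffuse niche therefore makes the AUC ≥ 0.9 / TSS ≥ 0.7 gate
  unreachable no matter how good the algorithms are. The default niche is
  sharp (near-binary suitability) and occupies a small fraction of the
  region, the same regime in which published olive models report AUCs of
  0.87–0.94 with 6 of 13 algorithms passing the gate. Verified across
  seeds, five or six of the six algorithms pass at default settings.
* **Scenarios must generate losses.** Warming and drying push the dry, hot
  margin of the niche below the suitability cutoff; the fitted nonlinear
  models (envelope and tree-based scorers in particular) lose suitability
  where conditions exit the presence envelope, which concentrates losses on
  the arid side of the niche and yields the negative loss–AI relationship
  the attribution stage is built to measure. Gains are possible but small
  under uniformly adverse forcing; an empty gain (or even an all-lost
  future) is a legitimate outcome and the pipeline handles it.

Presences are sampled without replacement with probability proportional to
true suitability (256 by default, the size of a typical curated national
occurrence set); a flat truth (all coefficients zero) yields uniform
sampling, which the tests verify by a chi-square goodness-of-fit.

### What the synthetic world does *not* emulate

No weather-generator realism (no daily weather, no interannual
variability), no GCM spatial structure beyond uniform ΔT and a
precipitation factor, no soil or land-use constraints, no observation bias
in presences (real GBIF records cluster near roads and farms), and no
spatial autocorrelation in the presence sampling beyond what the smooth
suitability surface induces. Passing tests therefore demonstrate that the
machinery is correct and that parameters are recoverable under clean
conditions — not that the workflow is robust to the sampling pathologies of
real occurrence data.

## Raster model and I/O

Rasters are in-memory float64 matrices with a cell-center-registered
affine transform restricted to square cells, a CRS tag, and `NA` nodata.
On disk they are ESRI ASCII grids — a plain-text, widely readable raster
exchange format — written at full double precision with a one-line `.crs`
sidecar; round-trips are exact. Alignment is checked by exact transform and
shape equality everywhere: the pipeline never resamples silently, and
inputs must share one grid. Geographic masks arrive as rasters; no vector
clipping is provided.

## Problem sizes and determinism

Default problem sizes keep a full run light: the 100 × 160 default world
runs the entire pipeline (six algorithms × ten replicates, five periods) in
about ninety seconds on one core; the parameter-recovery checks use a
200 × 200 world and n = 20,000 logistic draws. Every stochastic stage takes
an explicit seed derived from the master seed, and a rerun with the same
configuration reproduces every table bit-for-bit; the run report records
the seeds. The analysis drivers under `analysis/` chain the stages through
plain-text artifacts in `results/analysis/`, so any stage can be rerun or
inspected in isolation.

## Known limitations

* The 13-algorithm roster of the R `sdm` ecosystem is represented by six
  algorithms spanning the presence/absence and presence-only families;
  MaxEnt, MARS, GAM, GLMNET, CART, FDA and Domain are out of scope.
* Presence-only scorers (bioclim, Mahalanobis) are trained on presences
  only but evaluated against the shared absence set — how published studies
  supplied absences to such models is typically not documented.
* No spatial block cross-validation; replicates are random stratified
  splits, so evaluation optimism from spatial autocorrelation is not
  corrected (as in the emulated workflow).
* The loss regression is univariable and spatially naive by design.
* No reprojection, resampling or vector geometry; one grid per analysis.
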