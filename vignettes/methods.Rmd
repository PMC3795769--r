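---
title: "Methods: from presence-only trawl records to fuzzy conservation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from presence-only trawl records to fuzzy conservation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

Bottom-trawl surveys record where commercial species were caught, not
where they are absent: gear selectivity and catchability mean a species
can occupy a site and still be missed (a *false absence*), and confirmed
absences would require far more effort than presences. Discrimination
models (logistic regression and its spatial extensions) nonetheless
outperform profile methods when absences are available. `fuzzsdm`
implements the hybrid compromise: a presence-only niche model supplies a
suitability surface, artificial absences are placed where that surface
*and* the geography argue the species is truly absent, and a spatially
explicit logistic model is then fit to the balanced presence /
pseudo-absence set. Downstream, a fuzzy-set overlay converts per-species
probability maps into a joint conservation-priority surface without
committing to a single presence/absence threshold.

# Stages, assumptions and tunable parameters

## Raster model and terrain

All layers live on one co-registered grid (square cells, upper-left
origin; a cell covers the half-open box `[x, x+c) × (y−c, y]`, so shared
edges belong to exactly one cell — the convention is applied uniformly to
point extraction, haul placement and pseudo-absence emission). Slope uses
Horn's 3×3 weighted differences (the standard GIS stencil; only the
window size is dictated by the data source). Aspect is reported as
eastness/northness (sine and cosine of the downslope azimuth) to avoid
the circular discontinuity at north; flat cells get the neutral value 0
on both components rather than nodata, so flat seabeds remain
modellable. Distance to shore is cell-centre-to-cell-centre Euclidean
distance in map units; no geodesic correction (a local projected CRS is
assumed, as with any UTM-like coastal DEM). Raster I/O is single-band
ESRI ASCII grid, written at 17 significant digits so a write/read round
trip is bit-exact; reprojection and multi-band imagery are out of scope.

## Hill–Smith ordination

Mixed predictor tables (quantitative + categorical seafloor type) are
ordinated before any niche or regression analysis: quantitative columns
are standardised by the population standard deviation, each factor level
becomes the contrast `x/p − 1` with column weight `p` (its relative
frequency), and a weighted PCA is diagonalised. With only quantitative
columns this reduces exactly to correlation-matrix PCA (the unit test
checks this against an independent oracle); a k-level factor contributes
k − 1 units of inertia, as in multiple correspondence analysis. The
pipeline drops axes with eigenvalue below 0.02: such axes carry
essentially no environmental signal but can make the niche analysis's
presence covariance numerically singular when occurrences concentrate in
few categorical classes.

## ENFA, HSI and the marginality test

Predictors (in practice: ordination scores) are standardised over the
*background* — by default every valid cell of the study area, the natural
reference when the question is "how does occupied habitat differ from
what is available". The marginality vector is the mean standardised
presence row; its norm is divided by 1.96 so that `M ≈ 1` places the
niche centroid near the background's 95% bound (the conventional scaling
in the ENFA literature). Specialisation factors maximise the ratio of
background to niche variance in the subspace orthogonal (in the niche
covariance metric) to marginality; eigenvalues above 1 indicate a niche
narrower than the background. Retained factors are the smallest set
explaining ≥ 90% of total specialisation, capped at 5.

The HSI algorithm is the median/rank-count rule: on each retained factor
a location's suitability is the share of presence observations at least
as far (two-sided) from the presence median as the location itself;
factors are combined by eigenvalue-share weights with the marginality
factor given the largest eigenvalue, and scaled to 0–100. A
distance-based alternative exists in the literature; the rank rule is
used because it is parameter-free, bounded and exactly testable by a
counting oracle. If the presence covariance is nearly singular (all
presences sharing a level of some category), the degenerate directions
are capped rather than failing, with a warning: a direction in which all
presences coincide is extreme specialisation, not an error.

The marginality test relocates the presences to uniformly drawn
background rows (without replacement), refits `M`, and reports
`p = (1 + #{M_perm ≥ M_obs}) / (1 + n_perm)` with `n_perm = 100` by
default, giving the familiar floor of 1/101. Calibration under the null
(uniform presences) is asserted at α = 0.05 over 500 replicates in the
test suite.

## Weighted pseudo-absences

The sampling weight is implemented as

τ = [((100 − HSI)/100) · (d_R/100)]² · 100

with `d_R` the distance to the nearest presence normalised to [0, 100] by
its maximum over valid cells. The printed form of the source equation is
embedded in a figure and not machine-readable, so this algebra — the
squared product of scaled unsuitability and scaled distance, increasing
in both and zero whenever either factor is zero — follows the verbal
description and the cited weighting method. It is deliberately isolated
in `weight_map()` so an alternative reading is a one-line change.
Consequences asserted in tests: τ = 0 at every presence cell and at
HSI = 100; the maximum sits where HSI = 0 and `d_R` = 100; empirical
sampling density is proportional to τ (chi-square goodness of fit at
10⁵ draws).

Sampling is without replacement (a trawl site is one record) and points
are emitted at cell centres for reproducibility. The replicate design is
10 weighted groups plus 1 uniform-random baseline, each of size equal to
the presence count, so every merged training set has prevalence exactly
0.5 — the balanced design that minimises prediction variance.

## Regression kriging

The trend is a binomial GLM on the ordination components with
bidirectional stepwise AIC from the full model (the search direction is
unstated in the tradition this follows; bidirectional is chosen and ties
resolve toward the smaller model, then the earlier term, making selection
deterministic). Complete separation is flagged and handled by a lightly
ridge-penalised refit so coefficients stay finite.

Residuals are taken on the response scale, `r = y − p̂`: binary labels
make link-scale residuals unbounded, and the binomial case of the
regression-kriging framework does the same. The empirical variogram uses
12 equal-width lags to half the maximum pairwise distance and WLS weights
`N(h)/h²` (both configurable). Fitting is over the spherical and
exponential families with box bounds on the log-parameters — nugget at
most twice, partial sill at most ten times the largest empirical
semivariance, range between 2% and 400% of the largest lag — because the
unconstrained WLS problem drifts into the unidentifiable near-linear
limit (huge sill with huge range). `fit_variogram_model()` accepts a
`min_nugget` floor for cases where the micro-scale variance is known
(e.g. the Bernoulli variance of binary residuals).

Spatial structure is declared absent when any of: the structured share of
the sill is below 5%; the fitted range is shorter than the first lag; the
structured model improves the WLS loss by less than 5% over a flat
(pure-nugget) variogram; or a Moran's I permutation test on the residuals
(inverse-distance weights restricted to the closest 10% of pairwise
distances, 199 permutations, one-sided) is not significant at α = 0.05.
The first three are curve-shape heuristics; the Moran gate is the
calibrated part — a 3-parameter curve can always improve slightly on a
flat line, but only genuinely autocorrelated residuals pass a
permutation test. Without structure the pipeline *is* the logistic
regression, bit for bit.

When structure is present, ordinary kriging of the residuals is added to
the trend and the sum clamped to [0, 1]. The OK primitive
(`krige_points`) is an exact unbiased interpolator — semivariance zero at
zero separation, weights summing to 1 via the Lagrange multiplier,
duplicate locations deduplicated by averaging — and is verified against a
hand-solved 5-point system. The *map* prediction, however, uses
nugget-filtered kriging (`filter_nugget = TRUE`): at a sampled cell the
residual is a binary label minus a probability, dominated by binomial
noise, and reproducing it exactly would write that noise into the map.
Filtering the nugget predicts only the spatially structured residual
component — the standard geostatistical treatment of measurement error —
while leaving the exact-interpolation contract of the primitive intact.
The kriging neighbourhood is global (all training points; a few hundred
per species at this scale), so no moving window is needed.

## Evaluation

Stratified k-fold cross-validation (default k = 10) refits the entire
stepwise-GLM(+kriging) pipeline inside each fold; kriging uses
training-fold residuals only, so no information leaks from the held-out
fold. Sensitivity and specificity are evaluated at threshold 0.5, the
natural cut for training sets balanced at prevalence 0.5 by design.
AUC is the rank-based (Mann–Whitney) statistic with half credit for
ties; PBC is the Pearson correlation between the 0/1 labels and the
predicted probabilities. The best pseudo-absence group per species is
the one with the highest mean AUC, ties going to higher mean PBC, then
the lowest group id. Prediction stability across the 10 weighted groups
is the set of 45 pairwise Pearson correlations over jointly valid cells.
For the downstream overlay, "high" accuracy means mean AUC ≥ 0.8 and
"excellent" ≥ 0.9 — the conventional AUC banding, stated here because
accuracy classes are used as a filter but band edges are a choice, not a
fact of the method.

## Thresholds and the fuzzy overlay

Candidate thresholds are the midpoints of consecutive sorted unique
scores plus 0 and 1 — every achievable confusion table is visited, so the
exhaustive-search optimum is attained by construction (a fixed 0.01 grid
was rejected as resolution-dependent). Four criteria are computed:
the threshold where sensitivity is closest to specificity; the maximum of
sensitivity + specificity (equivalently the Youden point on the ROC
curve, asserted by an independent computation in the tests); the maximum
of Cohen's kappa (from the 2×2 table); and the maximum percent correctly
classified. Ties go to the lowest threshold. Thresholds are fitted on
the full training set of the selected group (fitting on pooled
cross-validation predictions is a configurable alternative; full-data is
the default because it uses the model actually deployed on the map).

Fuzzification ramps each probability map linearly from membership 0 at
the smallest of its four thresholds to 1 at the largest; if all four
coincide the ramp degenerates to a crisp step at that value. The
seagrass recovery layer ramps between 30% and 60% (defaults, exposed as
configuration). The fuzzy AND — cell-wise minimum, nodata-propagating —
combines all species memberships and the seagrass membership; the
surface is reported together with its nonzero-favourability area.

# The synthetic seascape

`generate_environment()` emulates a coastal shelf at a trawl-survey
scale: a shoreline along the western edge; depth rising smoothly offshore
to 200 m as a power profile of distance to shore, plus a smoothed noise
field (default standard deviation 6 m); slope, eastness, northness and
distance to shore derived by the package's own raster operators; and a
categorical seafloor layer cut from a smoothed field into 8
equally-likely classes. A virtual species is a logistic response on
standardised quantitative layers, optionally plus a Gaussian random field
on the logit scale (exponential covariance, simulated by dense Cholesky
factorisation at the valid cell centres) representing the spatially
structured processes — biotic interactions, fishing pressure — that no
habitat predictor captures and that give kriging a recoverable signal.
Surveys are stratified-random over the depth strata 0–25, 25–65 and
65–200 m with fractions (0.40, 0.35, 0.25) of 360 hauls by default — the
haul count and strata mirror a real shelf survey design; the fractions
are a free choice. Haul counts per stratum follow the fractions exactly
by largest-remainder rounding. At each haul the species is recorded with
probability `suitability × detection_prob`, and only presences are
returned; the truth grid is exposed for validation only.

What the generator does *not* emulate: vessel and gear mechanics,
temporal dynamics, multi-species interactions, and the rasterisation of
real seafloor polygon maps. Tests passing on this generator therefore
show that the estimators recover what they claim to estimate under
idealised sampling — not that any particular real survey satisfies those
assumptions.

One inconsistency in the tradition this package follows is documented
rather than resolved: a strict ">10% of hauls" commonness rule is
implemented as stated, although published species lists under that rule
sometimes include species with fewer occurrences (e.g. 34 of 360). The
rule here is exactly `count / n_hauls > min_frac`.

# Study conditions used by the test suite

Problem sizes in the tests are the package's choices, picked so each
property is identifiable at desk scale:

- Sampler goodness of fit: 20×20 grid, 3 presences, 10⁵ single draws.
- ENFA recovery: 1-D background N(0,1) vs presences N(1, 0.25²) at
  n = 2000 (closed forms m = 1, λ = 16); null calibration with 40
  uniform presences from a 600×2 background, 500 replicates.
- GLM recovery: logit p = −1 + 2x₁ at n = 2000; stepwise selection with
  one informative and five noise components, 100 replicates.
- Weighted-vs-random contrast: 30×22 seascape, 140 hauls, detection
  probability 0.6, 30 seeds, paired one-sided Wilcoxon on held-out
  sensitivity and PBC from 5-fold cross-validation of one weighted and
  one random group. Imperfect detection plus unsurveyed suitable cells
  is exactly the regime where random pseudo-absences land on occupied
  habitat and depress sensitivity.
- Regression-kriging benefit: 40×30 seascape, 400 hauls, presence–absence
  labels at the hauls, logit-scale field with standard deviation 2 and
  range 600 m. The field is deliberately strong and of shorter range
  than the smooth environmental gradients: a long-range field is partly
  absorbed by the depth and distance-to-shore trends, leaving residuals
  indistinguishable from noise, in which case no calibrated detector can
  (or should) fire. Truth RMSE is compared over all valid cells against
  the GLM-only surface across 50 seeds; the no-field branch checks that
  the structure detector stays quiet (it is calibrated, so a rare false
  alarm at its nominal rate is tolerated) and that the map then equals
  the GLM surface bitwise.

# Known limitations

- No CRS handling or reprojection; coordinates are taken as planar map
  units. GeoTIFF is not read or written — ESRI ASCII only.
- The Gaussian-field simulator is dense-Cholesky and is meant for grids
  of a few thousand valid cells; larger domains need a sparse or
  spectral simulator.
- Pseudo-absence evaluation is partly circular: specificity and AUC
  measure agreement with *simulated* absences, so the weighted method's
  advantage is assessed on sensitivity and PBC, which are anchored to
  known presences.
- The variogram is fitted to residuals of a model chosen by AIC on the
  same data; no allowance is made for selection uncertainty.
- The fuzzy AND is the only overlay operator; OR/gamma operators and
  cost-weighted conservation planning are out of scope.
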