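---
title: "Methods: presence-background distribution models, land-cover correction and climate macrorefugia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background distribution models, land-cover correction and climate macrorefugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`dipterocarpSDM`, the parameters that matter, the synthetic study system used
to exercise them, and the numerical and design choices a maintainer should
know about. The package follows the workflow used to assess climate-change
and land-cover impacts on Philippine dipterocarp distributions: per-species
maximum-entropy models with bespoke background calibration and tuning,
post-hoc land-cover correction, and change analytics (loss/stable/gain,
richness stacking, protected-area coverage, elevation profiles).

## The model

The engine is a presence-background maximum-entropy model in its penalized
Gibbs/point-process form. Landscape cells \(x\) carry features \(f_j(x)\)
built from the covariates; the model is

\[
P(x) \;=\; \frac{e^{\eta(x)}}{\sum_{x' \in \mathrm{bg}} e^{\eta(x')}},
\qquad \eta(x) = \sum_j \beta_j f_j(x),
\]

and the coefficients minimize

\[
-\frac{1}{n_p}\sum_{\mathrm{presences}} \eta(x)
\;+\; \log \sum_{\mathrm{bg}} e^{\eta(x)}
\;+\; \sum_j \lambda_j |\beta_j|.
\]

The per-feature penalty is
\(\lambda_j = rm \cdot s(\mathrm{class}, n_p) \cdot \mathrm{sd}(f_j)/\sqrt{n_p}\),
where \(rm\) is the user's regularization multiplier, \(s\) is the published
per-feature-class default scalar interpolated in the presence sample size
(shipped as `extdata/maxent_default_regularization.csv`), and the standard
deviation is taken over the background. Feature classes follow the standard
menu: linear, quadratic, pairwise products, and forward/reverse hinges at
equally spaced interior knots, all rescaled to \([0,1]\) over the background.

Optimization is cyclic coordinate descent with soft-thresholding
(`src/maxent_cd.cpp`). Each coordinate takes a penalized Newton step and
backtracks until the exact objective does not increase, so the objective is
non-increasing across sweeps; an active-set strategy (full sweeps bracketing
sweeps over nonzero coefficients) keeps hinge-rich fits fast. Convergence is
declared when the largest coefficient change in a full sweep falls below
`convergence_tol`; hitting `max_iterations` flags the model as unconverged
but still returns it. With the penalty switched off on separable data the
coefficients diverge — the iteration cap exists for exactly that case, and a
test documents why \(rm > 0\) is required.

Predictions come in two transforms: `raw` (the Gibbs probability, summing to
1 over the training background) and `cloglog`,
\(1 - \exp(-e^{H} \cdot \mathrm{raw})\) with \(H\) the entropy of the fitted
raw distribution — the bounded suitability scale used everywhere downstream.
Covariates outside the training range are clamped to the range bounds before
feature evaluation. Whether the original study used the cloglog or logistic
output is not stated; cloglog (the modern default) is assumed, and the
synthetic truth uses the same link so the fitted family can match the truth
exactly — parameter recovery is then a fair test.

## The per-species protocol

1. **Thinning.** Occurrences are thinned to a 10 km minimum pairwise
   distance. Only the distance is prescribed by the protocol; the algorithm
   here is a randomized greedy (delete one member of the closest violating
   pair, random tie-break) with 20 restarts keeping the largest survivor —
   the `spThin` approach. On small instances it attains the true maximum
   independent set (verified against subset enumeration).
2. **Predictor preparation.** Climate layers are pruned at \(|r| > 0.7\)
   (greedy by mean absolute correlation among violators, with a `keep_list`
   to force a known retained set on real data); soil layers are standardized
   and replaced by the principal components cumulatively explaining > 90% of
   variance, with current-scenario loadings reused for future scenarios. The
   pruning rule and standardization are package choices: the study states the
   thresholds but not the algorithms.
3. **Background-extent calibration.** For each buffer distance (the full
   protocol uses 20–2000 km in 10 km steps; the desk-scale default is
   20–200 km in 20 km steps), 1000 pseudo-absences are sampled uniformly
   from the annulus between a fixed 10 km exclusion ring and the buffer,
   a default-settings model (LQPH, \(rm = 1\)) is fitted, and spatially
   blocked cross-validated AUC is scored. A Michaelis–Menten curve
   \(y = V_m d/(K + d)\) is fitted to (buffer, AUC) by nonlinear least
   squares, and the smallest buffer whose AUC reaches \(V_m\) is selected
   ("exceeds the asymptote" is read as \(\ge V_m\): the curve approaches
   \(V_m\) from below, so only noise crosses it; if nothing crosses, the
   best-performing buffer is used). Block partitioning is used here for all
   species regardless of sample size.
4. **Tuning.** 2000 pseudo-absences (10,000 at full scale) within the
   selected extent; presences partitioned into four spatial blocks by
   median-x then median-y splits with counts equal to within one (jackknife
   for \(n \le 25\)); every feature-class × \(rm\) candidate is
   cross-validated. The default \(rm\) grid is the only 19-value composition
   consistent with the protocol's description: \(0.75^k, k = 1..8\) plus
   \(1.0, 1.5, \dots, 6.0\). Selection takes the lowest mean held-out
   omission rate at the lowest presence threshold (strict `<`, so training
   omission is exactly zero), breaking ties by the highest mean held-out
   AUC. AUC and OR aggregate as means over folds; fold test AUC uses the
   fold-local background.
5. **Evaluation gates.** The selected configuration is refit on everything
   and reported with mean held-out AUC, the maxSSS threshold scanned on the
   pooled held-out scores, TSS and omission at that threshold. Models with
   AUC < 0.75, TSS < 0.45 or OR > 0.25 are rejected (inclusive boundaries).
6. **Projection and correction.** Cloglog suitability is projected per
   scenario and binarized at the maxSSS threshold; the static contemporary
   land-cover map then zeroes suitable cells on unsuitable classes (post-hoc
   correction, applied identically to every scenario — the reason land cover
   is not a model covariate is the temporal mismatch between historical
   occurrences and contemporary land cover).
7. **Change analytics.** Cells classify into loss/stable/gain/never; stable
   cells are the species' in-situ climate macrorefugia. Gain assumes full
   dispersal (a `dispersal = "none"` variant empties the class). Areas use
   per-cell km² (exact for planar grids, spherical-zone areas for
   longitude/latitude grids — the projection used for areas is not stated in
   the source protocol, so the spherical choice is a documented assumption),
   rounded to the nearest km². Richness stacks count species per cell;
   protected proportions are suppressed below 50 km² to avoid tiny
   denominators. Elevation profiles count cells in half-open 50 m bins
   (values below sea level clamp to the lowest bin) and scale every category
   by the species' maximum current-scenario bin count, so the current
   profile peaks at exactly 1.

## The synthetic study system

Real inputs (global occurrence databases, CHELSA climate, SoilGrids,
national land cover, protected-area and elevation rasters) are out of scope;
`simulate_study()` generates a landscape with the statistical structure the
workflow assumes:

- **Grid**: 64 × 64 cells at 4 km on a planar-km CRS (256 km extent) — large
  enough that 10 km thinning, the 10 km exclusion ring and 20–200 km buffers
  are all meaningful. Fields are sums of random cosine surfaces with a 30 km
  correlation length, standardized per layer.
- **Layers**: four climate-like (`bio1` is temperature-like: built with a
  −0.75 loading on the DEM field, the lapse-rate analogue) and four
  soil-like layers. The soil fields are mutually independent, so the soil
  PCA acts as a rotation rather than a reduction there (unlike real soil
  products, whose collinearity the PCA test emulates with noisy-copy
  fixtures). An optional `cross_correlation` builds a shared component into
  two designated layers to exercise the collinearity pruning.
- **Species truth**: cloglog link over standardized covariates with a strong
  quadratic thermal optimum slightly cooler than the landscape mean
  (linear `bio1` −1, quadratic −3) plus a moisture-like optimum on `bio2`
  (linear 2, quadratic −2), intercept calibrated by bisection to a mean
  occurrence probability of 0.15. The optimum placement matters
  scientifically: warming then simultaneously erodes warm-edge habitat and
  opens formerly too-cold habitat upslope, as expected for tropical montane
  trees. A monotone thermal response would make "gain" structurally empty
  and the recovery task ill-posed.
- **Sampling**: 200 presence-only records drawn proportionally to the truth
  (optionally times a bias surface), jittered within cells.
- **Land cover / protected areas**: 22 classes grown as warped-Voronoi
  blobs; a subset is marked unsuitable to cover ≈ 60% of the landscape
  (matching the order of the real study's ~2/3 reduction); protected blobs
  cover ≈ 15% (the ballpark of national protected-area shares).
- **Futures**: two scenarios shift `bio1` by +1 and +2 standardized units
  ("best-case"/"worst-case" warming); five realisations with smooth noise
  (sd 0.1) emulate GCM disagreement and are averaged per scenario.

What the passing tests do **not** show about real data: the generator has no
observation error in coordinates, no niche truncation at domain borders, no
temporal mismatch between records and land cover, and its land-cover classes
are spatially simple blobs; real performance gates and extents will differ.

## Numerical choices

- Degenerate Michaelis–Menten fits (flat performance) return \(V_m\) = the
  constant and \(K = \varepsilon\), so the smallest buffer is selected.
- Constant covariates are dropped with a warning before feature expansion;
  features with zero background variance are dropped before fitting.
- maxSSS scans all unique pooled scores; ties take the smallest threshold.
  Sensitivity uses \(\ge\) (a presence at the threshold counts as present).
- The coordinate-descent Newton step is guarded by a curvature floor
  (\(10^{-9}\)) and 30 backtracking halvings; proposals that cannot decrease
  the objective are skipped.
- Areas are reported to the nearest km²; percentage ledgers are computed on
  full precision and rounded only for display.
- The desk-scale defaults (6 hinge knots, `convergence_tol` \(10^{-4}\),
  200 sweeps, 1000/2000 background points, 10-buffer grid, 7-value \(rm\)
  grid) keep one full species run around 20 s; the headline protocol values
  (10 knots default, 199 buffers, 19 multipliers, 10,000 background) are all
  reachable through arguments.

## Known limitations

- Minimum-training-presence omission selection can prefer over-smoothed
  models: a near-flat model omits no held-out presences (OR exactly 0) while
  a well-fitted model omits the odd spatially extrapolated one. On the
  synthetic system this picks a linear-only model in roughly one seed in
  ten, which then fails the TSS gate — mirroring the original study, which
  rejected 7 of 26 modelled species at the same gates. The package reports
  and gates such models rather than papering over them.
- The raster model is deliberately minimal (single-band ASCII grids, square
  cells, two CRS modes, no reprojection); protected areas must arrive
  pre-rasterized.
- Jackknife evaluation reuses the full background in every fold; with very
  few presences the pooled maxSSS threshold rests on few distinct scores.
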