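# dipterocarpSDM

Species distribution modelling for climate-change impact assessment on
tropical trees, built around the workflow used for Philippine dipterocarps:
per-species maximum-entropy (MaxEnt-style) models with species-specific
background-extent calibration and hyperparameter tuning, post-hoc land-cover
correction of the projections, and climate-change range analytics —
loss/stable/gain classification (stable areas are in-situ climate
macrorefugia), species-richness stacking, protected-area coverage, and
elevation-shift profiles.

The modelling engine is written from scratch in the penalized Gibbs form: the
cell distribution \(P(x) \propto e^{\sum_j \beta_j f_j(x)}\) over background
cells, with linear/quadratic/product/hinge features and per-feature lasso
penalties \(\lambda_j = rm \cdot s(\text{class}, n_p) \cdot
\mathrm{sd}(f_j)/\sqrt{n_p}\), fitted by cyclic coordinate descent
(Rcpp) and reported on the cloglog suitability scale. Around it sit the
study's protocol stages: 10 km occurrence thinning, \(|r| > 0.7\)
collinearity pruning, soil PCA (> 90% variance), Michaelis–Menten
background-extent selection over distance buffers, spatial block / jackknife
cross-validation, minimum-omission-rate model selection over the 95-candidate
feature-class × regularization grid, AUC/TSS/OR acceptance gates, and maxSSS
binarization.

Because the real inputs (GBIF occurrences, CHELSA climate, SoilGrids, land
cover, protected areas, DEM) are not redistributable at desk scale, the
package ships a synthetic-landscape generator with the statistical structure
the workflow assumes — correlated smooth environmental fields, a species with
known cloglog suitability, biased presence-only sampling, blob land cover and
protected areas, and noisy future-climate realisations — so the whole
pipeline is testable end to end. The published 19-species results table is
included as a plain-text fixture for the cross-species summary statistics.

## Worked example

```r
library(dipterocarpSDM)

res <- run_synthetic_study(seed = 2)      # simulate + preprocess + fit + project
res$fit$extent$selected_buffer_km
#> [1] 20
res$fit$tuning$grid[res$fit$tuning$selected, ]
#>   feature_classes  rm mean_or mean_auc
#> 9             LQH 0.3       0    0.904
r <- res$fit$report
round(c(auc = r$auc, tss = r$tss, or = r$or_maxsss), 3)
#>   auc   tss    or
#> 0.904 0.692 0.124
res$fit$gate$accept
#> [1] TRUE
```

The species' background extent saturated at the smallest buffer (20 km); the
tuned model (linear+quadratic+hinge features, rm = 0.3) holds a held-out AUC
of 0.90 and passes all three acceptance gates (AUC ≥ 0.75, TSS ≥ 0.45,
OR ≤ 0.25). Projection and change analysis:

```r
tab <- build_species_table(res$proj$areas)
round(unlist(tab[c("reduced_pct_national", "loss_rcp85_nat", "gain_rcp85_nat")]), 1)
#> reduced_pct_national       loss_rcp85_nat       gain_rcp85_nat
#>                 60.5                 95.2                 19.1
```

Land-cover correction removes 60.5% of the modelled current range (the real
study's median was ~2/3); under the stronger warming scenario this realization
loses most of its corrected range (95.2%) and gains 19.1%, with gains sitting
higher on the elevation gradient than losses:

```r
ch <- res$proj$changes$rcp85
round(c(loss_m = mean_category_elevation(ch, res$sim$dem, "loss"),
        gain_m = mean_category_elevation(ch, res$sim$dem, "gain")))
#> loss_m gain_m
#>    785   1284
```

The numbered drivers under `analysis/` run the same workflow as a file-based
narrative (simulate → preprocess → background calibration → tuning/gates →
projection/change → summaries), writing plain-text rasters and tables under
`results/`.

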