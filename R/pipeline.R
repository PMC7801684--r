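#' Simulate a complete synthetic study landscape
#'
#' One call producing everything the modelling workflow consumes: a current
#' environmental stack (climate-like + soil-like layers) with DEM, a species
#' with known cloglog suitability, presence-only occurrences, land cover with
#' a reclass table, a protected-area mask, and two future scenarios (several
#' GCM realisations each, pre-averaged). Defaults describe a 256 x 256 km
#' planar landscape at 4 km resolution with a warming-dominated contrast
#' between the two future scenarios.
#'
#' @param seed integer seed driving every random component.
#' @param n_rows,n_cols,dx grid shape and cell size (km).
#' @param n_bioclim,n_soil layer counts.
#' @param spatial_range field correlation length, km.
#' @param n_presence occurrence count before thinning.
#' @param prevalence species mean occurrence probability.
#' @param coef_linear,coef_quad species truth coefficients (defaults: a
#'   species with a quadratic thermal optimum slightly cooler than the
#'   landscape mean — so warming both erodes warm-edge habitat and opens
#'   formerly too-cold habitat upslope — plus a secondary moisture-like
#'   optimum on `bio2`).
#' @param warming additive shifts on the temperature-like layer `bio1` for
#'   the two scenarios (standardized units).
#' @param n_gcms,gcm_noise_sd future-realisation count and noise level.
#' @param sampling_bias optional bias grid passed to [sample_occurrences()].
#' @return list with `stack`, `dem`, `species`, `occ`, `landcover`,
#'   `reclass`, `pa_mask`, `futures` (named list of averaged [env_stack()]s).
#' @export
simulate_study <- function(seed = 1, n_rows = 64, n_cols = 64, dx = 4,
                           n_bioclim = 4, n_soil = 4, spatial_range = 30,
                           n_presence = 200, prevalence = 0.15,
                           coef_linear = c(bio1 = -1, bio2 = 2),
                           coef_quad = c(bio1 = -3, bio2 = -2),
                           warming = c(rcp45 = 1, rcp85 = 2),
                           n_gcms = 5, gcm_noise_sd = 0.1,
                           sampling_bias = NULL) {
  env <- generate_env_stack(n_rows, n_cols, n_bioclim, n_soil,
                            spatial_range = spatial_range, seed = seed, dx = dx)
  sp <- generate_species(env$stack, coef_linear, coef_quad, prevalence)
  occ <- sample_occurrences(sp$prob, n_presence, sampling_bias, seed = seed + 1)
  lcpa <- generate_landcover_and_pa(env$stack, n_classes = 22,
                                    anthropogenic_fraction = 0.6,
                                    pa_fraction = 0.15, seed = seed + 2)
  futures <- list()
  for (i in seq_along(warming)) {
    nm <- names(warming)[i]
    off <- scenario_offsets(shift = c(bio1 = unname(warming[i])))
    gcms <- generate_future(env$stack, off, n_gcms = n_gcms,
                            gcm_noise_sd = gcm_noise_sd,
                            seed = seed + 10 * i, scenario_id = nm)
    futures[[nm]] <- average_gcms(gcms, scenario_id = nm)
  }
  list(stack = env$stack, dem = env$dem, species = sp, occ = occ,
       landcover = lcpa$landcover, reclass = lcpa$reclass,
       pa_mask = lcpa$pa_mask, futures = futures)
}

#' Build modelling covariates: collinearity pruning + soil PCA
#'
#' Applies the study's predictor preparation to a current stack and projects
#' the same transformations onto future stacks: climate-like layers are
#' pruned at `|r| > r_threshold`, soil-like layers are replaced by the
#' principal components explaining > `pca_var_target` of their variance (the
#' current-scenario loadings are reused for every future scenario).
#'
#' @param current the current [env_stack()].
#' @param futures named list of future [env_stack()]s (same layers).
#' @param soil_pattern regex picking the soil layers (default `"^soil"`).
#' @param r_threshold,pca_var_target pruning and PCA targets.
#' @return list with `current`, `futures` (transformed stacks), `retained`
#'   (climate layers kept) and `pca` (the [soil_pca()] fit).
#' @export
prepare_covariates <- function(current, futures = list(),
                               soil_pattern = "^soil",
                               r_threshold = 0.7, pca_var_target = 0.90) {
  nms <- names(current$layers)
  soil_nms <- grep(soil_pattern, nms, value = TRUE)
  clim_nms <- setdiff(nms, soil_nms)
  clim <- env_stack(current$layers[clim_nms], current$scenario_id)
  retained <- correlation_filter(clim, r_threshold)
  pca <- NULL
  transform <- function(stk, is_current = FALSE) {
    layers <- stk$layers[retained]
    if (length(soil_nms) >= 2) {
      soil <- env_stack(stk$layers[soil_nms], stk$scenario_id)
      pcs <- if (is_current) {
        pca <<- soil_pca(soil, pca_var_target)
        pca$pc_stack
      } else {
        soil_pca_project(pca, soil)
      }
      layers <- c(layers, pcs$layers)
    }
    env_stack(layers, stk$scenario_id)
  }
  cur <- transform(current, is_current = TRUE)
  futs <- lapply(futures, transform)
  list(current = cur, futures = futs, retained = retained, pca = pca)
}

#' Fit one species' tuned distribution model
#'
#' The per-species modelling protocol: thin occurrences, calibrate the
#' background extent (Michaelis-Menten over a buffer grid), draw the tuning
#' background within the selected extent, partition (block for n > 25, else
#' jackknife), tune feature class x regularization multiplier by lowest mean
#' omission rate (AUC tie-break), refit, evaluate on pooled held-out
#' predictions and apply the acceptance gates.
#'
#' @param occ an [occurrence_set()].
#' @param stack modelling covariates ([prepare_covariates()] output).
#' @param buffer_grid background-extent candidates, km.
#' @param n_bg_extent pseudo-absences per buffer during extent tuning.
#' @param n_bg_tune pseudo-absences for model tuning.
#' @param rm_grid,fc_menu tuning grids.
#' @param thin_km thinning distance, km.
#' @param exclusion_km background exclusion distance, km.
#' @param n_hinge_knots hinge knots for all fits.
#' @param seed integer seed.
#' @param max_iterations,convergence_tol optimizer settings.
#' @return list with `occ` (thinned), `extent` (background tuning), `background`,
#'   `partition`, `tuning`, `report`, `gate`, `model`, `threshold` (maxSSS).
#' @export
fit_species_sdm <- function(occ, stack,
                            buffer_grid = seq(20, 200, by = 20),
                            n_bg_extent = 1000, n_bg_tune = 2000,
                            rm_grid = default_rm_grid(),
                            fc_menu = default_fc_menu(),
                            thin_km = 10, exclusion_km = 10,
                            n_hinge_knots = 6, seed = 1,
                            max_iterations = 200, convergence_tol = 1e-4) {
  occ_t <- thin_occurrences(occ, thin_km, seed = seed,
                            crs = stack$layers[[1]]$crs)
  extent <- select_background_extent(
    occ_t, stack, buffer_grid, n_points = n_bg_extent,
    exclusion_km = exclusion_km, seed = seed,
    config = maxent_config("LQPH", 1, n_hinge_knots, max_iterations, convergence_tol))
  bg <- sample_background(occ_t, stack$layers[[1]], extent$selected_buffer_km,
                          exclusion_km, n_bg_tune, seed = seed + 1)
  part <- make_partitions(occ_t, bg)
  tuning <- tune_model(occ_t, bg, stack, part, rm_grid, fc_menu,
                       n_hinge_knots, max_iterations, convergence_tol)
  report <- evaluate_model(occ_t, bg, stack, part, tuning$config)
  list(occ = occ_t, extent = extent, background = bg, partition = part,
       tuning = tuning, report = report, gate = gate_model(report),
       model = tuning$model, threshold = report$maxsss_threshold)
}

#' Project a fitted model across scenarios and analyse change
#'
#' Predicts cloglog suitability for the current and each future stack,
#' binarizes at the given threshold, applies land-cover correction, computes
#' the per-species area ledger (national and within protected areas, with and
#' without LCC) and the loss/stable/gain change maps against each future.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param threshold binarization threshold (typically maxSSS).
#' @param current,futures modelling stacks (future list named by scenario).
#' @param landcover,reclass land-cover grid and reclass table.
#' @param pa_mask 0/1 protected-area [raster_grid()].
#' @param species species label.
#' @return list with `maps` (binary maps per scenario, LCC applied),
#'   `maps_nolcc`, `changes` (change map per future scenario), and `areas`
#'   (one-row data.frame for [build_species_table()]).
#' @export
project_species <- function(model, threshold, current, futures,
                            landcover, reclass, pa_mask,
                            species = "species") {
  lc <- landcover_map(landcover, reclass)
  bin_of <- function(stk, id) {
    suit <- predict(model, stk, output = "cloglog")
    binarize(suit, threshold, species = species, scenario_id = id)
  }
  cur_raw <- bin_of(current, "current")
  cur <- apply_lcc(cur_raw, lc)
  fut_raw <- lapply(names(futures), function(nm) bin_of(futures[[nm]], nm))
  names(fut_raw) <- names(futures)
  fut <- lapply(fut_raw, apply_lcc, lc = lc)
  changes <- lapply(fut, function(f) classify_change(cur, f))
  areas <- data.frame(
    species = species,
    area_current_nolcc = suitable_area_km2(cur_raw),
    area_current_lcc = suitable_area_km2(cur),
    area_current_nolcc_pa = suitable_area_km2(cur_raw, pa_mask),
    area_current_lcc_pa = suitable_area_km2(cur, pa_mask)
  )
  area_of <- function(map, cat, mask = NULL) {
    ind <- category_indicator(map, cat)
    bm <- structure(list(grid = ind, species = species, scenario_id = "x",
                         lcc_applied = TRUE, threshold = NA_real_),
                    class = "binary_map")
    suitable_area_km2(bm, mask)
  }
  for (nm in names(changes)) {
    areas[[paste0("loss_", nm, "_nat")]] <- area_of(changes[[nm]], "loss")
    areas[[paste0("gain_", nm, "_nat")]] <- area_of(changes[[nm]], "gain")
    areas[[paste0("stable_", nm, "_nat")]] <- area_of(changes[[nm]], "stable")
    areas[[paste0("loss_", nm, "_pa")]] <- area_of(changes[[nm]], "loss", pa_mask)
    areas[[paste0("gain_", nm, "_pa")]] <- area_of(changes[[nm]], "gain", pa_mask)
  }
  list(maps = c(list(current = cur), fut),
       maps_nolcc = c(list(current = cur_raw), fut_raw),
       changes = changes, areas = areas)
}

#' Hold-out AUC against the generating truth
#'
#' Draws a fresh, independent evaluation set — presences sampled from the
#' known true-probability surface and background cells sampled uniformly from
#' the valid landscape, none used in fitting — and scores the model's
#' presence-background AUC on it. Only possible in synthetic studies (where
#' the truth is known); it measures recovered discrimination without the
#' spatial-extrapolation pessimism of blocked cross-validation.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param truth_prob the species' true-probability [raster_grid()].
#' @param stack covariate [env_stack()] for scoring.
#' @param n_presence,n_background evaluation sample sizes.
#' @param seed integer seed (use one never given to the fitting pipeline).
#' @return AUC in `[0, 1]`.
#' @export
holdout_auc <- function(model, truth_prob, stack, n_presence = 200,
                        n_background = 2000, seed = 1) {
  occ_eval <- sample_occurrences(truth_prob, n_presence, seed = seed,
                                 replace = TRUE, species = "holdout")
  valid <- stack_valid_cells(stack)
  ctr <- cell_centers(stack$layers[[1]])
  bg_cells <- with_seed(seed + 1, sample(valid, n_background, replace = TRUE))
  sp <- maxent_scores(model, stack_extract(stack, occ_eval$x, occ_eval$y))
  sb <- maxent_scores(model, stack_values(stack, bg_cells))
  ok <- !is.na(sp)
  auc_pb(sp[ok], sb[!is.na(sb)])
}

#' Run the full synthetic study for one seed
#'
#' Convenience wrapper: [simulate_study()] + [prepare_covariates()] +
#' [fit_species_sdm()] + [project_species()]. The reduced default grids keep
#' a single run at desk scale.
#'
#' @param seed integer seed.
#' @param rm_grid tuning multipliers (default: 7-value thinning of the
#'   19-value grid).
#' @param ... passed to [simulate_study()].
#' @return list with `sim`, `prep`, `fit`, `proj`.
#' @export
run_synthetic_study <- function(seed = 1,
                                rm_grid = c(0.1, 0.3, 0.75, 1, 2, 4, 6),
                                ...) {
  sim <- simulate_study(seed, ...)
  prep <- prepare_covariates(sim$stack, sim$futures)
  fit <- fit_species_sdm(sim$occ, prep$current, rm_grid = rm_grid, seed = seed)
  proj <- project_species(fit$model, fit$threshold, prep$current, prep$futures,
                          sim$landcover, sim$reclass, sim$pa_mask,
                          species = sim$occ$species)
  list(sim = sim, prep = prep, fit = fit, proj = proj)
}
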