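#!/usr/bin/env Rscript
# Stage 5 — projection, land-cover correction and change analysis.
#
# Refits the selected model, projects cloglog suitability onto the current
# and both future climates, binarizes at the maxSSS threshold, masks
# unsuitable land-cover classes (post-hoc LCC), classifies loss/stable/gain,
# and derives the area ledger, richness-by-protection table and elevation
# profiles.

suppressMessages(library(dipterocarpSDM))

out <- "results/change"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_stack <- function(dir, prefix, scenario_id) {
  files <- Sys.glob(file.path(dir, paste0(prefix, "_*.asc")))
  layers <- lapply(files, read_asc)
  names(layers) <- sub(paste0("^", prefix, "_(.*)\\.asc$"), "\\1", basename(files))
  env_stack(layers, scenario_id)
}
stack <- read_stack("results/preprocess", "current", "current")
futures <- list(rcp45 = read_stack("results/preprocess", "rcp45", "rcp45"),
                rcp85 = read_stack("results/preprocess", "rcp85", "rcp85"))
occ <- read_occurrences("results/preprocess/occurrences_thinned.csv")
bg <- read.csv("results/model/tuning_background.csv")
rep_json <- jsonlite::read_json("results/model/model_report.json")
landcover <- read_asc("results/synthetic/landcover.asc")
reclass <- read_reclass("results/synthetic/reclass.csv")
pa_mask <- read_asc("results/synthetic/pa_mask.asc")
dem <- read_asc("results/synthetic/dem.asc")

cfg <- maxent_config(rep_json$selected$feature_classes, rep_json$selected$rm,
                     n_hinge_knots = 6, max_iterations = 200,
                     convergence_tol = 1e-4)
model <- suppressWarnings(fit_maxent(stack_extract(stack, occ$x, occ$y),
                                     stack_extract(stack, bg$x, bg$y), cfg))
threshold <- rep_json$report$maxsss_threshold

proj <- project_species(model, threshold, stack, futures,
                        landcover, reclass, pa_mask, species = occ$species)
write.csv(proj$areas, file.path(out, "areas_km2.csv"), row.names = FALSE)
tab <- build_species_table(proj$areas)
write.csv(tab, file.path(out, "change_percent.csv"), row.names = FALSE)
message(sprintf("Current range %d km2 (no LCC) -> %d km2 with LCC (%.1f%% removed).",
                proj$areas$area_current_nolcc, proj$areas$area_current_lcc,
                tab$reduced_pct_national))
for (sc in c("rcp45", "rcp85")) {
  message(sprintf("  %s: loss %.1f%%, gain %.1f%% of the current LCC range.",
                  sc, tab[[paste0("loss_", sc, "_nat")]],
                  tab[[paste0("gain_", sc, "_nat")]]))
}

for (sc in names(proj$changes)) {
  ch <- proj$changes[[sc]]
  write_asc(ch$grid, file.path(out, paste0("change_", sc, ".asc")))
  prof <- elevation_profile(ch, dem)
  write.csv(cbind(bin_start_m = prof$breaks, as.data.frame(prof$scaled)),
            file.path(out, paste0("elevation_profile_", sc, ".csv")),
            row.names = FALSE)
  ge <- mean_category_elevation(ch, dem, "gain")
  le <- mean_category_elevation(ch, dem, "loss")
  message(sprintf("  %s elevation: mean loss at %.0f m, mean gain at %.0f m.",
                  sc, le, ge))
}

# protected-area coverage of the current LCC-corrected range
rich <- stack_richness(list(proj$maps$current))
write.csv(area_by_richness(rich, pa_mask), file.path(out, "richness_pa.csv"),
          row.names = FALSE)
write_asc(proj$maps$current$grid, file.path(out, "current_binary_lcc.asc"))
message("Outputs under ", out)
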