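#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Builds the synthetic landscape the rest of the workflow analyses: correlated
# climate- and soil-like fields with a DEM, a tree species whose true
# suitability is a known cloglog response (thermal optimum + moisture
# optimum), biased presence-only records, a 22-class land-cover map with a
# suitability reclass table, protected-area blobs, and two warming scenarios
# (5 GCM realisations each, averaged). Everything is written as plain-text
# rasters/CSV under results/synthetic/ with a manifest of parameters.

suppressMessages(library(dipterocarpSDM))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating landscape and species (seed ", seed, ") ...")
sim <- simulate_study(seed = seed)

for (nm in names(sim$stack$layers)) {
  write_asc(sim$stack$layers[[nm]], file.path(out, paste0("current_", nm, ".asc")))
}
for (sc in names(sim$futures)) {
  for (nm in names(sim$futures[[sc]]$layers)) {
    write_asc(sim$futures[[sc]]$layers[[nm]],
              file.path(out, paste0(sc, "_", nm, ".asc")))
  }
}
write_asc(sim$dem, file.path(out, "dem.asc"))
write_asc(sim$landcover, file.path(out, "landcover.asc"))
write_asc(sim$pa_mask, file.path(out, "pa_mask.asc"))
write_asc(sim$species$prob, file.path(out, "true_probability.asc"))
write_occurrences(sim$occ, file.path(out, "occurrences.csv"))
write.csv(sim$reclass, file.path(out, "reclass.csv"), row.names = FALSE)

manifest <- list(
  seed = seed, n_rows = 64, n_cols = 64, dx_km = 4,
  n_presence = length(sim$occ$x),
  prevalence_target = 0.15,
  truth = list(coef_linear = as.list(sim$species$coef_linear),
               coef_quad = as.list(sim$species$coef_quad),
               intercept = sim$species$intercept),
  scenarios = names(sim$futures),
  n_landcover_classes = nrow(sim$reclass),
  n_unsuitable_classes = sum(sim$reclass$suitable == 0),
  pa_share = mean(sim$pa_mask$values)
)
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

message(sprintf("Wrote %d presence records; %d/%d land-cover classes unsuitable; PA share %.3f.",
                length(sim$occ$x), manifest$n_unsuitable_classes,
                manifest$n_landcover_classes, manifest$pa_share))
message("Outputs under ", out)
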