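#!/usr/bin/env Rscript
# Stage 2 — predictor preparation.
#
# Reads the simulated rasters back from disk, thins the occurrence records at
# 10 km, prunes collinear climate layers at |r| > 0.7, and replaces the soil
# layers by the principal components explaining > 90% of their variance (the
# current-scenario loadings are stored and reused for the future scenarios).

suppressMessages(library(dipterocarpSDM))

src <- "results/synthetic"
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_stack <- function(prefix, scenario_id) {
  files <- Sys.glob(file.path(src, paste0(prefix, "_*.asc")))
  layers <- lapply(files, read_asc)
  names(layers) <- sub(paste0("^", prefix, "_(.*)\\.asc$"), "\\1", basename(files))
  env_stack(layers, scenario_id)
}
current <- read_stack("current", "current")
futures <- list(rcp45 = read_stack("rcp45", "rcp45"),
                rcp85 = read_stack("rcp85", "rcp85"))
occ <- read_occurrences(file.path(src, "occurrences.csv"))

occ_t <- thin_occurrences(occ, thin_km = 10, seed = 1)
message(sprintf("Thinning at 10 km: %d -> %d records.",
                length(occ$x), length(occ_t$x)))
write_occurrences(occ_t, file.path(out, "occurrences_thinned.csv"))

prep <- prepare_covariates(current, futures)
message("Retained climate layers after |r| > 0.7 pruning: ",
        paste(prep$retained, collapse = ", "))
message(sprintf("Soil PCA: kept %d components (%.2f%% variance).",
                prep$pca$n_components_kept,
                100 * sum(prep$pca$explained[seq_len(prep$pca$n_components_kept)])))

jsonlite::write_json(list(
  retained_climate = prep$retained,
  pca = list(n_components_kept = prep$pca$n_components_kept,
             explained = prep$pca$explained,
             center = as.list(prep$pca$center),
             scale = as.list(prep$pca$scale),
             loadings = as.data.frame(prep$pca$loadings))
), file.path(out, "preprocess.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

for (nm in names(prep$current$layers)) {
  write_asc(prep$current$layers[[nm]], file.path(out, paste0("current_", nm, ".asc")))
}
for (sc in names(prep$futures)) {
  for (nm in names(prep$futures[[sc]]$layers)) {
    write_asc(prep$futures[[sc]]$layers[[nm]],
              file.path(out, paste0(sc, "_", nm, ".asc")))
  }
}
message("Modelling covariates written under ", out)
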