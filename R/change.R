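#' Classify per-cell change between current and future binary projections
#'
#' Cells are partitioned into loss (suitable now, not in future), stable
#' (suitable in both — the species' in-situ climate macrorefugia), gain
#' (suitable only in future; assumes full dispersal) and never. A
#' no-dispersal variant empties the gain class.
#'
#' @param current,future co-registered [binarize()] maps for the same species
#'   with matching `lcc_applied` flags.
#' @param dispersal `"full"` (default) or `"none"` (gain forced to never).
#' @return an object of class `change_map`: `grid` with integer codes
#'   0 = never, 1 = loss, 2 = stable, 3 = gain (NA propagates), plus
#'   `species` and `scenario_pair`.
#' @export
classify_change <- function(current, future, dispersal = c("full", "none")) {
  dispersal <- match.arg(dispersal)
  stop_if_not_coregistered(current$grid, future$grid, "current and future maps")
  if (!identical(current$species, future$species))
    stop("maps belong to different species")
  if (!identical(current$lcc_applied, future$lcc_applied))
    stop("mismatched lcc_applied flags")
  cu <- current$grid$values; fu <- future$grid$values
  code <- ifelse(is.na(cu) | is.na(fu), NA_real_,
                 ifelse(cu == 1 & fu == 0, 1,
                        ifelse(cu == 1 & fu == 1, 2,
                               ifelse(cu == 0 & fu == 1, 3, 0))))
  if (dispersal == "none") code[code == 3] <- 0
  structure(list(grid = grid_like(current$grid, matrix(code, nrow(cu), ncol(cu))),
                 species = current$species,
                 scenario_pair = c(current$scenario_id, future$scenario_id)),
            class = "change_map")
}

# 0/1 indicator grid for one category of a change map or a binary map
category_indicator <- function(map, category = c("suitable", "loss", "stable", "gain")) {
  category <- match.arg(category)
  if (inherits(map, "binary_map")) {
    if (category != "suitable")
      stop("binary maps only provide the 'suitable' category")
    return(map$grid)
  }
  code <- c(loss = 1, stable = 2, gain = 3)[[category]]
  v <- map$grid$values
  grid_like(map$grid, matrix(ifelse(is.na(v), NA_real_, as.numeric(v == code)),
                             nrow(v), ncol(v)))
}

#' Stack species maps into a richness surface
#'
#' Per-cell count of species whose selected category covers the cell.
#'
#' @param maps list of [binarize()] maps (category `"suitable"`) or
#'   [classify_change()] maps (categories `"loss"`, `"stable"`, `"gain"`),
#'   one per species (duplicates are an error).
#' @param category which category to stack.
#' @return a [raster_grid()] of species counts in `[0, n_species]`.
#' @export
stack_richness <- function(maps, category = "suitable") {
  if (!length(maps)) stop("empty map list")
  sp <- vapply(maps, function(m) m$species, character(1))
  if (anyDuplicated(sp)) stop("duplicate species in stack: ",
                              paste(unique(sp[duplicated(sp)]), collapse = ", "))
  ind <- lapply(maps, category_indicator, category = category)
  acc <- ind[[1]]$values
  acc[is.na(acc)] <- 0
  if (length(ind) > 1) {
    for (g in ind[-1]) {
      stop_if_not_coregistered(ind[[1]], g, "richness stack members")
      v <- g$values
      v[is.na(v)] <- 0
      acc <- acc + v
    }
  }
  grid_like(ind[[1]], acc)
}

#' Area and protected-area coverage by richness level
#'
#' For every richness level >= 1: total area, area within the protected-area
#' mask and the protected proportion. The proportion is suppressed (`NA`) when
#' the level's total area falls below `min_area_km2`, since tiny denominators
#' give arbitrarily volatile proportions.
#'
#' @param richness a [stack_richness()] surface.
#' @param pa_mask co-registered 0/1 [raster_grid()] of protected areas.
#' @param min_area_km2 suppression floor for proportions (default 50).
#' @return data.frame with `richness`, `area_km2`, `area_pa_km2`,
#'   `prop_protected`.
#' @export
area_by_richness <- function(richness, pa_mask, min_area_km2 = 50) {
  stop_if_not_coregistered(richness, pa_mask, "richness and PA mask")
  a <- cell_area_km2(richness)
  lv <- as.vector(richness$values)
  pa <- as.vector(pa_mask$values) > 0 & !is.na(as.vector(pa_mask$values))
  levels <- sort(unique(lv[!is.na(lv) & lv >= 1]))
  rows <- lapply(levels, function(L) {
    sel <- !is.na(lv) & lv == L
    tot <- sum(as.vector(a)[sel])
    inpa <- sum(as.vector(a)[sel & pa])
    data.frame(richness = L, area_km2 = tot, area_pa_km2 = inpa,
               prop_protected = if (tot < min_area_km2) NA_real_ else inpa / tot)
  })
  do.call(rbind, rows)
}

#' Elevation profile of suitable habitat or change categories
#'
#' Counts cells per half-open 50 m elevation bin for each category and scales
#' every category by the species' maximum current-scenario bin count, so the
#' current profile peaks at exactly 1. For a change map the current scenario
#' is loss + stable. Cells below sea level clamp to the lowest bin; suitable
#' cells lacking a DEM value are excluded with a warning.
#'
#' @param map a [binarize()] map (categories: `current`) or a
#'   [classify_change()] map (categories: `current`, `loss`, `stable`,
#'   `gain`).
#' @param dem co-registered elevation [raster_grid()], metres.
#' @param bin_m bin width in metres (default 50).
#' @param n_bins optional fixed bin count (so profiles from one DEM share
#'   edges); default: enough bins for the DEM maximum.
#' @return an object of class `elevation_profile`: `breaks` (bin left edges),
#'   `counts` and `scaled` (matrices bins x categories), `scale_constant`.
#' @export
elevation_profile <- function(map, dem, bin_m = 50, n_bins = NULL) {
  stop_if_not_coregistered(map$grid, dem, "map and DEM")
  elev <- as.vector(dem$values)
  if (is.null(n_bins)) n_bins <- floor(max(elev, na.rm = TRUE) / bin_m) + 1L
  breaks <- (seq_len(n_bins) - 1L) * bin_m
  bin_of <- function(e) pmin(pmax(floor(e / bin_m), 0L) + 1L, n_bins)
  cats <- if (inherits(map, "binary_map")) "current" else c("current", "loss", "stable", "gain")
  v <- as.vector(map$grid$values)
  counts <- matrix(0, n_bins, length(cats), dimnames = list(NULL, cats))
  sel_for <- function(cat) {
    if (inherits(map, "binary_map")) v == 1
    else switch(cat, current = v %in% c(1, 2), loss = v == 1,
                stable = v == 2, gain = v == 3)
  }
  for (cat in cats) {
    sel <- !is.na(v) & sel_for(cat)
    if (any(sel & is.na(elev))) {
      warning(sum(sel & is.na(elev)), " ", cat, " cell(s) lack DEM values; excluded")
      sel <- sel & !is.na(elev)
    }
    if (any(sel)) {
      tb <- tabulate(bin_of(elev[sel]), nbins = n_bins)
      counts[, cat] <- tb
    }
  }
  scale_constant <- max(counts[, "current"])
  scaled <- if (scale_constant > 0) counts / scale_constant else counts
  structure(list(breaks = breaks, counts = counts, scaled = scaled,
                 scale_constant = scale_constant, bin_m = bin_m),
            class = "elevation_profile")
}

#' Average elevation profiles across species
#'
#' Per-bin arithmetic mean of per-species scaled values; all profiles must
#' share bin edges. Species with no suitable cells contribute all-zero
#' profiles.
#'
#' @param profiles non-empty list of [elevation_profile()]s.
#' @return an `elevation_profile` whose `scaled` is the mean (its `counts`
#'   are summed raw counts; `scale_constant` is `NA`).
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!identical(p$breaks, ref$breaks) || !identical(colnames(p$scaled), colnames(ref$scaled)))
      stop("inconsistent bin edges or categories across profiles")
  }
  scaled <- Reduce(`+`, lapply(profiles, `[[`, "scaled")) / length(profiles)
  counts <- Reduce(`+`, lapply(profiles, `[[`, "counts"))
  structure(list(breaks = ref$breaks, counts = counts, scaled = scaled,
                 scale_constant = NA_real_, bin_m = ref$bin_m),
            class = "elevation_profile")
}

#' Mean elevation of a change category
#'
#' Area-weighted (cell-count) mean elevation of cells in one category; used
#' for directional shift checks (e.g. gains sitting higher than losses under
#' a warming scenario).
#'
#' @param change a [classify_change()] map.
#' @param dem co-registered elevation [raster_grid()].
#' @param category `"loss"`, `"stable"` or `"gain"`.
#' @return mean elevation in metres (`NaN` if the category is empty).
#' @export
mean_category_elevation <- function(change, dem, category) {
  ind <- category_indicator(change, category)
  sel <- !is.na(ind$values) & ind$values == 1 & !is.na(dem$values)
  mean(dem$values[sel])
}
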