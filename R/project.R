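#' Land-cover map with suitability reclassification
#'
#' @param classes integer-class [raster_grid()].
#' @param reclass data.frame with columns `class_id`, `suitable` (0/1) and
#'   optionally `class_name`. Every class present in the raster must appear.
#' @return an object of class `landcover_map`.
#' @export
landcover_map <- function(classes, reclass) {
  if (!all(c("class_id", "suitable") %in% names(reclass)))
    stop("reclass table needs columns class_id and suitable")
  present <- unique(as.vector(classes$values))
  present <- present[!is.na(present)]
  missing <- setdiff(present, reclass$class_id)
  if (length(missing))
    stop("land-cover class(es) missing from reclass table: ",
         paste(missing, collapse = ", "))
  structure(list(classes = classes, reclass = reclass), class = "landcover_map")
}

#' Read a reclass table CSV (`class_id,class_name,suitable`)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_reclass <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class_id", "suitable") %in% names(df)))
    stop("reclass CSV needs columns class_id,class_name,suitable")
  df
}

#' Binarize a suitability surface at a threshold
#'
#' @param suitability a [raster_grid()] of continuous suitability.
#' @param threshold finite threshold (typically the maxSSS value); cells with
#'   suitability >= threshold become 1, others 0, NA propagates.
#' @param species,scenario_id labels carried on the map.
#' @return an object of class `binary_map` (fields `grid`, `species`,
#'   `scenario_id`, `lcc_applied`, `threshold`).
#' @export
binarize <- function(suitability, threshold, species = "species",
                     scenario_id = "current") {
  if (!is.finite(threshold)) stop("threshold must be finite")
  v <- suitability$values
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  structure(list(grid = grid_like(suitability, matrix(b, nrow(v), ncol(v))),
                 species = species, scenario_id = scenario_id,
                 lcc_applied = FALSE, threshold = threshold),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %s / %s: %d suitable cells (tau = %.4g, LCC %s)\n",
              x$species, x$scenario_id, sum(x$grid$values == 1, na.rm = TRUE),
              x$threshold, if (x$lcc_applied) "applied" else "not applied"))
  invisible(x)
}

#' Post-hoc land-cover correction of a binary projection
#'
#' Sets suitable cells that fall on unsuitable land-cover classes to 0.
#' Idempotent; the same static land-cover mask is meant to be applied to every
#' scenario of a species (the land-cover map is contemporary, not projected).
#'
#' @param bin_map a [binarize()] result.
#' @param lc a [landcover_map()], co-registered with the binary map.
#' @return the corrected `binary_map` with `lcc_applied = TRUE`.
#' @export
apply_lcc <- function(bin_map, lc) {
  stop_if_not_coregistered(bin_map$grid, lc$classes, "binary map and land cover")
  unsuitable <- lc$reclass$class_id[lc$reclass$suitable == 0]
  v <- bin_map$grid$values
  mask <- matrix(lc$classes$values %in% unsuitable,
                 nrow(v), ncol(v))
  v[mask & !is.na(v)] <- 0
  out <- bin_map
  out$grid <- grid_like(bin_map$grid, v)
  out$lcc_applied <- TRUE
  out
}

#' Suitable area in square kilometres
#'
#' Sums cell areas over suitable (value 1) cells, optionally intersected with
#' a 0/1 mask (e.g. protected areas), rounded to the nearest km^2.
#'
#' @param bin_map a [binarize()] result (possibly LCC-corrected).
#' @param within_mask optional co-registered 0/1 [raster_grid()].
#' @return area in km^2 (integer-rounded).
#' @export
suitable_area_km2 <- function(bin_map, within_mask = NULL) {
  a <- cell_area_km2(bin_map$grid)
  sel <- !is.na(bin_map$grid$values) & bin_map$grid$values == 1
  if (!is.null(within_mask)) {
    stop_if_not_coregistered(bin_map$grid, within_mask, "binary map and mask")
    sel <- sel & !is.na(within_mask$values) & within_mask$values > 0
  }
  round(sum(a[sel]))
}
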