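#' Single-band raster grid
#'
#' Lightweight in-memory raster: a numeric matrix plus an affine transform and
#' a coordinate-system tag. The grid origin is the **top-left corner**; row
#' index increases southward and cell values represent cell centers. Missing
#' cells are `NA` in memory (a sentinel is only used on disk).
#'
#' Two coordinate modes are supported: `"planar-km"` (coordinates and cell
#' sizes in kilometres, Euclidean distances) for synthetic landscapes, and
#' `"lonlat-deg"` (degrees, haversine distances, spherical cell areas) for
#' real-world grids.
#'
#' @param values numeric matrix (rows = north-to-south).
#' @param x0,y0 coordinates of the top-left corner of the grid.
#' @param dx,dy positive cell sizes (km or degrees, matching `crs`).
#' @param crs `"planar-km"` or `"lonlat-deg"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, x0 = 0, y0 = nrow(values), dx = 1, dy = 1,
                        crs = c("planar-km", "lonlat-deg")) {
  crs <- match.arg(crs)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!(dx > 0 && dy > 0)) stop("cell sizes dx and dy must be positive")
  structure(list(values = values, x0 = x0, y0 = y0, dx = dx, dy = dy, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %s, cell %g x %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$crs, x$dx, x$dy, x$x0, x$y0))
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_is_compatible <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol &&
    identical(a$crs, b$crs)
}

stop_if_not_coregistered <- function(a, b, what = "grids") {
  if (!grid_is_compatible(a, b)) stop(what, " are not co-registered (shape/transform/crs differ)")
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid a [raster_grid()].
#' @return data.frame with `x`, `y`, `row`, `col`, `cell` (column-major index).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  row <- rep.int(seq_len(nr), nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    x = grid$x0 + (col - 0.5) * grid$dx,
    y = grid$y0 - (row - 0.5) * grid$dy,
    row = row, col = col, cell = seq_len(nr * nc)
  )
}

#' Map point coordinates to cell indices (nearest cell center)
#'
#' Points outside the grid extent get `NA`.
#' @param grid a [raster_grid()].
#' @param x,y point coordinates.
#' @return integer column-major cell indices.
#' @export
cell_from_xy <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$x0) / grid$dx) + 1L
  row <- floor((grid$y0 - y) / grid$dy) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  idx <- (col - 1L) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Per-cell area in square kilometres
#'
#' Planar grids return the constant `dx * dy`. Longitude/latitude grids return
#' latitude-dependent spherical areas computed from the spherical-zone formula
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)} with the mean Earth
#' radius R = 6371.0088 km.
#'
#' @param grid a [raster_grid()].
#' @return matrix of cell areas (km^2), same shape as the grid (NA cells
#'   included: area is a property of the cell, not of the value).
#' @export
cell_area_km2 <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (grid$crs == "planar-km") {
    return(matrix(grid$dx * grid$dy, nr, nc))
  }
  if (grid$crs != "lonlat-deg") stop("unknown crs tag: ", grid$crs)
  R <- 6371.0088
  lat_top <- grid$y0 - (seq_len(nr) - 1L) * grid$dy
  lat_bot <- lat_top - grid$dy
  dlon <- grid$dx * pi / 180
  row_area <- R^2 * dlon * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  matrix(rep.int(row_area, nc), nr, nc)
}

#' Great-circle / planar distance between two points
#'
#' Haversine distance (via \pkg{geosphere}) for `"lonlat-deg"`, Euclidean for
#' `"planar-km"`. Symmetric, zero iff the points coincide.
#'
#' @param p1,p2 numeric length-2 vectors `(x, y)` (lon/lat in degrees for
#'   lonlat mode, km for planar mode).
#' @param crs coordinate mode tag.
#' @return distance in km.
#' @export
great_circle_km <- function(p1, p2, crs = c("planar-km", "lonlat-deg")) {
  crs <- match.arg(crs)
  if (!all(is.finite(c(p1, p2)))) stop("coordinates must be finite")
  if (crs == "planar-km") {
    sqrt((p1[1] - p2[1])^2 + (p1[2] - p2[2])^2)
  } else {
    geosphere::distHaversine(p1, p2, r = 6371008.8) / 1000
  }
}

# Pairwise distance matrix between two point sets (rows of 2-col matrices).
pairwise_dist_km <- function(a, b, crs) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (crs == "planar-km") {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx^2 + dy^2)
  } else {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b))) {
      out[, j] <- geosphere::distHaversine(a, b[j, ], r = 6371008.8) / 1000
    }
    out
  }
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by row-major values, north first).
#' Square cells only. The coordinate mode is not stored in the format and must
#' be supplied.
#'
#' @param path file path.
#' @param crs coordinate mode tag to attach.
#' @return a [raster_grid()]; sentinel cells become `NA`.
#' @export
read_asc <- function(path, crs = c("planar-km", "lonlat-deg")) {
  crs <- match.arg(crs)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("not an ESRI ASCII grid: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- length(lines[grepl("^[a-zA-Z]", trimws(lines))])
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("value count does not match header in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m,
              x0 = hdr$xllcorner, y0 = hdr$yllcorner + nr * hdr$cellsize,
              dx = hdr$cellsize, dy = hdr$cellsize, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid()] with square cells.
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  if (abs(grid$dx - grid$dy) > 1e-12) stop("ESRI ASCII grids require square cells")
  v <- grid$values
  v[is.na(v)] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0 - nr * grid$dy),
    sprintf("cellsize %.10g", grid$dx),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Named stack of co-registered raster layers
#'
#' @param layers named list of [raster_grid()] objects sharing shape,
#'   transform and crs.
#' @param scenario_id scenario label, e.g. `"current"`, `"rcp45"`, `"rcp85"`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, scenario_id = "current") {
  if (length(layers) < 1) stop("a stack needs at least one layer")
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layers must have unique, non-empty names")
  ref <- layers[[1]]
  for (i in seq_along(layers)) {
    stop_if_not_coregistered(ref, layers[[i]], sprintf("stack layers '%s' and '%s'", nms[1], nms[i]))
  }
  structure(list(layers = layers, scenario_id = scenario_id), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> scenario '%s': %d layers (%s), %d x %d cells\n",
              x$scenario_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values)))
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Extract stack values as a cells-by-layers matrix
#'
#' @param stack an [env_stack()].
#' @param cells optional column-major cell indices (default: all cells).
#' @return numeric matrix, one column per layer, `NA` where any layer is NA at
#'   that cell only in that layer's column (use [stack_valid_cells()] for the
#'   all-valid mask).
#' @export
stack_values <- function(stack, cells = NULL) {
  m <- vapply(stack$layers, function(g) as.vector(g$values),
              numeric(length(stack$layers[[1]]$values)))
  m <- matrix(m, ncol = length(stack$layers),
              dimnames = list(NULL, names(stack$layers)))
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  m
}

#' Cells valid (non-NA) in every layer of a stack
#' @param stack an [env_stack()].
#' @return integer vector of column-major cell indices.
#' @export
stack_valid_cells <- function(stack) {
  which(stats::complete.cases(stack_values(stack)))
}

#' Values of a stack at point coordinates
#'
#' @param stack an [env_stack()].
#' @param x,y point coordinates.
#' @return matrix, one row per point, one column per layer.
#' @export
stack_extract <- function(stack, x, y) {
  cells <- cell_from_xy(stack$layers[[1]], x, y)
  out <- matrix(NA_real_, length(x), length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  ok <- !is.na(cells)
  if (any(ok)) out[ok, ] <- stack_values(stack, cells[ok])
  out
}

# Build a grid shaped like `template` with `values` placed at `cells`.
grid_like <- function(template, values, cells = NULL, fill = NA_real_) {
  m <- matrix(fill, nrow(template$values), ncol(template$values))
  if (is.null(cells)) m[] <- values else m[cells] <- values
  raster_grid(m, x0 = template$x0, y0 = template$y0,
              dx = template$dx, dy = template$dy, crs = template$crs)
}

#' Occurrence set for one species
#'
#' @param species species label.
#' @param x,y presence coordinates (finite).
#' @param year optional integer collection years.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, x, y, year = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("occurrence coordinates must be finite")
  if (!is.null(year) && length(year) != length(x)) stop("year length mismatch")
  structure(list(species = species, x = as.numeric(x), y = as.numeric(y), year = year),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d points\n", x$species, length(x$x)))
  invisible(x)
}

#' Read occurrences from CSV (`species,x,y[,year]`)
#'
#' @param path CSV path with header.
#' @param species optional: restrict to one species (default: first present).
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(df)))
    stop("occurrence CSV must have columns species,x,y[,year]")
  if (is.null(species)) species <- df$species[1]
  df <- df[df$species == species, , drop = FALSE]
  occurrence_set(species, df$x, df$y, if ("year" %in% names(df)) df$year else NULL)
}

#' Write occurrences to CSV
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- data.frame(species = occ$species, x = occ$x, y = occ$y)
  if (!is.null(occ$year)) df$year <- occ$year
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Seeded evaluation that restores the RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
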