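#' Synthetic landscapes, species, land cover and future climates
#'
#' Generators that emulate the statistical structure the modelling workflow
#' assumes — smooth correlated environmental fields, species whose true
#' occurrence probability is a known cloglog function of a covariate subset,
#' spatially biased presence-only sampling, categorical land cover with
#' natural and anthropogenic classes, blob-shaped protected areas, and future
#' climates as offset/rescaled current climate plus GCM noise — so every
#' downstream stage can be exercised without external downloads.
#'
#' @name synthetic_data
NULL

# Smooth mean-zero unit-variance random field: a sum of random cosine basis
# surfaces with wavelengths around `spatial_range` (same units as coords).
smooth_field <- function(nr, nc, dx, dy, spatial_range, n_basis = 64) {
  cx <- (seq_len(nc) - 0.5) * dx
  cy <- (seq_len(nr) - 0.5) * dy
  f <- matrix(0, nr, nc)
  X <- matrix(rep(cx, each = nr), nr, nc)
  Y <- matrix(rep.int(cy, nc), nr, nc)
  for (k in seq_len(n_basis)) {
    wavelength <- spatial_range * exp(stats::runif(1, -0.5, 0.8))
    theta <- stats::runif(1, 0, 2 * pi)
    omega <- 2 * pi / wavelength
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * cos(omega * (cos(theta) * X + sin(theta) * Y) + phase)
  }
  (f - mean(f)) / stats::sd(as.vector(f))
}

#' Generate a synthetic environmental stack and DEM
#'
#' Produces `n_bioclim` climate-like layers (`bio1` is the designated
#' temperature-like layer, negatively correlated with elevation) and `n_soil`
#' soil-like layers, all smooth correlated Gaussian-style fields on a planar
#' kilometre grid, plus a digital elevation model in metres. When
#' `cross_correlation > 0` the two last bioclim layers are built from a shared
#' component so their sample correlation is approximately that value (used to
#' exercise collinearity pruning).
#'
#' @param n_rows,n_cols grid dimensions (>= 16).
#' @param n_bioclim,n_soil number of climate-like / soil-like layers.
#' @param spatial_range correlation length of the fields, km.
#' @param cross_correlation target correlation of the designated layer pair,
#'   in `[0, 1)`.
#' @param seed integer seed; output is deterministic given all arguments.
#' @param dx cell size, km.
#' @return list with `stack` (an [env_stack()], scenario `"current"`) and
#'   `dem` (a [raster_grid()], metres).
#' @export
generate_env_stack <- function(n_rows, n_cols, n_bioclim = 4, n_soil = 4,
                               spatial_range = 10, cross_correlation = 0,
                               seed = 1, dx = 1) {
  if (n_rows < 16 || n_cols < 16) stop("grid must be at least 16 x 16")
  if (cross_correlation < 0 || cross_correlation >= 1)
    stop("cross_correlation must be in [0, 1)")
  with_seed(seed, {
    dem_f <- smooth_field(n_rows, n_cols, dx, dx, spatial_range * 1.5)
    dem <- pmax(0, 700 + 450 * dem_f)
    layers <- list()
    for (i in seq_len(n_bioclim)) {
      own <- smooth_field(n_rows, n_cols, dx, dx, spatial_range)
      if (i == 1) {
        # temperature decreases with elevation (lapse-rate analogue)
        f <- -0.75 * dem_f + sqrt(1 - 0.75^2) * own
      } else {
        f <- own
      }
      layers[[paste0("bio", i)]] <- f
    }
    if (cross_correlation > 0 && n_bioclim >= 2) {
      a <- paste0("bio", n_bioclim - 1)
      b <- paste0("bio", n_bioclim)
      rho <- cross_correlation
      layers[[b]] <- rho * layers[[a]] + sqrt(1 - rho^2) * layers[[b]]
    }
    for (i in seq_len(n_soil)) {
      layers[[paste0("soil", i)]] <- smooth_field(n_rows, n_cols, dx, dx, spatial_range * 0.8)
    }
    grids <- lapply(layers, function(m) {
      raster_grid(m, x0 = 0, y0 = n_rows * dx, dx = dx, dy = dx, crs = "planar-km")
    })
    list(
      stack = env_stack(grids, scenario_id = "current"),
      dem = raster_grid(matrix(dem, n_rows, n_cols), x0 = 0, y0 = n_rows * dx,
                        dx = dx, dy = dx, crs = "planar-km")
    )
  })
}

#' Generate a species with known occurrence probability
#'
#' The per-cell true probability is the inverse cloglog
#' \eqn{p = 1 - \exp(-\exp(\eta))} of a linear predictor
#' \eqn{\eta = \alpha + \sum_i b_i z_i + \sum_i c_i z_i^2} over standardized
#' covariates, with the intercept \eqn{\alpha} calibrated by bisection so the
#' mean probability over valid cells equals `prevalence_target`.
#'
#' @param stack an [env_stack()].
#' @param coef_linear named vector of linear coefficients (names are layers).
#' @param coef_quad optional named vector of quadratic coefficients.
#' @param prevalence_target mean occurrence probability, in (0, 1).
#' @param species species label.
#' @return list with `species` (label), `coef_linear`, `coef_quad`,
#'   `intercept`, and `prob` (a [raster_grid()] of true probabilities).
#' @export
generate_species <- function(stack, coef_linear, coef_quad = NULL,
                             prevalence_target = 0.15, species = "synthetic_sp") {
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  nms <- unique(c(names(coef_linear), names(coef_quad)))
  if (length(nms) == 0) stop("at least one named coefficient is required")
  missing <- setdiff(nms, names(stack$layers))
  if (length(missing)) stop("coefficients name absent layers: ", paste(missing, collapse = ", "))
  vals <- stack_values(stack)
  valid <- which(stats::complete.cases(vals))
  zstd <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  eta0 <- rep(0, length(valid))
  for (nm in names(coef_linear)) {
    eta0 <- eta0 + coef_linear[[nm]] * zstd(vals[valid, nm])
  }
  for (nm in names(coef_quad)) {
    eta0 <- eta0 + coef_quad[[nm]] * zstd(vals[valid, nm])^2
  }
  mean_p <- function(alpha) mean(1 - exp(-exp(alpha + eta0)))
  lo <- -50; hi <- 20
  if (mean_p(lo) > prevalence_target || mean_p(hi) < prevalence_target)
    stop("prevalence_target unreachable for these covariates")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (mean_p(mid) < prevalence_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  alpha <- (lo + hi) / 2
  p <- 1 - exp(-exp(alpha + eta0))
  template <- stack$layers[[1]]
  list(
    species = species,
    coef_linear = coef_linear,
    coef_quad = coef_quad,
    intercept = alpha,
    prob = grid_like(template, p, cells = valid)
  )
}

#' Sample presence-only occurrences from a true-probability surface
#'
#' Presences are drawn from valid cells with probability proportional to
#' `true_prob` times the optional `sampling_bias` surface, then jittered
#' uniformly within the cell (so thinning distances are non-trivial while the
#' nearest cell center stays unambiguous).
#'
#' @param true_prob [raster_grid()] of occurrence probabilities.
#' @param n_presence number of presence points.
#' @param sampling_bias optional co-registered [raster_grid()] of relative
#'   sampling effort (e.g. road-proximity bias); `NULL` means uniform effort.
#' @param seed integer seed.
#' @param replace sample cells with replacement (default `FALSE`).
#' @param species species label for the output.
#' @return an [occurrence_set()].
#' @export
sample_occurrences <- function(true_prob, n_presence, sampling_bias = NULL,
                               seed = 1, replace = FALSE, species = "synthetic_sp") {
  w <- as.vector(true_prob$values)
  if (!is.null(sampling_bias)) {
    stop_if_not_coregistered(true_prob, sampling_bias, "probability and bias grids")
    w <- w * as.vector(sampling_bias$values)
  }
  w[is.na(w)] <- 0
  pos <- which(w > 0)
  if (!replace && n_presence > length(pos))
    stop("n_presence exceeds the number of cells with positive sampling weight")
  with_seed(seed, {
    cells <- sample(pos, n_presence, replace = replace, prob = w[pos])
    nr <- nrow(true_prob$values)
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    jx <- stats::runif(n_presence, -0.5, 0.5) * true_prob$dx
    jy <- stats::runif(n_presence, -0.5, 0.5) * true_prob$dy
    x <- true_prob$x0 + (col - 0.5) * true_prob$dx + jx
    y <- true_prob$y0 - (row - 0.5) * true_prob$dy + jy
    occurrence_set(species, x, y)
  })
}

#' Generate categorical land cover, a protected-area mask and a reclass table
#'
#' Land-cover classes are grown as spatial blobs (nearest-seed regions with a
#' smooth warp so boundaries are irregular). A subset of classes is marked
#' unsuitable so that unsuitable cells approximate `anthropogenic_fraction` of
#' the landscape; `n_unsuitable` fixes the number of unsuitable classes when
#' given. Protected areas are blobs around random seeds covering approximately
#' `pa_fraction` of cells.
#'
#' @param stack an [env_stack()] providing the grid template.
#' @param n_classes number of land-cover classes.
#' @param anthropogenic_fraction target unsuitable share of cells, in `[0, 1)`.
#' @param pa_fraction target protected share of cells, in `[0, 1)`.
#' @param seed integer seed.
#' @param n_unsuitable optional fixed count of unsuitable classes.
#' @param n_pa_blobs number of protected-area seed blobs.
#' @return list with `landcover` (integer-class [raster_grid()]), `reclass`
#'   (data.frame `class_id,class_name,suitable`), and `pa_mask` (0/1 grid).
#' @export
generate_landcover_and_pa <- function(stack, n_classes = 22,
                                      anthropogenic_fraction = 0.6,
                                      pa_fraction = 0.15, seed = 1,
                                      n_unsuitable = NULL, n_pa_blobs = 4) {
  if (anthropogenic_fraction < 0 || anthropogenic_fraction >= 1)
    stop("anthropogenic_fraction must be in [0, 1)")
  if (pa_fraction < 0 || pa_fraction >= 1) stop("pa_fraction must be in [0, 1)")
  template <- stack$layers[[1]]
  nr <- nrow(template$values); nc <- ncol(template$values)
  ctr <- cell_centers(template)
  with_seed(seed, {
    warp <- smooth_field(nr, nc, template$dx, template$dy,
                         spatial_range = 6 * template$dx)
    seeds <- ctr[sample.int(nrow(ctr), n_classes), c("x", "y")]
    d <- pairwise_dist_km(cbind(ctr$x, ctr$y), as.matrix(seeds), template$crs)
    d <- d + 2 * template$dx * matrix(as.vector(warp), nrow(d), ncol(d))
    cls <- max.col(-d, ties.method = "first")
    lc <- grid_like(template, as.numeric(cls))
    # pick unsuitable classes: random order, cumulative size closest to target
    sizes <- tabulate(cls, nbins = n_classes)
    ord <- sample.int(n_classes)
    cum <- cumsum(sizes[ord]) / length(cls)
    k <- if (!is.null(n_unsuitable)) {
      n_unsuitable
    } else if (anthropogenic_fraction == 0) {
      0L
    } else {
      which.min(abs(cum - anthropogenic_fraction))
    }
    unsuitable <- if (k > 0) ord[seq_len(k)] else integer(0)
    reclass <- data.frame(
      class_id = seq_len(n_classes),
      class_name = ifelse(seq_len(n_classes) %in% unsuitable,
                          paste0("anthropogenic_", seq_len(n_classes)),
                          paste0("natural_", seq_len(n_classes))),
      suitable = as.integer(!seq_len(n_classes) %in% unsuitable)
    )
    # protected areas: warped-distance blobs thresholded at the target share
    pa_seeds <- ctr[sample.int(nrow(ctr), n_pa_blobs), c("x", "y")]
    dpa <- pairwise_dist_km(cbind(ctr$x, ctr$y), as.matrix(pa_seeds), template$crs)
    dmin <- apply(dpa, 1, min) + 3 * template$dx * as.vector(smooth_field(
      nr, nc, template$dx, template$dy, spatial_range = 8 * template$dx))
    pa <- as.numeric(dmin <= stats::quantile(dmin, pa_fraction))
    list(landcover = lc, reclass = reclass, pa_mask = grid_like(template, pa))
  })
}

#' Scenario offsets defining a future climate from the current one
#'
#' @param shift named numeric vector of additive per-layer shifts (layers not
#'   named shift by 0).
#' @param scale named numeric vector of multiplicative per-layer scales
#'   (default 1); all scales must be positive.
#' @return An object of class `scenario_offsets`.
#' @export
scenario_offsets <- function(shift = numeric(0), scale = numeric(0)) {
  if (length(scale) && any(scale <= 0)) stop("scales must be positive")
  structure(list(shift = shift, scale = scale), class = "scenario_offsets")
}

# Apply offsets to one stack (no noise).
apply_offsets <- function(stack, offsets, scenario_id) {
  layers <- lapply(names(stack$layers), function(nm) {
    g <- stack$layers[[nm]]
    sc <- if (nm %in% names(offsets$scale)) offsets$scale[[nm]] else 1
    sh <- if (nm %in% names(offsets$shift)) offsets$shift[[nm]] else 0
    grid_like(g, g$values * sc + sh)
  })
  names(layers) <- names(stack$layers)
  env_stack(layers, scenario_id = scenario_id)
}

#' Generate future-climate GCM realisations
#'
#' Each realisation is the current stack with `offsets` applied plus
#' independent smooth noise of standard deviation `gcm_noise_sd` per layer,
#' emulating disagreement among global circulation models; averaging the
#' realisations (see [average_gcms()]) converges on the offset stack as the
#' noise shrinks.
#'
#' @param stack the current [env_stack()].
#' @param offsets a [scenario_offsets()].
#' @param n_gcms number of realisations (>= 1).
#' @param gcm_noise_sd standard deviation of the smooth per-layer noise.
#' @param seed integer seed.
#' @param scenario_id label for the future scenario (e.g. `"rcp85"`).
#' @return list of [env_stack()]s of length `n_gcms`.
#' @export
generate_future <- function(stack, offsets, n_gcms = 5, gcm_noise_sd = 0.1,
                            seed = 1, scenario_id = "future") {
  if (n_gcms < 1) stop("n_gcms must be at least 1")
  base <- apply_offsets(stack, offsets, scenario_id)
  template <- stack$layers[[1]]
  nr <- nrow(template$values); nc <- ncol(template$values)
  with_seed(seed, {
    lapply(seq_len(n_gcms), function(g) {
      layers <- lapply(base$layers, function(ly) {
        if (gcm_noise_sd == 0) return(ly)
        noise <- smooth_field(nr, nc, template$dx, template$dy,
                              spatial_range = 10 * template$dx)
        grid_like(ly, ly$values + gcm_noise_sd * noise)
      })
      names(layers) <- names(base$layers)
      env_stack(layers, scenario_id = paste0(scenario_id, "_gcm", g))
    })
  })
}
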