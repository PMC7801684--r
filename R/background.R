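# distance from every grid cell center to the nearest presence point
nearest_presence_dist <- function(grid, occ) {
  ctr <- cell_centers(grid)
  d <- pairwise_dist_km(cbind(ctr$x, ctr$y), cbind(occ$x, occ$y), grid$crs)
  apply(d, 1, min)
}

#' Sample pseudo-absence (background) points in a buffered annulus
#'
#' Background cells are those whose center lies strictly beyond the exclusion
#' distance and within the buffer distance of the nearest presence (and are
#' valid in the grid). `n_points` cells are sampled uniformly without
#' replacement, or with replacement if the annulus holds fewer cells. The
#' exclusion buffer prevents cells acting as both presence and pseudo-absence.
#'
#' @param occ an [occurrence_set()].
#' @param grid a [raster_grid()] defining cells and validity (NA = invalid).
#' @param buffer_km outer inclusion distance, km.
#' @param exclusion_km inner exclusion distance, km (default 10);
#'   must satisfy `buffer_km > exclusion_km >= 0`.
#' @param n_points number of background points (>= 1).
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `cell` of sampled background cells.
#' @export
sample_background <- function(occ, grid, buffer_km, exclusion_km = 10,
                              n_points = 1000, seed = 1) {
  if (!(buffer_km > exclusion_km && exclusion_km >= 0))
    stop("need buffer_km > exclusion_km >= 0")
  if (n_points < 1) stop("n_points must be >= 1")
  d <- nearest_presence_dist(grid, occ)
  ctr <- cell_centers(grid)
  ok <- d > exclusion_km & d <= buffer_km & !is.na(as.vector(grid$values))
  cells <- ctr$cell[ok]
  if (!length(cells)) stop("empty background annulus for buffer ", buffer_km, " km")
  with_seed(seed, {
    picked <- if (length(cells) >= n_points) {
      sample(cells, n_points)
    } else {
      sample(cells, n_points, replace = TRUE)
    }
    data.frame(x = ctr$x[picked], y = ctr$y[picked], cell = picked)
  })
}

#' Least-squares Michaelis-Menten fit of performance against buffer distance
#'
#' Fits \eqn{y = V_m d / (K + d)} to (buffer, performance) pairs by nonlinear
#' least squares (`minpack.lm::nlsLM`, with a coarse grid + `optim` polish as
#' fallback). A flat performance curve degenerates to `Vm = ` that value with
#' `K` at a small epsilon.
#'
#' @param buffers distance buffers, km (>= 3 distinct values).
#' @param performances model performance (e.g. AUC) per buffer, in `[0, 1]`.
#' @return list with `Vm` and `K`.
#' @export
fit_michaelis_menten <- function(buffers, performances) {
  if (length(unique(buffers)) < 3) stop("need at least 3 distinct buffers")
  if (!all(is.finite(buffers)) || !all(is.finite(performances)))
    stop("non-finite inputs")
  if (any(performances < 0 | performances > 1))
    stop("performances must be in [0, 1]")
  if (stats::sd(performances) == 0) {
    return(list(Vm = performances[1], K = 1e-8))
  }
  df <- data.frame(d = buffers, y = performances)
  rss <- function(par) sum((df$y - par[1] * df$d / (par[2] + df$d))^2)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(y ~ Vm * d / (K + d), data = df,
                           start = list(Vm = max(df$y), K = stats::median(df$d) / 2),
                           lower = c(1e-8, 1e-8), upper = c(1.5, Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(stats::coef(m))
  }, error = function(e) NULL)
  # coarse grid + polish; also used as a safeguard against nls local optima
  grid <- expand.grid(Vm = seq(0.05, 1.2, length.out = 40),
                      K = exp(seq(log(1e-3), log(10 * max(df$d)), length.out = 50)))
  grid_rss <- mapply(function(v, k) rss(c(v, k)), grid$Vm, grid$K)
  best <- as.numeric(grid[which.min(grid_rss), ])
  polish <- stats::optim(best, rss, method = "L-BFGS-B",
                         lower = c(1e-8, 1e-8), upper = c(1.5, Inf))
  alt <- list(Vm = polish$par[1], K = polish$par[2])
  if (is.null(fit) || rss(unlist(alt)) < rss(unlist(fit))) fit <- alt
  list(Vm = fit$Vm, K = fit$K)
}

#' Select a buffer from a performance curve by the Michaelis-Menten rule
#'
#' Fits the saturation curve and picks the smallest buffer whose observed
#' performance reaches the fitted asymptote `Vm` (a Michaelis-Menten curve
#' approaches `Vm` from below, so only noise pushes observations above it);
#' if no buffer crosses, falls back to the best-performing buffer. Adding
#' larger buffers to the grid never changes a selection that already crossed
#' at a smaller buffer.
#'
#' @param buffers ascending buffer distances, km.
#' @param performances observed performance per buffer, in `[0, 1]`.
#' @return list with `Vm`, `K`, `selected_index`, `selected_buffer_km`.
#' @export
select_buffer_mm <- function(buffers, performances) {
  mm <- fit_michaelis_menten(buffers, performances)
  crossing <- which(performances >= mm$Vm)
  idx <- if (length(crossing)) min(crossing) else which.max(performances)
  list(Vm = mm$Vm, K = mm$K, selected_index = idx,
       selected_buffer_km = buffers[idx])
}

#' Calibrate the species-specific background extent
#'
#' For each buffer in `buffer_grid`, samples `n_points` pseudo-absences in the
#' annulus (fixed exclusion distance), fits a default-settings model (LQPH,
#' rm = 1) and scores cross-validated AUC with 'block' partitioning (used for
#' all species regardless of sample size at this stage). A Michaelis-Menten
#' curve is fitted to (buffer, AUC) and the smallest buffer whose observed AUC
#' reaches the fitted asymptote `Vm` is selected; if no buffer crosses the
#' asymptote, the buffer with the highest AUC is used.
#'
#' @param occ an [occurrence_set()].
#' @param stack covariate [env_stack()].
#' @param buffer_grid ascending buffer distances, km (the study protocol uses
#'   `seq(20, 2000, by = 10)`, 199 buffers).
#' @param n_points pseudo-absences per buffer (study protocol: 1000).
#' @param exclusion_km inner exclusion distance, km.
#' @param seed integer seed.
#' @param config model settings for the per-buffer fits.
#' @return list (`background_tuning`): `buffers`, `auc` (per buffer), `Vm`,
#'   `K`, `selected_buffer_km`, `background` (points sampled at the selected
#'   buffer).
#' @export
select_background_extent <- function(occ, stack, buffer_grid,
                                     n_points = 1000, exclusion_km = 10,
                                     seed = 1, config = maxent_config("LQPH", 1)) {
  if (is.unsorted(buffer_grid, strictly = TRUE)) stop("buffer grid must be ascending")
  grid <- stack$layers[[1]]
  d_near <- nearest_presence_dist(grid, occ)
  ctr <- cell_centers(grid)
  valid <- !is.na(as.vector(grid$values))
  pres_cov <- stack_extract(stack, occ$x, occ$y)
  ok_p <- stats::complete.cases(pres_cov)
  aucs <- rep(NA_real_, length(buffer_grid))
  bgs <- vector("list", length(buffer_grid))
  for (i in seq_along(buffer_grid)) {
    b <- buffer_grid[i]
    ok <- d_near > exclusion_km & d_near <= b & valid
    cells <- ctr$cell[ok]
    if (!length(cells)) next
    bg <- with_seed(seed + i, {
      picked <- if (length(cells) >= n_points) sample(cells, n_points)
                else sample(cells, n_points, replace = TRUE)
      data.frame(x = ctr$x[picked], y = ctr$y[picked], cell = picked)
    })
    bgs[[i]] <- bg
    part <- make_partitions(occ, bg, threshold_n = 0)  # block for all species here
    part$pres_fold <- part$pres_fold[ok_p]
    bg_cov <- stack_extract(stack, bg$x, bg$y)
    sc <- cv_candidate(pres_cov[ok_p, , drop = FALSE], bg_cov, part, config)
    aucs[i] <- sc[["auc"]]
  }
  have <- which(!is.na(aucs))
  if (length(have) < 3) stop("fewer than 3 buffers could be evaluated")
  rule <- select_buffer_mm(buffer_grid[have], aucs[have])
  sel <- have[rule$selected_index]
  list(buffers = buffer_grid, auc = aucs, Vm = rule$Vm, K = rule$K,
       selected_buffer_km = buffer_grid[sel], background = bgs[[sel]])
}
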