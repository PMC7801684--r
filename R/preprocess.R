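#' Spatially thin occurrence records
#'
#' Enforces a minimum pairwise distance between retained records (the standard
#' defence against spatial sampling bias in presence-only data). The paper's
#' protocol fixes only the distance; the algorithm here is a randomized greedy
#' pass — repeatedly delete one member (random tie-break) of the closest
#' violating pair — restarted `n_restarts` times, keeping the largest
#' surviving set. This approximates the maximum independent set at the given
#' distance and is reproducible under `seed`.
#'
#' @param occ an [occurrence_set()].
#' @param thin_km minimum pairwise distance, km (default 10 as in the study
#'   protocol).
#' @param n_restarts randomized greedy restarts.
#' @param seed integer seed.
#' @param crs coordinate mode of the occurrence coordinates.
#' @return a thinned [occurrence_set()] (subset of the input).
#' @export
thin_occurrences <- function(occ, thin_km = 10, n_restarts = 20, seed = 1,
                             crs = "planar-km") {
  n <- length(occ$x)
  if (n <= 1) return(occ)
  pts <- cbind(occ$x, occ$y)
  d <- pairwise_dist_km(pts, pts, crs)
  diag(d) <- Inf
  if (min(d) >= thin_km) return(occ)
  best <- integer(0)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      keep <- rep(TRUE, n)
      dd <- d
      repeat {
        m <- min(dd[keep, keep, drop = FALSE])
        if (m >= thin_km) break
        idx <- which(dd == m & outer(keep, keep, "&"), arr.ind = TRUE)
        pair <- idx[sample.int(nrow(idx), 1), ]
        drop_i <- pair[[sample.int(2, 1)]]
        keep[drop_i] <- FALSE
        dd[drop_i, ] <- Inf
        dd[, drop_i] <- Inf
      }
      if (sum(keep) > length(best)) best <- which(keep)
    }
  })
  occurrence_set(occ$species, occ$x[best], occ$y[best],
                 if (!is.null(occ$year)) occ$year[best] else NULL)
}

#' Prune collinear predictor layers
#'
#' Computes pairwise Pearson correlations over cells valid in all layers and
#' greedily drops, among variables involved in violating pairs
#' (`|r| > r_threshold`), the non-protected variable with the largest mean
#' absolute correlation to the other violators, until no violating pair
#' remains.
#'
#' @param stack an [env_stack()] with at least 2 layers.
#' @param r_threshold absolute Pearson correlation bound (default 0.7).
#' @param keep_list layer names exempt from pruning (an error is raised if the
#'   protected set itself violates the threshold).
#' @return character vector of retained layer names.
#' @export
correlation_filter <- function(stack, r_threshold = 0.7, keep_list = character(0)) {
  if (length(stack$layers) < 2) stop("need at least two layers")
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0, 1)")
  vals <- stack_values(stack)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  keep <- colnames(vals)
  bad_protected <- function(cm) {
    pk <- intersect(keep_list, rownames(cm))
    if (length(pk) < 2) return(NULL)
    sub <- abs(cm[pk, pk, drop = FALSE])
    diag(sub) <- 0
    w <- which(sub > r_threshold, arr.ind = TRUE)
    if (nrow(w)) c(rownames(sub)[w[1, 1]], colnames(sub)[w[1, 2]]) else NULL
  }
  repeat {
    cm <- stats::cor(vals[, keep, drop = FALSE])
    bp <- bad_protected(cm)
    if (!is.null(bp))
      stop("keep_list variables violate the threshold: ", bp[1], " ~ ", bp[2])
    am <- abs(cm); diag(am) <- 0
    viol <- am > r_threshold
    if (!any(viol)) break
    involved <- rownames(am)[rowSums(viol) > 0]
    droppable <- setdiff(involved, keep_list)
    if (!length(droppable)) break  # protected pairs already checked above
    mean_r <- vapply(droppable, function(v) {
      others <- setdiff(involved, v)
      mean(am[v, others])
    }, numeric(1))
    drop_v <- droppable[which.max(mean_r)]
    keep <- setdiff(keep, drop_v)
  }
  keep
}

#' Principal component analysis of soil layers
#'
#' Standardizes each layer (centre, unit variance) over jointly valid cells,
#' decomposes, and keeps the smallest number of components whose cumulative
#' explained variance exceeds `pca_var_target`, emitting one raster per kept
#' component.
#'
#' @param soil_layers an [env_stack()] of soil variables (>= 2 layers).
#' @param pca_var_target cumulative explained-variance fraction (default 0.90).
#' @return list with `loadings` (variables x kept components), `explained`
#'   (all variance fractions, nonincreasing), `n_components_kept`, `center`,
#'   `scale`, and `pc_stack` (an [env_stack()] of PC rasters `PC1..PCk`).
#' @export
soil_pca <- function(soil_layers, pca_var_target = 0.90) {
  if (length(soil_layers$layers) < 2) stop("need at least two soil layers")
  if (pca_var_target <= 0 || pca_var_target >= 1) stop("pca_var_target must be in (0, 1)")
  vals <- stack_values(soil_layers)
  valid <- which(stats::complete.cases(vals))
  X <- vals[valid, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance soil layer(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) > pca_var_target)[1]
  template <- soil_layers$layers[[1]]
  pcs <- lapply(seq_len(k), function(i) grid_like(template, pc$x[, i], cells = valid))
  names(pcs) <- paste0("PC", seq_len(k))
  list(
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained = expl,
    n_components_kept = k,
    center = pc$center,
    scale = pc$scale,
    pc_stack = env_stack(pcs, scenario_id = soil_layers$scenario_id)
  )
}

#' Project soil layers of a new scenario onto fitted principal components
#'
#' Applies the centering, scaling and loadings from a [soil_pca()] fit to
#' another (co-registered) soil stack, so future scenarios use the same
#' component definitions as the current one.
#'
#' @param pca a [soil_pca()] result.
#' @param soil_layers an [env_stack()] with the same layer names as the fit.
#' @return an [env_stack()] of PC rasters.
#' @export
soil_pca_project <- function(pca, soil_layers) {
  vars <- rownames(pca$loadings)
  if (!all(vars %in% names(soil_layers$layers)))
    stop("soil stack is missing fitted variables")
  vals <- stack_values(soil_layers)[, vars, drop = FALSE]
  valid <- which(stats::complete.cases(vals))
  Z <- sweep(sweep(vals[valid, , drop = FALSE], 2, pca$center), 2, pca$scale, "/")
  scores <- Z %*% pca$loadings
  template <- soil_layers$layers[[1]]
  pcs <- lapply(seq_len(ncol(scores)), function(i) grid_like(template, scores[, i], cells = valid))
  names(pcs) <- colnames(pca$loadings)
  env_stack(pcs, scenario_id = soil_layers$scenario_id)
}

#' Average GCM realisations of a scenario
#'
#' Cellwise arithmetic mean per layer across co-registered stacks; any-NA
#' propagates to NA.
#'
#' @param gcm_stacks non-empty list of [env_stack()]s with identical layer
#'   names and grids.
#' @param scenario_id label for the averaged stack (default: first stack's).
#' @return an [env_stack()].
#' @export
average_gcms <- function(gcm_stacks, scenario_id = NULL) {
  if (length(gcm_stacks) == 0) stop("empty GCM list")
  nms <- names(gcm_stacks[[1]]$layers)
  for (s in gcm_stacks) {
    if (!identical(names(s$layers), nms)) stop("GCM stacks have mismatched layer names")
    stop_if_not_coregistered(gcm_stacks[[1]]$layers[[1]], s$layers[[1]], "GCM stacks")
  }
  layers <- lapply(nms, function(nm) {
    acc <- gcm_stacks[[1]]$layers[[nm]]$values
    if (length(gcm_stacks) > 1) {
      for (s in gcm_stacks[-1]) acc <- acc + s$layers[[nm]]$values
    }
    grid_like(gcm_stacks[[1]]$layers[[nm]], acc / length(gcm_stacks))
  })
  names(layers) <- nms
  env_stack(layers, scenario_id = scenario_id %||%
              sub("_gcm[0-9]+$", "", gcm_stacks[[1]]$scenario_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
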