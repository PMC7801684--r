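# Shared helpers for building tiny fixtures in code.

# small planar grid with given values (matrix or scalar fill)
tiny_grid <- function(values, nr = 10, nc = 10, dx = 1) {
  if (!is.matrix(values)) values <- matrix(values, nr, nc)
  raster_grid(values, x0 = 0, y0 = nrow(values) * dx, dx = dx, dy = dx,
              crs = "planar-km")
}

# stack of named constant/matrix layers on a shared grid
tiny_stack <- function(..., nr = 10, nc = 10, dx = 1, scenario_id = "current") {
  layers <- lapply(list(...), tiny_grid, nr = nr, nc = nc, dx = dx)
  env_stack(layers, scenario_id = scenario_id)
}

# independent oracle: penalized maxent objective at a given beta
maxent_objective_oracle <- function(beta, Fp, Fb, lambda) {
  eta_b <- as.vector(Fb %*% beta)
  -mean(as.vector(Fp %*% beta)) + log(sum(exp(eta_b))) + sum(lambda * abs(beta))
}

# independent oracle: size of the maximum subset with all pairwise distances
# >= thin_km, by exhaustive subset enumeration (n <= 12)
max_independent_set_size <- function(x, y, thin_km) {
  n <- length(x)
  stopifnot(n <= 12)
  d <- as.matrix(stats::dist(cbind(x, y)))
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    dd <- d[idx, idx, drop = FALSE]
    if (all(dd[upper.tri(dd)] >= thin_km)) best <- length(idx)
  }
  best
}

# independent oracle: maxSSS by direct scan over pooled unique scores
maxsss_oracle <- function(sp, sb) {
  cand <- sort(unique(c(sp, sb)))
  ss <- vapply(cand, function(tau) mean(sp >= tau) + mean(sb < tau), numeric(1))
  i <- which(ss >= max(ss) - 1e-15)[1]
  list(threshold = cand[i], tss = ss[i] - 1)
}

# independent oracle: AUC by exhaustive pairwise comparison
auc_oracle <- function(sp, sb) {
  cmp <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# temp file path helper
temp_path <- function(name) file.path(tempdir(), name)
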