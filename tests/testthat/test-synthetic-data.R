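test_that("generators are deterministic under seed and respond to seed changes", {
  a <- generate_env_stack(16, 16, n_bioclim = 2, n_soil = 2, seed = 3)
  b <- generate_env_stack(16, 16, n_bioclim = 2, n_soil = 2, seed = 3)
  c <- generate_env_stack(16, 16, n_bioclim = 2, n_soil = 2, seed = 4)
  expect_identical(stack_values(a$stack), stack_values(b$stack))
  expect_identical(a$dem$values, b$dem$values)
  expect_false(identical(stack_values(a$stack), stack_values(c$stack)))
  expect_error(generate_env_stack(8, 8), "16 x 16")
  expect_error(generate_env_stack(32, 32, cross_correlation = 1), "cross_correlation")
})

test_that("cross-correlation control: independent layers stay weak, rho=0.95 triggers pruning", {
  env0 <- generate_env_stack(64, 64, n_bioclim = 4, n_soil = 0,
                             cross_correlation = 0, seed = 11)
  cm0 <- abs(cor(stack_values(env0$stack)))
  diag(cm0) <- 0
  # bio1 carries the DEM lapse-rate component; exclude it from the independence check
  sub <- cm0[-1, -1]
  expect_lt(max(sub), 0.3)
  env1 <- generate_env_stack(64, 64, n_bioclim = 4, n_soil = 0,
                             cross_correlation = 0.95, seed = 11)
  cm1 <- cor(stack_values(env1$stack))
  expect_gt(abs(cm1["bio3", "bio4"]), 0.7)
  kept <- correlation_filter(env1$stack, 0.7)
  expect_length(setdiff(names(env1$stack$layers), kept), 1)
  expect_true(all(abs(cor(stack_values(env1$stack)[, kept]))[upper.tri(diag(length(kept)))] <= 0.7))
})

test_that("DEM is negatively correlated with the temperature-like layer", {
  env <- generate_env_stack(64, 64, n_bioclim = 3, n_soil = 0, seed = 5)
  r <- cor(as.vector(env$dem$values), as.vector(env$stack$layers$bio1$values))
  expect_lt(r, -0.4)
})

test_that("species truth: flat predictor, prevalence calibration, monotone scaling", {
  env <- generate_env_stack(32, 32, n_bioclim = 2, n_soil = 0, seed = 2)
  flat <- generate_species(env$stack, c(bio1 = 0), prevalence_target = 0.2)
  expect_true(all(abs(flat$prob$values - 0.2) < 1e-9))
  sp <- generate_species(env$stack, c(bio1 = 1.5), prevalence_target = 0.1)
  expect_lt(abs(mean(sp$prob$values) - 0.1), 1e-6)
  sp2 <- generate_species(env$stack, c(bio1 = 3), prevalence_target = 0.1)
  # doubling a positive coefficient preserves the cellwise probability ordering
  # (up to ties where the cloglog saturates)
  v2_sorted <- as.vector(sp2$prob$values)[order(sp$prob$values)]
  expect_true(all(diff(v2_sorted) >= -1e-12))
  expect_error(generate_species(env$stack, c(nope = 1)), "absent layers")
})

test_that("occurrence sampling: exhaustive draws, support restriction, frequency calibration", {
  g <- tiny_grid(1, nr = 10, nc = 10)
  occ <- sample_occurrences(g, 100, seed = 1)
  cells <- cell_from_xy(g, occ$x, occ$y)
  expect_setequal(cells, 1:100)  # uniform truth, n = cells: every cell once
  bias <- tiny_grid(0, nr = 10, nc = 10)
  bias$values[1:5, 1:5] <- 1
  occ_b <- sample_occurrences(g, 20, sampling_bias = bias, seed = 2)
  expect_true(all(occ_b$x <= 5 & occ_b$y >= 5))
  expect_error(sample_occurrences(g, 101), "exceeds")
  # with-replacement frequencies within 3 s.e. on a 2-cell grid
  g2 <- raster_grid(matrix(c(0.8, 0.2), 2, 1), x0 = 0, y0 = 2)
  occ2 <- sample_occurrences(g2, 10000, seed = 3, replace = TRUE)
  f1 <- mean(cell_from_xy(g2, occ2$x, occ2$y) == 1)
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(f1 - 0.8), 3 * se)
})

test_that("land cover and protected areas: class counts, fractions, reclass table", {
  env <- generate_env_stack(128, 128, n_bioclim = 2, n_soil = 0, seed = 9)
  lp <- generate_landcover_and_pa(env$stack, n_classes = 22,
                                  anthropogenic_fraction = 0.6,
                                  pa_fraction = 0.15, seed = 1,
                                  n_unsuitable = 17)
  expect_equal(sum(lp$reclass$suitable == 0), 17)
  expect_equal(nrow(lp$reclass), 22)
  expect_setequal(unique(as.vector(lp$landcover$values)), 1:22)
  pa_share <- mean(lp$pa_mask$values)
  expect_lt(abs(pa_share - 0.15), 0.03)
  # anthropogenic_fraction = 0: no unsuitable classes, LCC is the identity
  lp0 <- generate_landcover_and_pa(env$stack, n_classes = 5,
                                   anthropogenic_fraction = 0, seed = 2)
  expect_equal(sum(lp0$reclass$suitable == 0), 0)
  bin <- binarize(env$stack$layers$bio1, 0, species = "s")
  expect_equal(apply_lcc(bin, landcover_map(lp0$landcover, lp0$reclass))$grid$values,
               bin$grid$values)
})

test_that("future scenarios: noiseless limit, construction shift, CLT averaging", {
  env <- generate_env_stack(32, 32, n_bioclim = 2, n_soil = 0, seed = 4)
  off <- scenario_offsets(shift = c(bio1 = 2))
  g0 <- generate_future(env$stack, off, n_gcms = 3, gcm_noise_sd = 0, seed = 1)
  for (s in g0) {
    expect_equal(s$layers$bio1$values, env$stack$layers$bio1$values + 2)
    expect_equal(s$layers$bio2$values, env$stack$layers$bio2$values)
  }
  sd_n <- 0.3
  g5 <- generate_future(env$stack, off, n_gcms = 5, gcm_noise_sd = sd_n, seed = 2)
  avg <- average_gcms(g5)
  resid <- avg$layers$bio1$values - (env$stack$layers$bio1$values + 2)
  rms <- sqrt(mean(resid^2))
  expect_lt(rms, 2 * sd_n / sqrt(5))
  expect_gt(rms, 0.2 * sd_n / sqrt(5))
  expect_lt(abs(mean(avg$layers$bio1$values - env$stack$layers$bio1$values) - 2), 0.2)
  expect_error(generate_future(env$stack, off, n_gcms = 0), "n_gcms")
  expect_error(scenario_offsets(scale = c(bio1 = -1)), "positive")
})
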