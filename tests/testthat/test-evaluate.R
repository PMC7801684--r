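test_that("partitions: symmetric quadrants, jackknife switch, count equalization", {
  occ8 <- occurrence_set("s", x = c(1, 1, 1, 1, 9, 9, 9, 9),
                         y = c(1, 1.5, 9, 9.5, 1, 1.5, 9, 9.5))
  bg <- data.frame(x = runif(50, 0, 10), y = runif(50, 0, 10))
  p <- make_partitions(occ8, bg, threshold_n = 4)
  expect_equal(p$kind, "block4")
  expect_equal(unname(table(p$pres_fold)), rep(2L, 4), ignore_attr = TRUE)
  # background inherits the presence boundaries
  expect_equal(p$bg_fold[bg$x <= 5 & bg$y <= 5][1],
               p$pres_fold[occ8$x == 1 & occ8$y == 1][1])
  # n = 25: jackknife with 25 folds; n = 27: block bins {7,7,7,6}
  occ25 <- occurrence_set("s", runif(25), runif(25))
  p25 <- make_partitions(occ25, bg)
  expect_equal(p25$kind, "jackknife")
  expect_equal(p25$n_folds, 25)
  set.seed(1)
  occ27 <- occurrence_set("s", runif(27), runif(27))
  p27 <- make_partitions(occ27, bg)
  expect_equal(p27$kind, "block4")
  expect_equal(sort(as.integer(table(p27$pres_fold)), decreasing = TRUE),
               c(7L, 7L, 7L, 6L))
})

test_that("AUC: exact pairwise fraction, boundary cases, complement symmetry", {
  expect_equal(auc_pb(c(5, 6), c(1, 2)), 1.0)
  expect_equal(auc_pb(rep(1, 3), rep(1, 5)), 0.5)
  expect_equal(auc_pb(c(0.9, 0.4), c(0.5, 0.1, 0.3)), 5 / 6)
  set.seed(2)
  for (i in 1:20) {
    sp <- runif(7); sb <- runif(11)
    expect_equal(auc_pb(sp, sb), auc_oracle(sp, sb))
    expect_equal(auc_pb(sp, sb) + auc_pb(sb, sp), 1)
  }
  expect_error(auc_pb(numeric(0), 1), "empty")
})

test_that("omission rate at LPT uses a strict threshold", {
  tr <- c(0.2, 0.5, 0.9)
  expect_equal(omission_rate(tr, tr), 0)          # self-consistency
  expect_equal(omission_rate(tr, c(0.1, 0.3, 0.5)), 1 / 3)
  expect_equal(omission_rate(tr, c(0.2, 0.9)), 0) # at the threshold counts in
  expect_equal(omission_rate(tr, c(0.5), threshold = 0.6), 1)
  expect_error(omission_rate(numeric(0), 1), "empty")
})

test_that("maxSSS equals the exhaustive threshold scan", {
  r <- maxsss(c(0.8, 0.6), c(0.7, 0.2, 0.1))
  expect_equal(r$threshold, 0.6)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 2 / 3)
  expect_equal(r$tss, 2 / 3, tolerance = 1e-12)
  expect_equal(maxsss(c(5, 6), c(1, 2))$tss, 1)       # perfect separation
  expect_equal(maxsss(c(1, 2, 3), c(1, 2, 3))$tss, 0) # identical distributions
  set.seed(3)
  for (i in 1:20) {
    sp <- round(runif(9), 2); sb <- round(runif(13), 2)
    got <- maxsss(sp, sb)
    want <- maxsss_oracle(sp, sb)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$tss, want$tss)
  }
})

test_that("default tuning grids compose the study's 95 candidates", {
  rm <- default_rm_grid()
  expect_length(rm, 19)
  expect_true(all(diff(rm) > 0))
  expect_equal(rm[1], 0.75^8)
  expect_true(all(seq(1, 6, 0.5) %in% rm))
  expect_length(default_fc_menu(), 5)
  expect_equal(length(rm) * length(default_fc_menu()), 95)
})

test_that("model gates reject on any violated criterion with reasons", {
  ok <- list(auc = 0.91, tss = 0.69, or_maxsss = 0.13)  # accepted-model averages
  expect_true(gate_model(ok)$accept)
  bad_auc <- list(auc = 0.74, tss = 0.69, or_maxsss = 0.13)
  g <- gate_model(bad_auc)
  expect_false(g$accept)
  expect_length(g$reasons, 1)
  expect_match(g$reasons, "AUC")
  # boundaries are inclusive: exactly 0.75 / 0.45 / 0.25 pass
  edge <- list(auc = 0.75, tss = 0.45, or_maxsss = 0.25)
  expect_true(gate_model(edge)$accept)
  all_bad <- list(auc = 0.5, tss = 0.1, or_maxsss = 0.9)
  expect_length(gate_model(all_bad)$reasons, 3)
})

test_that("tuning selects min-OR with AUC tie-break on a small instance", {
  sim <- generate_env_stack(40, 40, n_bioclim = 2, n_soil = 0, seed = 21, dx = 2)
  sp <- generate_species(sim$stack, c(bio1 = -1, bio2 = 2),
                         coef_quad = c(bio2 = -2), prevalence_target = 0.2)
  occ <- sample_occurrences(sp$prob, 60, seed = 22)
  bg <- sample_background(occ, sim$stack$layers[[1]], buffer_km = 60,
                          exclusion_km = 2, n_points = 400, seed = 23)
  part <- make_partitions(occ, bg)
  expect_equal(part$kind, "block4")
  tun <- suppressWarnings(tune_model(occ, bg, sim$stack, part,
                                     rm_grid = c(0.5, 1, 2),
                                     fc_menu = c("L", "LQ"),
                                     n_hinge_knots = 4, max_iterations = 100,
                                     convergence_tol = 1e-3))
  expect_equal(nrow(tun$grid), 6)
  sel <- tun$grid[tun$selected, ]
  expect_equal(sel$mean_or, min(tun$grid$mean_or, na.rm = TRUE))
  ties <- tun$grid[abs(tun$grid$mean_or - sel$mean_or) < 1e-12, ]
  expect_equal(sel$mean_auc, max(ties$mean_auc))
  expect_s3_class(tun$model, "maxent_model")
  rep <- suppressWarnings(evaluate_model(occ, bg, sim$stack, part, tun$config))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$or_maxsss >= 0 && rep$or_maxsss <= 1)
  expect_true(rep$tss >= -1 && rep$tss <= 1)
  expect_true(rep$maxsss_threshold >= 0 && rep$maxsss_threshold <= 1)
})
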