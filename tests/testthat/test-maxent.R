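test_that("feature expansion counts and hinge endpoint values", {
  bg2 <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  F_lq <- evaluate_features(build_features(bg2, "LQ"), bg2)
  expect_equal(ncol(F_lq), 4)  # 2 L + 2 Q
  bg3 <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  F_all <- evaluate_features(build_features(bg3, "LQPH", n_hinge_knots = 10), bg3)
  expect_equal(ncol(F_all), 3 + 3 + 3 + 3 * 2 * 10)  # 69
  expect_true(all(F_all >= 0 & F_all <= 1))
  # forward hinge: 0 at its knot, 1 at the covariate maximum
  exp1 <- build_features(matrix(seq(0, 1, length.out = 11), ncol = 1,
                                dimnames = list(NULL, "x")), "H", 3)
  k <- exp1$knots[2]
  Fh <- evaluate_features(exp1, matrix(c(k, 1), ncol = 1, dimnames = list(NULL, "x")))
  fwd <- grep("^hf_x_0\\.5", colnames(Fh))
  expect_equal(Fh[1, fwd], 0, ignore_attr = TRUE)
  expect_equal(Fh[2, fwd], 1, ignore_attr = TRUE)
  expect_warning(build_features(cbind(a = rep(1, 10), b = runif(10)), "L"),
                 "constant")
})

test_that("total shrinkage gives the exact uniform distribution", {
  set.seed(1)
  pres <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_maxent(pres, bg, maxent_config("LQ", reg_multiplier = 1e6))
  expect_true(all(m$beta == 0))
  raw <- predict(m, bg, output = "raw")
  expect_equal(raw, rep(1 / 20, 20))
  cl <- predict(m, bg, output = "cloglog")
  expect_equal(length(unique(cl)), 1)  # flat model: constant cloglog output
})

test_that("one-feature fit matches a golden-section oracle", {
  # 6 background cells, 3 presences, linear feature, tiny penalty
  bgx <- matrix(seq(0, 1, length.out = 6), ncol = 1, dimnames = list(NULL, "x"))
  prx <- matrix(c(0.8, 0.9, 1.0), ncol = 1, dimnames = list(NULL, "x"))
  cfg <- maxent_config("L", reg_multiplier = 0.01, convergence_tol = 1e-9,
                       max_iterations = 2000)
  m <- fit_maxent(prx, bgx, cfg)
  Fb <- evaluate_features(m$expansion, bgx)[, names(m$beta), drop = FALSE]
  Fp <- evaluate_features(m$expansion, prx)[, names(m$beta), drop = FALSE]
  obj1 <- function(b) maxent_objective_oracle(b, Fp, Fb, m$lambda)
  oracle <- optimize(obj1, c(-50, 50), tol = 1e-10)
  expect_lt(abs(m$beta - oracle$minimum), 1e-4)
  expect_lt(abs(m$objective - oracle$objective), 1e-8)
})

test_that("score sign: a feature enriched at presences gets a positive weight", {
  set.seed(2)
  bg <- matrix(runif(60, 0, 1), 60, 1, dimnames = list(NULL, "x"))
  pres <- matrix(rep(1, 10), ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_maxent(pres, bg, maxent_config("L", 0.5))
  expect_gt(m$beta[["l_x"]], 0)
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  set.seed(3)
  pres <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  objs <- vapply(c(1, 2, 3, 5, 10, 25), function(k) {
    suppressWarnings(fit_maxent(pres, bg, maxent_config(
      "LQ", 0.1, max_iterations = k, convergence_tol = 1e-12)))$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("a separable problem with a vanishing penalty hits the iteration cap", {
  # presences strictly above all background: no finite optimum without penalty
  bg <- matrix(seq(0, 0.5, length.out = 8), ncol = 1, dimnames = list(NULL, "x"))
  pres <- matrix(c(0.9, 0.95, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_warning(
    m <- fit_maxent(pres, bg, maxent_config("L", reg_multiplier = 1e-9,
                                            max_iterations = 50)),
    "did not converge")
  expect_false(m$converged)
  expect_gt(abs(m$beta[["l_x"]]), 3)  # keeps growing toward the cap
})

test_that("raw predictions normalize over the training background and clamp novel values", {
  set.seed(4)
  pres <- matrix(runif(16, 0.4, 1), 8, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  m <- suppressWarnings(fit_maxent(pres, bg, maxent_config("LQH", 0.5)))
  expect_lt(abs(sum(predict(m, bg, output = "raw")) - 1), 1e-9)
  # clamping: predictions outside the training range equal the boundary value
  inside <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("a", "b")))
  outside <- matrix(c(5, 7), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, outside), predict(m, pmin(inside, apply(bg, 2, max))))
  expect_error(predict(m, tiny_stack(a = 1)), "missing covariate")
})

test_that("stack prediction recovers a known suitability ranking", {
  sim <- generate_env_stack(48, 48, n_bioclim = 2, n_soil = 0, seed = 6, dx = 2)
  sp <- generate_species(sim$stack, c(bio2 = 2), coef_quad = c(bio2 = -2),
                         prevalence_target = 0.15)
  occ <- sample_occurrences(sp$prob, 150, seed = 7)
  bg <- sample_background(occ, sim$stack$layers[[1]], buffer_km = 120,
                          exclusion_km = 0.5, n_points = 800, seed = 8)
  m <- suppressWarnings(fit_maxent(
    stack_extract(sim$stack, occ$x, occ$y),
    stack_values(sim$stack, bg$cell),
    maxent_config("LQ", 1, max_iterations = 300)))
  pred <- predict(m, sim$stack)
  rho <- cor(as.vector(pred$values), as.vector(sp$prob$values),
             method = "spearman")
  expect_gt(rho, 0.8)
})
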