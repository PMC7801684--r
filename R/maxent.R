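#' @useDynLib dipterocarpSDM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MaxEnt model configuration
#'
#' @param feature_classes one of `"L"`, `"LQ"`, `"H"`, `"LQH"`, `"LQPH"`
#'   (linear, quadratic, product, hinge).
#' @param reg_multiplier positive regularization multiplier (rm); larger
#'   values shrink more coefficients to zero.
#' @param n_hinge_knots interior hinge knots per covariate (default 10).
#' @param max_iterations coordinate-descent sweep cap.
#' @param convergence_tol stop when the largest coefficient change in a sweep
#'   falls below this.
#' @return an object of class `maxent_config`.
#' @export
maxent_config <- function(feature_classes = "LQPH", reg_multiplier = 1,
                          n_hinge_knots = 10, max_iterations = 500,
                          convergence_tol = 1e-5) {
  feature_classes <- match.arg(feature_classes, c("L", "LQ", "H", "LQH", "LQPH"))
  if (reg_multiplier <= 0) stop("reg_multiplier must be positive")
  structure(list(feature_classes = feature_classes,
                 reg_multiplier = reg_multiplier,
                 n_hinge_knots = n_hinge_knots,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "maxent_config")
}

#' Build a feature expansion from background covariates
#'
#' Covariates are rescaled to `[0, 1]` using their background minimum/maximum;
#' features are then: L — the rescaled covariate; Q — its square; P — pairwise
#' products; H — forward and reverse hinges
#' `max(0, (u - k) / (1 - k))` and `max(0, (k - u) / k)` at `n_hinge_knots`
#' equally spaced interior knots. All features lie in `[0, 1]` over the
#' background. Constant covariates are dropped with a warning.
#'
#' @param background matrix/data.frame of background covariate values (used
#'   for the rescaling bounds and knot placement).
#' @param feature_classes feature-class menu entry (see [maxent_config()]).
#' @param n_hinge_knots interior knots per covariate.
#' @return an object of class `feature_expansion`.
#' @export
build_features <- function(background, feature_classes = "LQPH", n_hinge_knots = 10) {
  feature_classes <- match.arg(feature_classes, c("L", "LQ", "H", "LQH", "LQPH"))
  X <- as.matrix(background)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  rng <- apply(X, 2, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    rng <- rng[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant covariates left")
  knots <- if (n_hinge_knots > 0) seq_len(n_hinge_knots) / (n_hinge_knots + 1) else numeric(0)
  structure(list(
    feature_classes = feature_classes,
    cov_names = colnames(X),
    cov_min = rng[1, ],
    cov_max = rng[2, ],
    knots = knots
  ), class = "feature_expansion")
}

# Evaluate the design matrix of an expansion at covariate values.
# Clamping restricts covariates to the training (background) range before
# feature evaluation, the standard MaxEnt treatment of novel conditions.
evaluate_features <- function(expansion, newdata, clamp = TRUE) {
  X <- as.matrix(newdata)[, expansion$cov_names, drop = FALSE]
  U <- sweep(sweep(X, 2, expansion$cov_min), 2,
             expansion$cov_max - expansion$cov_min, "/")
  if (clamp) U <- pmin(pmax(U, 0), 1)
  fc <- expansion$feature_classes
  p <- ncol(U)
  cols <- list()
  nms <- character(0)
  has <- function(ch) grepl(ch, fc)
  if (has("L")) {
    cols <- c(cols, lapply(seq_len(p), function(j) U[, j]))
    nms <- c(nms, paste0("l_", expansion$cov_names))
  }
  if (has("Q")) {
    cols <- c(cols, lapply(seq_len(p), function(j) U[, j]^2))
    nms <- c(nms, paste0("q_", expansion$cov_names))
  }
  if (has("P") && p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in seq((i + 1), p)) {
        cols <- c(cols, list(U[, i] * U[, j]))
        nms <- c(nms, paste0("p_", expansion$cov_names[i], ":", expansion$cov_names[j]))
      }
    }
  }
  if (has("H")) {
    for (j in seq_len(p)) {
      for (k in expansion$knots) {
        cols <- c(cols, list(pmax(0, (U[, j] - k) / (1 - k))))
        nms <- c(nms, sprintf("hf_%s_%.4f", expansion$cov_names[j], k))
      }
      for (k in expansion$knots) {
        cols <- c(cols, list(pmax(0, (k - U[, j]) / k)))
        nms <- c(nms, sprintf("hr_%s_%.4f", expansion$cov_names[j], k))
      }
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nms
  F
}

# feature class of each feature name, for the default regularization table
feature_reg_class <- function(feature_names) {
  cls <- rep("linear", length(feature_names))
  cls[startsWith(feature_names, "q_")] <- "quadratic"
  cls[startsWith(feature_names, "p_")] <- "product"
  cls[startsWith(feature_names, "hf_") | startsWith(feature_names, "hr_")] <- "hinge"
  cls
}

.reg_table_env <- new.env(parent = emptyenv())

#' Default per-class regularization scalars
#'
#' The published MaxEnt default tables: a per-feature-class scalar
#' interpolated linearly in the presence sample size (constant beyond the
#' table ends). Shipped as a CSV under `extdata` so it can be inspected or
#' overridden.
#'
#' @param class feature class: `"linear"`, `"quadratic"`, `"product"`,
#'   `"hinge"` (vectorized).
#' @param n_presence presence sample size.
#' @return numeric scalar(s).
#' @export
default_reg_scalar <- function(class, n_presence) {
  if (is.null(.reg_table_env$tab)) {
    path <- system.file("extdata", "maxent_default_regularization.csv",
                        package = "dipterocarpSDM")
    .reg_table_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .reg_table_env$tab
  vapply(class, function(cl) {
    sub <- tab[tab$class == cl, ]
    if (!nrow(sub)) stop("unknown feature class: ", cl)
    stats::approx(sub$n, sub$s, xout = n_presence, rule = 2)$y
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fit a lasso-penalized maximum-entropy presence-background model
#'
#' Minimizes the regularized Gibbs/point-process objective
#' \deqn{-\frac{1}{n_p}\sum_{pres}\eta(x) + \log\sum_{bg} e^{\eta(x)}
#'   + \sum_j \lambda_j |\beta_j|, \qquad \eta = \sum_j \beta_j f_j(x)}
#' by cyclic coordinate descent with soft-thresholding (each step backtracked
#' so the objective never increases). Per-feature penalties are
#' \eqn{\lambda_j = rm \cdot s(\mathrm{class}, n_p) \cdot
#' \mathrm{sd}(f_j)/\sqrt{n_p}} with the default class scalars of
#' [default_reg_scalar()] and the feature standard deviation taken over the
#' background. Features with zero background variance are dropped before
#' fitting.
#'
#' @param presence matrix/data.frame of covariates at presence points (>= 2).
#' @param background matrix/data.frame of covariates at background points
#'   (more rows than `presence`).
#' @param config a [maxent_config()].
#' @return an object of class `maxent_model` with elements `expansion`,
#'   `beta` (named, over kept features), `alpha` (log-normalizer so raw
#'   predictions sum to 1 over the training background), `entropy_H` (entropy
#'   of the fitted raw distribution), `config`, `lambda`, `converged`,
#'   `iterations`, `objective`.
#' @export
fit_maxent <- function(presence, background, config = maxent_config()) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  if (nrow(presence) < 2) stop("need at least 2 presence points")
  if (nrow(background) <= nrow(presence))
    stop("background must be larger than the presence set")
  expansion <- build_features(background, config$feature_classes, config$n_hinge_knots)
  Fb <- evaluate_features(expansion, background, clamp = FALSE)
  Fp <- evaluate_features(expansion, presence, clamp = TRUE)
  sdb <- apply(Fb, 2, stats::sd)
  keep <- sdb > 0
  Fb <- Fb[, keep, drop = FALSE]
  Fp <- Fp[, keep, drop = FALSE]
  sdb <- sdb[keep]
  if (ncol(Fb) == 0) stop("all features have zero background variance")
  np <- nrow(Fp)
  s_cls <- default_reg_scalar(feature_reg_class(colnames(Fb)), np)
  lambda <- config$reg_multiplier * s_cls * sdb / sqrt(np)
  fit <- maxent_cd(Fp, Fb, lambda, config$convergence_tol, config$max_iterations)
  if (!fit$converged)
    warning("coordinate descent did not converge in ", config$max_iterations, " sweeps")
  beta <- stats::setNames(fit$beta, colnames(Fb))
  eta_b <- as.vector(Fb %*% beta)
  raw <- exp(eta_b + fit$alpha)
  H <- -sum(raw * log(pmax(raw, 1e-300)))
  structure(list(
    expansion = expansion,
    beta = beta,
    alpha = fit$alpha,
    entropy_H = H,
    config = config,
    lambda = stats::setNames(lambda, colnames(Fb)),
    converged = fit$converged,
    iterations = fit$iterations,
    objective = fit$objective,
    n_presence = np,
    n_background = nrow(Fb)
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %s, rm = %g: %d/%d nonzero features, entropy %.3f%s\n",
              x$config$feature_classes, x$config$reg_multiplier,
              sum(x$beta != 0), length(x$beta), x$entropy_H,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Linear predictor + raw/cloglog scores for a covariate matrix.
maxent_scores <- function(model, newdata, output = c("cloglog", "raw")) {
  output <- match.arg(output)
  F <- evaluate_features(model$expansion, newdata, clamp = TRUE)
  F <- F[, names(model$beta), drop = FALSE]
  raw <- exp(as.vector(F %*% model$beta) + model$alpha)
  if (output == "raw") return(raw)
  pmin(pmax(1 - exp(-exp(model$entropy_H) * raw), 0), 1)
}

#' Predict habitat suitability
#'
#' Projects a fitted model onto an environmental stack (returning a raster) or
#' a covariate matrix (returning a vector). `raw` output is the Gibbs
#' probability over the training background (sums to 1 on the training
#' background); `cloglog` is the standard bounded suitability transform
#' \eqn{1 - \exp(-e^{H} \cdot raw)}. Covariate values outside the training
#' range are clamped to the range bounds before feature evaluation.
#'
#' @param object a [fit_maxent()] model.
#' @param newdata an [env_stack()] containing every fitted covariate, or a
#'   matrix/data.frame of covariates.
#' @param output `"cloglog"` (default) or `"raw"`.
#' @param ... unused.
#' @return a [raster_grid()] for stack input, else a numeric vector.
#' @export
predict.maxent_model <- function(object, newdata, output = c("cloglog", "raw"), ...) {
  output <- match.arg(output)
  if (inherits(newdata, "env_stack")) {
    missing <- setdiff(object$expansion$cov_names, names(newdata$layers))
    if (length(missing))
      stop("stack is missing covariate layer(s): ", paste(missing, collapse = ", "))
    vals <- stack_values(newdata)[, object$expansion$cov_names, drop = FALSE]
    valid <- which(stats::complete.cases(vals))
    scores <- maxent_scores(object, vals[valid, , drop = FALSE], output)
    return(grid_like(newdata$layers[[1]], scores, cells = valid))
  }
  maxent_scores(object, newdata, output)
}
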