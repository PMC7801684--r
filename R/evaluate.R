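#' Spatial partitions for cross-validation
#'
#' Species with more than `threshold_n` presences get 'block' partitioning:
#' presences are split at their median x, then each half at its own median y,
#' giving four geographic bins with counts differing by at most one (ties
#' broken by index); background points inherit the same boundaries. Smaller
#' samples get jackknife folds (one held-out presence per fold, full
#' background in every fold).
#'
#' @param occ an [occurrence_set()] (>= 2 presences).
#' @param background data.frame/matrix with background `x`, `y`.
#' @param threshold_n block/jackknife switch (default 25: block iff n > 25).
#' @return list with `kind` (`"block4"` or `"jackknife"`), `n_folds`,
#'   `pres_fold` (fold id per presence) and `bg_fold` (fold id per background
#'   point; `NA` for jackknife, meaning every fold uses the full background).
#' @export
make_partitions <- function(occ, background, threshold_n = 25) {
  n <- length(occ$x)
  if (n < 2) stop("need at least 2 presences")
  if (n <= threshold_n) {
    return(list(kind = "jackknife", n_folds = n,
                pres_fold = seq_len(n),
                bg_fold = rep(NA_integer_, nrow(as.matrix(background)))))
  }
  bg <- as.matrix(background)
  # split presences at the median x (count-equalized, ties by index)
  ord_x <- order(occ$x, seq_len(n))
  n_left <- ceiling(n / 2)
  left <- ord_x[seq_len(n_left)]
  right <- ord_x[-seq_len(n_left)]
  x_cut <- (max(occ$x[left]) + min(occ$x[right])) / 2
  split_y <- function(idx) {
    m <- length(idx)
    ord_y <- idx[order(occ$y[idx], idx)]
    m_low <- ceiling(m / 2)
    low <- ord_y[seq_len(m_low)]
    high <- ord_y[-seq_len(m_low)]
    list(low = low, high = high,
         y_cut = (max(occ$y[low]) + min(occ$y[high])) / 2)
  }
  L <- split_y(left); R <- split_y(right)
  pres_fold <- integer(n)
  pres_fold[L$low] <- 1L; pres_fold[L$high] <- 2L
  pres_fold[R$low] <- 3L; pres_fold[R$high] <- 4L
  bg_left <- bg[, 1] <= x_cut
  bg_fold <- ifelse(bg_left,
                    ifelse(bg[, 2] <= L$y_cut, 1L, 2L),
                    ifelse(bg[, 2] <= R$y_cut, 3L, 4L))
  list(kind = "block4", n_folds = 4L, pres_fold = pres_fold,
       bg_fold = as.integer(bg_fold))
}

#' Presence-background AUC (Mann-Whitney form)
#'
#' Fraction of (presence, background) score pairs where the presence scores
#' higher, ties counted one half.
#'
#' @param presence_scores,background_scores numeric score vectors (nonempty).
#' @return AUC in `[0, 1]`.
#' @export
auc_pb <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("empty score vector")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Omission rate at the lowest presence threshold (or a given threshold)
#'
#' LPT (lowest presence threshold, a.k.a. minimum training presence) is the
#' smallest predicted value at any training presence. The omission rate is the
#' fraction of evaluation presences scoring strictly below the threshold, so
#' training omission at LPT is exactly zero.
#'
#' @param train_presence_scores training presence scores (nonempty; sets LPT).
#' @param test_presence_scores evaluation presence scores (nonempty).
#' @param threshold optional explicit threshold (e.g. maxSSS) replacing LPT.
#' @return omission rate in `[0, 1]`.
#' @export
omission_rate <- function(train_presence_scores, test_presence_scores,
                          threshold = NULL) {
  if (length(train_presence_scores) == 0) stop("empty training scores")
  if (length(test_presence_scores) == 0) stop("empty test scores")
  thr <- threshold %||% min(train_presence_scores)
  mean(test_presence_scores < thr)
}

#' maxSSS threshold and True Skill Statistic
#'
#' Scans all unique pooled scores as candidate thresholds; sensitivity is the
#' fraction of presences at or above the threshold, specificity the fraction
#' of background strictly below it. Returns the threshold maximizing
#' sensitivity + specificity (smallest such threshold on ties).
#'
#' @param presence_scores,background_scores numeric score vectors (nonempty).
#' @return list with `threshold`, `tss`, `sensitivity`, `specificity`.
#' @export
maxsss <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0)
    stop("empty score vector")
  cand <- sort(unique(c(presence_scores, background_scores)))
  best <- NULL
  for (tau in cand) {
    sens <- mean(presence_scores >= tau)
    spec <- mean(background_scores < tau)
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity + 1e-15) {
      best <- list(threshold = tau, tss = sens + spec - 1,
                   sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' The 19-value default regularization-multiplier grid
#'
#' A ratio-0.75 geometric progression of eight values below 1 plus 0.5-step
#' increments from the default 1 to 6, in ascending order.
#' @return numeric vector of length 19.
#' @export
default_rm_grid <- function() {
  sort(c(0.75^(8:1), seq(1, 6, by = 0.5)))
}

#' The five-entry default feature-class menu
#' @return character vector.
#' @export
default_fc_menu <- function() c("L", "LQ", "H", "LQH", "LQPH")

# Cross-validate one configuration: returns mean held-out OR (LPT rule) and
# mean held-out AUC over folds (fold-local background for block partitions).
cv_candidate <- function(pres_cov, bg_cov, partition, config) {
  ors <- aucs <- numeric(0)
  for (f in seq_len(partition$n_folds)) {
    p_test <- partition$pres_fold == f
    if (partition$kind == "block4") {
      b_test <- partition$bg_fold == f
      b_train <- !b_test
    } else {
      b_test <- rep(TRUE, nrow(bg_cov))
      b_train <- rep(TRUE, nrow(bg_cov))
    }
    if (sum(!p_test) < 2 || sum(b_train) <= sum(!p_test) || sum(p_test) == 0 ||
        sum(b_test) == 0) next
    model <- suppressWarnings(fit_maxent(pres_cov[!p_test, , drop = FALSE],
                        bg_cov[b_train, , drop = FALSE], config))
    s_train_p <- maxent_scores(model, pres_cov[!p_test, , drop = FALSE])
    s_test_p <- maxent_scores(model, pres_cov[p_test, , drop = FALSE])
    s_test_b <- maxent_scores(model, bg_cov[b_test, , drop = FALSE])
    ors <- c(ors, omission_rate(s_train_p, s_test_p))
    aucs <- c(aucs, auc_pb(s_test_p, s_test_b))
  }
  c(or = mean(ors), auc = mean(aucs))
}

#' Tune feature class and regularization multiplier
#'
#' Cross-validates every (feature class, rm) candidate on the given partition,
#' scoring held-out omission rate (LPT rule) and AUC, then selects the
#' candidate with the lowest mean omission rate — ties broken by the highest
#' mean AUC — and refits it on all presences and the full background. The
#' default grids give the study's 95 candidates.
#'
#' @param occ an [occurrence_set()].
#' @param background data.frame with background `x`, `y` (as from
#'   [sample_background()]).
#' @param stack covariate [env_stack()].
#' @param partition a [make_partitions()] result (built from `occ` and
#'   `background`).
#' @param rm_grid regularization multipliers (default [default_rm_grid()]).
#' @param fc_menu feature-class menu (default [default_fc_menu()]).
#' @param n_hinge_knots,max_iterations,convergence_tol passed to
#'   [maxent_config()].
#' @return list with `grid` (one row per candidate: `feature_classes`, `rm`,
#'   `mean_or`, `mean_auc`), `selected` (row index), `model` (final refit),
#'   `config`.
#' @export
tune_model <- function(occ, background, stack, partition,
                       rm_grid = default_rm_grid(),
                       fc_menu = default_fc_menu(),
                       n_hinge_knots = 10, max_iterations = 500,
                       convergence_tol = 1e-5) {
  if (!length(rm_grid) || !length(fc_menu)) stop("empty tuning grid")
  pres_cov <- stack_extract(stack, occ$x, occ$y)
  ok_p <- stats::complete.cases(pres_cov)
  pres_cov <- pres_cov[ok_p, , drop = FALSE]
  bg_cov <- stack_extract(stack, background$x, background$y)
  grid <- expand.grid(feature_classes = fc_menu, rm = rm_grid,
                      stringsAsFactors = FALSE)
  grid$mean_or <- NA_real_
  grid$mean_auc <- NA_real_
  part <- partition
  if (any(!ok_p)) {
    part$pres_fold <- partition$pres_fold[ok_p]
    if (part$kind == "jackknife") part$n_folds <- sum(ok_p)
  }
  for (i in seq_len(nrow(grid))) {
    cfg <- maxent_config(grid$feature_classes[i], grid$rm[i], n_hinge_knots,
                         max_iterations, convergence_tol)
    sc <- cv_candidate(pres_cov, bg_cov, part, cfg)
    grid$mean_or[i] <- sc[["or"]]
    grid$mean_auc[i] <- sc[["auc"]]
  }
  if (all(is.na(grid$mean_or))) stop("no candidate could be evaluated")
  best_or <- min(grid$mean_or, na.rm = TRUE)
  cand <- which(grid$mean_or <= best_or + 1e-12)
  sel <- cand[which.max(grid$mean_auc[cand])]
  final_cfg <- maxent_config(grid$feature_classes[sel], grid$rm[sel],
                             n_hinge_knots, max_iterations, convergence_tol)
  model <- fit_maxent(pres_cov, bg_cov, final_cfg)
  list(grid = grid, selected = sel, model = model, config = final_cfg)
}

#' Cross-validated evaluation report for a configuration
#'
#' Pools held-out presence/background predictions across folds and reports
#' AUC, omission at LPT, the maxSSS threshold, omission at maxSSS and TSS —
#' the quantities gated by [gate_model()].
#'
#' @param occ an [occurrence_set()].
#' @param background background points data.frame (`x`, `y`).
#' @param stack covariate [env_stack()].
#' @param partition a [make_partitions()] result.
#' @param config a [maxent_config()].
#' @return list (`eval_report`): `auc`, `or_lpt`, `or_maxsss`, `tss`,
#'   `maxsss_threshold`, `sensitivity`, `specificity`.
#' @export
evaluate_model <- function(occ, background, stack, partition, config) {
  pres_cov <- stack_extract(stack, occ$x, occ$y)
  ok_p <- stats::complete.cases(pres_cov)
  pres_cov <- pres_cov[ok_p, , drop = FALSE]
  bg_cov <- stack_extract(stack, background$x, background$y)
  part <- partition
  if (any(!ok_p)) {
    part$pres_fold <- partition$pres_fold[ok_p]
    if (part$kind == "jackknife") part$n_folds <- sum(ok_p)
  }
  sp <- sb <- numeric(0)
  ors <- aucs <- numeric(0)
  for (f in seq_len(part$n_folds)) {
    p_test <- part$pres_fold == f
    if (part$kind == "block4") {
      b_test <- part$bg_fold == f
      b_train <- !b_test
    } else {
      b_test <- rep(TRUE, nrow(bg_cov))
      b_train <- rep(TRUE, nrow(bg_cov))
    }
    if (sum(!p_test) < 2 || sum(p_test) == 0) next
    model <- suppressWarnings(fit_maxent(pres_cov[!p_test, , drop = FALSE],
                        bg_cov[b_train, , drop = FALSE], config))
    s_train_p <- maxent_scores(model, pres_cov[!p_test, , drop = FALSE])
    s_test_p <- maxent_scores(model, pres_cov[p_test, , drop = FALSE])
    s_test_b <- maxent_scores(model, bg_cov[b_test, , drop = FALSE])
    ors <- c(ors, omission_rate(s_train_p, s_test_p))
    aucs <- c(aucs, auc_pb(s_test_p, s_test_b))
    sp <- c(sp, s_test_p)
    sb <- c(sb, s_test_b)
  }
  # AUC and OR aggregate as means over folds; the maxSSS threshold needs a
  # single value per species, so it is scanned on the pooled held-out scores.
  mx <- maxsss(sp, sb)
  structure(list(
    auc = mean(aucs),
    or_lpt = mean(ors),
    or_maxsss = mean(sp < mx$threshold),
    tss = mx$tss,
    maxsss_threshold = mx$threshold,
    sensitivity = mx$sensitivity,
    specificity = mx$specificity
  ), class = "eval_report")
}

#' Accept or reject a model on the study's performance gates
#'
#' A model is rejected iff AUC < 0.75, TSS < 0.45, or omission rate (at
#' maxSSS) > 0.25; every violated gate is listed as a reason.
#'
#' @param report an [evaluate_model()] report (needs `auc`, `tss`,
#'   `or_maxsss`).
#' @return list with `accept` (logical) and `reasons` (character).
#' @export
gate_model <- function(report) {
  reasons <- character(0)
  if (report$auc < 0.75) reasons <- c(reasons, sprintf("AUC %.3f < 0.75", report$auc))
  if (report$tss < 0.45) reasons <- c(reasons, sprintf("TSS %.3f < 0.45", report$tss))
  if (report$or_maxsss > 0.25) reasons <- c(reasons, sprintf("OR %.3f > 0.25", report$or_maxsss))
  list(accept = length(reasons) == 0, reasons = reasons)
}
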