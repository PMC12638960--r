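with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Assign samples to cross-validation folds
#'
#' Seeded, deterministic partition into `k` near-equal folds (sizes differ by
#' at most 1). With `strata` (e.g. the treatment arm) the arm proportions are
#' preserved within each fold, which guarantees both arms appear in every
#' fold whenever each arm has at least `k` members.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @param strata optional vector of stratum labels (length n).
#' @return integer vector of fold labels in 1..k with attribute `"seed"`.
#' @export
assign_folds <- function(n, k, seed, strata = NULL) {
  if (n < k) stop("n must be at least k")
  if (k < 2) stop("k must be at least 2")
  labels <- integer(n)
  with_seed(seed, {
    cycle <- rep(sample.int(k), length.out = n)
    pos <- 0L
    groups <- if (is.null(strata)) list(seq_len(n)) else
      split(seq_len(n), strata)
    for (g in groups) {
      g <- g[sample.int(length(g))]
      labels[g] <- cycle[pos + seq_along(g)]
      pos <- pos + length(g)
    }
  })
  attr(labels, "seed") <- seed
  labels
}

#' Hyperparameter grid for the penalized descent
#'
#' The learning-rate ladder is `eta_multiplier / d`, where the denominator
#' `d` is either the estimated spectral norm of `X'X` (default; the smallest
#' rung is then guaranteed stable and the larger rungs probe progressively
#' more aggressive steps, with diverging cells discarded by the guard) or the
#' number `m` of variants with nonzero pre-trained weight
#' (`eta_scale = "active_count"`; the two rules agree up to a small constant
#' when the active set is much larger than the sample size, the regime in
#' which the `/m` rule originates). The shrinkage `lambda` lies in `[0, 1)`;
#' within the `n_iter` recorded iterations the best stopping point `r` is
#' tuned jointly with `(eta, lambda)`.
#'
#' @param eta_multipliers positive multipliers (default `c(1, 10, 50, 100)`).
#' @param lambdas shrinkage values in `[0, 1)` (default `c(0, 0.5, 0.99)`).
#' @param n_iter iteration cap (default 30).
#' @return object of class `tune_grid`.
#' @export
tune_grid <- function(eta_multipliers = c(1, 10, 50, 100),
                      lambdas = c(0, 0.5, 0.99), n_iter = 30L) {
  if (any(eta_multipliers <= 0)) stop("eta multipliers must be positive")
  if (any(lambdas < 0 | lambdas >= 1)) stop("lambdas must be in [0, 1)")
  structure(list(eta_multipliers = eta_multipliers, lambdas = lambdas,
                 n_iter = as.integer(n_iter)), class = "tune_grid")
}

#' Convert a weight table to a cohort-aligned initial state
#'
#' Harmonizes allele orientation against the cohort's variants and converts
#' per-allele weights to the standardized-dosage scale by multiplying with
#' the cohort dosage standard deviation, so the implied score equals the
#' usual centered per-allele PRS.
#'
#' @param weights a [weight_table()] or [effect_pair()] (returned as-is after
#'   id alignment).
#' @param cohort a [pgx_cohort()].
#' @param scale_to_std multiply by dosage sd (default `TRUE`); set `FALSE`
#'   when the weights are already on the standardized scale.
#' @return an [effect_pair()] aligned to the cohort variants (zero where a
#'   cohort variant has no weight).
#' @export
align_weights_to_cohort <- function(weights, cohort, scale_to_std = TRUE) {
  ids <- cohort$genotypes$variants$id
  if (inherits(weights, "effect_pair")) {
    idx <- match(ids, weights$variant_ids)
    return(effect_pair(ifelse(is.na(idx), 0, weights$beta_g[idx]),
                       ifelse(is.na(idx), 0, weights$beta_gt[idx]), ids))
  }
  h <- harmonize_weights(weights, cohort$genotypes$variants)
  w <- h$weight
  if (scale_to_std) {
    d <- impute_missing(subset_genotypes(cohort$genotypes,
                                         variants = h$variant_id))$dosages
    w <- w * col_sds(d)
  }
  idx <- match(ids, h$variant_id)
  effect_pair(ifelse(is.na(idx), 0, w[idx]), rep(0, length(ids)), ids)
}

# argmax over the (eta, lambda, r) score array; ties broken toward larger
# lambda, then smaller eta, then smaller r (most regularized, earliest stop)
select_best_cell <- function(scores) {
  best <- NULL
  best_score <- -Inf
  for (li in rev(seq_len(dim(scores)[2]))) {
    for (ei in seq_len(dim(scores)[1])) {
      for (r in seq_len(dim(scores)[3])) {
        s <- scores[ei, li, r]
        if (is.finite(s) && s > best_score + 1e-12) {
          best_score <- s
          best <- c(ei, li, r)
        }
      }
    }
  }
  best
}

# power-iteration estimate of ||X'X||_2 for X = [Z, Z*T]; deterministic start
spectral_norm_xtx <- function(z, treatment, n_iter = 20L) {
  m <- ncol(z)
  v <- rep(1 / sqrt(2 * m), 2L * m)
  lam <- 1
  for (i in seq_len(n_iter)) {
    xv <- as.numeric(z %*% v[seq_len(m)]) +
      treatment * as.numeric(z %*% v[m + seq_len(m)])
    u1 <- as.numeric(crossprod(z, xv))
    u2 <- as.numeric(crossprod(z, treatment * xv))
    u <- c(u1, u2)
    lam <- sqrt(sum(u^2))
    if (lam == 0) return(1)
    v <- u / lam
  }
  lam
}

crit_score <- function(pg, pgt, tval, yval, sst, criterion) {
  pgt_t <- pgt * tval
  Xr <- cbind(1, pg)
  sse_red <- sum(stats::lm.fit(Xr, yval)$residuals^2)
  sse_full <- sum(stats::lm.fit(cbind(Xr, pgt_t), yval)$residuals^2)
  if (criterion == "overall_r2") {
    if (sst == 0) return(-Inf)
    1 - sse_full / sst
  } else {
    if (sse_red == 0) return(0)
    (sse_red - sse_full) / sse_red
  }
}

# batched descent over all (eta, lambda) cells of a grid on one fold:
# one weight column per cell, updated jointly with level-3 BLAS; returns a
# (n_cell x n_iter) matrix of validation criterion values (-Inf once a cell
# diverges). Cell order: eta index fastest.
grid_fold_scores <- function(z_tr, t_tr, y_tr, z_val, t_val, y_val,
                             bg0, bgt0, etas, lambdas, n_iter,
                             update_mode, criterion) {
  m <- ncol(z_tr)
  cells <- expand.grid(ei = seq_along(etas), li = seq_along(lambdas))
  eta_c <- etas[cells$ei]
  keep_c <- 1 - lambdas[cells$li]
  nc <- nrow(cells)
  gt_tr <- z_tr * t_tr
  cols <- seq_len(nc) # original cell index of each live column
  keep_live <- keep_c
  eta_live <- eta_c
  Bg <- matrix(bg0, m, nc)
  Bgt <- matrix(bgt0, m, nc)
  scores <- matrix(-Inf, nc, n_iter)
  sst <- sum((y_val - mean(y_val))^2)
  fg0_tr <- if (update_mode == "gt_only") as.numeric(z_tr %*% bg0)
  fg0_val <- if (update_mode == "gt_only") as.numeric(z_val %*% bg0)
  for (r in seq_len(n_iter)) {
    if (!length(cols)) break
    fit_tr <- gt_tr %*% Bgt
    fit_tr <- fit_tr + if (update_mode == "gt_only") fg0_tr else z_tr %*% Bg
    resid <- y_tr - fit_tr
    if (update_mode == "both") {
      Bg <- Bg * rep(keep_live, each = m) +
        crossprod(z_tr, resid) * rep(eta_live, each = m)
    }
    Bgt <- Bgt * rep(keep_live, each = m) +
      crossprod(gt_tr, resid) * rep(eta_live, each = m)
    norm2 <- sqrt(colSums(Bg^2) + colSums(Bgt^2))
    ok <- is.finite(norm2) & norm2 <= 1e8
    if (!all(ok)) {
      # drop diverged cells from the batch; their scores stay -Inf
      Bg <- Bg[, ok, drop = FALSE]
      Bgt <- Bgt[, ok, drop = FALSE]
      cols <- cols[ok]
      keep_live <- keep_live[ok]
      eta_live <- eta_live[ok]
      if (!length(cols)) break
    }
    pg_val <- if (update_mode == "gt_only") NULL else z_val %*% Bg
    pgt_val <- z_val %*% Bgt
    for (k in seq_along(cols)) {
      pg <- if (update_mode == "gt_only") fg0_val else pg_val[, k]
      scores[cols[k], r] <- crit_score(pg, pgt_val[, k], t_val, y_val, sst,
                                       criterion)
    }
  }
  scores
}

#' Tune (eta, lambda, r) by inner k-fold cross-validation
#'
#' Splits the training cohort into `k_inner` treatment-stratified folds. For
#' each fold the descent is run on the remaining folds from the strategy's
#' initial state for every `(eta, lambda)` cell, the whole iteration trace is
#' kept, and the strategy's criterion (overall R^2 of
#' `Y' ~ PRS_G + PRS_GT x T`, or the partial R^2 of the interaction term
#' given PRS_G) is computed on the held-out fold at every iteration `r`.
#' Scores are averaged across folds and the best cell returned. A diverging
#' cell scores `-Inf` instead of aborting the grid. Ties are broken toward
#' larger lambda, then smaller eta, then smaller r.
#'
#' @param train a [pgx_cohort()].
#' @param pre_weights [weight_table()], [effect_pair()] or numeric vector of
#'   pre-trained prognostic weights (see [align_weights_to_cohort()]).
#' @param strategy a [strategy_config()].
#' @param grid a [tune_grid()].
#' @param seed integer seed for the fold split.
#' @param k_inner number of inner folds (default 4).
#' @param eta_scale "spectral" (default): learning rates are
#'   `eta_multipliers / lambda_max_hat(X'X)` with the norm estimated on the
#'   standardized training design; "active_count": `eta_multipliers / m`.
#' @return object of class `tune_result`: `best_eta`, `best_lambda`,
#'   `best_r`, `score_table` (array eta x lambda x r), `etas`, `m_active`.
#' @export
tune_hyperparameters <- function(train, pre_weights, strategy, grid = tune_grid(),
                                 seed = 1L, k_inner = 4L,
                                 eta_scale = c("spectral", "active_count")) {
  stopifnot(inherits(train, "pgx_cohort"), inherits(strategy, "strategy_config"))
  eta_scale <- match.arg(eta_scale)
  init <- align_weights_to_cohort(pre_weights, train)
  active <- which(init$beta_g != 0)
  if (!length(active)) stop("no variant has a nonzero pre-trained weight")
  m <- length(active)
  folds <- assign_folds(length(train$phenotype), k_inner, seed,
                        strata = train$treatment)
  g_act <- impute_missing(subset_genotypes(train$genotypes, variants = active))
  ids_act <- g_act$variants$id
  denom <- if (eta_scale == "spectral") {
    spectral_norm_xtx(standardize_genotypes(g_act$dosages)$mat,
                      train$treatment)
  } else m
  etas <- grid$eta_multipliers / denom
  bg0 <- init$beta_g[active]
  dims <- c(length(etas), length(grid$lambdas), grid$n_iter)
  scores <- array(0, dims,
                  dimnames = list(paste0("eta", grid$eta_multipliers),
                                  paste0("lambda", grid$lambdas),
                                  paste0("r", seq_len(grid$n_iter))))
  for (f in seq_len(k_inner)) {
    tr <- folds != f
    std <- standardize_genotypes(g_act$dosages[tr, , drop = FALSE])
    ytr <- residualize(train$phenotype[tr],
                       if (is.null(train$covariates)) NULL else
                         train$covariates[tr, , drop = FALSE],
                       train$treatment[tr])
    zval <- standardize_genotypes(g_act$dosages[!tr, , drop = FALSE],
                                  reference_stats = std$stats)$mat
    yval <- apply_residualizer(train$phenotype[!tr],
                               if (is.null(train$covariates)) NULL else
                                 train$covariates[!tr, , drop = FALSE],
                               train$treatment[!tr],
                               attr(ytr, "coefficients"))
    tval <- train$treatment[!tr]
    bgt0 <- if (strategy$gt_init == "pre") bg0 else rep(0, m)
    fold_sc <- grid_fold_scores(std$mat, train$treatment[tr], as.numeric(ytr),
                                zval, tval, yval, bg0, bgt0,
                                etas, grid$lambdas, grid$n_iter,
                                strategy$update_mode,
                                strategy$tuning_criterion)
    for (li in seq_along(grid$lambdas)) {
      rows <- (li - 1L) * length(etas) + seq_along(etas)
      scores[, li, ] <- scores[, li, ] +
        fold_sc[rows, , drop = FALSE] / k_inner
    }
  }
  if (all(!is.finite(scores))) stop("all grid cells diverged")
  best <- select_best_cell(scores)
  structure(list(best_eta = etas[best[1]],
                 best_eta_multiplier = grid$eta_multipliers[best[1]],
                 best_lambda = grid$lambdas[best[2]],
                 best_r = best[3],
                 best_score = scores[best[1], best[2], best[3]],
                 score_table = scores,
                 etas = etas,
                 eta_scale = eta_scale,
                 m_active = m,
                 criterion = strategy$tuning_criterion),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("tune_result: eta = %.3g (x%g/m, m = %d), lambda = %.3g, r = %d, score = %.4f (%s)\n",
              x$best_eta, x$best_eta_multiplier, x$m_active, x$best_lambda,
              x$best_r, x$best_score, x$criterion))
  invisible(x)
}

#' Tune and fit on a training cohort
#'
#' Runs [tune_hyperparameters()] and re-applies the descent with the selected
#' `(eta, lambda)` for `best_r` iterations on the whole training cohort.
#'
#' @inheritParams tune_hyperparameters
#' @return object of class `tl_fit`: `effects` (final [effect_pair()] on the
#'   active set), `tune` (the [tune_hyperparameters()] result), `strategy`,
#'   `standardize_stats`, `residualizer`, `pre` (initial state).
#' @export
fit_tl_prs <- function(train, pre_weights, strategy = strategy_config("M1"),
                       grid = tune_grid(), seed = 1L, k_inner = 4L,
                       eta_scale = c("spectral", "active_count")) {
  tune <- tune_hyperparameters(train, pre_weights, strategy, grid, seed,
                               k_inner, eta_scale = eta_scale)
  init <- align_weights_to_cohort(pre_weights, train)
  # a cell near the stability edge can pass the inner folds yet diverge on
  # the full training set; invalidate it and fall back to the next-best cell
  scores <- tune$score_table
  trace <- NULL
  repeat {
    best <- select_best_cell(scores)
    if (is.null(best)) stop("all grid cells diverged")
    tune$best_eta <- tune$etas[best[1]]
    tune$best_eta_multiplier <- grid$eta_multipliers[best[1]]
    tune$best_lambda <- grid$lambdas[best[2]]
    tune$best_r <- best[3]
    tune$best_score <- scores[best[1], best[2], best[3]]
    settings <- descent_settings(tune$best_eta, tune$best_lambda,
                                 tune$best_r)
    trace <- tryCatch(run_descent(train, init, settings, strategy),
                      pgxtl_divergence = function(e) NULL)
    if (!is.null(trace)) break
    scores[best[1], best[2], ] <- -Inf
  }
  effects <- trace_state(trace, tune$best_r)
  structure(list(effects = effects, tune = tune, strategy = strategy,
                 standardize_stats = attr(trace, "standardize_stats"),
                 residualizer = attr(trace, "residualizer"),
                 pre = init),
            class = "tl_fit")
}

#' @export
print.tl_fit <- function(x, ...) {
  cat(sprintf("tl_fit (%s): %d active variants\n", x$strategy$name,
              length(x$effects$beta_g)))
  print(x$tune)
  invisible(x)
}

#' Score new genotypes with a fitted model
#'
#' Standardizes the new genotypes with the fitting-set statistics and returns
#' the prognostic and predictive scores.
#'
#' @param object a [fit_tl_prs()] result.
#' @param newdata a [genotype_matrix()] or [pgx_cohort()].
#' @param ... unused.
#' @return list with `prs_g` and `prs_gt`.
#' @export
predict.tl_fit <- function(object, newdata, ...) {
  g <- if (inherits(newdata, "pgx_cohort")) newdata$genotypes else newdata
  g <- impute_missing(subset_genotypes(g,
                                       variants = object$effects$variant_ids))
  z <- standardize_genotypes(g, reference_stats = object$standardize_stats)$mat
  compute_prs(z, object$effects)
}

#' Nested cross-validated polygenic scores
#'
#' The real-data workflow: the cohort is split into `k_outer` treatment-
#' stratified folds; for each fold the hyperparameters are tuned by inner
#' cross-validation on the remaining folds, the descent is refit there with
#' the selected cell, and the held-out fold receives its out-of-fold
#' prognostic and predictive scores. Every sample is scored exactly once and
#' the whole procedure is deterministic given the seed.
#'
#' @inheritParams tune_hyperparameters
#' @param cohort a [pgx_cohort()].
#' @param k_outer number of outer folds (default 5).
#' @param global_residualize residualize the phenotype once on the full
#'   cohort before splitting (one-shot residualization) instead of per
#'   training fold.
#' @return object of class `nested_cv_prs`: data.frame `prs` (sample_id,
#'   prs_g, prs_gt, fold), list `fits` of per-fold `tl_fit`s, `fold_labels`.
#' @export
nested_cv_prs <- function(cohort, pre_weights, strategy = strategy_config("M1"),
                          grid = tune_grid(), k_outer = 5L, seed = 1L,
                          k_inner = 4L, global_residualize = FALSE,
                          eta_scale = c("spectral", "active_count")) {
  eta_scale <- match.arg(eta_scale)
  stopifnot(inherits(cohort, "pgx_cohort"))
  if (global_residualize) {
    y <- residualize(cohort$phenotype, cohort$covariates, cohort$treatment)
    cohort <- pgx_cohort(cohort$genotypes, cohort$treatment, as.numeric(y))
  }
  n <- length(cohort$phenotype)
  folds <- assign_folds(n, k_outer, seed, strata = cohort$treatment)
  prs_g <- rep(NA_real_, n)
  prs_gt <- rep(NA_real_, n)
  fits <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    train <- subset_cohort(cohort, folds != f)
    fit <- tryCatch(
      fit_tl_prs(train, pre_weights, strategy, grid,
                 seed = derive_seed(seed, f), k_inner = k_inner,
                 eta_scale = eta_scale),
      error = function(e) stop("outer fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    test_g <- subset_genotypes(cohort$genotypes, samples = which(folds == f))
    p <- predict(fit, test_g)
    prs_g[folds == f] <- p$prs_g
    prs_gt[folds == f] <- p$prs_gt
    fits[[f]] <- fit
  }
  structure(list(
    prs = data.frame(sample_id = rownames(cohort$genotypes$dosages),
                     prs_g = prs_g, prs_gt = prs_gt, fold = as.integer(folds),
                     stringsAsFactors = FALSE),
    fits = fits, fold_labels = as.integer(folds)),
    class = "nested_cv_prs")
}

#' @export
print.nested_cv_prs <- function(x, ...) {
  cat(sprintf("nested_cv_prs: %d samples, %d folds\n",
              nrow(x$prs), length(x$fits)))
  invisible(x)
}
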