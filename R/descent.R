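#' Paired prognostic / predictive SNP effects
#'
#' The two-dimensional weight state `b = [beta_g, beta_gt]`: per-variant
#' genotype main (prognostic) effects and genotype-by-treatment interaction
#' (predictive) effects, on the standardized-dosage scale.
#'
#' @param beta_g,beta_gt numeric vectors of equal length, finite.
#' @param variant_ids aligned variant identifiers.
#' @return object of class `effect_pair`.
#' @export
effect_pair <- function(beta_g, beta_gt, variant_ids) {
  beta_g <- as.numeric(beta_g)
  beta_gt <- as.numeric(beta_gt)
  variant_ids <- as.character(variant_ids)
  if (length(beta_g) != length(beta_gt) ||
      length(beta_g) != length(variant_ids)) {
    stop("beta_g, beta_gt and variant_ids must have equal length")
  }
  if (!all(is.finite(beta_g)) || !all(is.finite(beta_gt))) {
    stop("effect sizes must be finite")
  }
  structure(list(beta_g = beta_g, beta_gt = beta_gt,
                 variant_ids = variant_ids),
            class = "effect_pair")
}

#' @export
print.effect_pair <- function(x, ...) {
  cat(sprintf("effect_pair: %d variants (%d nonzero prognostic, %d nonzero predictive)\n",
              length(x$beta_g), sum(x$beta_g != 0), sum(x$beta_gt != 0)))
  invisible(x)
}

#' Fitting strategy (M1-M6)
#'
#' The six strategies differ in (1) whether both effect blocks are updated or
#' only the predictive block with the prognostic block frozen at its
#' pre-trained value, (2) whether the predictive block starts at zero or at
#' the pre-trained prognostic weights, and (3) whether hyperparameters are
#' tuned by overall R^2 of `Y' ~ PRS_G + PRS_GT x T` or by the partial R^2 of
#' the interaction term given PRS_G. With the prognostic block frozen (M5,
#' M6) the two criteria induce the same ranking, and overall R^2 is used.
#'
#' @param name one of "M1".."M6".
#' @return object of class `strategy_config` with fields `name`,
#'   `update_mode` ("both" or "gt_only"), `gt_init` ("zero" or "pre") and
#'   `tuning_criterion` ("overall_r2" or "conditional_r2").
#' @export
strategy_config <- function(name = c("M1", "M2", "M3", "M4", "M5", "M6")) {
  name <- match.arg(name)
  tab <- list(
    M1 = list(update_mode = "both",    gt_init = "zero", tuning_criterion = "overall_r2"),
    M2 = list(update_mode = "both",    gt_init = "pre",  tuning_criterion = "overall_r2"),
    M3 = list(update_mode = "both",    gt_init = "zero", tuning_criterion = "conditional_r2"),
    M4 = list(update_mode = "both",    gt_init = "pre",  tuning_criterion = "conditional_r2"),
    M5 = list(update_mode = "gt_only", gt_init = "zero", tuning_criterion = "overall_r2"),
    M6 = list(update_mode = "gt_only", gt_init = "pre",  tuning_criterion = "overall_r2")
  )
  structure(c(list(name = name), tab[[name]]), class = "strategy_config")
}

#' Gradient-descent settings
#'
#' `learning_rate` and `penalty` are the reparameterized step size and
#' shrinkage of the update `b <- (1 - penalty) b + learning_rate X^T (y - Xb)`
#' (they absorb the factor 2 of the raw gradient). `penalty` must stay below
#' 1 so the retained fraction of `b` cannot change sign between iterations.
#'
#' @param learning_rate positive step size.
#' @param penalty shrinkage in `[0, 1)`.
#' @param n_iter iteration cap (>= 1).
#' @return object of class `descent_settings`.
#' @export
descent_settings <- function(learning_rate, penalty = 0, n_iter = 30L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be positive")
  }
  if (penalty < 0 || penalty >= 1) stop("penalty must be in [0, 1)")
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  structure(list(learning_rate = learning_rate, penalty = penalty,
                 n_iter = n_iter), class = "descent_settings")
}

#' Penalized least-squares loss
#'
#' `loss = (y - X b)^T (y - X b) + penalty_raw * b^T b`, where `X = [G, G*T]`
#' and `y` is the covariate/treatment-residualized phenotype (the covariate
#' term is absorbed by the residualization).
#'
#' @param b an [effect_pair()].
#' @param x design matrix `n x 2M`, columns `[G, G*T]` (standardized).
#' @param y residualized phenotype.
#' @param penalty_raw nonnegative ridge penalty on `b`.
#' @return nonnegative scalar loss.
#' @export
penalized_loss <- function(b, x, y, penalty_raw = 0) {
  stopifnot(inherits(b, "effect_pair"))
  bv <- c(b$beta_g, b$beta_gt)
  if (ncol(x) != length(bv)) stop("design matrix must have 2M columns")
  if (nrow(x) != length(y)) stop("x and y dimension mismatch")
  if (penalty_raw < 0) stop("penalty_raw must be nonnegative")
  r <- y - as.numeric(x %*% bv)
  sum(r^2) + penalty_raw * sum(bv^2)
}

#' One penalized gradient-descent step
#'
#' Applies `b_next = (1 - penalty) b + learning_rate * X^T (y - X b)`. Under
#' `update_mode = "gt_only"` the gradient is computed at the full current
#' state but only the predictive block is moved; the prognostic block is
#' returned unchanged.
#'
#' @param b current [effect_pair()].
#' @param x design matrix `n x 2M` `[G, G*T]`.
#' @param y residualized phenotype.
#' @param settings a [descent_settings()].
#' @param strategy a [strategy_config()] (only `update_mode` is used).
#' @return updated `effect_pair`.
#' @export
descent_step <- function(b, x, y, settings,
                         strategy = strategy_config("M1")) {
  stopifnot(inherits(b, "effect_pair"), inherits(settings, "descent_settings"))
  m <- length(b$beta_g)
  bv <- c(b$beta_g, b$beta_gt)
  if (ncol(x) != 2L * m) stop("design matrix must have 2M columns")
  grad_part <- as.numeric(crossprod(x, y - as.numeric(x %*% bv)))
  new <- (1 - settings$penalty) * bv + settings$learning_rate * grad_part
  if (strategy$update_mode == "gt_only") new[seq_len(m)] <- b$beta_g
  if (!all(is.finite(new))) {
    stop_divergence("non-finite update in descent_step", iteration = 1L)
  }
  effect_pair(new[seq_len(m)], new[m + seq_len(m)], b$variant_ids)
}

stop_divergence <- function(msg, iteration) {
  stop(structure(
    class = c("pgxtl_divergence", "error", "condition"),
    list(message = sprintf("%s (iteration %d)", msg, iteration),
         call = sys.call(-1), iteration = iteration)))
}

#' Low-level trace of the two-dimensional penalized descent
#'
#' Iterates the reparameterized update on pre-standardized inputs, recording
#' the state after every iteration so early stopping can be tuned without
#' re-running. Aborts with a divergence error (class `pgxtl_divergence`) if
#' any coordinate becomes non-finite or exceeds 1e8 in magnitude.
#'
#' @param g_std standardized genotype matrix (n x m, active variants only).
#' @param treatment 0/1 vector.
#' @param y residualized phenotype.
#' @param beta_g0,beta_gt0 initial states (length m).
#' @param learning_rate,penalty,n_iter see [descent_settings()].
#' @param update_mode "both" or "gt_only".
#' @param variant_ids identifiers for the active variants.
#' @return object of class `descent_trace`: list with `beta_g`, `beta_gt`
#'   (m x n_iter matrices, column r = state after iteration r), `variant_ids`,
#'   `update_mode`.
#' @export
descent_trace <- function(g_std, treatment, y, beta_g0, beta_gt0,
                          learning_rate, penalty, n_iter,
                          update_mode = c("both", "gt_only"),
                          variant_ids = colnames(g_std)) {
  update_mode <- match.arg(update_mode)
  m <- ncol(g_std)
  n_iter <- as.integer(n_iter)
  gt <- g_std * treatment
  bg <- as.numeric(beta_g0)
  bgt <- as.numeric(beta_gt0)
  out_g <- matrix(NA_real_, m, n_iter)
  out_gt <- matrix(NA_real_, m, n_iter)
  keep <- 1 - penalty
  for (r in seq_len(n_iter)) {
    resid <- y - as.numeric(g_std %*% bg) - as.numeric(gt %*% bgt)
    if (update_mode == "both") {
      bg <- keep * bg + learning_rate * as.numeric(crossprod(g_std, resid))
    }
    bgt <- keep * bgt + learning_rate * as.numeric(crossprod(gt, resid))
    if (!all(is.finite(bg)) || !all(is.finite(bgt)) ||
        max(abs(bg), abs(bgt)) > 1e8) {
      stop_divergence("descent diverged", iteration = r)
    }
    out_g[, r] <- bg
    out_gt[, r] <- bgt
  }
  structure(list(beta_g = out_g, beta_gt = out_gt,
                 variant_ids = variant_ids, update_mode = update_mode),
            class = "descent_trace")
}

#' @export
print.descent_trace <- function(x, ...) {
  cat(sprintf("descent_trace: %d variants x %d iterations (%s)\n",
              nrow(x$beta_g), ncol(x$beta_g), x$update_mode))
  invisible(x)
}

#' Extract the state after iteration r from a trace
#' @param trace a [descent_trace()] result.
#' @param r iteration index (1..n_iter).
#' @return an [effect_pair()].
#' @export
trace_state <- function(trace, r) {
  stopifnot(inherits(trace, "descent_trace"))
  r <- as.integer(r)
  if (r < 1L || r > ncol(trace$beta_g)) stop("iteration index out of range")
  effect_pair(trace$beta_g[, r], trace$beta_gt[, r], trace$variant_ids)
}

#' Run the penalized descent on a cohort
#'
#' Prepares a cohort (mean-imputes and column-standardizes the genotypes,
#' residualizes the phenotype on intercept + covariates + treatment),
#' restricts to the active variant set (variants with nonzero pre-trained
#' prognostic weight), initializes per the strategy, and iterates the update
#' for `settings$n_iter` iterations.
#'
#' @param cohort a [pgx_cohort()].
#' @param pre_weights an [effect_pair()] (its `beta_g` is the pre-trained
#'   state; `beta_gt` is ignored -- the strategy dictates the predictive
#'   initialization) or a numeric vector aligned to the cohort variants.
#' @param settings a [descent_settings()].
#' @param strategy a [strategy_config()].
#' @return a [descent_trace()] with attributes `"standardize_stats"` and
#'   `"residualizer"` (coefficients used), for applying the fit to new data.
#' @export
run_descent <- function(cohort, pre_weights, settings,
                        strategy = strategy_config("M1")) {
  stopifnot(inherits(cohort, "pgx_cohort"),
            inherits(settings, "descent_settings"))
  ids <- cohort$genotypes$variants$id
  if (inherits(pre_weights, "effect_pair")) {
    idx <- match(ids, pre_weights$variant_ids)
    bg_pre <- ifelse(is.na(idx), 0, pre_weights$beta_g[idx])
  } else {
    bg_pre <- as.numeric(pre_weights)
    if (length(bg_pre) != length(ids)) {
      stop("pre_weights length must match cohort variant count")
    }
  }
  active <- which(bg_pre != 0)
  if (length(active) == 0L) stop("no variant has a nonzero pre-trained weight")
  g <- impute_missing(subset_genotypes(cohort$genotypes, variants = active))
  std <- standardize_genotypes(g)
  y <- residualize(cohort$phenotype, cohort$covariates, cohort$treatment)
  bg0 <- bg_pre[active]
  bgt0 <- if (strategy$gt_init == "pre") bg0 else rep(0, length(active))
  tr <- descent_trace(std$mat, cohort$treatment, as.numeric(y),
                      bg0, bgt0, settings$learning_rate, settings$penalty,
                      settings$n_iter, update_mode = strategy$update_mode,
                      variant_ids = ids[active])
  attr(tr, "standardize_stats") <- std$stats
  attr(tr, "residualizer") <- attr(y, "coefficients")
  tr
}

#' Compute prognostic and predictive polygenic scores
#'
#' Aligns a genotype matrix with a weight state by variant id (inner join).
#' Where the effect allele of the weights is the genotype's other allele, the
#' dosage is flipped to `2 - dosage` before standardization; unreconcilable
#' alleles are dropped. Scores are `PRS_G = Z beta_g` and `PRS_GT = Z
#' beta_gt` on the standardized dosages `Z`.
#'
#' @param g a [genotype_matrix()], or an already standardized and aligned
#'   numeric matrix (then no alignment or standardization is performed and
#'   `effects` must match its columns).
#' @param effects an [effect_pair()]; `variant_ids` must intersect `g`.
#' @param effect_alleles,other_alleles allele orientation of `effects`
#'   (required for flipping when `g` is a `genotype_matrix`; default assumes
#'   the orientations already agree).
#' @param reference_stats optional fitting-set standardization statistics
#'   (see [standardize_genotypes()]).
#' @return list with numeric vectors `prs_g` and `prs_gt` (length n).
#' @export
compute_prs <- function(g, effects, effect_alleles = NULL,
                        other_alleles = NULL, reference_stats = NULL) {
  stopifnot(inherits(effects, "effect_pair"))
  if (is.matrix(g)) {
    if (ncol(g) != length(effects$beta_g)) {
      stop("matrix g and effects are not aligned")
    }
    return(list(prs_g = as.numeric(g %*% effects$beta_g),
                prs_gt = as.numeric(g %*% effects$beta_gt)))
  }
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  idx <- match(effects$variant_ids, v$id)
  keep <- which(!is.na(idx))
  if (length(keep) == 0L) stop("no variant shared between genotypes and weights")
  gi <- idx[keep]
  bg <- effects$beta_g[keep]
  bgt <- effects$beta_gt[keep]
  dos <- g$dosages[, gi, drop = FALSE]
  if (!is.null(effect_alleles)) {
    ea <- toupper(effect_alleles[keep])
    oa <- if (is.null(other_alleles)) rep(NA_character_, length(keep)) else
      toupper(other_alleles[keep])
    same <- ea == v$effect_allele[gi]
    swapped <- ea == v$other_allele[gi] &
      (is.na(oa) | oa == v$effect_allele[gi])
    bad <- !same & !swapped
    if (any(bad)) {
      dos <- dos[, !bad, drop = FALSE]
      bg <- bg[!bad]; bgt <- bgt[!bad]
      swapped <- swapped[!bad]
      if (ncol(dos) == 0L) stop("no variant shared after allele reconciliation")
    }
    if (any(swapped)) dos[, swapped] <- 2 - dos[, swapped]
  }
  dos[is.na(dos)] <- NA # keep NA explicit, impute below
  gm <- genotype_matrix(dos, colnames(dos),
                        rep("A", ncol(dos)), rep("G", ncol(dos)))
  z <- standardize_genotypes(impute_missing(gm), reference_stats)$mat
  list(prs_g = as.numeric(z %*% bg), prs_gt = as.numeric(z %*% bgt))
}
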