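#' Evaluate prognostic and predictive polygenic scores
#'
#' Implements the evaluation model `Y' ~ PRS_G + PRS_GT x T`, where `Y'` is
#' the residual of the phenotype after adjusting for intercept, covariates
#' and treatment. Reports the model R^2, the partial R^2 of each term, the
#' two-sided t-test p-value on the interaction coefficient, and the
#' coefficient itself. The partial R^2 of the interaction term is the classic
#' `(SSE_reduced - SSE_full) / SSE_reduced` with the PRS_G-only model as the
#' reduced model; `partial_method = "r2_diff"` reports the plain R^2
#' difference instead.
#'
#' @param y phenotype vector.
#' @param t treatment 0/1 vector.
#' @param covariates optional covariate matrix.
#' @param prs_g,prs_gt score vectors (length n, not both constant).
#' @param partial_method "sse" (default) or "r2_diff".
#' @param center_t center the treatment indicator inside the interaction
#'   regressor (`PRS_GT * (T - mean(T))`). With the raw-0/1 default the
#'   interaction coefficient absorbs any prognostic signal carried by
#'   `prs_gt` but missed by `prs_g`, so its t-test over-rejects when no true
#'   interaction exists; centering makes the population coefficient exactly
#'   zero under the null for any fixed weights.
#' @return object of class `eval_report`: list with `overall_r2`,
#'   `partial_r2_g`, `partial_r2_gt`, `interaction_p`, `interaction_coef`.
#' @export
evaluate_prs <- function(y, t, covariates = NULL, prs_g, prs_gt,
                         partial_method = c("sse", "r2_diff"),
                         center_t = FALSE) {
  partial_method <- match.arg(partial_method)
  n <- length(y)
  stopifnot(length(t) == n, length(prs_g) == n, length(prs_gt) == n)
  yp <- as.numeric(residualize(y, covariates, t))
  if (stats::sd(yp) == 0) stop("residualized phenotype is constant")
  inter <- prs_gt * (if (center_t) t - mean(t) else t)
  if (stats::sd(prs_g) == 0 && stats::sd(inter) == 0) {
    stop("both score regressors are constant")
  }
  full <- stats::lm(yp ~ prs_g + inter)
  reduced <- stats::lm(yp ~ prs_g)
  sm <- summary(full)
  sse_full <- sum(stats::residuals(full)^2)
  sse_red <- sum(stats::residuals(reduced)^2)
  r2_full <- sm$r.squared
  r2_red <- summary(reduced)$r.squared
  coefs <- stats::coef(sm)
  if ("inter" %in% rownames(coefs) &&
      is.finite(coefs["inter", "Pr(>|t|)"])) {
    interaction_coef <- coefs["inter", "Estimate"]
    interaction_p <- coefs["inter", "Pr(>|t|)"]
  } else {
    # interaction column dropped (constant/collinear) or the full model fits
    # exactly: no detectable interaction beyond the reduced model
    interaction_coef <- 0
    interaction_p <- 1
  }
  sst <- sum((yp - mean(yp))^2)
  partial_gt <- if (partial_method == "sse") {
    # an exactly-fitting reduced model leaves nothing for the interaction
    if (sse_red <= sst * 1e-12) 0 else (sse_red - sse_full) / sse_red
  } else {
    r2_full - r2_red
  }
  structure(list(overall_r2 = r2_full,
                 partial_r2_g = r2_red,
                 partial_r2_gt = partial_gt,
                 interaction_p = interaction_p,
                 interaction_coef = interaction_coef),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report: overall R2 = %.4f | partial R2 (PRS_G) = %.4f | ",
                     "partial R2 (PRS_GT x T | PRS_G) = %.4f\n",
                     "  interaction coef = %.4g, p = %.3g\n"),
              x$overall_r2, x$partial_r2_g, x$partial_r2_gt,
              x$interaction_coef, x$interaction_p))
  invisible(x)
}

rank_bins <- function(score, n_bins) {
  # stable tie-breaking by original order
  r <- order(order(score, seq_along(score)))
  cut(r, breaks = stats::quantile(seq_along(score),
                                  probs = seq(0, 1, length.out = n_bins + 1)),
      include.lowest = TRUE, labels = FALSE)
}

te_and_ci <- function(y, t) {
  y1 <- y[t == 1]; y0 <- y[t == 0]
  te <- mean(y1) - mean(y0)
  half <- 1.959964 * sqrt(stats::var(y1) / length(y1) +
                            stats::var(y0) / length(y0))
  c(te = te, half = half, n1 = length(y1), n0 = length(y0))
}

#' Treatment effect by score quantile
#'
#' Bins samples into `n_bins` score quantiles (ranks with stable tie-breaking
#' on sample order) and reports the within-bin treatment effect (mean treated
#' minus mean control) with a 95% normal-approximation (Welch) confidence
#' interval.
#'
#' @param score stratifying score (e.g. the predictive PRS).
#' @param y phenotype; `t` treatment 0/1.
#' @param t treatment indicator.
#' @param n_bins number of quantile bins (default 4).
#' @return data.frame of class `stratification_result`: columns `bin,
#'   n_treated, n_control, te, ci_low, ci_high`.
#' @export
quantile_treatment_effects <- function(score, y, t, n_bins = 4L) {
  n <- length(score)
  stopifnot(length(y) == n, length(t) == n)
  bins <- rank_bins(score, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bins == b
    if (sum(t[sel] == 1) < 2 || sum(t[sel] == 0) < 2) {
      stop("bin ", b, " has fewer than 2 samples in one arm")
    }
    s <- te_and_ci(y[sel], t[sel])
    data.frame(bin = b, n_treated = s[["n1"]], n_control = s[["n0"]],
               te = s[["te"]], ci_low = s[["te"]] - s[["half"]],
               ci_high = s[["te"]] + s[["half"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratification_result", "data.frame")
  out
}

#' Differential treatment effect across top-percentile cutoffs
#'
#' For each cutoff `c` the samples are split into the top `c` fraction by
#' score (ranks, stable ties) versus the rest, and the differential treatment
#' effect `TE(top) - TE(rest)` is reported with a 95% CI from the Welch
#' variances of the two group contrasts.
#'
#' @param score stratifying score.
#' @param y phenotype; `t` treatment indicator.
#' @param t treatment 0/1.
#' @param cutoffs top fractions in (0, 1) (default 0.1..0.9).
#' @return data.frame of class `stratification_result`: columns `cutoff,
#'   n_top, n_rest, te_top, te_rest, diff_te, ci_low, ci_high`.
#' @export
differential_te_by_cutoff <- function(score, y, t,
                                      cutoffs = seq(0.1, 0.9, by = 0.1)) {
  n <- length(score)
  stopifnot(length(y) == n, length(t) == n)
  r <- order(order(-score, seq_along(score))) # 1 = highest score
  rows <- lapply(cutoffs, function(cf) {
    top <- r <= round(cf * n)
    if (sum(top) < 4 || sum(!top) < 4 ||
        min(sum(t[top] == 1), sum(t[top] == 0),
            sum(t[!top] == 1), sum(t[!top] == 0)) < 2) {
      stop("degenerate group at cutoff ", cf)
    }
    s1 <- te_and_ci(y[top], t[top])
    s0 <- te_and_ci(y[!top], t[!top])
    d <- s1[["te"]] - s0[["te"]]
    half <- sqrt(s1[["half"]]^2 + s0[["half"]]^2)
    data.frame(cutoff = cf, n_top = sum(top), n_rest = sum(!top),
               te_top = s1[["te"]], te_rest = s0[["te"]], diff_te = d,
               ci_low = d - half, ci_high = d + half)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratification_result", "data.frame")
  out
}
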