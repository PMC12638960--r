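#' GWAS summary statistics table
#'
#' @param variant_id,effect_allele,other_allele per-variant identity and
#'   allele orientation (effect sizes refer to `effect_allele`).
#' @param beta per-variant marginal effect estimates.
#' @param se positive standard errors (same units as `beta`).
#' @param p two-sided p-values in (0, 1].
#' @param chr,pos optional chromosome and 1-based position.
#' @param freq,n optional effect-allele frequency and per-variant sample size.
#' @return data.frame of class `sumstats`.
#' @export
sumstats <- function(variant_id, effect_allele, other_allele, beta, se, p,
                     chr = NULL, pos = NULL, freq = NULL, n = NULL) {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id)) {
    stop("duplicate variant id: ", variant_id[duplicated(variant_id)][1L])
  }
  if (any(se <= 0)) stop("se must be positive")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  m <- length(variant_id)
  out <- data.frame(
    variant_id = variant_id,
    chr = if (is.null(chr)) rep(1L, m) else as.integer(chr),
    pos = if (is.null(pos)) seq_len(m) else as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  if (!is.null(freq)) out$freq <- as.numeric(freq)
  if (!is.null(n)) out$n <- as.numeric(n)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Per-SNP weight table
#'
#' @param variant_id unique identifiers.
#' @param effect_allele,other_allele allele orientation of the weights.
#' @param weight finite per-variant weights (pre-trained prognostic effects).
#' @return data.frame of class `weight_table`.
#' @export
weight_table <- function(variant_id, effect_allele, other_allele, weight) {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id)) {
    stop("duplicate variant id: ", variant_id[duplicated(variant_id)][1L])
  }
  if (!all(is.finite(weight))) stop("weights must be finite")
  out <- data.frame(variant_id = variant_id,
                    effect_allele = toupper(as.character(effect_allele)),
                    other_allele = toupper(as.character(other_allele)),
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  class(out) <- c("weight_table", "data.frame")
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Reconcile a weight table with target variant metadata
#'
#' Inner join on variant id. Weights whose alleles are swapped relative to the
#' target orientation have their sign flipped; variants whose alleles cannot
#' be reconciled are dropped. Optionally drops strand-ambiguous (A/T, C/G)
#' variants.
#'
#' @param weights a [weight_table()].
#' @param target_variants data.frame with columns
#'   `id, effect_allele, other_allele` (e.g. `genotype_matrix$variants`).
#' @param drop_palindromic drop A/T and C/G variants when `TRUE`.
#' @return a `weight_table` in the target orientation, with attribute
#'   `"counts"` = c(kept, flipped, dropped).
#' @export
harmonize_weights <- function(weights, target_variants,
                              drop_palindromic = FALSE) {
  tv <- target_variants
  idx <- match(weights$variant_id, tv$id)
  keep <- !is.na(idx)
  n_drop <- sum(!keep)
  w <- weights[keep, , drop = FALSE]
  t_ea <- toupper(tv$effect_allele[idx[keep]])
  t_oa <- toupper(tv$other_allele[idx[keep]])
  same <- w$effect_allele == t_ea & w$other_allele == t_oa
  swapped <- w$effect_allele == t_oa & w$other_allele == t_ea
  ok <- same | swapped
  if (drop_palindromic) ok <- ok & !is_palindromic(t_ea, t_oa)
  n_drop <- n_drop + sum(!ok)
  if (!any(ok)) stop("no variant shared between weights and target")
  w <- w[ok, , drop = FALSE]
  flipped <- swapped[ok]
  out <- weight_table(w$variant_id,
                      t_ea[ok], t_oa[ok],
                      ifelse(flipped, -w$weight, w$weight))
  attr(out, "counts") <- c(kept = nrow(out), flipped = sum(flipped),
                           dropped = n_drop)
  out
}

#' Block-diagonal LD reference from a genotype panel
#'
#' Builds per-block variant correlation matrices from a reference genotype
#' panel. Blocks are formed by a fixed base-pair window per chromosome:
#' consecutive variants are grouped until the span exceeds `window_kb`;
#' correlation between blocks is treated as zero.
#'
#' @param panel a [genotype_matrix()] (reference individuals).
#' @param window_kb block span in kilobases (default 250).
#' @return object of class `ld_reference`: list with `blocks` (each a list
#'   `ids`, `R` symmetric with unit diagonal) and `variants` metadata.
#' @export
ld_reference <- function(panel, window_kb = 250) {
  stopifnot(inherits(panel, "genotype_matrix"))
  v <- panel$variants
  d <- impute_missing(panel)$dosages
  ord <- order(v$chr, v$pos)
  blocks <- list()
  start <- 1L
  while (start <= length(ord)) {
    i <- ord[start]
    end <- start
    while (end < length(ord) &&
           v$chr[ord[end + 1L]] == v$chr[i] &&
           v$pos[ord[end + 1L]] - v$pos[i] <= window_kb * 1000) {
      end <- end + 1L
    }
    idx <- ord[start:end]
    sub <- d[, idx, drop = FALSE]
    sdv <- col_sds(sub)
    R <- diag(length(idx))
    nz <- sdv > 0
    if (sum(nz) > 1L) R[nz, nz] <- stats::cor(sub[, nz, drop = FALSE])
    dimnames(R) <- list(v$id[idx], v$id[idx])
    blocks[[length(blocks) + 1L]] <- list(ids = v$id[idx], R = R)
    start <- end + 1L
  }
  structure(list(blocks = blocks, variants = v), class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("ld_reference: %d variants in %d blocks\n",
              nrow(x$variants), length(x$blocks)))
  invisible(x)
}

ld_lookup_r2 <- function(ld) {
  # map variant id -> (block index, within-block index)
  ids <- unlist(lapply(ld$blocks, `[[`, "ids"))
  blk <- rep(seq_along(ld$blocks), vapply(ld$blocks, function(b)
    length(b$ids), 1L))
  within <- unlist(lapply(ld$blocks, function(b) seq_along(b$ids)))
  list(ids = ids, blk = blk, within = within)
}

#' Clumping + p-value thresholding baseline
#'
#' Greedy clumping: variants are visited by ascending p-value (ties broken by
#' variant id); a variant is retained unless its squared correlation with an
#' already-retained variant within `window_kb` exceeds `r2_threshold`. For
#' each p-value threshold, retained variants with `p <= threshold` keep their
#' marginal effect as weight and all others get zero. When `tuning_data` is
#' supplied the threshold maximizing the prognostic R^2 (phenotype ~ PRS_G)
#' on it is returned; otherwise the most permissive threshold.
#'
#' @param stats a [sumstats()] with positions.
#' @param ld an [ld_reference()] covering the variants (correlations outside
#'   its blocks are zero).
#' @param r2_threshold squared-correlation cutoff (1 disables clumping).
#' @param window_kb clumping window in kilobases.
#' @param p_thresholds nonempty vector of p-value cutoffs.
#' @param tuning_data optional [pgx_cohort()] used to pick the threshold.
#' @return a [weight_table()] (zero weights included) with attributes
#'   `"retained"` (clump-retained ids) and `"p_threshold"` (selected cutoff).
#' @export
clump_and_threshold <- function(stats, ld, r2_threshold = 0.1,
                                window_kb = 250,
                                p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3,
                                                 0.01, 0.05, 0.1, 0.5, 1),
                                tuning_data = NULL) {
  if (length(p_thresholds) == 0L) stop("p_thresholds must be nonempty")
  s <- stats[order(stats$p, stats$variant_id), , drop = FALSE]
  lut <- ld_lookup_r2(ld)
  pos_of <- stats$pos[match(lut$ids, stats$variant_id)]
  retained <- character(0)
  retained_key <- integer(0) # rows into lut for retained variants
  for (i in seq_len(nrow(s))) {
    id <- s$variant_id[i]
    k <- match(id, lut$ids)
    ok <- TRUE
    if (r2_threshold < 1 && !is.na(k) && length(retained_key)) {
      same_block <- retained_key[lut$blk[retained_key] == lut$blk[k]]
      if (length(same_block)) {
        near <- same_block[abs(pos_of[same_block] - s$pos[i]) <=
                             window_kb * 1000]
        if (length(near)) {
          R <- ld$blocks[[lut$blk[k]]]$R
          r2 <- R[lut$within[k], lut$within[near]]^2
          if (any(r2 > r2_threshold)) ok <- FALSE
        }
      }
    }
    if (ok) {
      retained <- c(retained, id)
      if (!is.na(k)) retained_key <- c(retained_key, k)
    }
  }
  p_thresholds <- sort(p_thresholds)
  make_weights <- function(thr) {
    w <- ifelse(stats$variant_id %in% retained & stats$p <= thr,
                stats$beta, 0)
    weight_table(stats$variant_id, stats$effect_allele,
                 stats$other_allele, w)
  }
  if (!any(stats$p[stats$variant_id %in% retained] <= max(p_thresholds))) {
    warning("no variant passes any p-value threshold; all weights zero")
    out <- make_weights(max(p_thresholds))
    attr(out, "retained") <- retained
    attr(out, "p_threshold") <- max(p_thresholds)
    return(out)
  }
  best_thr <- max(p_thresholds)
  if (!is.null(tuning_data)) {
    best_r2 <- -Inf
    for (thr in p_thresholds) {
      wt <- make_weights(thr)
      if (all(wt$weight == 0)) next
      ep <- effect_pair(wt$weight, rep(0, nrow(wt)), wt$variant_id)
      prs <- compute_prs(tuning_data$genotypes, ep,
                         effect_alleles = wt$effect_allele,
                         other_alleles = wt$other_allele)
      if (stats::sd(prs$prs_g) == 0) next
      r2 <- summary(stats::lm(tuning_data$phenotype ~ prs$prs_g))$r.squared
      if (r2 > best_r2 + 1e-12) {
        best_r2 <- r2
        best_thr <- thr
      }
    }
  }
  out <- make_weights(best_thr)
  attr(out, "retained") <- retained
  attr(out, "p_threshold") <- best_thr
  out
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Sparse summary-statistic lasso baseline
#'
#' A self-contained sparse baseline operating on GWAS summary statistics and
#' a block LD reference. Per LD block it minimizes
#' `beta' ((1-s) R + s I) beta - 2 beta' r + l1 ||beta||_1`
#' over standardized marginal effects `r_j = beta_j / (se_j * sqrt(n_j))`, by
#' cyclic coordinate descent with soft-thresholding (converged when the
#' largest coordinate change drops below 1e-6). The `l1` value is chosen by
#' pseudo-validation -- maximizing `beta' r / sqrt(beta' ((1-s)R + sI) beta)`,
#' the summary-statistic analogue of the correlation between the implied PRS
#' and the phenotype -- unless `tuning_data` supplies an individual-level
#' cohort, in which case the prognostic R^2 on it decides.
#'
#' @param stats a [sumstats()]; needs column `n` (per-variant sample size),
#'   else `n_base`.
#' @param ld an [ld_reference()] aligned with `stats` (same orientation).
#' @param l1_grid decreasing or arbitrary positive penalties to try.
#' @param shrink_s LD shrinkage `s` in (0, 1]; `s = 1` ignores LD.
#' @param n_base fallback GWAS sample size when `stats$n` is absent.
#' @param tuning_data optional [pgx_cohort()] for validation-based selection.
#' @param max_sweeps coordinate-descent sweep cap per block.
#' @return a [weight_table()] on the standardized-dosage scale, with
#'   attributes `"l1"` (selected penalty) and `"pseudo_score"`.
#' @export
fit_sparse_sumstat_baseline <- function(stats, ld,
                                        l1_grid = exp(seq(log(0.2),
                                                          log(0.002),
                                                          length.out = 20)),
                                        shrink_s = 0.5, n_base = NULL,
                                        tuning_data = NULL,
                                        max_sweeps = 1000L) {
  if (shrink_s <= 0 || shrink_s > 1) stop("shrink_s must be in (0, 1]")
  nvec <- if (!is.null(stats$n)) stats$n else {
    if (is.null(n_base)) stop("supply stats$n or n_base")
    rep(n_base, nrow(stats))
  }
  r_all <- stats$beta / (stats$se * sqrt(nvec))
  names(r_all) <- stats$variant_id
  blocks <- lapply(ld$blocks, function(b) {
    keep <- b$ids %in% stats$variant_id
    if (!any(keep)) return(NULL)
    ids <- b$ids[keep]
    R <- b$R[keep, keep, drop = FALSE]
    A <- (1 - shrink_s) * R + shrink_s * diag(nrow(R))
    list(ids = ids, A = A, r = r_all[ids])
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (!length(blocks)) stop("LD reference shares no variant with stats")

  solve_block <- function(b, l1, beta = numeric(length(b$r))) {
    p <- length(b$r)
    if (p == 1L) return(soft_threshold(b$r, l1 / 2))
    thr <- l1 / 2
    Abeta <- as.numeric(b$A %*% beta)
    for (sweep in seq_len(max_sweeps)) {
      delta <- 0
      for (j in seq_len(p)) {
        zj <- b$r[j] - (Abeta[j] - b$A[j, j] * beta[j])
        new <- if (zj > thr) (zj - thr) / b$A[j, j]
               else if (zj < -thr) (zj + thr) / b$A[j, j] else 0
        if (new != beta[j]) {
          Abeta <- Abeta + b$A[, j] * (new - beta[j])
          delta <- max(delta, abs(new - beta[j]))
          beta[j] <- new
        }
      }
      if (delta < 1e-6) return(beta)
    }
    stop("coordinate descent failed to converge in block containing ",
         b$ids[1L])
  }

  # solve the whole path per block, warm-starting from the sparser solution
  path <- sort(unique(l1_grid), decreasing = TRUE)
  ids_all <- unlist(lapply(blocks, `[[`, "ids"))
  path_betas <- lapply(path, function(...) NULL)
  warm <- lapply(blocks, function(b) numeric(length(b$r)))
  for (k in seq_along(path)) {
    warm <- Map(function(b, w) solve_block(b, path[k], w), blocks, warm)
    beta <- unlist(warm)
    names(beta) <- ids_all
    path_betas[[k]] <- beta
  }
  fit_grid <- function(l1) path_betas[[match(l1, path)]]

  pseudo_score <- function(beta) {
    num <- 0; den <- 0
    off <- 0
    for (b in blocks) {
      p <- length(b$r)
      bb <- beta[off + seq_len(p)]
      num <- num + sum(bb * b$r)
      den <- den + as.numeric(t(bb) %*% b$A %*% bb)
      off <- off + p
    }
    if (den <= 0) return(0)
    num / sqrt(den)
  }

  best <- NULL
  best_score <- -Inf
  best_l1 <- NA_real_
  for (l1 in path) {
    beta <- fit_grid(l1)
    if (!is.null(tuning_data)) {
      ids <- names(beta)
      ii <- match(ids, stats$variant_id)
      if (all(beta == 0)) next
      ep <- effect_pair(beta, rep(0, length(beta)), ids)
      prs <- compute_prs(tuning_data$genotypes, ep,
                         effect_alleles = stats$effect_allele[ii],
                         other_alleles = stats$other_allele[ii])
      score <- if (stats::sd(prs$prs_g) == 0) -Inf else
        summary(stats::lm(tuning_data$phenotype ~ prs$prs_g))$r.squared
    } else {
      score <- pseudo_score(unname(beta))
    }
    if (score > best_score + 1e-12) {
      best_score <- score
      best <- beta
      best_l1 <- l1
    }
  }
  if (is.null(best)) best <- fit_grid(min(l1_grid))
  ids <- names(best)
  ii <- match(ids, stats$variant_id)
  out <- weight_table(ids, stats$effect_allele[ii], stats$other_allele[ii],
                      unname(best))
  attr(out, "l1") <- best_l1
  attr(out, "pseudo_score") <- best_score
  out
}
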