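#' Simulation scenario for linked disease / drug-response architectures
#'
#' Collects every generative parameter of the simulator: a spike-and-slab
#' trivariate effect model linking disease effects (`mu`), prognostic
#' drug-response effects (`beta`) and predictive genotype-by-treatment
#' effects (`alpha`); LD-structured genotypes; normally perturbed disease
#' summary statistics; and a two-arm phenotype with target heritability.
#'
#' @param m total SNP count.
#' @param p_causal causal proportion in (0, 1].
#' @param h_t2 heritability of the disease trait in the base cohort; fixes
#'   the per-causal effect variance `h_t2 / (m * p_causal)` so total genetic
#'   variance is `h_t2` regardless of `m`.
#' @param h_d2 target heritability of the drug response in the target cohort.
#' @param rho_dt disease/prognostic effect correlation in [0, 1).
#' @param rho_e prognostic/predictive effect correlation in [0, 1).
#' @param gamma scale factor on predictive effects (`alpha* = gamma * alpha`).
#' @param beta_t treatment main effect (trait units).
#' @param n_train,n_test,n_base target-cohort training/testing sizes and the
#'   base disease-GWAS sample size.
#' @param shared_fraction fraction of causal SNPs affecting both phenotypes;
#'   `disease_only` and `drug_only` give the remaining splits (must sum to 1
#'   with `shared_fraction`).
#' @param disease_only,drug_only fractions of causal SNPs specific to the
#'   disease (`beta = alpha = 0`) or to the drug response (`mu = 0`).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param ld_block_size SNPs per LD block; `block_rho` the within-block
#'   latent correlation; `ld_type` "exchangeable" or "ar1".
#' @param block_rho within-block correlation of the latent Gaussian.
#' @param ld_type correlation structure of a block.
#' @param seed default seed carried with the scenario.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(m = 2000L, p_causal = 0.01, h_t2 = 0.5, h_d2 = 0.3,
                         rho_dt = 0.5, rho_e = 0.5, gamma = 1, beta_t = 0.5,
                         n_train = 4000L, n_test = 1000L, n_base = 100000L,
                         shared_fraction = 1, disease_only = 0, drug_only = 0,
                         maf_range = c(0.05, 0.5), ld_block_size = 20L,
                         block_rho = 0.3,
                         ld_type = c("exchangeable", "ar1"), seed = 1L) {
  ld_type <- match.arg(ld_type)
  if (p_causal <= 0 || p_causal > 1) stop("p_causal must be in (0, 1]")
  if (h_t2 <= 0 || h_t2 >= 1 || h_d2 <= 0 || h_d2 >= 1) {
    stop("heritabilities must be in (0, 1)")
  }
  if (abs(shared_fraction + disease_only + drug_only - 1) > 1e-8) {
    stop("shared_fraction + disease_only + drug_only must equal 1")
  }
  if (m * p_causal < 1) stop("expected causal count below 1")
  if (min(maf_range) <= 0 || max(maf_range) > 0.5) {
    stop("maf_range must lie in (0, 0.5]")
  }
  build_omega(rho_dt, rho_e) # validates correlations / PSD
  structure(list(m = as.integer(m), p_causal = p_causal, h_t2 = h_t2,
                 h_d2 = h_d2, rho_dt = rho_dt, rho_e = rho_e, gamma = gamma,
                 beta_t = beta_t, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), n_base = as.integer(n_base),
                 shared_fraction = shared_fraction,
                 disease_only = disease_only, drug_only = drug_only,
                 maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size),
                 block_rho = block_rho, ld_type = ld_type,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Trivariate effect correlation matrix
#'
#' `Omega` couples the disease effect `mu`, the prognostic effect `beta` and
#' the predictive effect `alpha` of a causal SNP:
#' corr(mu, beta) = rho_dt, corr(beta, alpha) = rho_e,
#' corr(mu, alpha) = rho_dt * rho_e.
#'
#' @param rho_dt,rho_e correlations in [0, 1).
#' @return 3x3 correlation matrix (verified positive semidefinite).
#' @export
build_omega <- function(rho_dt, rho_e) {
  if (rho_dt < 0 || rho_dt >= 1 || rho_e < 0 || rho_e >= 1) {
    stop("rho_dt and rho_e must be in [0, 1)")
  }
  omega <- matrix(c(1, rho_dt, rho_dt * rho_e,
                    rho_dt, 1, rho_e,
                    rho_dt * rho_e, rho_e, 1), 3, 3,
                  dimnames = list(c("mu", "beta", "alpha"),
                                  c("mu", "beta", "alpha")))
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("Omega is not positive semidefinite")
  }
  omega
}

sym_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

#' Draw spike-and-slab effect triples
#'
#' Each SNP is causal with probability `p_causal`; causal triples
#' `(mu, beta, alpha)` are multivariate normal with covariance
#' `h_t2 / (m * p_causal) * Omega(rho_dt, rho_e)`. With
#' `shared_fraction < 1` the causal set is partitioned uniformly at random
#' into shared, disease-only (`beta = alpha = 0`, `mu` from its marginal) and
#' drug-only (`mu = 0`, `(beta, alpha)` from the bivariate marginal with
#' correlation `rho_e`) groups, preserving each component's marginal
#' variance. Effects are on the standardized-dosage scale.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional override of `scenario$seed`.
#' @return object of class `effect_triple`: `mu`, `beta`, `alpha` (length m,
#'   non-causal entries exactly 0), logical `causal`, character `group`.
#' @export
simulate_effects <- function(scenario, seed = scenario$seed) {
  m <- scenario$m
  s2 <- scenario$h_t2 / (m * scenario$p_causal)
  omega <- build_omega(scenario$rho_dt, scenario$rho_e)
  half3 <- sym_sqrt(s2 * omega)
  half2 <- sym_sqrt(s2 * omega[2:3, 2:3])
  mu <- beta <- alpha <- numeric(m)
  group <- rep("none", m)
  with_seed(seed, {
    causal <- which(stats::runif(m) < scenario$p_causal)
    mc <- length(causal)
    if (mc > 0) {
      n_dis <- floor(scenario$disease_only * mc)
      n_drug <- floor(scenario$drug_only * mc)
      perm <- sample(causal)
      dis <- perm[seq_len(n_dis)]
      drug <- perm[n_dis + seq_len(n_drug)]
      both <- setdiff(perm, c(dis, drug))
      group[dis] <- "disease_only"
      group[drug] <- "drug_only"
      group[both] <- "both"
      if (length(both)) {
        z <- matrix(stats::rnorm(3 * length(both)), ncol = 3) %*% half3
        mu[both] <- z[, 1]; beta[both] <- z[, 2]; alpha[both] <- z[, 3]
      }
      if (length(dis)) mu[dis] <- stats::rnorm(length(dis), sd = sqrt(s2))
      if (length(drug)) {
        z <- matrix(stats::rnorm(2 * length(drug)), ncol = 2) %*% half2
        beta[drug] <- z[, 1]; alpha[drug] <- z[, 2]
      }
    }
  })
  structure(list(mu = mu, beta = beta, alpha = alpha,
                 causal = group != "none", group = group),
            class = "effect_triple")
}

#' Simulate LD-structured genotype dosages
#'
#' Per block of `ld_block_size` SNPs, a latent multivariate normal with
#' exchangeable (or AR-1) correlation `block_rho` is thresholded into
#' Hardy-Weinberg dosages {0, 1, 2} at a minor-allele frequency drawn
#' uniformly from `maf_range`; blocks are independent. Variants are placed
#' 2 kb apart on one chromosome.
#'
#' @param n samples; `m` SNPs.
#' @param m number of variants.
#' @param maf_range MAF range in (0, 0.5].
#' @param ld_block_size,block_rho,ld_type block structure (see
#'   [sim_scenario()]).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with attribute `"maf"` (the drawn
#'   frequencies, effect-allele oriented).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 20L, block_rho = 0.3,
                               ld_type = c("exchangeable", "ar1"),
                               seed = 1L) {
  ld_type <- match.arg(ld_type)
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    z <- matrix(stats::rnorm(n * m), n, m)
    if (block_rho > 0) {
      starts <- seq(1L, m, by = ld_block_size)
      for (s in starts) {
        idx <- s:min(s + ld_block_size - 1L, m)
        if (length(idx) < 2L) next
        if (ld_type == "exchangeable") {
          shared <- stats::rnorm(n)
          z[, idx] <- sqrt(block_rho) * shared +
            sqrt(1 - block_rho) * z[, idx]
        } else {
          for (k in seq_along(idx)[-1]) {
            z[, idx[k]] <- block_rho * z[, idx[k - 1L]] +
              sqrt(1 - block_rho^2) * z[, idx[k]]
          }
        }
      }
    }
    # HWE thresholds: P(0) = (1-f)^2, P(1) = 2f(1-f), P(2) = f^2
    c0 <- stats::qnorm((1 - maf)^2)
    c1 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
    d <- matrix(0, n, m)
    d[sweep(z, 2L, c0, ">")] <- 1
    d[sweep(z, 2L, c1, ">")] <- 2
  })
  g <- genotype_matrix(d, paste0("snp", seq_len(m)),
                       rep("A", m), rep("G", m),
                       sample_ids = paste0("S", seq_len(n)),
                       chr = rep(1L, m), pos = 1L + (seq_len(m) - 1L) * 2000L)
  attr(g, "maf") <- maf
  g
}

#' Simulate disease GWAS summary statistics
#'
#' Observed effects are drawn as `mu_hat_j ~ N(mu_j, s_j^2)`; two-sided
#' p-values are `2 * (1 - Phi(|mu_hat_j / s_j|))`. When no `se` vector is
#' supplied, `s_j = 1 / sqrt(2 n_base f_j (1 - f_j))` (the standard error of
#' a per-allele effect for a standardized trait), and the true standardized
#' effects are converted to the per-allele scale
#' (`mu / sqrt(2 f (1 - f))`) before perturbation so the z-scores are
#' consistent.
#'
#' @param effects an [effect_triple()] (its `mu` component is used).
#' @param freq effect-allele frequencies (length m), e.g. `attr(g, "maf")`.
#' @param n_base base-cohort GWAS sample size.
#' @param se optional per-variant standard errors; when given, `mu` is
#'   perturbed on its own (standardized) scale with these SEs.
#' @param variant_ids,effect_alleles,other_alleles variant metadata; defaults
#'   match [simulate_genotypes()].
#' @param chr,pos optional positions.
#' @param seed integer seed.
#' @return a [sumstats()] table with columns `freq` and `n`.
#' @export
simulate_sumstats <- function(effects, freq, n_base, se = NULL,
                              variant_ids = NULL, effect_alleles = NULL,
                              other_alleles = NULL, chr = NULL, pos = NULL,
                              seed = 1L) {
  mu <- effects$mu
  m <- length(mu)
  if (is.null(se)) {
    if (length(freq) != m) stop("freq must have one entry per variant")
    se <- 1 / sqrt(2 * n_base * freq * (1 - freq))
    mu <- mu / sqrt(2 * freq * (1 - freq))
  }
  if (any(se <= 0)) stop("se must be positive")
  with_seed(seed, {
    mu_hat <- stats::rnorm(m, mean = mu, sd = se)
  })
  z <- abs(mu_hat / se)
  p <- pmax(2 * stats::pnorm(z, lower.tail = FALSE), .Machine$double.xmin)
  sumstats(
    variant_id = if (is.null(variant_ids)) paste0("snp", seq_len(m)) else variant_ids,
    effect_allele = if (is.null(effect_alleles)) rep("A", m) else effect_alleles,
    other_allele = if (is.null(other_alleles)) rep("G", m) else other_alleles,
    beta = mu_hat, se = se, p = p, chr = chr,
    pos = if (is.null(pos)) 1L + (seq_len(m) - 1L) * 2000L else pos,
    freq = freq, n = rep(n_base, m))
}

#' Simulate two-arm drug-response phenotypes
#'
#' `Y = beta_t T + Z beta + (Z o T) gamma alpha + eps`, with treatment
#' `T ~ Bernoulli(0.5)`, `Z` the in-sample standardized dosages and
#' `eps ~ N(0, sigma^2)` where `sigma^2 = Var_emp(genetic) (1 - h_d2) /
#' h_d2`, so the realized genetic variance fraction of `Y - beta_t T`
#' matches the target heritability in each generated dataset.
#'
#' @param g a [genotype_matrix()].
#' @param effects an [effect_triple()] aligned with `g` columns.
#' @param scenario a [sim_scenario()] (uses `beta_t`, `gamma`, `h_d2`).
#' @param seed integer seed.
#' @return a [pgx_cohort()] with attribute `"genetic"` (the noiseless
#'   genetic component) and `"sigma2"`.
#' @export
simulate_phenotypes <- function(g, effects, scenario, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  z <- standardize_genotypes(impute_missing(g))$mat
  n <- nrow(z)
  with_seed(seed, {
    t <- stats::rbinom(n, 1, 0.5)
    genetic <- as.numeric(z %*% effects$beta) +
      as.numeric((z * t) %*% (scenario$gamma * effects$alpha))
    vg <- stats::var(genetic)
    if (vg == 0) stop("all genetic effects are zero; phenotype undefined")
    sigma2 <- vg * (1 - scenario$h_d2) / scenario$h_d2
    y <- scenario$beta_t * t + genetic + stats::rnorm(n, sd = sqrt(sigma2))
  })
  cohort <- pgx_cohort(g, t, y)
  attr(cohort, "genetic") <- genetic
  attr(cohort, "sigma2") <- sigma2
  cohort
}

score_disease_weights <- function(weights, train, test_g) {
  ep <- align_weights_to_cohort(weights, train)
  active <- which(ep$beta_g != 0)
  if (!length(active)) stop("disease baseline produced no nonzero weight")
  ids <- ep$variant_ids[active]
  tr_d <- impute_missing(subset_genotypes(train$genotypes,
                                          variants = ids))
  std <- standardize_genotypes(tr_d)
  te_d <- impute_missing(subset_genotypes(test_g, variants = ids))
  z <- standardize_genotypes(te_d, reference_stats = std$stats)$mat
  prs <- as.numeric(z %*% ep$beta_g[active])
  # a disease PRS has no interaction component; the proportionality
  # assumption scores both terms with the same vector
  list(prs_g = prs, prs_gt = prs)
}

#' Run a full simulation scenario end to end
#'
#' Per repeat: draw effect triples, LD-structured genotypes for training plus
#' independent testing samples, two-arm phenotypes, and disease summary
#' statistics; fit the disease baseline (summary-statistic lasso or
#' clumping+thresholding, using the training genotypes as LD reference);
#' tune and fit each requested strategy on the training cohort by inner
#' cross-validation; and evaluate every method on the independent test set.
#'
#' @param scenario a [sim_scenario()].
#' @param strategies character vector of strategy names ("M1".."M6").
#' @param baseline "lasso" (pseudo-validated sparse summary-statistic lasso)
#'   or "ct" (clumping+thresholding tuned on the training cohort).
#' @param n_repeats number of repeats.
#' @param seed master seed; repeat r uses a seed derived from it.
#' @param grid a [tune_grid()].
#' @param k_inner inner folds for tuning.
#' @param include_baseline evaluate the raw disease PRS as its own method.
#' @return data.frame with one row per repeat x method: columns `repeat_id,
#'   method, overall_r2, partial_r2_g, partial_r2_gt, interaction_p,
#'   interaction_coef, n_active`; failures are collected in the `"errors"`
#'   attribute instead of aborting the batch.
#' @export
run_scenario <- function(scenario, strategies = "M1",
                         baseline = c("lasso", "ct"), n_repeats = 1L,
                         seed = scenario$seed, grid = tune_grid(),
                         k_inner = 4L, include_baseline = TRUE) {
  baseline <- match.arg(baseline)
  rows <- list()
  errors <- list()
  for (rep_i in seq_len(n_repeats)) {
    res <- tryCatch(
      run_scenario_once(scenario, strategies, baseline,
                        seed = derive_seed(seed, rep_i), grid = grid,
                        k_inner = k_inner,
                        include_baseline = include_baseline),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        list(repeat_id = rep_i, message = conditionMessage(res))
    } else {
      res$repeat_id <- rep_i
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(repeat_id = integer(0), method = character(0))
  attr(out, "errors") <- errors
  out
}

run_scenario_once <- function(scenario, strategies, baseline, seed, grid,
                              k_inner, include_baseline) {
  n_all <- scenario$n_train + scenario$n_test
  effects <- simulate_effects(scenario, seed = derive_seed(seed, 1L))
  g_all <- simulate_genotypes(n_all, scenario$m, scenario$maf_range,
                              scenario$ld_block_size, scenario$block_rho,
                              scenario$ld_type, seed = derive_seed(seed, 2L))
  cohort_all <- simulate_phenotypes(g_all, effects, scenario,
                                    seed = derive_seed(seed, 3L))
  idx_train <- seq_len(scenario$n_train)
  train <- subset_cohort(cohort_all, idx_train)
  test <- subset_cohort(cohort_all, scenario$n_train + seq_len(scenario$n_test))
  ss <- simulate_sumstats(effects, attr(g_all, "maf"), scenario$n_base,
                          seed = derive_seed(seed, 4L))
  ld <- ld_reference(train$genotypes)
  weights <- if (baseline == "lasso") {
    fit_sparse_sumstat_baseline(ss, ld)
  } else {
    clump_and_threshold(ss, ld, tuning_data = train)
  }
  if (all(weights$weight == 0)) stop("baseline produced all-zero weights")
  out <- list()
  if (include_baseline) {
    p <- score_disease_weights(weights, train, test$genotypes)
    ev <- evaluate_prs(test$phenotype, test$treatment, NULL,
                       p$prs_g, p$prs_gt)
    out[[length(out) + 1L]] <- data.frame(
      method = paste0("disease_", baseline),
      overall_r2 = ev$overall_r2, partial_r2_g = ev$partial_r2_g,
      partial_r2_gt = ev$partial_r2_gt, interaction_p = ev$interaction_p,
      interaction_coef = ev$interaction_coef,
      n_active = sum(weights$weight != 0), stringsAsFactors = FALSE)
  }
  for (s in strategies) {
    strat <- strategy_config(s)
    fit <- fit_tl_prs(train, weights, strat, grid,
                      seed = derive_seed(seed, 5L), k_inner = k_inner)
    p <- predict(fit, test$genotypes)
    ev <- evaluate_prs(test$phenotype, test$treatment, NULL,
                       p$prs_g, p$prs_gt)
    out[[length(out) + 1L]] <- data.frame(
      method = s, overall_r2 = ev$overall_r2,
      partial_r2_g = ev$partial_r2_g, partial_r2_gt = ev$partial_r2_gt,
      interaction_p = ev$interaction_p,
      interaction_coef = ev$interaction_coef,
      n_active = length(fit$effects$beta_g), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
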