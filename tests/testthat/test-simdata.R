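test_that("omega matrix follows the correlation parameterization and is PSD", {
  expect_equal(build_omega(0, 0), diag(3), ignore_attr = TRUE)
  om <- build_omega(0.5, 0.5)
  expect_equal(om[1, 2], 0.5)
  expect_equal(om[2, 3], 0.5)
  expect_equal(om[1, 3], 0.25)
  expect_equal(om, t(om))
  for (rdt in c(0, 0.2, 0.5, 0.8, 0.99)) {
    for (re in c(0, 0.2, 0.5, 0.8, 0.99)) {
      ev <- eigen(build_omega(rdt, re), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
    }
  }
  expect_error(build_omega(1, 0.5), "\\[0, 1\\)")
  expect_error(build_omega(0.5, -0.1), "\\[0, 1\\)")
})

test_that("effect draws reproduce the target moments", {
  sc <- sim_scenario(m = 50000, p_causal = 1, h_t2 = 0.5, rho_dt = 0.5,
                     rho_e = 0.8, seed = 70)
  eff <- simulate_effects(sc)
  v_target <- sc$h_t2 / sc$m
  for (comp in c("mu", "beta", "alpha")) {
    expect_lt(abs(var(eff[[comp]]) / v_target - 1), 0.03)
  }
  cs <- eff$causal
  expect_lt(abs(cor(eff$beta[cs], eff$alpha[cs]) - 0.8), 0.02)
  expect_lt(abs(cor(eff$mu[cs], eff$beta[cs]) - 0.5), 0.02)
  expect_lt(abs(cor(eff$mu[cs], eff$alpha[cs]) - 0.4), 0.02)

  # non-causal entries are exactly zero under a sparse scenario
  sc2 <- sim_scenario(m = 5000, p_causal = 0.05, seed = 71)
  eff2 <- simulate_effects(sc2)
  expect_true(all(eff2$mu[!eff2$causal] == 0))
  expect_true(all(eff2$beta[!eff2$causal] == 0))
  expect_true(all(eff2$alpha[!eff2$causal] == 0))
})

test_that("shared/disease-only/drug-only splits have the stated structure", {
  sc <- sim_scenario(m = 4000, p_causal = 0.5, shared_fraction = 0.6,
                     disease_only = 0.2, drug_only = 0.2, seed = 72)
  eff <- simulate_effects(sc)
  mc <- sum(eff$causal)
  expect_equal(sum(eff$group == "disease_only"), floor(0.2 * mc))
  expect_equal(sum(eff$group == "drug_only"), floor(0.2 * mc))
  dis <- eff$group == "disease_only"
  expect_true(all(eff$beta[dis] == 0 & eff$alpha[dis] == 0))
  expect_true(all(eff$mu[dis] != 0))
  drug <- eff$group == "drug_only"
  expect_true(all(eff$mu[drug] == 0))
  expect_true(all(eff$beta[drug] != 0))
  # group-specific marginals preserve the per-component variance
  s2 <- sc$h_t2 / (sc$m * sc$p_causal)
  expect_lt(abs(var(eff$mu[dis]) / s2 - 1), 0.15)
  expect_lt(abs(var(eff$beta[drug]) / s2 - 1), 0.15)
  expect_lt(abs(cor(eff$beta[drug], eff$alpha[drug]) - sc$rho_e), 0.1)
  expect_error(sim_scenario(shared_fraction = 0.7, disease_only = 0.2,
                            drug_only = 0.2), "equal 1")
})

test_that("genotype simulator respects MAF, LD blocks and the seed", {
  g <- simulate_genotypes(5000, 60, maf_range = c(0.1, 0.4),
                          ld_block_size = 10, block_rho = 0, seed = 73)
  maf <- attr(g, "maf")
  freq_hat <- colMeans(g$dosages) / 2
  expect_lt(max(abs(freq_hat - maf)), 4 * sqrt(0.25 / (2 * 5000)) + 0.02)
  cors <- cor(g$dosages[, 1:10])
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05) # block_rho = 0

  g2 <- simulate_genotypes(2000, 20, ld_block_size = 10, block_rho = 0.6,
                           seed = 74)
  c_in <- cor(g2$dosages[, 1:10])
  c_out <- cor(g2$dosages[, 1:10], g2$dosages[, 11:20])
  expect_gt(mean(c_in[upper.tri(c_in)]), 0.2)  # within-block LD present
  expect_lt(max(abs(c_out)), 0.1)              # blocks independent

  expect_identical(simulate_genotypes(100, 10, seed = 75)$dosages,
                   simulate_genotypes(100, 10, seed = 75)$dosages)
  expect_true(all(g$dosages %in% c(0, 1, 2)))
})

test_that("summary-statistic simulator produces consistent z and p values", {
  sc <- sim_scenario(m = 10000, p_causal = 0.01, seed = 76)
  eff <- simulate_effects(sc)
  # null p-values are uniform when all true effects are zero
  eff0 <- eff
  eff0$mu <- rep(0, sc$m)
  ss0 <- simulate_sumstats(eff0, freq = rep(0.3, sc$m), n_base = 1e5,
                           se = rep(1, sc$m), seed = 77)
  expect_gt(suppressWarnings(ks.test(ss0$p, "punif")$p.value), 0.01)

  # p is the two-sided normal tail of |beta/se|; z = 1.959964 -> p = 0.05
  ss <- simulate_sumstats(eff, freq = runif(sc$m, 0.05, 0.5), n_base = 1e5,
                          seed = 78)
  expect_equal(ss$p, 2 * pnorm(abs(ss$beta / ss$se), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(2 * pnorm(1.959964, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)

  # vanishing SE with nonzero effect drives p to zero
  ss2 <- simulate_sumstats(list(mu = c(0.5, 0.5)), freq = c(0.3, 0.3),
                           n_base = 1e5, se = c(1e-8, 1e-12), seed = 79)
  expect_lt(max(ss2$p), 1e-100)
})

test_that("phenotype simulator hits the target heritability", {
  sc <- sim_scenario(m = 400, p_causal = 0.1, h_d2 = 0.3, gamma = 1,
                     beta_t = 0.5, seed = 80)
  eff <- simulate_effects(sc)
  g <- simulate_genotypes(10000, sc$m, seed = 81)
  coh <- simulate_phenotypes(g, eff, sc, seed = 82)
  genetic <- attr(coh, "genetic")
  resid_y <- coh$phenotype - sc$beta_t * coh$treatment
  expect_lt(abs(var(genetic) / var(resid_y) - sc$h_d2), 0.02)

  # gamma = 0 removes the interaction contribution entirely
  sc0 <- sc; sc0$gamma <- 0
  coh0 <- simulate_phenotypes(g, eff, sc0, seed = 82)
  z <- standardize_genotypes(g$dosages)$mat
  expect_equal(attr(coh0, "genetic"), as.numeric(z %*% eff$beta))

  # beta_t = 0: arms differ only by sampling noise
  scn <- sc; scn$beta_t <- 0
  cohn <- simulate_phenotypes(g, eff, scn, seed = 83)
  tt <- t.test(cohn$phenotype[cohn$treatment == 1],
               cohn$phenotype[cohn$treatment == 0])
  expect_gt(tt$p.value, 1e-4)

  # all-zero effects are rejected
  effz <- eff; effz$beta <- rep(0, sc$m); effz$alpha <- rep(0, sc$m)
  expect_error(simulate_phenotypes(g, effz, sc, seed = 82), "zero")
})

test_that("total genetic variance is invariant to the SNP count", {
  # the h_t2/(m p) scaling conserves total genetic variance in expectation;
  # average a few effect draws to tame the chi-square spread of sum(beta^2)
  h <- numeric(2)
  for (k in 1:2) {
    m <- c(500, 5000)[k]
    sc <- sim_scenario(m = m, p_causal = 0.5, h_t2 = 0.5, seed = 84)
    g <- simulate_genotypes(4000, m, block_rho = 0, seed = 85)
    z <- standardize_genotypes(g$dosages)$mat
    h[k] <- mean(vapply(1:5, function(i) {
      eff <- simulate_effects(sc, seed = 84 + i)
      var(as.numeric(z %*% eff$beta))
    }, numeric(1)))
  }
  expect_lt(abs(h[1] - h[2]), 0.08 * 0.5) # both close to h_t2 = 0.5
  expect_lt(abs(h[1] - 0.5), 0.06)
  expect_lt(abs(h[2] - 0.5), 0.06)
})

test_that("run_scenario is reproducible and collects failures", {
  sc <- sim_scenario(m = 120, n_train = 300, n_test = 200, p_causal = 0.1,
                     n_base = 5e4, seed = 86)
  r1 <- run_scenario(sc, strategies = "M5", baseline = "ct",
                     n_repeats = 2, seed = 86, grid = tune_grid(1, 0.5, 5L))
  r2 <- run_scenario(sc, strategies = "M5", baseline = "ct",
                     n_repeats = 2, seed = 86, grid = tune_grid(1, 0.5, 5L))
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4L) # baseline + M5, two repeats
  expect_setequal(unique(r1$method), c("disease_ct", "M5"))
  expect_true(all(is.finite(r1$overall_r2)))
})

test_that("fitted predictive effects track the true interaction effects", {
  cors <- sapply(1:4, function(i) {
    sc <- sim_scenario(m = 500, n_train = 2000, n_test = 500,
                       p_causal = 0.05, h_d2 = 0.5, gamma = 1, seed = 300)
    s <- pgxtl:::derive_seed(300, i)
    eff <- simulate_effects(sc, seed = pgxtl:::derive_seed(s, 1))
    g <- simulate_genotypes(sc$n_train, sc$m, seed = pgxtl:::derive_seed(s, 2))
    coh <- simulate_phenotypes(g, eff, sc, seed = pgxtl:::derive_seed(s, 3))
    ss <- simulate_sumstats(eff, attr(g, "maf"), sc$n_base,
                            seed = pgxtl:::derive_seed(s, 4))
    w <- clump_and_threshold(ss, ld_reference(coh$genotypes),
                             tuning_data = coh)
    fit <- fit_tl_prs(coh, w, strategy_config("M1"), seed = s)
    idx <- match(fit$effects$variant_ids, coh$genotypes$variants$id)
    cor(fit$effects$beta_gt, sc$gamma * eff$alpha[idx])
  })
  expect_gt(mean(cors), 0.2)
})
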