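test_that("penalized loss matches its definition", {
  withr::with_seed(1, {
    x <- matrix(rnorm(6 * 2), 6, 2)
    y <- rnorm(6)
  })
  b0 <- effect_pair(0, 0, "s1")
  expect_equal(penalized_loss(b0, x, y, 0), sum(y^2)) # zero-weight case

  # penalty = 0 at the OLS solution equals the closed-form RSS
  bols <- solve(crossprod(x), crossprod(x, y))
  b <- effect_pair(bols[1], bols[2], "s1")
  expect_equal(penalized_loss(b, x, y, 0),
               sum((y - x %*% bols)^2))

  # direct expansion: y = 0, ||b||^2 = 4, penalty 0.5 -> ||Xb||^2 + 2
  b2 <- effect_pair(2, 0, "s1")
  expect_equal(penalized_loss(b2, x, rep(0, 6), 0.5),
               sum((x %*% c(2, 0))^2) + 2)

  expect_error(penalized_loss(b2, x[, 1, drop = FALSE], y), "2M")
})

test_that("descent_step applies the reparameterized update", {
  x <- diag(2)
  y <- c(2, 4)
  b <- effect_pair(0, 0, "s1")
  s <- descent_settings(0.1, 0)
  nb <- descent_step(b, x, y, s)
  expect_equal(c(nb$beta_g, nb$beta_gt), c(0.2, 0.4)) # identity design

  # pure shrinkage when the gradient term vanishes (eta -> 0 limit taken as
  # a tiny learning rate; the shrinkage factor dominates)
  b1 <- effect_pair(1, 1, "s1")
  s2 <- descent_settings(1e-300, 0.99)
  nb2 <- descent_step(b1, x, c(0, 0), s2)
  expect_equal(c(nb2$beta_g, nb2$beta_gt), c(0.01, 0.01))

  # gt_only: first (prognostic) coordinate untouched, second updated
  nb3 <- descent_step(b1, x, y, descent_settings(0.1, 0),
                      strategy_config("M5"))
  expect_identical(nb3$beta_g, b1$beta_g)
  expect_equal(nb3$beta_gt, 1 + 0.1 * (4 - 1))
})

test_that("update with raw (eta, lambda) equals reparameterized update", {
  # b - eta * dloss/db == (1 - 2 eta lambda) b + 2 eta X'(y - Xb):
  # the two forms coincide exactly when eta_new = 2 eta, lambda_new = 2 eta lambda
  withr::with_seed(3, {
    x <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
    bv <- rnorm(4)
  })
  eta <- 0.01; lambda <- 2.5
  raw <- bv - eta * (-2 * crossprod(x, y - x %*% bv) + 2 * lambda * bv)
  b <- effect_pair(bv[1:2], bv[3:4], c("s1", "s2"))
  rep_ <- descent_step(b, x, y,
                       descent_settings(2 * eta, 2 * eta * lambda))
  expect_equal(c(rep_$beta_g, rep_$beta_gt), as.numeric(raw))
})

test_that("descent trace converges to the ridge fixed point", {
  withr::with_seed(11, {
    z <- matrix(rnorm(50 * 5), 50, 5)
    t <- rbinom(50, 1, 0.5)
    y <- rnorm(50)
  })
  x <- cbind(z, z * t)
  eta <- 0.9 / max(eigen(crossprod(x), only.values = TRUE)$values)
  for (lambda in c(0, 0.5, 0.99)) {
    tr <- descent_trace(z, t, y, rep(0, 5), rep(0, 5), eta, lambda,
                        n_iter = 4000, update_mode = "both",
                        variant_ids = paste0("s", 1:5))
    b_hat <- c(tr$beta_g[, 4000], tr$beta_gt[, 4000])
    b_star <- as.numeric(ridge_fixed_point(x, y, eta, lambda))
    expect_lt(max(abs(b_hat - b_star)) / max(abs(b_star)), 1e-8)
  }
})

test_that("loss is non-increasing along an unpenalized stable trace", {
  withr::with_seed(12, {
    z <- matrix(rnorm(40 * 4), 40, 4)
    t <- rbinom(40, 1, 0.5)
    y <- rnorm(40)
  })
  x <- cbind(z, z * t)
  eta <- 1.9 / max(eigen(crossprod(x), only.values = TRUE)$values)
  tr <- descent_trace(z, t, y, rep(0.2, 4), rep(0, 4), eta, 0, 60,
                      update_mode = "both", variant_ids = paste0("s", 1:4))
  losses <- vapply(seq_len(60), function(r) {
    sum((y - x %*% c(tr$beta_g[, r], tr$beta_gt[, r]))^2)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("run_descent respects strategy initialization and active set", {
  fx <- toy_cohort(n = 120, m = 12, seed = 5)
  pre <- effect_pair(c(rep(0.1, 6), rep(0, 6)), rep(0, 12),
                     fx$g$variants$id)
  s <- descent_settings(1e-4, 0.5, 8)

  # n_iter = 1 reproduces a single step; gt_only keeps beta_g frozen
  for (nm in c("M5", "M6")) {
    tr <- run_descent(fx$cohort, pre, s, strategy_config(nm))
    expect_identical(nrow(tr$beta_g), 6L) # only nonzero pre-weights enter
    for (r in 1:8) expect_identical(tr$beta_g[, r], rep(0.1, 6))
  }
  # gt initialization differs between zero-init and pre-init strategies
  tr2 <- run_descent(fx$cohort, pre, descent_settings(1e-6, 0, 1),
                     strategy_config("M2"))
  tr1 <- run_descent(fx$cohort, pre, descent_settings(1e-6, 0, 1),
                     strategy_config("M1"))
  expect_false(isTRUE(all.equal(tr1$beta_gt[, 1], tr2$beta_gt[, 1])))
  expect_error(run_descent(fx$cohort, effect_pair(rep(0, 12), rep(0, 12),
                                                  fx$g$variants$id), s),
               "nonzero")
})

test_that("divergence is caught and reported with the iteration", {
  withr::with_seed(2, z <- matrix(rnorm(30 * 3), 30, 3))
  err <- tryCatch(
    descent_trace(z, rbinom(30, 1, 0.5), rnorm(30), rep(1, 3), rep(0, 3),
                  learning_rate = 10, penalty = 0, n_iter = 50,
                  update_mode = "both", variant_ids = paste0("s", 1:3)),
    pgxtl_divergence = function(e) e)
  expect_s3_class(err, "pgxtl_divergence")
  expect_match(conditionMessage(err), "iteration")
})

test_that("compute_prs aligns by id, flips alleles and scales linearly", {
  g <- toy_genotypes(50, 4, seed = 9)
  eff <- effect_pair(c(0.5, -0.2, 0.1, 0), c(0.1, 0, -0.3, 0),
                     g$variants$id)
  p <- compute_prs(g, eff, effect_alleles = g$variants$effect_allele,
                   other_alleles = g$variants$other_allele)

  # zero effects -> zero scores
  p0 <- compute_prs(g, effect_pair(rep(0, 4), rep(0, 4), g$variants$id))
  expect_equal(p0$prs_g, rep(0, 50))
  expect_equal(p0$prs_gt, rep(0, 50))

  # permutation of the weight table leaves the scores unchanged
  perm <- c(3, 1, 4, 2)
  effp <- effect_pair(eff$beta_g[perm], eff$beta_gt[perm],
                      eff$variant_ids[perm])
  pp <- compute_prs(g, effp, effect_alleles = g$variants$effect_allele[perm],
                    other_alleles = g$variants$other_allele[perm])
  expect_equal(pp$prs_g, p$prs_g)
  expect_equal(pp$prs_gt, p$prs_gt)

  # swapped alleles: flipping dosage 2-d is a sign flip after standardization
  pf <- compute_prs(g, eff, effect_alleles = g$variants$other_allele,
                    other_alleles = g$variants$effect_allele)
  expect_equal(pf$prs_g, -p$prs_g)
  expect_equal(pf$prs_gt, -p$prs_gt)

  # scaling equivariance
  eff2 <- effect_pair(2 * eff$beta_g, 2 * eff$beta_gt, eff$variant_ids)
  p2 <- compute_prs(g, eff2, effect_alleles = g$variants$effect_allele,
                    other_alleles = g$variants$other_allele)
  expect_equal(p2$prs_g, 2 * p$prs_g)
  expect_equal(p2$prs_gt, 2 * p$prs_gt)

  # single standardized SNP: scalar product
  g1 <- genotype_matrix(cbind(s = c(0, 1, 2)), "s", "A", "G")
  p1 <- compute_prs(g1, effect_pair(2, -1, "s"))
  expect_equal(p1$prs_g, c(-2, 0, 2))
  expect_equal(p1$prs_gt, c(1, 0, -1))

  expect_error(compute_prs(g, effect_pair(1, 1, "absent")), "shared")
})

test_that("strategy table reproduces the six update/init/criterion combos", {
  tab <- lapply(paste0("M", 1:6), strategy_config)
  expect_equal(vapply(tab, `[[`, "", "update_mode"),
               c("both", "both", "both", "both", "gt_only", "gt_only"))
  expect_equal(vapply(tab, `[[`, "", "gt_init"),
               c("zero", "pre", "zero", "pre", "zero", "pre"))
  expect_equal(vapply(tab, `[[`, "", "tuning_criterion"),
               c("overall_r2", "overall_r2", "conditional_r2",
                 "conditional_r2", "overall_r2", "overall_r2"))
  expect_error(strategy_config("M7"))
  expect_error(descent_settings(0.1, penalty = 1), "\\[0, 1\\)")
})
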