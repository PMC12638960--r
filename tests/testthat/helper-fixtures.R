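# In-code fixtures shared across test files. Everything is generated at test
# time from fixed seeds; no data files are shipped.

# independent HWE genotypes (no LD) with fixed MAFs
toy_genotypes <- function(n, m, seed = 1, maf = NULL) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
    d <- vapply(maf, function(f) rbinom(n, 2, f), numeric(n))
  })
  genotype_matrix(d, paste0("snp", seq_len(m)), rep("A", m), rep("G", m),
                  sample_ids = paste0("S", seq_len(n)),
                  chr = rep(1L, m), pos = 1L + (seq_len(m) - 1L) * 2000L)
}

# cohort with known sparse architecture: y = bt*t + Z beta + (Z*t) alpha + e
toy_cohort <- function(n = 200, m = 20, seed = 1, beta = NULL, alpha = NULL,
                       bt = 0.5, sd_e = 1, covariates = NULL) {
  g <- toy_genotypes(n, m, seed = seed)
  z <- standardize_genotypes(g$dosages)$mat
  withr::with_seed(seed + 1000, {
    t <- rep(c(0, 1), length.out = n)[sample.int(n)]
    if (is.null(beta)) beta <- c(rep(0.3, min(5, m)), rep(0, m - min(5, m)))
    if (is.null(alpha)) alpha <- c(rep(0.2, min(3, m)), rep(0, m - min(3, m)))
    y <- bt * t + as.numeric(z %*% beta) + as.numeric((z * t) %*% alpha) +
      rnorm(n, sd = sd_e)
    if (!is.null(covariates)) y <- y + as.numeric(covariates %*%
                                                    rep(0.3, ncol(covariates)))
  })
  list(cohort = pgx_cohort(g, t, y, covariates), z = z,
       beta = beta, alpha = alpha, g = g, t = t, y = y)
}

# uniform nonzero pre-weights over all variants, as an effect_pair
flat_pre_weights <- function(g, value = 0.05) {
  m <- ncol(g$dosages)
  effect_pair(rep(value, m), rep(0, m), g$variants$id)
}

# closed-form ridge fixed point of the reparameterized update:
# b* = (X'X + (lambda/eta) I)^-1 X'y
ridge_fixed_point <- function(x, y, eta, lambda) {
  k <- ncol(x)
  solve(crossprod(x) + diag(lambda / eta, k), crossprod(x, y))
}
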