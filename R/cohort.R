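#' Two-arm pharmacogenomic cohort
#'
#' Bundles genotypes, the randomized treatment indicator, a continuous
#' drug-response phenotype and optional non-genetic covariates for one cohort.
#'
#' @param genotypes a [genotype_matrix()].
#' @param treatment integer/numeric vector in {0, 1}; both arms must be
#'   represented by at least two samples.
#' @param phenotype finite numeric vector (trait units).
#' @param covariates optional numeric matrix/data.frame, n x c.
#' @return object of class `pgx_cohort`.
#' @export
pgx_cohort <- function(genotypes, treatment, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- nrow(genotypes$dosages)
  treatment <- as.numeric(treatment)
  phenotype <- as.numeric(phenotype)
  if (length(treatment) != n || length(phenotype) != n) {
    stop("treatment and phenotype must have one entry per sample")
  }
  if (!all(treatment %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (sum(treatment == 1) < 2 || sum(treatment == 0) < 2) {
    stop("each treatment arm needs at least 2 samples")
  }
  if (!all(is.finite(phenotype))) stop("phenotype must be finite")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop("covariates must have n rows")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
  }
  structure(list(genotypes = genotypes, treatment = treatment,
                 phenotype = phenotype, covariates = covariates),
            class = "pgx_cohort")
}

#' @export
print.pgx_cohort <- function(x, ...) {
  cat(sprintf("pgx_cohort: %d samples (%d treated / %d control), %d variants, %d covariates\n",
              length(x$phenotype), sum(x$treatment == 1),
              sum(x$treatment == 0), ncol(x$genotypes$dosages),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Subset a cohort by sample index
#' @param cohort a [pgx_cohort()].
#' @param idx sample index vector.
#' @return a `pgx_cohort` restricted to `idx`.
#' @export
subset_cohort <- function(cohort, idx) {
  pgx_cohort(subset_genotypes(cohort$genotypes, samples = idx),
             cohort$treatment[idx], cohort$phenotype[idx],
             if (is.null(cohort$covariates)) NULL else
               cohort$covariates[idx, , drop = FALSE])
}

#' Residualize a phenotype on covariates and treatment
#'
#' Fits ordinary least squares of the phenotype on an intercept, the
#' covariates and the treatment indicator, returning either the in-sample
#' residuals or a reusable residualizer that can be applied to held-out data
#' with the coefficients estimated here (fold hygiene).
#'
#' @param phenotype numeric vector.
#' @param covariates optional numeric matrix (n x c).
#' @param treatment 0/1 vector.
#' @return numeric residual vector with attribute `"coefficients"`; residuals
#'   sum to zero and are in-sample orthogonal to every regressor.
#' @export
residualize <- function(phenotype, covariates = NULL, treatment) {
  phenotype <- as.numeric(phenotype)
  n <- length(phenotype)
  if (stats::var(phenotype) == 0) stop("phenotype is constant")
  X <- residual_design(covariates, treatment, n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, phenotype)
  res <- as.numeric(fit$residuals)
  attr(res, "coefficients") <- fit$coefficients
  res
}

residual_design <- function(covariates, treatment, n) {
  treatment <- as.numeric(treatment)
  if (length(treatment) != n) stop("treatment length mismatch")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates length mismatch")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  cbind(X, treatment = treatment)
}

#' Apply a previously fitted residualizer to new data
#'
#' @param phenotype,covariates,treatment held-out data.
#' @param coefficients the `"coefficients"` attribute from [residualize()]
#'   fitted on the training portion.
#' @return numeric residual vector (not guaranteed to sum to zero out of
#'   sample).
#' @export
apply_residualizer <- function(phenotype, covariates = NULL, treatment,
                               coefficients) {
  X <- residual_design(covariates, treatment, length(phenotype))
  if (ncol(X) != length(coefficients)) {
    stop("coefficient/design mismatch in residualizer")
  }
  as.numeric(phenotype - X %*% coefficients)
}
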