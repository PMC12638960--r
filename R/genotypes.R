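#' Genotype matrix with variant metadata
#'
#' Container for allele-dosage genotypes. Rows are samples, columns are
#' variants; each entry is the dosage (0 to 2, possibly fractional after
#' imputation) of the declared effect allele. Variant metadata travels with
#' the matrix so that weight tables from external studies can be reconciled
#' by identifier and allele orientation.
#'
#' @param dosages numeric matrix, n_samples x n_variants, entries in [0, 2]
#'   or NA (missing, to be imputed downstream).
#' @param variant_ids character vector of unique variant identifiers.
#' @param effect_alleles,other_alleles per-variant allele symbols; dosage
#'   counts copies of `effect_alleles`.
#' @param sample_ids sample identifiers; defaults to row names or S1..Sn.
#' @param chr,pos optional chromosome codes and 1-based base-pair positions
#'   (needed for windowed LD operations such as clumping).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages` (matrix with dimnames) and `variants` (data.frame with columns
#'   `id, chr, pos, effect_allele, other_allele`).
#' @export
genotype_matrix <- function(dosages, variant_ids, effect_alleles,
                            other_alleles, sample_ids = NULL,
                            chr = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  m <- ncol(dosages)
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != m) {
    stop("length(variant_ids) must equal ncol(dosages)")
  }
  if (anyDuplicated(variant_ids)) {
    stop("duplicate variant id: ",
         variant_ids[duplicated(variant_ids)][1L])
  }
  if (length(effect_alleles) != m || length(other_alleles) != m) {
    stop("allele vectors must have one entry per variant")
  }
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  if (any(is.nan(dosages)) || any(is.infinite(dosages))) {
    stop("dosages must be finite or NA")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("length(sample_ids) must equal nrow(dosages)")
  }
  dimnames(dosages) <- list(as.character(sample_ids), variant_ids)
  variants <- data.frame(
    id = variant_ids,
    chr = if (is.null(chr)) rep(1L, m) else as.integer(chr),
    pos = if (is.null(pos)) seq_len(m) else as.integer(pos),
    effect_allele = toupper(as.character(effect_alleles)),
    other_allele = toupper(as.character(other_alleles)),
    stringsAsFactors = FALSE
  )
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

# fast path for internal use: inputs already validated
new_genotype_matrix <- function(dosages, variants) {
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(pmax(colSums(x * x) - n * mu^2, 0) / (n - 1))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param g a [genotype_matrix()].
#' @param samples row index (integer/logical/character).
#' @param variants column index (integer/logical/character id).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  v <- g$variants
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, v$id) else
      seq_len(ncol(d))[variants]
    if (anyNA(idx)) stop("unknown variant id in selection")
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  new_genotype_matrix(d, v)
}

#' Mean-impute missing dosages per variant
#'
#' Missing entries are replaced by the variant mean computed on the observed
#' entries of the same (fitting) data. A variant with no observed entry is
#' set to 0.
#'
#' @param g a [genotype_matrix()].
#' @return a `genotype_matrix` with no missing entries.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (anyNA(d)) {
    mns <- colMeans(d, na.rm = TRUE)
    mns[is.nan(mns)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mns[idx[, 2L]]
    g$dosages <- d
  }
  g
}

#' Column-standardize genotype dosages
#'
#' Centers and scales each variant column. The statistics are computed on the
#' data being standardized unless `reference_stats` is supplied, in which case
#' those (fitting-set) statistics are applied instead -- the rule used when
#' transforming a held-out fold. Zero-variance columns are left at 0 and
#' flagged rather than producing NaN.
#'
#' @param x numeric matrix or [genotype_matrix()].
#' @param reference_stats optional data.frame as returned in `$stats`
#'   (columns `id, mean, sd, zero_var`), aligned by variant id when ids are
#'   available, otherwise by position.
#' @return list with `mat` (standardized matrix) and `stats` (data.frame
#'   `id, mean, sd, zero_var`; `sd` uses denominator n-1).
#' @export
standardize_genotypes <- function(x, reference_stats = NULL) {
  mat <- if (inherits(x, "genotype_matrix")) x$dosages else as.matrix(x)
  ids <- colnames(mat)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(mat)))
  if (is.null(reference_stats)) {
    mu <- colMeans(mat)
    sdv <- col_sds(mat)
    zv <- !is.finite(sdv) | sdv == 0
  } else {
    ord <- match(ids, reference_stats$id)
    if (anyNA(ord)) {
      if (nrow(reference_stats) == ncol(mat)) ord <- seq_len(ncol(mat))
      else stop("reference_stats do not cover all variants")
    }
    mu <- reference_stats$mean[ord]
    sdv <- reference_stats$sd[ord]
    zv <- reference_stats$zero_var[ord]
  }
  denom <- ifelse(zv, 1, sdv)
  n <- nrow(mat)
  out <- (mat - rep(mu, each = n)) / rep(denom, each = n)
  if (any(zv)) out[, zv] <- 0
  list(mat = out,
       stats = data.frame(id = ids, mean = mu, sd = sdv, zero_var = zv,
                          stringsAsFactors = FALSE))
}
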