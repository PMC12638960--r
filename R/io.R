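# File formats: headered TSVs for genotypes/weights/sumstats/phenotypes/PRS,
# PLINK 1 bed/bim/fam for genotype panels. All writers emit headers and
# 10-significant-digit floats; readers reject headerless files.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_tsv_impl <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv_impl <- function(path, required) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop(path, ": missing or headerless TSV; expected column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read genotypes from PLINK bed/bim/fam or a TSV dosage matrix
#'
#' PLINK: dosage counts the bim A1 allele (A1 becomes the effect allele).
#' TSV: rows are samples (first column `sample_id`), remaining columns are
#' variant ids; an optional sidecar `<path>.vars.tsv` with columns
#' `id, chr, pos, effect_allele, other_allele` supplies variant metadata
#' (defaults A/G at 2 kb spacing otherwise).
#'
#' @param path PLINK prefix (no extension) or TSV path.
#' @param format "plink" or "tsv".
#' @return a [genotype_matrix()]; missing dosages are NA (impute with
#'   [impute_missing()]).
#' @export
read_genotypes <- function(path, format = c("plink", "tsv")) {
  format <- match.arg(format)
  if (format == "plink") return(read_plink(path))
  df <- read_tsv_impl(path, "sample_id")
  ids <- colnames(df)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate variant id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  d <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(d) <- "double"
  vars_path <- paste0(path, ".vars.tsv")
  if (file.exists(vars_path)) {
    v <- read_tsv_impl(vars_path, c("id", "effect_allele", "other_allele"))
    ord <- match(ids, v$id)
    if (anyNA(ord)) stop("variant metadata missing for: ",
                         ids[is.na(ord)][1L])
    genotype_matrix(d, ids, v$effect_allele[ord], v$other_allele[ord],
                    sample_ids = df$sample_id,
                    chr = if ("chr" %in% names(v)) v$chr[ord] else NULL,
                    pos = if ("pos" %in% names(v)) v$pos[ord] else NULL)
  } else {
    genotype_matrix(d, ids, rep("A", length(ids)), rep("G", length(ids)),
                    sample_ids = df$sample_id)
  }
}

#' Write genotypes as a TSV dosage matrix (plus variant sidecar)
#' @param g a [genotype_matrix()].
#' @param path output TSV path; metadata goes to `<path>.vars.tsv`.
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_impl(df, path)
  v <- g$variants
  write_tsv_impl(data.frame(id = v$id, chr = v$chr, pos = v$pos,
                            effect_allele = v$effect_allele,
                            other_allele = v$other_allele),
                 paste0(path, ".vars.tsv"))
  invisible(path)
}

plink_lookup <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      # 2-bit codes, little-endian within byte: 00 hom A1 (dosage 2),
      # 01 missing, 10 het, 11 hom A2 (dosage 0)
      decode <- c(2, NA, 1, 0)
      lut <<- t(vapply(0:255, function(b) {
        decode[1 + c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                     bitwAnd(bitwShiftR(b, 4L), 3L),
                     bitwAnd(bitwShiftR(b, 6L), 3L))]
      }, numeric(4)))
    }
    lut
  }
})

#' Read a PLINK 1 bed/bim/fam fileset
#' @param prefix path without extension.
#' @return a [genotype_matrix()]; dosage counts the bim A1 allele.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(bim$id)) {
    stop("duplicate variant id in bim: ", bim$id[duplicated(bim$id)][1L])
  }
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: bad magic number")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m) {
    stop("bed byte count inconsistent with fam/bim dimensions")
  }
  lut <- plink_lookup()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  d <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    # each byte expands to 4 consecutive samples, lowest bits first
    d[, j] <- as.vector(t(lut[body[, j] + 1L, , drop = FALSE]))[seq_len(n)]
  }
  genotype_matrix(d, bim$id, bim$a1, bim$a2,
                  sample_ids = fam[[2]], chr = bim$chr, pos = bim$pos)
}

#' Write a PLINK 1 bed/bim/fam fileset
#' @param g a [genotype_matrix()] with integer dosages in {0, 1, 2} or NA.
#' @param prefix output path without extension.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("PLINK bed stores hard calls; dosages must be integers or NA")
  }
  v <- g$variants
  utils::write.table(
    data.frame(v$chr, v$id, 0L, v$pos, v$effect_allele, v$other_allele),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- rownames(d)
  utils::write.table(data.frame(ids, ids, 0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(d); m <- ncol(d)
  code <- matrix(3L, 4L * ceiling(n / 4), m) # pad with hom A2 (dosage 0)
  codes <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  dv <- matrix(ifelse(is.na(d), 1L, codes[as.character(d)]), n, m)
  code[seq_len(n), ] <- dv
  i4 <- seq(1L, nrow(code), by = 4L)
  bytes <- code[i4, , drop = FALSE] +
    4L * code[i4 + 1L, , drop = FALSE] +
    16L * code[i4 + 2L, , drop = FALSE] +
    64L * code[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read / write per-SNP weight tables
#'
#' TSV with header `variant_id, effect_allele, other_allele, weight`.
#' @param path TSV path.
#' @return a [weight_table()].
#' @export
read_weights <- function(path) {
  df <- read_tsv_impl(path, c("variant_id", "effect_allele",
                              "other_allele", "weight"))
  weight_table(df$variant_id, df$effect_allele, df$other_allele, df$weight)
}

#' @rdname read_weights
#' @param w a [weight_table()].
#' @export
write_weights <- function(w, path) {
  write_tsv_impl(as.data.frame(w), path)
  invisible(path)
}

#' Read / write GWAS summary statistics
#'
#' TSV with header `variant_id, chr, pos, effect_allele, other_allele, beta,
#' se, p` and optional `freq, n`; positions are 1-based.
#' @param path TSV path.
#' @return a [sumstats()] table.
#' @export
read_sumstats <- function(path) {
  df <- read_tsv_impl(path, c("variant_id", "effect_allele", "other_allele",
                              "beta", "se", "p"))
  sumstats(df$variant_id, df$effect_allele, df$other_allele, df$beta,
           df$se, df$p,
           chr = if ("chr" %in% names(df)) df$chr else NULL,
           pos = if ("pos" %in% names(df)) df$pos else NULL,
           freq = if ("freq" %in% names(df)) df$freq else NULL,
           n = if ("n" %in% names(df)) df$n else NULL)
}

#' @rdname read_sumstats
#' @param s a [sumstats()] table.
#' @export
write_sumstats <- function(s, path) {
  write_tsv_impl(as.data.frame(s), path)
  invisible(path)
}

#' Read / write phenotype tables
#'
#' TSV keyed by `sample_id` with columns `treatment`, `phenotype` and any
#' further columns treated as covariates.
#' @param path TSV path.
#' @return data.frame with attributes preserved.
#' @export
read_phenotypes <- function(path) {
  read_tsv_impl(path, c("sample_id", "treatment", "phenotype"))
}

#' @rdname read_phenotypes
#' @param cohort a [pgx_cohort()].
#' @export
write_phenotypes <- function(cohort, path) {
  df <- data.frame(sample_id = rownames(cohort$genotypes$dosages),
                   treatment = cohort$treatment,
                   phenotype = cohort$phenotype, stringsAsFactors = FALSE)
  if (!is.null(cohort$covariates)) df <- cbind(df, cohort$covariates)
  write_tsv_impl(df, path)
  invisible(path)
}

#' Assemble a cohort from a genotype object and a phenotype table
#'
#' Joins by sample id (phenotype rows are reordered to the genotype order);
#' samples missing from either side are an error.
#'
#' @param g a [genotype_matrix()].
#' @param pheno data.frame from [read_phenotypes()].
#' @return a [pgx_cohort()].
#' @export
make_cohort <- function(g, pheno) {
  ids <- rownames(g$dosages)
  ord <- match(ids, as.character(pheno$sample_id))
  if (anyNA(ord)) stop("phenotype table lacks sample(s): ",
                       ids[is.na(ord)][1L])
  covar_cols <- setdiff(names(pheno), c("sample_id", "treatment", "phenotype"))
  pgx_cohort(g, pheno$treatment[ord], pheno$phenotype[ord],
             if (length(covar_cols)) as.matrix(pheno[ord, covar_cols,
                                                     drop = FALSE]) else NULL)
}

#' Write out-of-fold scores
#' @param prs data.frame `sample_id, prs_g, prs_gt, fold`.
#' @param path output TSV.
#' @export
write_prs <- function(prs, path) {
  write_tsv_impl(prs, path)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' Structured text mirroring the fitting options: paths (`genotypes`,
#' `phenotypes`, `weights`, `out`), `strategy`, `grid` (eta_multipliers,
#' lambdas, n_iter), `seed`, `mode` ("real" or "simulation"),
#' `global_residualize`.
#'
#' @param path YAML file.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(strategy = "M1", seed = 1L, mode = "real",
                   global_residualize = FALSE,
                   grid = list(eta_multipliers = c(1, 10, 50, 100),
                               lambdas = c(0, 0.5, 0.99), n_iter = 30L))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$strategy %in% paste0("M", 1:6)) {
    stop("invalid strategy in config: ", cfg$strategy)
  }
  cfg
}
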