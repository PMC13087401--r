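#' Genotype dosage matrices for simulation studies
#'
#' A `genotype_matrix` holds an N x M dosage matrix together with variant
#' metadata. Dosages are allele counts on the 0-2 scale until
#' [standardize_genotypes()] is applied, after which each column has mean 0
#' and unit population standard deviation so that `crossprod(X)/n` is a
#' correlation matrix.
#'
#' @param dosages Numeric N x M matrix of allele dosages.
#' @param variant_ids Character vector of M unique variant identifiers.
#' @param ref_allele,eff_allele Per-variant allele labels (effect allele is
#'   the counted allele).
#' @param maf Per-variant minor-allele frequency in (0, 0.5].
#' @param sample_ids Character vector of N unique sample identifiers.
#' @param standardized Logical; whether columns are centered/scaled.
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_ids, ref_allele, eff_allele, maf,
                            sample_ids, standardized = FALSE, seed = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  variant_ids <- as.character(variant_ids)
  sample_ids <- as.character(sample_ids)
  if (length(variant_ids) != m) abort_domain("variant_ids length must equal ncol(dosages)")
  if (length(sample_ids) != n) abort_domain("sample_ids length must equal nrow(dosages)")
  if (anyDuplicated(variant_ids)) abort_domain("variant_ids must be unique")
  if (anyDuplicated(sample_ids)) abort_domain("sample_ids must be unique")
  maf <- rep_len(as.numeric(maf), m)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort_domain("maf must lie in (0, 0.5]")
  }
  if (length(ref_allele) != m || length(eff_allele) != m) {
    abort_domain("allele labels must have one entry per variant")
  }
  if (!standardized && (min(dosages) < 0 || max(dosages) > 2)) {
    abort_domain("raw dosages must lie in [0, 2]")
  }
  structure(
    list(
      dosages = dosages,
      variant_ids = variant_ids,
      ref_allele = as.character(ref_allele),
      eff_allele = as.character(eff_allele),
      maf = maf,
      sample_ids = sample_ids,
      standardized = isTRUE(standardized),
      seed = seed
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%s)\n",
    nrow(x$dosages), ncol(x$dosages),
    if (x$standardized) "standardized" else "raw dosages 0-2"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Simulate independent biallelic genotypes
#'
#' Draws dosages as independent Binomial(2, maf) counts (Hardy-Weinberg
#' equilibrium), the generating model used for the minimal inflation
#' example (1,000 individuals, 999 independent SNPs at MAF 0.4).
#'
#' @param n_samples,n_snps Positive counts.
#' @param maf Minor-allele frequency in (0, 0.5]; scalar or one per SNP.
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return A raw (unstandardized) [genotype_matrix()].
#' @export
#' @examples
#' g <- simulate_genotypes(100, 10, maf = 0.4, seed = 1)
#' range(g$dosages)
simulate_genotypes <- function(n_samples, n_snps, maf, seed = NULL) {
  if (!is_count(n_samples) || n_samples < 1) abort_domain("n_samples must be a positive count")
  if (!is_count(n_snps) || n_snps < 1) abort_domain("n_snps must be a positive count")
  maf <- rep_len(as.numeric(maf), n_snps)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort_domain("maf must lie in (0, 0.5]")
  }
  dos <- with_seed(seed, {
    matrix(
      stats::rbinom(n_samples * n_snps, size = 2L, prob = rep(maf, each = n_samples)),
      nrow = n_samples, ncol = n_snps
    )
  })
  genotype_matrix(
    dosages = dos,
    variant_ids = paste0("snp_", seq_len(n_snps)),
    ref_allele = rep("A", n_snps),
    eff_allele = rep("G", n_snps),
    maf = maf,
    sample_ids = paste0("sample_", seq_len(n_samples)),
    standardized = FALSE,
    seed = seed
  )
}

#' Linkage-disequilibrium correlation matrix
#'
#' Validates an M x M SNP correlation matrix: symmetric, unit diagonal,
#' positive semi-definite (smallest eigenvalue >= -1e-8).
#'
#' @param sigma Numeric square matrix.
#' @param variant_ids Optional variant identifiers aligned with `sigma`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(sigma, variant_ids = NULL) {
  sigma <- as.matrix(sigma)
  m <- nrow(sigma)
  if (ncol(sigma) != m) abort_domain("LD matrix must be square")
  if (max(abs(sigma - t(sigma))) > 1e-8) abort_domain("LD matrix must be symmetric")
  if (max(abs(diag(sigma) - 1)) > 1e-8) abort_domain("LD matrix must have unit diagonal")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_domain(sprintf(
      "LD matrix is not positive semi-definite (min eigenvalue %.3g)", min(ev)
    ))
  }
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(m))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != m || anyDuplicated(variant_ids)) {
    abort_domain("variant_ids must be unique and match the LD dimension")
  }
  structure(list(sigma = sigma, variant_ids = variant_ids), class = "ld_matrix")
}

#' Simulate genotypes with block-correlated SNPs
#'
#' Generates two haplotypes per individual by thresholding correlated
#' Gaussians (a Gaussian copula) at the MAF quantile and summing them, so
#' the realized dosage correlation structure approximates the requested LD
#' matrix. Used to exercise the analytic inflation slope away from the
#' independent-SNP case.
#'
#' @param n_samples Positive count.
#' @param ld An [ld_matrix()].
#' @param maf Scalar minor-allele frequency in (0, 0.5].
#' @param seed Optional integer seed.
#' @return A raw [genotype_matrix()].
#' @export
simulate_ld_genotypes <- function(n_samples, ld, maf, seed = NULL) {
  if (!inherits(ld, "ld_matrix")) ld <- ld_matrix(ld)
  if (!is_count(n_samples) || n_samples < 1) abort_domain("n_samples must be a positive count")
  if (!is_scalar_num(maf) || maf <= 0 || maf > 0.5) abort_domain("maf must lie in (0, 0.5]")
  m <- ncol(ld$sigma)
  eg <- eigen(ld$sigma, symmetric = TRUE)
  a <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
  thr <- stats::qnorm(maf)
  dos <- with_seed(seed, {
    h1 <- (matrix(stats::rnorm(n_samples * m), n_samples, m) %*% t(a)) < thr
    h2 <- (matrix(stats::rnorm(n_samples * m), n_samples, m) %*% t(a)) < thr
    h1 + h2
  })
  genotype_matrix(
    dosages = dos,
    variant_ids = ld$variant_ids,
    ref_allele = rep("A", m),
    eff_allele = rep("G", m),
    maf = rep(maf, m),
    sample_ids = paste0("sample_", seq_len(n_samples)),
    standardized = FALSE,
    seed = seed
  )
}

#' Standardize genotype columns
#'
#' Centers each dosage column and scales it to unit population standard
#' deviation (divisor n, not n-1), so `crossprod(X)/n` is exactly the
#' sample correlation matrix and the correlation-based Z statistic
#' `sqrt(n) * r` is algebraically clean.
#'
#' @param g A raw [genotype_matrix()].
#' @return The standardized `genotype_matrix`.
#' @export
#' @examples
#' g <- simulate_genotypes(50, 5, 0.3, seed = 2)
#' gs <- standardize_genotypes(g)
#' colMeans(gs$dosages)
standardize_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) abort_domain("genotype matrix is already standardized")
  std <- pop_standardize_columns(g$dosages)
  if (any(std$zero)) {
    abort_degenerate(sprintf(
      "zero-variance variant(s) cannot be standardized: %s",
      paste(g$variant_ids[std$zero], collapse = ", ")
    ))
  }
  g$dosages <- std$x
  g$standardized <- TRUE
  g
}

#' Write a dosage matrix to a delimited file
#'
#' Tab-delimited, one variant per row, header
#' `variant_id ref eff maf sample_1 ... sample_N`. Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param g A raw [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$standardized) abort_domain("dosage files store raw 0-2 dosages; write before standardizing")
  df <- data.frame(
    variant_id = g$variant_ids,
    ref = g$ref_allele,
    eff = g$eff_allele,
    maf = g$maf,
    t(g$dosages),
    check.names = FALSE
  )
  colnames(df)[-(1:4)] <- g$sample_ids
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from a delimited file
#'
#' @param path File written by [write_dosages()] (optionally gzipped).
#' @return A raw [genotype_matrix()].
#' @export
read_dosages <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("dosage file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "ref", "eff", "maf")
  if (!all(need %in% colnames(df)[1:4])) {
    abort_format("dosage file must start with columns variant_id, ref, eff, maf")
  }
  if (ncol(df) <= 4L) abort_format("dosage file contains no sample columns")
  dos <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  genotype_matrix(
    dosages = unname(dos),
    variant_ids = df$variant_id,
    ref_allele = df$ref,
    eff_allele = df$eff,
    maf = df$maf,
    sample_ids = colnames(df)[-(1:4)],
    standardized = FALSE
  )
}
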