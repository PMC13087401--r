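# Variance-control correction: divide each Z by the square root of its
# expected null variance, sqrt(1 + Phi * N * h2), with a mediator-specific
# Phi. A conventional genomic-control baseline (single global lambda) is
# provided for comparison; inflation is gene-specific, so a single global
# factor cannot calibrate all mediators at once.

#' Context for variance-control correction
#'
#' @param n GWAS sample size (>= 1).
#' @param h2_delta Target-trait heritability in \[0, 1\] (user-supplied,
#'   e.g. from LD score regression).
#' @param phi_table Data frame with columns `mediator_id` and `phi`
#'   (nonnegative), e.g. from [read_phi_table()], or a list of
#'   `phi_estimate` objects.
#' @return An object of class `correction_context`.
#' @export
correction_context <- function(n, h2_delta, phi_table) {
  if (!is_scalar_num(n) || n < 1) abort_domain("n must be >= 1")
  if (!is_scalar_num(h2_delta) || h2_delta < 0 || h2_delta > 1) {
    abort_domain("h2_delta must lie in [0, 1]")
  }
  if (inherits(phi_table, "phi_estimate")) phi_table <- list(phi_table)
  if (is.list(phi_table) && !is.data.frame(phi_table) &&
      all(vapply(phi_table, inherits, logical(1), "phi_estimate"))) {
    phi_table <- data.frame(
      mediator_id = vapply(phi_table, `[[`, character(1), "mediator_id"),
      phi = vapply(phi_table, `[[`, numeric(1), "phi"),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(phi_table) ||
      !all(c("mediator_id", "phi") %in% colnames(phi_table))) {
    abort_domain("phi_table must have columns mediator_id and phi")
  }
  if (any(!is.finite(phi_table$phi)) || any(phi_table$phi < 0)) {
    abort_domain("phi values must be finite and nonnegative")
  }
  if (anyDuplicated(phi_table$mediator_id)) {
    abort_domain("phi_table mediator ids must be unique")
  }
  structure(list(n = n, h2_delta = h2_delta, phi_table = phi_table),
            class = "correction_context")
}

normalize_assoc <- function(results) {
  if (inherits(results, "association_result")) results <- association_table(results)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "association_result"))) {
    results <- association_table(results)
  }
  if (!is.data.frame(results)) abort_domain("results must be a data frame of associations")
  if (!"zscore" %in% colnames(results) && "z" %in% colnames(results)) {
    results$zscore <- results$z
  }
  if (!all(c("mediator_id", "zscore") %in% colnames(results))) {
    abort_domain("association results need columns mediator_id and zscore")
  }
  if (nrow(results) == 0L) abort_domain("association results are empty")
  results
}

corrected_frame <- function(ids, z, p_raw, factor, phi, corrected) {
  data.frame(
    mediator_id = ids,
    z_raw = z,
    z_corrected = z / factor,
    p_raw = p_raw,
    p_corrected = 2 * stats::pnorm(-abs(z / factor)),
    correction_factor = factor,
    phi = phi,
    corrected = corrected,
    stringsAsFactors = FALSE
  )
}

#' Variance-control correction of association Z scores
#'
#' Rescales each Z by `1 / sqrt(1 + phi * n * h2_delta)` using the
#' mediator's own inflation slope, and recomputes two-sided normal p
#' values. Mediators without a phi entry are passed through uncorrected
#' with a warning (`missing_phi = "warn"`, the default) or trigger an
#' error (`missing_phi = "error"`).
#'
#' @param results Association table (data frame with `mediator_id`,
#'   `zscore`, optionally `pvalue`) or `association_result` objects.
#' @param ctx A [correction_context()].
#' @param missing_phi `"warn"` or `"error"`.
#' @return Data frame with columns `mediator_id z_raw z_corrected p_raw
#'   p_corrected correction_factor phi corrected`.
#' @export
#' @examples
#' ctx <- correction_context(100000, 0.5,
#'                           data.frame(mediator_id = "g1", phi = 4.2e-5))
#' variance_control(data.frame(mediator_id = "g1", zscore = 3), ctx)
variance_control <- function(results, ctx, missing_phi = c("warn", "error")) {
  missing_phi <- match.arg(missing_phi)
  stopifnot(inherits(ctx, "correction_context"))
  results <- normalize_assoc(results)
  i <- match(results$mediator_id, ctx$phi_table$mediator_id)
  phi <- ctx$phi_table$phi[i]
  miss <- is.na(phi)
  if (any(miss)) {
    msg <- sprintf("no phi entry for %d mediator(s): %s", sum(miss),
                   paste(utils::head(results$mediator_id[miss], 5), collapse = ", "))
    if (missing_phi == "error") abort_domain(msg)
    warning(msg, "; passed through uncorrected")
    phi[miss] <- 0
  }
  factor <- sqrt(1 + phi * ctx$n * ctx$h2_delta)
  p_raw <- if ("pvalue" %in% colnames(results)) results$pvalue else {
    2 * stats::pnorm(-abs(results$zscore))
  }
  out <- corrected_frame(results$mediator_id, results$zscore, p_raw, factor,
                         phi, !miss)
  attr(out, "method") <- "variance_control"
  attr(out, "n") <- ctx$n
  attr(out, "h2_delta") <- ctx$h2_delta
  out
}

#' Genomic-control correction baseline
#'
#' Computes the classical inflation factor
#' `lambda = median(z^2) / qchisq(0.5, 1)` and divides every Z by
#' `sqrt(lambda)` when `lambda > 1` (one-sided: deflation is never applied).
#' A single global factor cannot undo mediator-specific inflation; this is
#' the comparison baseline.
#'
#' @param results Association table (>= 2 rows) as in [variance_control()].
#' @return Data frame in the same format as [variance_control()], with a
#'   `lambda` attribute.
#' @export
genomic_control <- function(results) {
  results <- normalize_assoc(results)
  if (nrow(results) < 2) abort_domain("genomic control needs at least 2 results")
  lambda <- stats::median(results$zscore^2) / stats::qchisq(0.5, df = 1)
  factor <- rep(if (lambda > 1) sqrt(lambda) else 1, nrow(results))
  p_raw <- if ("pvalue" %in% colnames(results)) results$pvalue else {
    2 * stats::pnorm(-abs(results$zscore))
  }
  out <- corrected_frame(results$mediator_id, results$zscore, p_raw, factor,
                         NA_real_, lambda > 1)
  attr(out, "method") <- "genomic_control"
  attr(out, "lambda") <- lambda
  out
}

#' Write a corrected association table
#'
#' TSV with columns `mediator_id z_raw z_corrected p_raw p_corrected
#' correction_factor phi`.
#'
#' @param corrected Data frame from [variance_control()] or
#'   [genomic_control()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corrected <- function(corrected, path) {
  cols <- c("mediator_id", "z_raw", "z_corrected", "p_raw", "p_corrected",
            "correction_factor", "phi")
  if (!all(cols %in% colnames(corrected))) {
    abort_format("corrected table is missing required columns")
  }
  utils::write.table(corrected[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
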