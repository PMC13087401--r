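# Correlation-based association statistics between a predicted mediator and
# a target trait. The score-form statistic Z = sqrt(n) * r is referred to
# the standard normal; under a well-calibrated null Z^2 is chi-square(1).

# Shared scalar correlation kernel: both the single-pair and the batch path
# evaluate exactly this expression, so replicate batches are bit-identical
# to the per-replicate loop.
cor_kernel <- function(tc, yc, st2) {
  sy2 <- sum(yc^2)
  if (sy2 == 0) abort_degenerate("trait vector has zero variance")
  sum(tc * yc) / sqrt(st2 * sy2)
}

as_trait_vector <- function(y) {
  if (inherits(y, "sim_trait")) y$y else as.numeric(y)
}

as_mediator_vector <- function(t) {
  if (inherits(t, "predicted_mediator")) t$values else as.numeric(t)
}

#' TWAS association statistic for one mediator
#'
#' Computes the sample correlation `r` between the predicted mediator and
#' the trait, the score-form statistic `z = sqrt(n) * r` (the form obtained
#' when correlations are computed in bulk via matrix multiplication), and a
#' two-sided normal p value. `method = "t"` gives the regression
#' t-statistic `r * sqrt(n - 2) / sqrt(1 - r^2)` instead; the two agree
#' asymptotically.
#'
#' @param t A [predict_mediator()] result or numeric vector.
#' @param y A `sim_trait` or numeric trait vector of the same length (>= 3).
#' @param method `"score"` (default) or `"t"`.
#' @return An object of class `association_result` with fields
#'   `mediator_id`, `z`, `p`, `n`, `raw_r`, `method`.
#' @export
#' @examples
#' g <- standardize_genotypes(simulate_genotypes(500, 20, 0.4, seed = 5))
#' w <- simulate_true_weights(20, 1, seed = 6)
#' tm <- predict_mediator(g, w)
#' y <- simulate_null_trait(g, null_trait_spec(0, seed = 7))
#' twas_z(tm, y)
twas_z <- function(t, y, method = c("score", "t")) {
  method <- match.arg(method)
  mediator_id <- if (inherits(t, "predicted_mediator")) t$mediator_id else "mediator"
  tv <- as_mediator_vector(t)
  yv <- as_trait_vector(y)
  n <- length(tv)
  if (length(yv) != n) abort_domain("mediator and trait must have equal length")
  if (n < 3) abort_domain("need at least 3 observations")
  tc <- tv - mean(tv)
  st2 <- sum(tc^2)
  if (st2 == 0) abort_degenerate("mediator has zero variance")
  r <- cor_kernel(tc, yv - mean(yv), st2)
  if (abs(r) >= 1 - 1e-12) {
    abort_twasvc("mediator and trait are perfectly collinear (|r| = 1)",
                 c("twasvc_collinear_error", "twasvc_degenerate_error"))
  }
  z <- if (method == "score") sqrt(n) * r else r * sqrt(n - 2) / sqrt(1 - r^2)
  structure(
    list(mediator_id = mediator_id, z = z, p = 2 * stats::pnorm(-abs(z)),
         n = n, raw_r = r, method = method),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association '%s': z = %.4f, p = %.3g, n = %d (%s statistic)\n",
              x$mediator_id, x$z, x$p, x$n, x$method))
  invisible(x)
}

#' Collect association results into a table
#'
#' @param results A list of `association_result` objects.
#' @return Data frame with columns `mediator_id`, `zscore`, `pvalue`, `n`,
#'   `raw_r`.
#' @export
association_table <- function(results) {
  if (inherits(results, "association_result")) results <- list(results)
  data.frame(
    mediator_id = vapply(results, `[[`, character(1), "mediator_id"),
    zscore = vapply(results, `[[`, numeric(1), "z"),
    pvalue = vapply(results, `[[`, numeric(1), "p"),
    n = vapply(results, `[[`, numeric(1), "n"),
    raw_r = vapply(results, `[[`, numeric(1), "raw_r"),
    stringsAsFactors = FALSE
  )
}

#' Null-trait replicate associations for one mediator
#'
#' Simulates `n_replicates` independent null traits from `spec` (per-replicate
#' seeds split deterministically from `seed`) and computes the score-form Z
#' against the fixed predicted mediator, returning the mean squared Z and
#' its Monte-Carlo standard error — the simulation summary whose growth in
#' `N * h2` defines the inflation slope.
#'
#' @param g A standardized [genotype_matrix()].
#' @param t A [predict_mediator()] result aligned with `g`.
#' @param spec A [null_trait_spec()]; its `seed` is ignored in favor of the
#'   split per-replicate seeds when `seed` is given.
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Optional root seed.
#' @return An object of class `replicate_summary`: `mediator_id`, `mean_z2`,
#'   `se_mean_z2`, `n_replicates`, `n`, `h2_delta`, plus the per-replicate
#'   `z` and `p` vectors.
#' @export
batch_null_associations <- function(g, t, spec, n_replicates, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "null_trait_spec"))
  if (!is_count(n_replicates) || n_replicates < 2) {
    abort_domain("n_replicates must be >= 2 (the standard error is undefined otherwise)")
  }
  tv <- as_mediator_vector(t)
  n <- nrow(g$dosages)
  if (length(tv) != n) abort_domain("mediator length must match the genotype sample count")
  tc <- tv - mean(tv)
  st2 <- sum(tc^2)
  if (st2 == 0) abort_degenerate("mediator has zero variance")
  z <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- split_seed(seed, r)
    y <- tryCatch(
      simulate_null_trait(g, spec_r),
      twasvc_degenerate_error = function(e) {
        abort_degenerate(sprintf("replicate %d: %s", r, conditionMessage(e)))
      }
    )
    yc <- y$y - mean(y$y)
    z[r] <- sqrt(n) * cor_kernel(tc, yc, st2)
  }
  z2 <- z^2
  structure(
    list(
      mediator_id = if (inherits(t, "predicted_mediator")) t$mediator_id else "mediator",
      mean_z2 = mean(z2),
      se_mean_z2 = stats::sd(z2) / sqrt(n_replicates),
      n_replicates = n_replicates,
      n = n,
      h2_delta = spec$h2_delta,
      z = z,
      p = 2 * stats::pnorm(-abs(z))
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "replicate_summary '%s': mean Z^2 = %.4f (SE %.4f), %d replicates, n = %d, h2 = %g\n",
    x$mediator_id, x$mean_z2, x$se_mean_z2, x$n_replicates, x$n, x$h2_delta
  ))
  invisible(x)
}

#' Write an association table
#'
#' TSV with columns `mediator_id zscore pvalue n` (extra columns are kept).
#'
#' @param assoc Data frame as from [association_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  need <- c("mediator_id", "zscore", "pvalue", "n")
  if (!all(need %in% colnames(assoc))) {
    abort_format(sprintf("association table must have columns: %s",
                         paste(need, collapse = " ")))
  }
  utils::write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association table
#'
#' Accepts the package's own format as well as external Z-score tables for
#' correction-only workflows; only `mediator_id` and `zscore` are required,
#' unknown columns are ignored (but preserved).
#'
#' @param path TSV path.
#' @return Data frame with at least `mediator_id` and `zscore`.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("association file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("mediator_id", "zscore") %in% colnames(df))) {
    abort_format("association table must have columns mediator_id and zscore")
  }
  df
}
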