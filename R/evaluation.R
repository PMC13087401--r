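# Calibration and power diagnostics: QQ data, type-I error, Bonferroni
# precision/recall, and mean-Z^2-vs-N*h2 regression summaries.

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 7131)
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1) {
    abort_domain("alpha must lie in (0, 1)")
  }
  if (!is_count(n_tests) || n_tests < 1) abort_domain("n_tests must be >= 1")
  alpha / n_tests
}

#' Precision and recall of a discovery set
#'
#' Declares discoveries at `p < threshold` and compares them with the known
#' causal set. Precision (probability a declared gene is truly causal) is
#' reported as `NA` with `precision_defined = FALSE` when there are no
#' discoveries, rather than an arbitrary 0 or 1.
#'
#' @param results Data frame with `mediator_id` and a p-value column
#'   (`p_corrected` is used when present, else `pvalue`/`p_raw`).
#' @param causal_ids Identifiers of truly causal mediators; must all be
#'   among the tested ids.
#' @param threshold P-value discovery bound, e.g. from
#'   [bonferroni_threshold()].
#' @return An object of class `discovery_report`: `threshold`,
#'   `n_discoveries`, `precision`, `precision_defined`, `recall`,
#'   `causal_ids`, `discovered_ids`.
#' @export
precision_recall <- function(results, causal_ids, threshold) {
  if (!is.data.frame(results) || !"mediator_id" %in% colnames(results)) {
    abort_domain("results must be a data frame with a mediator_id column")
  }
  pcol <- intersect(c("p_corrected", "pvalue", "p_raw"), colnames(results))[1]
  if (is.na(pcol)) abort_domain("results must contain a p-value column")
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold > 1) {
    abort_domain("threshold must lie in (0, 1]")
  }
  causal_ids <- as.character(causal_ids)
  if (!all(causal_ids %in% results$mediator_id)) {
    abort_twasvc("causal_ids contains mediators that were never tested",
                 c("twasvc_consistency_error", "twasvc_domain_error"))
  }
  discovered <- results$mediator_id[results[[pcol]] < threshold]
  hits <- length(intersect(discovered, causal_ids))
  precision_defined <- length(discovered) > 0
  structure(
    list(
      threshold = threshold,
      n_discoveries = length(discovered),
      precision = if (precision_defined) hits / length(discovered) else NA_real_,
      precision_defined = precision_defined,
      recall = if (length(causal_ids)) hits / length(causal_ids) else NA_real_,
      causal_ids = causal_ids,
      discovered_ids = discovered
    ),
    class = "discovery_report"
  )
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf(
    "discovery_report: %d discoveries at p < %.3g; precision %s, recall %.3f\n",
    x$n_discoveries, x$threshold,
    if (x$precision_defined) sprintf("%.3f", x$precision) else "undefined",
    x$recall
  ))
  invisible(x)
}

#' Calibration diagnostics for a set of p values
#'
#' Compares the empirical p-value distribution to Uniform(0, 1):
#' Kolmogorov-Smirnov statistic and p value, empirical type-I error at the
#' requested alpha levels, QQ points on the -log10 scale with expected
#' quantiles `rank / (n + 1)`, and the genomic-control lambda implied by
#' the p values (identical to [genomic_control()]'s lambda on the matching
#' Z set).
#'
#' @param pvalues Numeric vector, all in (0, 1\].
#' @param alphas Type-I error levels to tabulate.
#' @return An object of class `calibration_report`.
#' @export
calibration_report <- function(pvalues, alphas = c(0.05, 0.01, 1e-3)) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0L) abort_domain("pvalues must be nonempty")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort_domain("all p values must lie in (0, 1]")
  }
  ks <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  n <- length(pvalues)
  sorted <- sort(pvalues)
  qq <- data.frame(
    expected = -log10(seq_len(n) / (n + 1)),
    observed = -log10(sorted)
  )
  qq <- qq[order(qq$expected), , drop = FALSE]
  typeI <- vapply(alphas, function(a) mean(pvalues < a), numeric(1))
  names(typeI) <- paste0("alpha_", alphas)
  lambda_gc <- stats::median(stats::qchisq(pvalues, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  structure(
    list(
      n_tests = n,
      ks_statistic = unname(ks$statistic),
      ks_p = ks$p.value,
      typeI_at_alpha = typeI,
      qq_points = qq,
      lambda_gc = lambda_gc,
      qq_expected_rule = "rank/(n+1)"
    ),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "calibration_report: %d tests, KS = %.4f (p = %.3g), lambda_GC = %.3f\n",
    x$n_tests, x$ks_statistic, x$ks_p, x$lambda_gc
  ))
  cat("  type I error:",
      paste(sprintf("%s = %.4g", names(x$typeI_at_alpha), x$typeI_at_alpha),
            collapse = ", "), "\n")
  invisible(x)
}

#' Regression of a Z^2 summary on N * h2
#'
#' Fits the inflation regression used both to estimate the slope and, after
#' correction, to verify that the linear dependence of mean Z^2 on
#' `N * h2` is gone. Accepts mean, median, or first-quartile summaries.
#'
#' @param summaries Data frame with the summary column and either `nh2` or
#'   both `n` and `h2_delta`; at least 3 points. A list of
#'   `replicate_summary` objects is also accepted.
#' @param response Name of the summary column (default `"mean_z2"`).
#' @return A list with `slope`, `slope_se`, `intercept`, `r2`, `p`
#'   (Wald test of zero slope), `n_points`.
#' @export
inflation_regression <- function(summaries, response = "mean_z2") {
  if (is.list(summaries) && !is.data.frame(summaries) &&
      all(vapply(summaries, inherits, logical(1), "replicate_summary"))) {
    summaries <- data.frame(
      n = vapply(summaries, `[[`, numeric(1), "n"),
      h2_delta = vapply(summaries, `[[`, numeric(1), "h2_delta"),
      mean_z2 = vapply(summaries, `[[`, numeric(1), "mean_z2")
    )
  }
  df <- as.data.frame(summaries)
  if (!"nh2" %in% colnames(df)) {
    if (!all(c("n", "h2_delta") %in% colnames(df))) {
      abort_domain("summaries must contain nh2 or both n and h2_delta")
    }
    df$nh2 <- df$n * df$h2_delta
  }
  if (!response %in% colnames(df)) {
    abort_domain(sprintf("summaries must contain the response column '%s'", response))
  }
  if (nrow(df) < 3) abort_rank("inflation regression needs at least 3 points")
  if (length(unique(df$nh2)) < 2) abort_rank("inflation regression needs >= 2 distinct n * h2")
  fit <- stats::lm(df[[response]] ~ df$nh2)
  sm <- suppressWarnings(summary(fit)) # exact lines trip the perfect-fit warning
  list(
    slope = unname(stats::coef(fit)[2]),
    slope_se = sm$coefficients[2, "Std. Error"],
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p = sm$coefficients[2, "Pr(>|t|)"],
    n_points = nrow(df)
  )
}

#' Serialize an evaluation report to JSON
#'
#' QQ points are included as parallel arrays; write them separately as TSV
#' with [write_qq_points()] for plotting.
#'
#' @param report A `calibration_report` or `discovery_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  if (!is.null(obj$qq_points)) obj$qq_points <- as.list(obj$qq_points)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write QQ points as TSV
#'
#' @param report A `calibration_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qq_points <- function(report, path) {
  stopifnot(inherits(report, "calibration_report"))
  utils::write.table(report$qq_points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
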