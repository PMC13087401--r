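# Inflation-slope (Phi) estimation. Under a polygenic null target trait the
# expected squared TWAS statistic grows linearly, E[Z^2] ~ 1 + N * h2 * Phi,
# with a mediator-specific slope Phi. Phi is estimated empirically by
# simulating null traits over a grid of (N, h2) and regressing the mean Z^2
# on N * h2; the analytic form (quadratic forms of the weights in the LD
# matrix) is retained as a validation oracle.

#' Simulate the mean-Z^2 inflation grid for one mediator
#'
#' For every combination of sample size and polygenic heritability,
#' subsamples individuals without replacement, simulates `n_replicates`
#' polygenic null traits, and records the mean squared Z of the mediator
#' association with its Monte-Carlo standard error.
#'
#' @param g A [genotype_matrix()]; raw dosages are standardized per
#'   subsample (a standardized matrix is accepted and re-centered/scaled on
#'   the subsample).
#' @param t A [predict_mediator()] result aligned with the rows of `g`.
#' @param n_values Sample sizes, each at most `nrow(g)`.
#' @param h2_values Heritabilities in \[0, 1\].
#' @param n_replicates Replicates per grid cell (>= 2).
#' @param seed Optional root seed, split deterministically per cell.
#' @param prop_nonzero Proportion of SNPs with nonzero polygenic effect.
#' @param df Optional Student-t degrees of freedom for effect/noise draws.
#' @return An `inflation_grid`: data frame with columns `n`, `h2_delta`,
#'   `nh2`, `mean_z2`, `se`, `seed`, plus `mediator_id` and `n_replicates`
#'   attributes.
#' @export
run_inflation_grid <- function(g, t, n_values, h2_values, n_replicates,
                               seed = NULL, prop_nonzero = 1, df = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_total <- nrow(g$dosages)
  if (any(n_values > n_total)) {
    abort_domain(sprintf("requested sample size exceeds available samples (%d)", n_total))
  }
  if (any(n_values < 3)) abort_domain("grid sample sizes must be >= 3")
  if (any(h2_values < 0 | h2_values > 1)) abort_domain("h2 values must lie in [0, 1]")
  tv <- as_mediator_vector(t)
  if (length(tv) != n_total) abort_domain("mediator length must match the genotype sample count")
  cells <- expand.grid(n = n_values, h2_delta = h2_values)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    nn <- cells$n[i]
    h2 <- cells$h2_delta[i]
    cell_seed <- split_seed(seed, i)
    idx <- if (nn == n_total) seq_len(n_total) else {
      with_seed(split_seed(seed, i, salt = 1L), sample.int(n_total, nn))
    }
    std <- pop_standardize_columns(g$dosages[idx, , drop = FALSE])
    if (any(std$zero)) {
      abort_degenerate(sprintf(
        "grid cell (n = %d, h2 = %g): zero-variance variant(s) in subsample: %s",
        nn, h2, paste(g$variant_ids[std$zero], collapse = ", ")
      ))
    }
    sub <- genotype_matrix(std$x, g$variant_ids, g$ref_allele, g$eff_allele,
                           g$maf, g$sample_ids[idx], standardized = TRUE)
    spec <- null_trait_spec(h2, prop_nonzero = prop_nonzero, df = df)
    bs <- batch_null_associations(sub, tv[idx], spec, n_replicates, seed = cell_seed)
    rows[[i]] <- data.frame(n = nn, h2_delta = h2, nh2 = nn * h2,
                            mean_z2 = bs$mean_z2, se = bs$se_mean_z2,
                            seed = if (is.null(cell_seed)) NA_integer_ else cell_seed)
  }
  out <- do.call(rbind, rows)
  attr(out, "mediator_id") <- if (inherits(t, "predicted_mediator")) t$mediator_id else "mediator"
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("inflation_grid", "data.frame")
  out
}

#' Estimate the inflation slope from a grid
#'
#' Ordinary least squares of mean Z^2 on `N * h2` with a free intercept.
#' The reported `phi` is the fitted slope plus one standard error — a
#' conservative adjustment for estimation uncertainty — clipped at zero
#' (a negative slope signals no detectable inflation).
#'
#' @param grid An `inflation_grid` from [run_inflation_grid()], or any data
#'   frame with columns `nh2` (or `n` and `h2_delta`) and `mean_z2`.
#' @return An object of class `phi_estimate`: `mediator_id`, `slope`,
#'   `slope_se`, `phi`, `intercept`, `r2`, `n_points`, and the `grid`.
#' @export
estimate_phi <- function(grid) {
  df <- as.data.frame(grid)
  if (!"nh2" %in% colnames(df)) {
    if (!all(c("n", "h2_delta") %in% colnames(df))) {
      abort_domain("grid must contain nh2 or both n and h2_delta")
    }
    df$nh2 <- df$n * df$h2_delta
  }
  if (!"mean_z2" %in% colnames(df)) abort_domain("grid must contain mean_z2")
  if (length(unique(df$nh2)) < 2) {
    abort_rank("inflation grid needs at least 2 distinct values of n * h2")
  }
  fit <- stats::lm(mean_z2 ~ nh2, data = df)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit)) # exact grids trip the perfect-fit warning
  se <- sm$coefficients["nh2", "Std. Error"]
  if (!is.finite(se)) se <- 0 # saturated fit (2 points): no residual df
  slope <- unname(cf["nh2"])
  structure(
    list(
      mediator_id = attr(grid, "mediator_id") %||% "mediator",
      slope = slope,
      slope_se = se,
      phi = max(slope + se, 0),
      intercept = unname(cf["(Intercept)"]),
      r2 = sm$r.squared,
      n_points = nrow(df),
      grid = df
    ),
    class = "phi_estimate"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phi_estimate <- function(x, ...) {
  cat(sprintf(
    "phi_estimate '%s': slope = %.4g (SE %.3g), phi = %.4g, intercept = %.3f, R^2 = %.3f\n",
    x$mediator_id, x$slope, x$slope_se, x$phi, x$intercept, x$r2
  ))
  invisible(x)
}

#' Analytic inflation slope for known LD
#'
#' Computes `(1/m_causal) * (w' Sigma^2 w) / (w' Sigma w)` for a weight
#' vector `w` and SNP correlation matrix `Sigma`; weights for variants
#' absent from `Sigma` are set to zero. With independent standardized SNPs
#' (`Sigma = I`) this reduces to `1 / m_causal`. The effective number of
#' causal SNPs and the true LD matrix are rarely available in practice, so
#' this is a validation oracle for the empirical estimator, not the
#' production path.
#'
#' @param weights A [weight_set()] (matched to `sigma` by variant id) or a
#'   numeric vector already aligned with `sigma`.
#' @param sigma An [ld_matrix()].
#' @param m_causal Effective number of causal SNPs for the target trait.
#' @return The inflation slope, a nonnegative scalar.
#' @export
#' @examples
#' s <- ld_matrix(diag(5))
#' theoretical_phi(rep(1, 5), s, m_causal = 5) # 1/5
theoretical_phi <- function(weights, sigma, m_causal) {
  if (!inherits(sigma, "ld_matrix")) sigma <- ld_matrix(sigma)
  if (!is_count(m_causal) || m_causal < 1) abort_domain("m_causal must be >= 1")
  m <- ncol(sigma$sigma)
  if (inherits(weights, "weight_set")) {
    w <- numeric(m)
    i <- match(weights$entries$variant_id, sigma$variant_ids)
    w[i[!is.na(i)]] <- weights$entries$weight[!is.na(i)]
  } else {
    w <- as.numeric(weights)
    if (length(w) != m) abort_domain("weight vector length must match the LD dimension")
  }
  if (all(w == 0)) abort_degenerate("weight vector is identically zero")
  sw <- as.vector(sigma$sigma %*% w)
  denom <- sum(w * sw)
  if (denom <= 1e-12) abort_degenerate("w' Sigma w is zero; weights lie in the LD null space")
  (sum(sw^2) / denom) / m_causal
}

#' Expected squared Z under the polygenic null
#'
#' `E[Z^2] = 1 + n * h2_delta * phi`.
#'
#' @param n GWAS sample size.
#' @param h2_delta Polygenic heritability of the target trait in \[0, 1\].
#' @param phi Inflation slope (>= 0).
#' @return Expected mean squared Z.
#' @export
expected_z2 <- function(n, h2_delta, phi) {
  if (!is_scalar_num(n) || n < 0) abort_domain("n must be nonnegative")
  if (!is_scalar_num(h2_delta) || h2_delta < 0 || h2_delta > 1) {
    abort_domain("h2_delta must lie in [0, 1]")
  }
  if (!is_scalar_num(phi) || phi < 0) abort_domain("phi must be nonnegative")
  1 + n * h2_delta * phi
}

#' Expected squared Z with a nonzero mediator effect
#'
#' `E[Z^2] = 1 + n*h2_delta/(1 - tau2*h2_gene) * phi
#'             + n*tau2*h2_gene/(1 - tau2*h2_gene)`,
#' where `tau2 = var(T)/var(T~)` is the prediction precision and `h2_gene`
#' the variance share of the mediator. With `h2_gene = 0` this reduces to
#' [expected_z2()] regardless of `tau2`: prediction precision affects power
#' only, never null calibration.
#'
#' @param n GWAS sample size.
#' @param h2_delta Polygenic heritability in \[0, 1\].
#' @param phi Inflation slope (>= 0).
#' @param tau2 Prediction precision in \[0, 1\].
#' @param h2_gene Variance share explained by the mediator, with
#'   `tau2 * h2_gene < 1`.
#' @return Expected mean squared Z under the alternative.
#' @export
expected_z2_alt <- function(n, h2_delta, phi, tau2, h2_gene) {
  if (!is_scalar_num(tau2) || tau2 < 0 || tau2 > 1) abort_domain("tau2 must lie in [0, 1]")
  if (!is_scalar_num(h2_gene) || h2_gene < 0) abort_domain("h2_gene must be nonnegative")
  if (tau2 * h2_gene >= 1) abort_domain("tau2 * h2_gene must be < 1")
  base <- expected_z2(n, h2_delta, phi) # validates n, h2_delta, phi
  denom <- 1 - tau2 * h2_gene
  1 + (n * h2_delta / denom) * phi + n * tau2 * h2_gene / denom
}

#' Write a per-mediator phi table
#'
#' TSV with columns
#' `mediator_id phi slope slope_se intercept r2 n_replicates`.
#'
#' @param estimates A `phi_estimate` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phi_table <- function(estimates, path) {
  if (inherits(estimates, "phi_estimate")) estimates <- list(estimates)
  df <- data.frame(
    mediator_id = vapply(estimates, `[[`, character(1), "mediator_id"),
    phi = vapply(estimates, `[[`, numeric(1), "phi"),
    slope = vapply(estimates, `[[`, numeric(1), "slope"),
    slope_se = vapply(estimates, `[[`, numeric(1), "slope_se"),
    intercept = vapply(estimates, `[[`, numeric(1), "intercept"),
    r2 = vapply(estimates, `[[`, numeric(1), "r2"),
    n_replicates = vapply(estimates, function(e) e$n_points, numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-mediator phi table
#'
#' @param path TSV with at least `mediator_id` and `phi` columns.
#' @return Data frame.
#' @export
read_phi_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("phi table not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("mediator_id", "phi") %in% colnames(df))) {
    abort_format("phi table must have columns mediator_id and phi")
  }
  df
}
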