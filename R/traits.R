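#' Specification of a polygenic null target trait
#'
#' A null trait has no causal mediator effect (beta = 0). Its polygenic
#' component is `X delta` with `delta_k` i.i.d. normal on a random subset of
#' SNPs (proportion `prop_nonzero`), rescaled in-sample to explain exactly
#' `h2_delta` of the trait variance; the remaining `1 - h2_delta` is
#' independent noise.
#'
#' @param h2_delta Polygenic heritability in \[0, 1\].
#' @param prop_nonzero Proportion of SNPs with nonzero direct effect, in
#'   (0, 1\].
#' @param seed Optional integer seed.
#' @param df Optional degrees of freedom; when set, SNP effects and noise are
#'   drawn from a Student-t (scaled to unit variance) instead of the normal,
#'   a robustness option for heavy-tailed architectures. Requires `df > 2`.
#' @return An object of class `null_trait_spec`.
#' @export
null_trait_spec <- function(h2_delta, prop_nonzero = 1, seed = NULL, df = NULL) {
  if (!is_scalar_num(h2_delta) || h2_delta < 0 || h2_delta > 1) {
    abort_domain("h2_delta must lie in [0, 1]")
  }
  if (!is_scalar_num(prop_nonzero) || prop_nonzero <= 0 || prop_nonzero > 1) {
    abort_domain("prop_nonzero must lie in (0, 1]")
  }
  if (!is.null(df) && (!is_scalar_num(df) || df <= 2)) {
    abort_domain("df must exceed 2 for unit-variance scaling")
  }
  structure(
    list(h2_delta = h2_delta, prop_nonzero = prop_nonzero, seed = seed, df = df),
    class = "null_trait_spec"
  )
}

#' Specification of an alternative target trait
#'
#' An alternative trait adds a mediated component: `n_causal` mediators are
#' sampled uniformly and contribute `sum_g T_g * beta_g`, rescaled to
#' explain exactly `h2_gene` of the trait variance, on top of a polygenic
#' component (`h2_delta`) and noise (`1 - h2_delta - h2_gene`).
#'
#' @param h2_delta Polygenic heritability.
#' @param h2_gene Variance share explained by causal mediators; requires
#'   `h2_delta + h2_gene < 1`.
#' @param n_causal Number of causal mediators (>= 1).
#' @param beta_g Fixed per-mediator effect size; the realized genic variance
#'   is pinned to `h2_gene` by rescaling regardless of its magnitude.
#' @param prop_nonzero Proportion of SNPs with nonzero polygenic effect.
#' @param seed Optional integer seed.
#' @param df Optional Student-t degrees of freedom (see [null_trait_spec()]).
#' @return An object of class `alt_trait_spec`.
#' @export
alt_trait_spec <- function(h2_delta, h2_gene, n_causal, beta_g = 1,
                           prop_nonzero = 1, seed = NULL, df = NULL) {
  if (!is_scalar_num(h2_delta) || h2_delta < 0 || h2_delta > 1) {
    abort_domain("h2_delta must lie in [0, 1]")
  }
  if (!is_scalar_num(h2_gene) || h2_gene < 0 || h2_gene > 1) {
    abort_domain("h2_gene must lie in [0, 1]")
  }
  if (h2_delta + h2_gene > 1) abort_domain("h2_delta + h2_gene must not exceed 1")
  if (!is_count(n_causal) || n_causal < 1) abort_domain("n_causal must be >= 1")
  if (!is_scalar_num(beta_g)) abort_domain("beta_g must be a finite scalar")
  if (!is_scalar_num(prop_nonzero) || prop_nonzero <= 0 || prop_nonzero > 1) {
    abort_domain("prop_nonzero must lie in (0, 1]")
  }
  if (!is.null(df) && (!is_scalar_num(df) || df <= 2)) {
    abort_domain("df must exceed 2 for unit-variance scaling")
  }
  structure(
    list(h2_delta = h2_delta, h2_gene = h2_gene, n_causal = n_causal,
         beta_g = beta_g, prop_nonzero = prop_nonzero, seed = seed, df = df),
    class = "alt_trait_spec"
  )
}

# Unit-variance draws: normal by default, scaled Student-t when df is set.
draw_effects <- function(n, df) {
  if (is.null(df)) stats::rnorm(n) else stats::rt(n, df) / sqrt(df / (df - 2))
}

new_sim_trait <- function(y, polygenic, genic, noise, causal_ids, spec) {
  structure(
    list(y = y, polygenic_component = polygenic, genic_component = genic,
         noise_component = noise, causal_ids = causal_ids, spec = spec),
    class = "sim_trait"
  )
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf(
    "sim_trait: n = %d, var shares polygenic %.3f / genic %.3f / noise %.3f%s\n",
    length(x$y), stats::var(x$polygenic_component), stats::var(x$genic_component),
    stats::var(x$noise_component),
    if (length(x$causal_ids)) sprintf(", %d causal mediators", length(x$causal_ids)) else ""
  ))
  invisible(x)
}

# Draw the polygenic component X * delta (centered), resampling on the
# pathological all-zero draw, and return it scaled to variance h2.
draw_polygenic <- function(g, h2, prop_nonzero, df) {
  n <- nrow(g$dosages)
  if (h2 == 0) return(rep(0, n))
  m <- ncol(g$dosages)
  n_nonzero <- max(1L, as.integer(round(prop_nonzero * m)))
  for (try in 1:10) {
    delta <- draw_effects(m, df)
    if (n_nonzero < m) {
      keep <- sample.int(m, n_nonzero)
      mask <- numeric(m)
      mask[keep] <- 1
      delta <- delta * mask
    }
    raw <- as.vector(g$dosages %*% delta)
    raw <- raw - mean(raw)
    if (stats::sd(raw) > 0) return(scale_to_var(raw, h2, "polygenic component"))
    warning("degenerate zero polygenic draw; resampling")
  }
  abort_degenerate("polygenic component X * delta has zero variance after 10 resampling attempts")
}

#' Simulate a polygenic null target trait
#'
#' Generates `Y = X delta + epsilon` with `beta = 0`: SNP effects on a
#' random `prop_nonzero` subset, polygenic part rescaled to sample variance
#' `h2_delta`, noise rescaled to `1 - h2_delta`. The noise is residualized
#' in-sample against the polygenic part before rescaling so the variance
#' partition — and `var(y) = 1` — hold exactly per replicate, not just in
#' expectation.
#'
#' @param g A standardized [genotype_matrix()] with at least 3 samples.
#' @param spec A [null_trait_spec()].
#' @return A `sim_trait` with empty `causal_ids`.
#' @export
#' @examples
#' g <- standardize_genotypes(simulate_genotypes(200, 50, 0.4, seed = 3))
#' y <- simulate_null_trait(g, null_trait_spec(h2_delta = 0.5, seed = 4))
#' var(y$y)
simulate_null_trait <- function(g, spec) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "null_trait_spec"))
  if (!g$standardized) abort_domain("genotypes must be standardized")
  n <- nrow(g$dosages)
  if (n < 3) abort_domain("need at least 3 samples")
  with_seed(spec$seed, {
    polygenic <- draw_polygenic(g, spec$h2_delta, spec$prop_nonzero, spec$df)
    noise <- if (spec$h2_delta == 1) {
      rep(0, n)
    } else {
      e <- draw_effects(n, spec$df)
      e <- e - mean(e)
      if (spec$h2_delta > 0) e <- orthogonalize(e, list(polygenic))
      scale_to_var(e, 1 - spec$h2_delta, "noise component")
    }
    genic <- rep(0, n)
    new_sim_trait(polygenic + genic + noise, polygenic, genic, noise,
                  character(0), spec)
  })
}

#' Simulate an alternative target trait with causal mediators
#'
#' Samples `n_causal` mediators uniformly without replacement, forms the
#' genic component `sum_g T_g * beta_g`, and assembles
#' `Y = polygenic + genic + noise` with exact variance shares
#' `(h2_delta, h2_gene, 1 - h2_delta - h2_gene)`. As in
#' [simulate_null_trait()], later components are residualized in-sample
#' against earlier ones before rescaling; the polygenic component itself is
#' untouched, so mediator-polygenic correlation (the source of inflation)
#' is preserved.
#'
#' @param g A standardized [genotype_matrix()].
#' @param mediators List of [predict_mediator()] outputs, length >=
#'   `spec$n_causal`.
#' @param spec An [alt_trait_spec()].
#' @return A `sim_trait`; `causal_ids` records the sampled mediators.
#' @export
simulate_alt_trait <- function(g, mediators, spec) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "alt_trait_spec"))
  if (!g$standardized) abort_domain("genotypes must be standardized")
  if (inherits(mediators, "predicted_mediator")) mediators <- list(mediators)
  if (spec$h2_delta + spec$h2_gene >= 1) {
    abort_domain("h2_delta + h2_gene must be < 1 (noise share would vanish)")
  }
  if (spec$n_causal > length(mediators)) {
    abort_domain("n_causal exceeds the number of available mediators")
  }
  n <- nrow(g$dosages)
  if (n < 3) abort_domain("need at least 3 samples")
  with_seed(spec$seed, {
    pick <- sample.int(length(mediators), spec$n_causal)
    causal_ids <- vapply(mediators[pick], function(m) m$mediator_id, character(1))
    polygenic <- draw_polygenic(g, spec$h2_delta, spec$prop_nonzero, spec$df)
    genic <- if (spec$h2_gene == 0) {
      rep(0, n)
    } else {
      if (spec$beta_g == 0) {
        abort_degenerate("h2_gene > 0 requires beta_g != 0")
      }
      graw <- Reduce(`+`, lapply(mediators[pick], function(m) m$values * spec$beta_g))
      graw <- graw - mean(graw)
      if (spec$h2_delta > 0) graw <- orthogonalize(graw, list(polygenic))
      scale_to_var(graw, spec$h2_gene, "genic component")
    }
    e <- draw_effects(n, spec$df)
    e <- e - mean(e)
    e <- orthogonalize(e, list(polygenic, genic))
    noise <- scale_to_var(e, 1 - spec$h2_delta - spec$h2_gene, "noise component")
    new_sim_trait(polygenic + genic + noise, polygenic, genic, noise,
                  causal_ids, spec)
  })
}

#' Write a simulated trait and its generating specification
#'
#' The trait is written as TSV (`sample_id y polygenic genic noise`); the
#' spec is serialized to YAML alongside (`<path>.yaml`).
#'
#' @param trait A `sim_trait`.
#' @param path Output TSV path.
#' @param sample_ids Optional sample identifiers.
#' @return `path`, invisibly.
#' @export
write_trait <- function(trait, path, sample_ids = NULL) {
  stopifnot(inherits(trait, "sim_trait"))
  n <- length(trait$y)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  df <- data.frame(
    sample_id = sample_ids,
    y = trait$y,
    polygenic = trait$polygenic_component,
    genic = trait$genic_component,
    noise = trait$noise_component
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- trait$spec
  spec_list <- unclass(spec)
  spec_list$type <- class(spec)[1]
  spec_list <- spec_list[!vapply(spec_list, is.null, logical(1))]
  yaml::write_yaml(spec_list, paste0(path, ".yaml"))
  invisible(path)
}
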