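#' Mediator prediction weights
#'
#' A `weight_set` holds the per-variant prediction weights of one mediating
#' molecular trait (gene expression, metabolite level, brain feature). The
#' genetic component of the mediator is the linear combination of genotype
#' dosages with these weights.
#'
#' @param mediator_id Identifier of the mediator.
#' @param variant_ids Character vector of unique variant identifiers.
#' @param ref_allele,eff_allele Allele labels per variant; the weight applies
#'   to the dosage of the effect allele.
#' @param weights Numeric weights, at least one nonzero.
#' @param mediator_class One of `"gene"`, `"metabolite"`, `"brain_feature"`,
#'   `"other"`.
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(mediator_id, variant_ids, ref_allele, eff_allele, weights,
                       mediator_class = c("gene", "metabolite", "brain_feature", "other")) {
  mediator_class <- match.arg(mediator_class)
  variant_ids <- as.character(variant_ids)
  m <- length(variant_ids)
  if (m == 0L) abort_domain("weight_set needs at least one variant")
  if (anyDuplicated(variant_ids)) abort_domain("variant_ids must be unique within a weight_set")
  weights <- as.numeric(weights)
  if (length(weights) != m || any(!is.finite(weights))) {
    abort_domain("weights must be finite with one entry per variant")
  }
  if (all(weights == 0)) abort_domain("weight_set must contain at least one nonzero weight")
  entries <- data.frame(
    variant_id = variant_ids,
    ref_allele = as.character(rep_len(ref_allele, m)),
    eff_allele = as.character(rep_len(eff_allele, m)),
    weight = weights,
    stringsAsFactors = FALSE
  )
  structure(
    list(mediator_id = as.character(mediator_id), entries = entries,
         mediator_class = mediator_class),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf(
    "weight_set '%s' (%s): %d variants, %d nonzero weights\n",
    x$mediator_id, x$mediator_class, nrow(x$entries), sum(x$entries$weight != 0)
  ))
  invisible(x)
}

#' Simulate true mediator weights
#'
#' Draws i.i.d. standard-normal weights on a uniformly chosen subset of
#' variants (size `round(sparsity * n_snps)`, at least one), zero elsewhere.
#' With `sparsity = 1` this is the fully polygenic mediator of the minimal
#' inflation example.
#'
#' @param n_snps Number of variants.
#' @param sparsity Proportion in (0, 1] of variants with nonzero weight.
#' @param seed Optional integer seed.
#' @param variant_ids Optional ids; defaults to the `snp_<k>` ids used by
#'   [simulate_genotypes()].
#' @param mediator_id Identifier for the simulated mediator.
#' @param mediator_class Mediator class label.
#' @return A [weight_set()].
#' @export
simulate_true_weights <- function(n_snps, sparsity, seed = NULL, variant_ids = NULL,
                                  mediator_id = "mediator_1", mediator_class = "gene") {
  if (!is_count(n_snps) || n_snps < 1) abort_domain("n_snps must be a positive count")
  if (!is_scalar_num(sparsity) || sparsity <= 0 || sparsity > 1) {
    abort_domain("sparsity must lie in (0, 1]")
  }
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", seq_len(n_snps))
  n_nonzero <- max(1L, as.integer(round(sparsity * n_snps)))
  w <- with_seed(seed, {
    idx <- sample.int(n_snps, n_nonzero)
    out <- numeric(n_snps)
    out[idx] <- stats::rnorm(n_nonzero)
    out
  })
  weight_set(mediator_id, variant_ids, rep("A", n_snps), rep("G", n_snps), w,
             mediator_class = mediator_class)
}

#' Add independent noise to prediction weights
#'
#' Returns noisy weights `w + e` with `e ~ N(0, noise_sd^2)` independent of
#' everything else — the error-in-variables setting in which imperfect
#' prediction reduces power but does not inflate type I error.
#'
#' @param w A [weight_set()].
#' @param noise_sd Standard deviation of the additive weight noise.
#' @param seed Optional integer seed.
#' @return A [weight_set()] with perturbed weights.
#' @export
perturb_weights <- function(w, noise_sd, seed = NULL) {
  stopifnot(inherits(w, "weight_set"))
  if (!is_scalar_num(noise_sd) || noise_sd < 0) abort_domain("noise_sd must be >= 0")
  e <- with_seed(seed, stats::rnorm(nrow(w$entries), sd = noise_sd))
  weight_set(w$mediator_id, w$entries$variant_id, w$entries$ref_allele,
             w$entries$eff_allele, w$entries$weight + e,
             mediator_class = w$mediator_class)
}

weights_to_frame <- function(ws) {
  data.frame(
    gene = ws$mediator_id,
    rsid = ws$entries$variant_id,
    ref_allele = ws$entries$ref_allele,
    eff_allele = ws$entries$eff_allele,
    weight = ws$entries$weight,
    stringsAsFactors = FALSE
  )
}

frame_to_weights <- function(df, mediator_class = "gene") {
  if (nrow(df) == 0L) abort_format("empty weight table")
  if (anyDuplicated(df[, c("gene", "rsid")])) {
    abort_format("duplicate (gene, rsid) rows in weight table")
  }
  out <- lapply(split(df, df$gene), function(d) {
    weight_set(d$gene[1], d$rsid, d$ref_allele, d$eff_allele, d$weight,
               mediator_class = mediator_class)
  })
  out[order(names(out))]
}

#' Read mediator prediction weights
#'
#' Two dialects are supported: a plain TSV with header
#' `gene rsid ref_allele eff_allele weight`, and a PredictDB-style
#' single-file SQLite database with a `weights` table (and an optional
#' `extra` table carrying inflation-slope metadata, returned as the
#' `"phi_table"` attribute).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"predictdb"`.
#' @param mediator_class Class label applied to all mediators read.
#' @return A named list of [weight_set()] objects, ordered by mediator id.
#' @export
load_weights <- function(path, dialect = c("tsv", "predictdb"), mediator_class = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format(sprintf("weights file not found: %s", path))
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene", "rsid", "ref_allele", "eff_allele", "weight")
    if (!all(need %in% colnames(df))) {
      abort_format(sprintf(
        "weights TSV %s must have columns: %s", path, paste(need, collapse = " ")
      ))
    }
    return(frame_to_weights(df[need], mediator_class))
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  if (!"weights" %in% DBI::dbListTables(con)) {
    abort_format(sprintf("predictdb file %s has no 'weights' table", path))
  }
  df <- DBI::dbReadTable(con, "weights")
  out <- frame_to_weights(df[c("gene", "rsid", "ref_allele", "eff_allele", "weight")],
                          mediator_class)
  if ("extra" %in% DBI::dbListTables(con)) {
    attr(out, "phi_table") <- DBI::dbReadTable(con, "extra")
  }
  out
}

#' Write mediator prediction weights
#'
#' Emits either the canonical TSV dialect or a PredictDB-style SQLite file
#' with `weights(gene, rsid, varID, ref_allele, eff_allele, weight)` and
#' `extra(gene, n_snps_in_model, phi, phi_se)`; inflation-slope metadata is
#' filled from `phi_table` when supplied.
#'
#' @param weight_sets A [weight_set()] or list of them.
#' @param path Output file path.
#' @param dialect `"tsv"` or `"predictdb"`.
#' @param phi_table Optional data frame with columns `mediator_id`, `phi`,
#'   and optionally `slope_se`, written to the `extra` table.
#' @return `path`, invisibly.
#' @export
save_weights <- function(weight_sets, path, dialect = c("tsv", "predictdb"),
                         phi_table = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(weight_sets, "weight_set")) weight_sets <- list(weight_sets)
  if (length(weight_sets) == 0L) abort_format("no weight sets to write")
  df <- do.call(rbind, lapply(weight_sets, weights_to_frame))
  df <- df[order(df$gene, df$rsid), , drop = FALSE]
  if (dialect == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  df$varID <- df$rsid
  DBI::dbWriteTable(con, "weights",
                    df[c("gene", "rsid", "varID", "ref_allele", "eff_allele", "weight")])
  extra <- data.frame(
    gene = vapply(weight_sets, function(w) w$mediator_id, character(1)),
    n_snps_in_model = vapply(weight_sets, function(w) nrow(w$entries), integer(1)),
    phi = NA_real_, phi_se = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(phi_table)) {
    i <- match(extra$gene, phi_table$mediator_id)
    extra$phi <- phi_table$phi[i]
    if ("slope_se" %in% colnames(phi_table)) extra$phi_se <- phi_table$slope_se[i]
  }
  DBI::dbWriteTable(con, "extra", extra)
  invisible(path)
}

#' Predict a mediator from genotypes and weights
#'
#' Computes the genetic component of the mediator as the weighted sum of
#' standardized dosage columns. Weight variants absent from the genotype
#' matrix are skipped and counted; when the weight's ref/eff alleles are
#' swapped relative to the genotype metadata, the weight sign is flipped
#' (`allele_policy = "flip"`) or the variant is dropped
#' (`allele_policy = "drop"`).
#'
#' @param g A standardized [genotype_matrix()].
#' @param w A [weight_set()].
#' @param allele_policy `"flip"` or `"drop"`.
#' @param strict If `TRUE`, any missing or dropped variant is an error.
#' @return An object of class `predicted_mediator` with fields
#'   `mediator_id`, `values`, `n_variants_used`, `n_variants_missing`.
#' @export
predict_mediator <- function(g, w, allele_policy = c("flip", "drop"), strict = FALSE) {
  allele_policy <- match.arg(allele_policy)
  stopifnot(inherits(g, "genotype_matrix"), inherits(w, "weight_set"))
  if (!g$standardized) abort_domain("genotypes must be standardized before prediction")
  idx <- match(w$entries$variant_id, g$variant_ids)
  present <- !is.na(idx)
  wts <- w$entries$weight
  use <- logical(nrow(w$entries))
  for (i in which(present)) {
    j <- idx[i]
    same <- w$entries$ref_allele[i] == g$ref_allele[j] &&
      w$entries$eff_allele[i] == g$eff_allele[j]
    swapped <- w$entries$ref_allele[i] == g$eff_allele[j] &&
      w$entries$eff_allele[i] == g$ref_allele[j]
    if (same) {
      use[i] <- TRUE
    } else if (swapped && allele_policy == "flip") {
      use[i] <- TRUE
      wts[i] <- -wts[i]
    }
    # swapped + drop, or allele mismatch: variant is dropped and counted
  }
  n_used <- sum(use)
  n_missing <- nrow(w$entries) - n_used
  if (n_used == 0L) {
    abort_twasvc(
      sprintf("no weight variant of '%s' matched the genotype matrix", w$mediator_id),
      c("twasvc_empty_overlap_error", "twasvc_domain_error")
    )
  }
  if (strict && n_missing > 0L) {
    abort_domain(sprintf(
      "%d weight variant(s) of '%s' missing from genotypes (strict mode)",
      n_missing, w$mediator_id
    ))
  }
  if (n_missing > 0L) {
    message(sprintf("predict_mediator: %d of %d variants of '%s' not used",
                    n_missing, nrow(w$entries), w$mediator_id))
  }
  values <- as.vector(g$dosages[, idx[use], drop = FALSE] %*% wts[use])
  structure(
    list(mediator_id = w$mediator_id, values = values,
         n_variants_used = n_used, n_variants_missing = n_missing),
    class = "predicted_mediator"
  )
}

#' @export
print.predicted_mediator <- function(x, ...) {
  cat(sprintf("predicted_mediator '%s': n = %d, %d variants used, %d missing\n",
              x$mediator_id, length(x$values), x$n_variants_used, x$n_variants_missing))
  invisible(x)
}
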