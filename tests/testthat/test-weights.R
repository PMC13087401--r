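test_that("TSV weight tables round-trip and preserve per-gene structure", {
  ws <- list(
    weight_set("geneA", c("rs1", "rs2", "rs3"), "A", "G", c(0.5, -2, 0.1)),
    weight_set("geneB", c("rs1", "rs4", "rs5"), "A", "G", c(1, 2, 3))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  save_weights(ws, path, dialect = "tsv")
  got <- load_weights(path, dialect = "tsv")
  expect_named(got, c("geneA", "geneB"))
  expect_equal(vapply(got, function(w) nrow(w$entries), integer(1)),
               c(geneA = 3L, geneB = 3L))
  expect_equal(got$geneA$entries$weight, c(0.5, -2, 0.1))
})

test_that("predictdb dialect round-trips weights and phi metadata", {
  ws <- list(
    weight_set("geneA", c("rs1", "rs2"), "A", "G", c(0.5, -2)),
    weight_set("geneB", c("rs3"), "C", "T", 1.5)
  )
  db <- withr::local_tempfile(fileext = ".db")
  phi_tab <- data.frame(mediator_id = c("geneA", "geneB"),
                        phi = c(2e-5, 5e-5), slope_se = c(1e-6, 2e-6))
  save_weights(ws, db, dialect = "predictdb", phi_table = phi_tab)
  got <- load_weights(db, dialect = "predictdb")
  expect_named(got, c("geneA", "geneB"))
  expect_equal(got$geneA$entries$weight, c(0.5, -2))
  expect_equal(got$geneB$entries$ref_allele, "C")
  extra <- attr(got, "phi_table")
  expect_equal(extra$phi[match(c("geneA", "geneB"), extra$gene)], c(2e-5, 5e-5))
})

test_that("malformed weight tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\trsid\tref_allele\teff_allele\tweight",
               "g1\trs1\tA\tG\t0.5",
               "g1\trs1\tA\tG\t0.7"), path)
  expect_error(load_weights(path), class = "twasvc_format_error")

  writeLines("gene\trsid\tref_allele\teff_allele\tweight", path)
  expect_error(load_weights(path), class = "twasvc_format_error")

  expect_error(weight_set("g", c("rs1", "rs1"), "A", "G", c(1, 2)),
               class = "twasvc_domain_error")
  expect_error(weight_set("g", "rs1", "A", "G", 0),
               class = "twasvc_domain_error")
})

test_that("simulated true weights honor the sparsity contract", {
  w_full <- simulate_true_weights(999, 1, seed = 51)
  expect_equal(sum(w_full$entries$weight != 0), 999L)
  w_sparse <- simulate_true_weights(100, 0.01, seed = 52)
  expect_equal(sum(w_sparse$entries$weight != 0), 1L)
  expect_error(simulate_true_weights(100, 0), class = "twasvc_domain_error")
})

test_that("prediction reproduces hand arithmetic on standardized dosages", {
  dos <- cbind(c(0, 1, 2), c(2, 1, 0))
  g <- standardize_genotypes(genotype_matrix(dos, c("rs1", "rs2"),
                                             c("A", "A"), c("G", "G"),
                                             c(0.4, 0.4), paste0("s", 1:3)))
  # single variant, weight 1: identity on the standardized column
  w1 <- weight_set("g1", "rs1", "A", "G", 1)
  expect_equal(predict_mediator(g, w1)$values, pop_standardize(dos[, 1]),
               tolerance = 1e-12)

  # two variants, weights (0.5, -2): hand arithmetic
  w2 <- weight_set("g2", c("rs1", "rs2"), "A", "G", c(0.5, -2))
  by_hand <- 0.5 * pop_standardize(dos[, 1]) - 2 * pop_standardize(dos[, 2])
  expect_equal(predict_mediator(g, w2)$values, by_hand, tolerance = 1e-10)
})

test_that("allele orientation is resolved by flipping or dropping", {
  p <- make_panel(n = 100, m = 4, seed = 61)
  base <- weight_set("g", p$g$variant_ids, p$g$ref_allele, p$g$eff_allele,
                     c(1, -0.5, 2, 0.3))
  swapped <- weight_set("g", p$g$variant_ids, p$g$eff_allele, p$g$ref_allele,
                        -c(1, -0.5, 2, 0.3))
  # every entry allele-flipped with negated weight predicts identically
  expect_equal(predict_mediator(p$gs, swapped, allele_policy = "flip")$values,
               predict_mediator(p$gs, base)$values, tolerance = 1e-12)

  one_swap <- weight_set("g", p$g$variant_ids,
                         c(p$g$eff_allele[1], p$g$ref_allele[-1]),
                         c(p$g$ref_allele[1], p$g$eff_allele[-1]),
                         c(-1, -0.5, 2, 0.3))
  expect_equal(predict_mediator(p$gs, one_swap, allele_policy = "flip")$values,
               predict_mediator(p$gs, base)$values, tolerance = 1e-12)
  dropped <- predict_mediator(p$gs, one_swap, allele_policy = "drop")
  expect_equal(dropped$n_variants_used, 3L)
  expect_equal(dropped$n_variants_missing, 1L)
})

test_that("missing model variants are skipped and counted", {
  p <- make_panel(n = 50, m = 3, seed = 62)
  w <- weight_set("g", c(p$g$variant_ids, "rs_absent"), "A", "G", c(1, 2, 3, 4))
  expect_message(pm <- predict_mediator(p$gs, w), "not used")
  expect_equal(pm$n_variants_used, 3L)
  expect_equal(pm$n_variants_missing, 1L)
  expect_equal(pm$n_variants_used + pm$n_variants_missing, nrow(w$entries))
  expect_error(predict_mediator(p$gs, w, strict = TRUE),
               class = "twasvc_domain_error")

  none <- weight_set("g", c("rs_x", "rs_y"), "A", "G", c(1, 2))
  expect_error(predict_mediator(p$gs, none), class = "twasvc_empty_overlap_error")
  expect_error(predict_mediator(p$g, w), class = "twasvc_domain_error") # unstandardized
})

test_that("prediction is linear in the weights", {
  p <- make_panel(n = 80, m = 10, seed = 63)
  set.seed(64)
  for (i in 1:20) {
    w1 <- rnorm(10); w2 <- rnorm(10)
    ws1 <- weight_set("a", p$g$variant_ids, p$g$ref_allele, p$g$eff_allele, w1)
    ws2 <- weight_set("b", p$g$variant_ids, p$g$ref_allele, p$g$eff_allele, w2)
    ws12 <- weight_set("ab", p$g$variant_ids, p$g$ref_allele, p$g$eff_allele, w1 + w2)
    # brute-force loop over variants as the independent oracle
    by_loop <- numeric(80)
    for (k in 1:10) by_loop <- by_loop + p$gs$dosages[, k] * (w1[k] + w2[k])
    expect_equal(predict_mediator(p$gs, ws12)$values,
                 predict_mediator(p$gs, ws1)$values + predict_mediator(p$gs, ws2)$values,
                 tolerance = 1e-10)
    expect_equal(predict_mediator(p$gs, ws12)$values, by_loop, tolerance = 1e-10)
  }
})

test_that("weight noise perturbation preserves structure", {
  w <- simulate_true_weights(50, 1, seed = 65)
  wn <- perturb_weights(w, 0.5, seed = 66)
  expect_equal(wn$entries$variant_id, w$entries$variant_id)
  expect_false(any(wn$entries$weight == w$entries$weight))
  expect_equal(perturb_weights(w, 0)$entries$weight, w$entries$weight)
})
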