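test_that("inflation grid has one summary per (n, h2) cell", {
  p <- make_panel(n = 300, m = 40, seed = 301)
  grid <- run_inflation_grid(p$g, p$t, n_values = c(100, 200, 300),
                             h2_values = c(0, 0.5), n_replicates = 30, seed = 302)
  expect_equal(nrow(grid), 6L)
  expect_equal(grid$nh2, grid$n * grid$h2_delta)
  expect_true(all(grid$mean_z2 >= 0))
  expect_error(
    run_inflation_grid(p$g, p$t, n_values = 600, h2_values = 0.5,
                       n_replicates = 10),
    class = "twasvc_domain_error"
  )
  expect_error(
    run_inflation_grid(p$g, p$t, n_values = 100, h2_values = 1.5,
                       n_replicates = 10),
    class = "twasvc_domain_error"
  )
})

test_that("zero-heritability grids stay inside the chi-square(1) band", {
  p <- make_panel(n = 250, m = 40, seed = 303)
  grid <- run_inflation_grid(p$g, p$t, n_values = c(120, 250), h2_values = 0,
                             n_replicates = 300, seed = 304)
  for (i in seq_len(nrow(grid))) {
    expect_lt(abs(grid$mean_z2[i] - 1), chisq1_band(300))
  }
})

test_that("estimate_phi reproduces an exact linear grid", {
  grid <- data.frame(n = rep(c(1000, 2000, 5000), 2),
                     h2_delta = rep(c(0.5, 1), each = 3))
  grid$nh2 <- grid$n * grid$h2_delta
  grid$mean_z2 <- 1 + 3e-5 * grid$nh2
  est <- estimate_phi(grid)
  expect_equal(est$slope, 3e-5, tolerance = 1e-12)
  expect_equal(est$intercept, 1, tolerance = 1e-10)
  expect_equal(est$slope_se, 0, tolerance = 1e-12)
  expect_equal(est$phi, 3e-5, tolerance = 1e-12)
  expect_equal(est$r2, 1, tolerance = 1e-10)

  expect_error(estimate_phi(data.frame(nh2 = c(500, 500), mean_z2 = c(1, 2))),
               class = "twasvc_rank_error")
})

test_that("estimate_phi recovers a planted slope within 2 SEs, phi always >= slope", {
  set.seed(305)
  phi_true <- 4.2e-5
  nh2 <- rep(c(0, 1000, 5000, 10000, 20000), each = 2)
  n_inside <- 0
  for (rep in 1:50) {
    mean_z2 <- 1 + phi_true * nh2 + rnorm(length(nh2), sd = 0.05)
    est <- estimate_phi(data.frame(nh2 = nh2, mean_z2 = mean_z2))
    if (abs(est$slope - phi_true) <= 2 * est$slope_se) n_inside <- n_inside + 1
    expect_gte(est$phi, est$slope)
    expect_gte(est$phi, 0)
  }
  expect_gte(n_inside, 45) # ~95% coverage of the 2 SE interval
})

test_that("empirical phi matches the analytic 1/M oracle for independent SNPs", {
  p <- make_panel(n = 600, m = 150, seed = 306)
  grid <- run_inflation_grid(p$g, p$t, n_values = c(300, 600),
                             h2_values = c(0, 0.5, 1), n_replicates = 250,
                             seed = 307)
  est <- estimate_phi(grid)
  expect_lt(abs(est$slope - 1 / 150), 2 * est$slope_se + 1e-4)
})

test_that("analytic phi reduces to closed forms", {
  # identity LD: quadratic forms cancel to 1/m_causal for any weights
  set.seed(308)
  for (m in c(3, 10, 50)) {
    w <- rnorm(m)
    expect_equal(theoretical_phi(w, ld_matrix(diag(m)), m_causal = m), 1 / m,
                 tolerance = 1e-12)
  }
  # 2 SNPs, weight on the first only: (1 + r^2) / 2
  for (r in c(-0.9, 0.3, 0.7)) {
    s <- ld_matrix(matrix(c(1, r, r, 1), 2))
    expect_equal(theoretical_phi(c(1, 0), s, m_causal = 2), (1 + r^2) / 2,
                 tolerance = 1e-12)
  }
  expect_error(theoretical_phi(c(0, 0), ld_matrix(diag(2)), 2),
               class = "twasvc_degenerate_error")
})

test_that("weight sets align to the LD matrix with absent variants zeroed", {
  s <- ld_matrix(diag(4), variant_ids = paste0("rs", 1:4))
  w <- weight_set("g", c("rs2", "rs9"), "A", "G", c(2, 5))
  # rs9 is absent, so only rs2 contributes; identity LD still gives 1/m
  expect_equal(theoretical_phi(w, s, m_causal = 4), 1 / 4, tolerance = 1e-12)
})

test_that("expected Z^2 formulas match hand arithmetic and reduce correctly", {
  expect_equal(expected_z2(5000, 0.7, 0), 1)
  expect_equal(expected_z2(100000, 0.5, 4.2e-5), 3.1, tolerance = 1e-12)
  expect_error(expected_z2(100, 0.5, -1e-5), class = "twasvc_domain_error")

  # tau2 = 1, h2_gene = 0.05, h2_delta = 0, n = 1000: 1 + 50/0.95
  expect_equal(expected_z2_alt(1000, 0, 1e-5, 1, 0.05), 1 + 1000 * 0.05 / 0.95,
               tolerance = 1e-12)
  expect_equal(round(expected_z2_alt(1000, 0, 1e-5, 1, 0.05), 2), 53.63)
  expect_error(expected_z2_alt(1000, 0.5, 1e-5, 1, 1),
               class = "twasvc_domain_error")
})

test_that("null reduction of the alternative expectation is exact", {
  set.seed(309)
  for (i in 1:200) {
    n <- sample(1e3:1e6, 1)
    h2 <- runif(1)
    phi <- runif(1, 0, 1e-4)
    tau2 <- runif(1)
    expect_identical(expected_z2_alt(n, h2, phi, tau2, 0), expected_z2(n, h2, phi))
  }
})

test_that("expected Z^2 is monotone in n, h2, and phi", {
  base <- expected_z2(10000, 0.5, 2e-5)
  expect_gte(expected_z2(20000, 0.5, 2e-5), base)
  expect_gte(expected_z2(10000, 0.8, 2e-5), base)
  expect_gte(expected_z2(10000, 0.5, 4e-5), base)
})

test_that("phi estimates are stable across the nonzero-effect proportion", {
  # sensitivity of the slope to the polygenic architecture: estimates at
  # pi in {0.3, 0.5, 0.9} stay within 2 combined SEs of the pi = 1 estimate
  p <- make_panel(n = 500, m = 100, seed = 310)
  est_at <- function(pi, seed) {
    grid <- run_inflation_grid(p$g, p$t, n_values = c(150, 300, 500),
                               h2_values = c(0, 0.4, 0.8), n_replicates = 250,
                               seed = seed, prop_nonzero = pi)
    estimate_phi(grid)
  }
  ref <- est_at(1, 311)
  for (pi in c(0.3, 0.5, 0.9)) {
    est <- est_at(pi, 312 + round(10 * pi))
    combined <- sqrt(est$slope_se^2 + ref$slope_se^2)
    # sparser architectures may yield a slightly smaller slope (which only
    # makes the correction conservative); they must not yield a larger one
    expect_lt(est$slope - ref$slope, 2 * combined)
    if (pi > 0.3) expect_lt(ref$slope - est$slope, 2 * combined + 1e-4)
  }
})

test_that("phi tables round-trip through TSV", {
  p <- make_panel(n = 200, m = 20, seed = 320)
  grid <- run_inflation_grid(p$g, p$t, c(100, 200), c(0, 1), 30, seed = 321)
  est <- estimate_phi(grid)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phi_table(est, path)
  back <- read_phi_table(path)
  expect_equal(back$phi, est$phi, tolerance = 1e-10)
  expect_equal(back$slope_se, est$slope_se, tolerance = 1e-10)
})
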