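# Shared in-code fixtures and independent oracles.

# Small standardized genotype panel with a predicted mediator.
make_panel <- function(n = 400, m = 60, maf = 0.4, sparsity = 1, seed = 101) {
  g <- simulate_genotypes(n, m, maf, seed = seed)
  gs <- standardize_genotypes(g)
  w <- simulate_true_weights(m, sparsity, seed = seed + 1)
  list(g = g, gs = gs, w = w, t = predict_mediator(gs, w))
}

# Definitional correlation oracle: double loop, no vectorized shortcuts.
cor_oracle <- function(t, y) {
  n <- length(t)
  mt <- 0; my <- 0
  for (i in seq_len(n)) { mt <- mt + t[i]; my <- my + y[i] }
  mt <- mt / n; my <- my / n
  num <- 0; dt <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (t[i] - mt) * (y[i] - my)
    dt <- dt + (t[i] - mt)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dt * dy)
}

# Hand-standardize a dosage vector with the population (divide-by-n) SD.
pop_standardize <- function(x) {
  xc <- x - mean(x)
  xc / sqrt(mean(xc^2))
}

# Chi-square(1) sample-mean band half-width: k standard errors.
chisq1_band <- function(n_replicates, k = 3) k * sqrt(2 / n_replicates)
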