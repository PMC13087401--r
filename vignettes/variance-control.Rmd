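---
title: "Calibrating TWAS/xWAS statistics under polygenic target traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating TWAS/xWAS statistics under polygenic target traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasvc)
```

## The problem

Transcriptome-wide association studies (TWAS) and their generalizations
(xWAS: metabolite, protein, brain-imaging features) test whether a
*genetically predicted* mediator is associated with a complex trait. The
mediator is a fixed linear combination of genotype dosages,

$$T = \sum_k X_k \,\tilde\gamma_k,$$

with weights $\tilde\gamma$ trained in an external reference panel. The
trait model is $Y = T\beta + \epsilon$, and the standard test refers the
correlation-based statistic $Z = \sqrt{n}\, r(T, Y)$ to the standard
normal.

When the target trait is itself polygenic — $Y = \sum_k X_k \delta_k +
\epsilon$ with genome-wide small direct effects $\delta_k$ — the
polygenic background shares the genotypes with the mediator. Even with
$\beta = 0$ the variance of $Z$ exceeds 1, and it does so systematically:

$$\mathrm{E}[Z^2] \approx 1 + N h^2_\delta \, \Phi,$$

where $N$ is the GWAS sample size, $h^2_\delta$ the heritability of the
target trait, and $\Phi$ a slope specific to each mediator. For known LD
$\Sigma$ and an effective number of causal SNPs $M$ the slope has the
closed form

$$\Phi = \frac{1}{M}\,
  \frac{\tilde\gamma^\top \Sigma^2 \tilde\gamma}
       {\tilde\gamma^\top \Sigma \tilde\gamma},$$

which reduces to $1/M$ for independent standardized SNPs. In practice $M$
and the genome-wide $\Sigma$ are not estimable with useful accuracy, so
`theoretical_phi()` serves as a validation oracle while the production
path estimates $\Phi$ by simulation. The correction divides each score by
its null standard deviation,

$$Z_{\mathrm{corr}} = \frac{Z}{\sqrt{1 + \Phi N h^2_\delta}},$$

which restores $\mathrm{Var}(Z) = 1$ under the polygenic null. Because
the inflation slope differs across mediators, a single global factor —
genomic control's $\lambda = \mathrm{median}(Z^2)/\chi^2_{1,0.5}$,
provided here as `genomic_control()` — cannot calibrate all mediators at
once; that contrast is part of the test suite.

## The simulation machinery

`simulate_genotypes()` draws independent Binomial(2, MAF) dosages
(Hardy–Weinberg), the setting of the minimal inflation example: 1,000
individuals, 999 independent SNPs at MAF 0.4. `simulate_ld_genotypes()`
adds block-correlated SNPs through a Gaussian copula on haplotypes; real
cohorts' LD is far richer, but the copula is the minimal mechanism that
exercises the analytic slope away from $\Sigma = I$. Standardization uses
the population (divide-by-$n$) SD so that $X^\top X/n$ is exactly a
correlation matrix and $Z = \sqrt{n}\,r$ is exact algebra, not an
approximation; trait components, by contrast, are scaled with the usual
$n-1$ sample SD. The two conventions never mix because the correlation is
scale-free.

`simulate_null_trait()` builds $Y = X\delta + \epsilon$ with the SNP
effects drawn i.i.d. normal on a `prop_nonzero` subset, the polygenic part
rescaled to sample variance $h^2_\delta$ and the noise to $1 -
h^2_\delta$. Two numerical choices matter:

* **Exact partition.** Rescaling each component by its realized SD fixes
  the component variances but leaves cross-covariances of order
  $1/\sqrt{N}$, so $\mathrm{var}(Y)$ would only approximate 1. We
  residualize each later component in-sample against the earlier ones
  (noise against polygenic; for alternative traits, genic against
  polygenic and noise against both) before rescaling. The partition and
  $\mathrm{var}(Y) = 1$ then hold to machine precision in every
  replicate. The polygenic component itself is never touched, so the
  mediator–background correlation that generates the inflation is fully
  preserved.
* **Heavy tails.** A Student-$t$ option (`df`, scaled to unit variance)
  reproduces the robustness variant of the simulations; the partition is
  unaffected because scaling uses realized SDs.

`simulate_alt_trait()` adds $\sum_g T_g \beta_g$ for a uniform sample of
causal mediators, rescaled to variance $h^2_{\mathrm{gene}}$; because
this rescaling pins the genic share, the raw magnitude of `beta_g` is a
free parameter. `h2_delta + h2_gene` must stay below 1 so a noise
component remains.

## Estimating the inflation slope

`run_inflation_grid()` subsamples individuals without replacement at each
requested sample size, simulates `n_replicates` polygenic null traits per
$(N, h^2_\delta)$ cell, and records the mean $Z^2$ with its Monte-Carlo
standard error. `estimate_phi()` regresses mean $Z^2$ on $N h^2_\delta$
by unweighted OLS with a **free intercept** (fixing it at 1 is tempting,
but reported real-data intercepts sit slightly above 1, and a free
intercept makes misfit visible); the reported $\Phi$ is the slope **plus
one standard error**, clipped at zero — a deliberately conservative
choice that errs towards over-correction.

Seeds: every simulation takes a root seed and derives per-cell and
per-replicate child seeds with a deterministic integer split, so whole
experiments are bit-reproducible while replicates remain independent.

```{r phi-example}
g  <- simulate_genotypes(1000, 300, maf = 0.4, seed = 1)
gs <- standardize_genotypes(g)
tm <- predict_mediator(gs, simulate_true_weights(300, 1, seed = 2))
grid <- run_inflation_grid(g, tm, n_values = c(500, 1000),
                           h2_values = c(0, 0.5, 1),
                           n_replicates = 200, seed = 3)
est <- estimate_phi(grid)
est
# independent SNPs: the analytic slope is 1/M
1 / 300
```

## Applying the correction

```{r correct-example}
ctx <- correction_context(n = 100000, h2_delta = 0.5,
                          phi_table = data.frame(mediator_id = "gene_1",
                                                 phi = 4.2e-5))
variance_control(data.frame(mediator_id = "gene_1", zscore = 3), ctx)
```

A $Z$ of 3 ($p = 0.0027$) at biobank scale becomes 1.70 ($p = 0.088$):
nominally significant hits over a polygenic background are often
polygenicity, not mediation. Under the null reduction
$h^2_{\mathrm{gene}} = 0$, `expected_z2_alt()` is identical to
`expected_z2()` for every prediction precision $\tau^2$ — noisy weights
cost power but never type-I error, the error-in-variables corollary that
the property tests verify by adding independent weight noise.

## Default problem sizes

The package's simulation defaults are the minimal-example conditions:
$N = 1000$, $M = 999$ independent SNPs at MAF 0.4, fully polygenic
mediator weights, 1,000 replicates per condition. The test suite uses a
desk-scale slope grid ($N \in \{500, 1000, 2000\}$, $h^2_\delta \in
\{0, 0.5, 1\}$, a few hundred replicates per cell) in place of the
biobank-scale grid ($N$ up to 20{,}000, five heritability levels, 1,000
replicates) that a production $\Phi$ estimation would run; with
independent SNPs the analytic $1/M$ oracle makes the smaller grid fully
informative. The robustness check varies the nonzero-effect proportion
over $\{0.3, 0.5, 0.9\}$ against the fully polygenic reference, at a high
heritability (0.8) where sensitivity would be most visible; sparser
backgrounds may yield slightly smaller slopes, which only makes the
correction conservative.

## What the synthetic data does and does not show

The generator emulates unlinked (or simply block-correlated) common
variants, Gaussian or $t$ effect sizes, and continuous traits with exact
variance partitions. It does not emulate realistic genome-wide LD, allele
frequency spectra, relatedness or population structure, binary traits
(logistic GWAS breaks the linear approximation for unbalanced designs),
or local pleiotropy and LD contamination, which are separate sources of
TWAS false positives that this correction does not address. Passing
calibration tests here therefore validates the statistical machinery —
the inflation law, the slope estimator, and the correction — not the
behavior of any particular cohort.

## Degenerate inputs and numerical conventions

Zero-variance genotype columns abort standardization with the offending
variant ids; an all-zero SNP-effect draw (possible only at toy $M$) is
resampled with a warning, at most ten times. A mediator orthogonal to the
trait yields $Z = 0$, $p = 1$; $|r| \ge 1 - 10^{-12}$ is reported as a
collinearity error rather than an infinite statistic. Genomic control is
one-sided ($\lambda$ clipped at 1). QQ expected quantiles use
$\mathrm{rank}/(n+1)$. Precision with an empty discovery set is an
explicit undefined flag, never 0 or 1. Missing $\Phi$ entries during
correction warn and pass through by default so external association
tables with partial coverage remain usable; `missing_phi = "error"`
makes this strict.

## Limitations

$h^2_\delta$ is a user input (e.g. from LD score regression), not
estimated here; $M$ and the true LD matrix are assumed unknowable, which
is why the empirical grid, not the closed form, is the production path.
Because the correction removes the polygenic background, only mediator
effects clearly above that background remain significant — that is the
intended behavior, not a loss of power to be tuned away.
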