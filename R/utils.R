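# Internal helpers: classed conditions and reproducible seed handling.

abort_twasvc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "twasvc_error")))
}

abort_domain <- function(msg) abort_twasvc(msg, "twasvc_domain_error")
abort_format <- function(msg) abort_twasvc(msg, "twasvc_format_error")
abort_degenerate <- function(msg) abort_twasvc(msg, "twasvc_degenerate_error")
abort_rank <- function(msg) abort_twasvc(msg, c("twasvc_rank_error", "twasvc_domain_error"))
abort_usage <- function(msg) abort_twasvc(msg, "twasvc_usage_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set to `seed`, then
#' restores the caller's stream, so seeded simulation calls do not perturb
#' the surrounding RNG state. With `seed = NULL` the expression simply uses
#' the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is_count(seed)) abort_domain("seed must be a single integer")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministically derive a child seed from a root seed and a stream index.
# MINSTD-style multiplicative step keeps everything below 2^31 and exactly
# representable in doubles.
split_seed <- function(seed, index, salt = 0L) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  s <- seed %% m
  if (s == 0) s <- 1
  s <- (s * 48271) %% m
  s <- (s + (index %% m) * 7919 + (salt %% m) * 104729) %% m
  as.integer(if (s == 0) 1 else s)
}

# Center a vector; population (divide-by-n) standardisation helper for
# genotype columns so that crossprod(X)/n is exactly a correlation matrix.
pop_standardize_columns <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sds <- sqrt(colMeans(xc^2))
  zero <- sds <= 0
  list(x = sweep(xc, 2L, ifelse(zero, 1, sds), "/"), zero = zero)
}

# Scale a centered vector to a target sample variance (n-1 denominator).
scale_to_var <- function(x, target_var, what = "component") {
  if (target_var == 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort_degenerate(sprintf("cannot rescale %s: realized variance is zero", what))
  }
  x / s * sqrt(target_var)
}

# Residualize a centered vector against one or more centered vectors.
orthogonalize <- function(x, against) {
  for (b in against) {
    ss <- sum(b^2)
    if (ss > 0) x <- x - b * (sum(b * x) / ss)
  }
  x
}
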