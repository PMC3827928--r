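# Internal helpers shared across modules.

# Derive a child RNG seed from a master seed and a counter, staying inside
# the 32-bit signed integer range.
childSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 104729) %% 2147483629L) + 1L
}

# Set the RNG seed only when one is supplied.
maybeSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Clip to a closed interval.
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Exact (Clopper-Pearson) binomial confidence bounds for x successes in n.
binomCI <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  cbind(lower = lo, upper = hi)
}

stopIf <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Upper-tail chi-squared(1) p-value; degenerate statistics map to p = 1.
chisq1P <- function(t) {
  p <- pchisq(t, df = 1, lower.tail = FALSE)
  p[!is.finite(t)] <- 1
  p
}
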