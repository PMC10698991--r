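# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the Fisher oracle enumerates the hypergeometric
# distribution directly, and the Clopper-Pearson oracle inverts binomial
# tail probabilities by bisection.

# Two-sided Fisher p by full enumeration of tables with the observed
# margins: sum of probabilities of tables no more probable than observed
# (with the conventional 1e-7 relative tolerance on "no more probable").
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  pobs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Clopper-Pearson bounds by vectorised bisection on exact binomial tails.
cp_bisect <- function(x, n, conf = 0.95, iters = 80L) {
  a <- (1 - conf) / 2
  # lower bound: P(X >= x | p) = a, increasing in p
  lo <- rep(0, length(x)); hi <- rep(1, length(x))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- stats::pbinom(x - 1, n, mid, lower.tail = FALSE) < a
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  lower <- ifelse(x == 0, 0, (lo + hi) / 2)
  # upper bound: P(X <= x | p) = a, decreasing in p
  lo <- rep(0, length(x)); hi <- rep(1, length(x))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- stats::pbinom(x, n, mid) > a
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  upper <- ifelse(x == n, 1, (lo + hi) / 2)
  list(lower = lower, upper = upper)
}

# small helper: default map + a light-weight parameter set for unit tests
test_map <- function() default_promoter_map()

quiet_params <- function(..., coverage = 1000L) {
  simulation_params(..., coverage = coverage,
                    conversion_failure_rate = 0,
                    methylation_miscall_rate = 0,
                    sequencing_error_rate = 0)
}
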