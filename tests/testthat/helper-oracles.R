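# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: explicit loops, textbook formulas, long-format
# recomputation.

# Explicit double sum for the kernel quadratic form.
brute_force_Q <- function(delta, A) {
  s <- 0
  for (j in seq_along(delta))
    for (l in seq_along(delta))
      s <- s + A[j, l] * delta[j] * delta[l]
  s
}

# The scan statistic written in terms of the count share, coverage share,
# overall rate and inverse total coverage (per-read scale): an independent
# re-derivation used as an anti-typo cross-check of the likelihood-ratio
# form.
scan_delta_shares <- function(rA, CA, rU, CU) {
  N <- CA + CU
  Tt <- (rA + rU) / N        # overall methylation rate
  b <- CA / N                # coverage share of the case group
  s <- rA / (rA + rU)        # methylated-count share of the case group
  Tt * (s * log(s / b) +
        (b / Tt - s) * log(1 - Tt * s / b) +
        (1 - s) * log((1 - s) / (1 - b)) +
        ((1 - b) / Tt - 1 + s) * log(1 - Tt * (1 - s) / (1 - b))) -
    (1 - Tt) * log(1 - Tt)
}

# G-squared (deviance) of the 2x2 methylated/unmethylated x group table.
g2_2x2 <- function(rA, CA, rU, CU) {
  o <- c(rA, CA - rA, rU, CU - rU)
  N <- CA + CU
  e <- c(CA * (rA + rU), CA * (N - rA - rU),
         CU * (rA + rU), CU * (N - rA - rU)) / N
  2 * sum(o * log(o / e))
}

# G-squared of a groups x {methylated, unmethylated} table.
g2_table <- function(meth, unmeth) {
  o <- cbind(meth, unmeth)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  2 * sum(o * log(o / e))
}

# Ten-line brute-force version of the no-covariate adjustment stage.
brute_force_adjust <- function(meth, coverage) {
  p <- sum(meth) / sum(coverage)
  r <- meth
  for (i in seq_len(nrow(meth)))
    for (j in seq_len(ncol(meth)))
      r[i, j] <- meth[i, j] - p * coverage[i, j]
  r
}

# One-way ANOVA moment estimator of the intraclass correlation for binary
# reads clustered by sample, recomputed from expanded read-level data.
icc_anova_reads <- function(meth_j, cov_j) {
  keep <- cov_j > 0
  meth_j <- meth_j[keep]; cov_j <- cov_j[keep]
  k <- length(cov_j)
  N <- sum(cov_j)
  if (k < 2) return(0)
  pbar <- sum(meth_j) / N
  pi <- meth_j / cov_j
  ssb <- sum(cov_j * (pi - pbar)^2)
  ssw <- sum(meth_j * (1 - pi))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(cov_j^2) / N) / (k - 1)
  den <- msb + (n0 - 1) * msw
  if (!is.finite(den) || den <= 0) return(0)
  (msb - msw) / den
}
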