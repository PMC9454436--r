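# Independent oracles used to check the package's statistics against
# brute-force enumeration. Kept deliberately naive and separate from the
# implementation paths they verify.

# Exact hypergeometric tail by direct combinatorial summation:
# X = co-altered count with margins m1, m2 in N cases.
hyper_tail_oracle <- function(a, m1, m2, N, direction) {
  lo <- max(0L, m1 + m2 - N)
  hi <- min(m1, m2)
  ks <- if (direction == "concurrent") seq(a, hi) else seq(lo, a)
  ks <- ks[ks >= lo & ks <= hi]
  sum(choose(m1, ks) * choose(N - m1, m2 - ks)) / choose(N, m2)
}

# Literal BH step-up: adj_(i) = min_{j >= i} m * p_(j) / j, clipped to 1.
bh_oracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Normal-equation OLS with the mutant-term t test, for cross-checking
# fit_feature_model on small full-rank designs.
ols_oracle <- function(y, lineage, mutant) {
  X <- if (length(unique(lineage)) >= 2)
    stats::model.matrix(~ factor(lineage) + mutant)
  else stats::model.matrix(~ mutant)
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(r^2) / df
  covb <- sigma2 * solve(crossprod(X))
  j <- ncol(X)
  tval <- beta[j] / sqrt(covb[j, j])
  list(coefficient = unname(beta[j]), t_value = unname(tval),
       p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}
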