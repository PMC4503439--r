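# Shared oracle helpers, independent of the implementation paths they
# check where that matters.

# Noise-free one-compartment population spec (Q = 0 collapses the model).
one_cpt_spec <- function(cl = 31.4, v = 4304, ...) {
  pk_population_spec(cl = cl, v1 = v, q = 0, v2 = 1, omega = 0,
                     sigma_prop = 0, n_subjects = 1, ...)
}

# Disposition exponents recomputed independently via polyroot on
# s^2 + (k10 + k12 + k21) s + k10 k21 = 0.
exponents_oracle <- function(cl, v1, q, v2) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  r <- sort(Re(polyroot(c(k10 * k21, k10 + k12 + k21, 1))))
  list(beta = -r[2], alpha = -r[1])
}

# Tukey studentized-range statistics for a balanced/unbalanced one-way
# layout, used by the permutation oracle.
tukey_q_stats <- function(values, labels) {
  k <- length(unique(labels))
  ms <- tapply(values, labels, mean)
  n <- tapply(values, labels, length)
  mse <- sum((values - stats::ave(values, labels))^2) / (length(values) - k)
  d <- outer(ms, ms, "-")
  q <- abs(d) / sqrt(mse / 2 * outer(1 / n, 1 / n, "+"))
  q[lower.tri(q)]
}

# Permutation estimate of Tukey adjusted p-values: the null distribution
# of the maximum studentized-range statistic under label permutation.
tukey_perm_oracle <- function(values, labels, B = 20000) {
  obs <- tukey_q_stats(values, labels)
  qmax <- replicate(B, max(tukey_q_stats(values, sample(labels))))
  vapply(obs, function(o) mean(qmax >= o), numeric(1))
}

# Permutation estimate of the two-sided unpaired t-test p-value.
t_perm_oracle <- function(x, y, B = 20000) {
  obs <- abs(mean(x) - mean(y))
  v <- c(x, y)
  n <- length(x)
  stat <- replicate(B, {
    idx <- sample(length(v), n)
    abs(mean(v[idx]) - mean(v[-idx]))
  })
  mean(stat >= obs)
}
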