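# Independent oracles used across the suite. These are deliberately naive
# re-derivations (enumeration / closed form), kept separate from the
# package's own code paths.

# Two-sided Fisher exact p by brute-force enumeration over all 2x2 tables
# with the observed margins, probabilities from binomial coefficients.
oracle_fisher_p <- function(alt_a, ref_a, alt_b, ref_b) {
  m <- alt_a + ref_a
  nn <- alt_b + ref_b
  k <- alt_a + alt_b
  if (k == 0 || k == m + nn || m == 0 || nn == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  p_obs <- probs[support == alt_a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form Student two-sample t (pooled variance), two-tailed p.
oracle_t_unpaired <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form paired t on differences, two-tailed p.
oracle_t_paired <- function(pre, post) {
  d <- post - pre
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Probability that a majority vote over d duplicate reads recovers the
# molecule's true allele when each read flips independently with
# probability e, by exact enumeration of flip counts (ties lose).
oracle_majority_recovery <- function(d, e) {
  flips <- 0:d
  keep <- flips * 2 < d
  sum(choose(d, flips[keep]) * e^flips[keep] * (1 - e)^(d - flips[keep]))
}

# small convenience for building site-count data frames
counts <- function(depth, alt) data.frame(depth = depth, alt = alt)
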