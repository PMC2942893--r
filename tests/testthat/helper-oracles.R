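# Independent oracles used across the suite. These deliberately take
# different computational routes than the package code they check.

# Weir & Cockerham (1984) theta via the allele-indicator nested-ANOVA mean
# squares (observed mean squares among populations, among individuals within
# populations, and within individuals), rather than the closed-form variance
# components used by the package. Algebraically equivalent; numerically an
# independent transcription.
theta_anova_oracle <- function(n, p, h) {
  r <- length(n)
  n_tot <- sum(n)
  p_bar <- sum(n * p) / n_tot
  n_c <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  msp <- sum(2 * n * (p - p_bar)^2) / (r - 1)
  msi <- sum(2 * n * p * (1 - p) - n * h / 2) / (n_tot - r)
  msg <- sum(n * h / 2) / n_tot
  s_g <- msg
  s_i <- (msi - msg) / 2
  s_p <- (msp - msi) / (2 * n_c)
  denom <- s_p + s_i + s_g
  list(a = s_p, b = s_i, c = s_g,
       theta = if (denom != 0) s_p / denom else NA_real_,
       defined = denom != 0)
}

# Random multi-population genotype-count table as pop_sample summaries.
random_sample_table <- function(r, n_min = 10, n_max = 500) {
  lapply(seq_len(r), function(i) {
    n <- sample(n_min:n_max, 1)
    counts <- stats::rmultinom(1, n, stats::runif(3))[, 1]
    pop_sample(n, (2 * counts[1] + counts[2]) / (2 * n), counts[2] / n)
  })
}

# Infinite-population viability-selection recursion for the additive scheme
# (w_AA = 1 + s, w_Aa = 1 + s/2, w_aa = 1), assuming Hardy-Weinberg parents.
deterministic_selection_recursion <- function(p, s, n_gen = 1) {
  w <- c(1 + s, 1 + s / 2, 1)
  for (g in seq_len(n_gen)) {
    wbar <- p^2 * w[1] + 2 * p * (1 - p) * w[2] + (1 - p)^2 * w[3]
    p <- (p^2 * w[1] + p * (1 - p) * w[2]) / wbar
  }
  p
}

# Brute-force empirical-percentile power by explicit counting.
power_counting_oracle <- function(null_dist, alt_dist, approach) {
  sorted <- sort(null_dist)
  n <- length(null_dist)
  if (approach == "low_fst") {
    thr <- sorted[ceiling(0.05 * n)]
    sum(alt_dist < thr) / length(alt_dist)
  } else {
    thr <- sorted[floor(0.95 * n)]
    sum(alt_dist > thr) / length(alt_dist)
  }
}

# Population with exact allele frequency p: counts (per sex) chosen so the
# realised frequency equals p with no sampling noise, at Hardy-Weinberg-like
# proportions where possible.
exact_freq_population <- function(size, n_aa_hom, n_het) {
  half <- size / 2
  counts <- c(n_aa_hom, n_het, half - n_aa_hom - n_het)
  stopifnot(all(counts >= 0))
  pop_state(counts, counts)
}
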