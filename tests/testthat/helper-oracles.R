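# Independent brute-force oracles used across the suite.

# AUC as the explicit all-pairs win probability (ties count one half)
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Mann-Whitney U for group a by explicit pair enumeration
brute_force_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Two-sided Fisher exact p by full hypergeometric enumeration at fixed margins
enumerate_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob_a <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(NA_real_)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
  }
  a_obs <- tab[1, 1]
  p_obs <- prob_a(a_obs)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, prob_a, 0)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Youden maximisation by exhaustive scan over every observed cut-off
scan_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- -Inf
  for (t in cuts) {
    sens <- sum(labels & scores >= t) / sum(labels)
    spec <- sum(!labels & scores < t) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Small classified cohort for reuse
make_classified <- function(n = 200, seed = 42) {
  classify_cohort(generate_cohort(synthetic_params(n_patients = n), seed = seed))
}
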