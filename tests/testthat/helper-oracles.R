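# Independent oracles, written before (and kept independent of) the
# implementations they check.

# Brute-force recovery-curve integration: walk the top-k ranking one
# position at a time, count cumulative hits, integrate the step curve and
# normalize by the best achievable area for a set of this size.
oracle_auc <- function(hit_ranks, k, set_size) {
    hits <- 0
    area <- 0
    for (i in seq_len(k)) {
        hits <- hits + sum(hit_ranks == i)
        area <- area + hits
    }
    m <- min(set_size, k)
    best <- 0; best_hits <- 0
    for (i in seq_len(k)) {
        best_hits <- min(i, m)
        best <- best + best_hits
    }
    area / best
}

# Exact two-sided rank-sum p by full enumeration of all C(n1+n2, n1)
# assignments of the pooled ranks to group 1 (tie-free data only).
oracle_ranksum_p <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- rank(c(x, y))
    w_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    w_all <- apply(combos, 2L, function(idx)
        sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
    p_le <- mean(w_all <= w_obs)
    p_ge <- mean(w_all >= w_obs)
    min(1, 2 * min(p_le, p_ge))
}

# 99% binomial interval for an observed proportion at the configured rate.
binom99 <- function(n, p) {
    stats::qbinom(c(0.005, 0.995), n, p) / n
}

# Cell-type proportions used by small unit-test simulations: rare types
# are boosted so every rule gene clears the 3-cell prevalence filter at a
# few hundred cells (the acceptance tests use the default composition at
# full scale).
testProportions <- function() {
    c(qNSC = 0.40, aNSC = 0.15, TAP = 0.15, EC = 0.07, Astro = 0.10,
      OL = 0.05, NB = 0.05, other = 0.03)
}
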