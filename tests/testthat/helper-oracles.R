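# Independent oracles and shared fixtures.
#
# Each brute-force implementation below deliberately takes a different route
# than the package code it checks (union-find instead of interval reduction,
# exhaustive hypergeometric enumeration instead of fisher.test, scalar loops
# instead of vectorized matrix algebra).

# Union-find merge of intervals: two intervals are connected iff they overlap
# or are separated by fewer than `gap` bases (half-open coordinates).
bf_merge_regions <- function(peaks, gap = 500) {
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j || peaks$chrom[i] != peaks$chrom[j]) next
      sep <- max(peaks$start[i] - peaks$end[j],
                 peaks$start[j] - peaks$end[i])
      if (sep < gap) parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = peaks$chrom[idx[1]],
               start = min(peaks$start[idx]),
               end = max(peaks$end[idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive two-sided hypergeometric probability for a 2x2 table, summing
# all tables (with the observed margins) at most as probable as the observed
# one (with the standard relative-error guard).
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2]
  k <- tab[1, 1] + tab[2, 1]
  n_tot <- sum(tab)
  support <- max(0, k - (n_tot - m)):min(k, m)
  probs <- dhyper(support, m, n_tot - m, k)
  p_obs <- dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Scalar re-implementation of the dispersion-trend Z-score: median and
# population SD computed with explicit loops, trend re-exponentiated per
# region.
bf_z_scores <- function(ppm, coefs) {
  out <- matrix(NA_real_, nrow(ppm), ncol(ppm))
  for (i in seq_len(nrow(ppm))) {
    x <- as.numeric(ppm[i, ])
    xs <- sort(x)
    n <- length(x)
    m <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    if (m <= 0) next
    u <- log10(m)
    s_fit <- m * sqrt(10^(coefs[1] + coefs[2] * u + coefs[3] * u^2))
    if (!is.finite(s_fit) || s_fit <= 0) next
    for (j in seq_len(n)) out[i, j] <- (x[j] - x[1]) / s_fit
  }
  out
}

# Evaluation cohort for the induction caller's operating characteristics:
# 2000 stable + 500 induced regions, counts background-corrected against the
# WCE control at nominal (equal) library depths and converted to ppm.
make_eval_cohort <- function(seed, n_stable = 2000, n_induced = 500,
                             noise = noise_model()) {
  stable <- synthetic_truth(n_stable, induced_fraction = 0, seed = seed)
  induced <- synthetic_truth(n_induced, induced_fraction = 1,
                             seed = seed + 50L)
  induced$region_id <- sprintf("ind_%05d", seq_len(n_induced))
  truth <- rbind(stable, induced)
  cs <- simulate_count_series(truth, noise, seed = seed + 100L)
  corrected <- correct_counts(cs$ip, cs$wce, noise$count_depth,
                              noise$count_depth)
  ppm <- corrected * 1e6 / noise$count_depth
  rownames(ppm) <- truth$region_id
  list(truth = truth, ppm = ppm, design = cs$design)
}

design_index <- function(times, design = default_design()) {
  match(times, design)
}
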