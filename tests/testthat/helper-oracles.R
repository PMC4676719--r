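# Independent oracles used to pin down the statistical machinery on tiny
# instances. Each is written from the definition, not from the package's
# implementation path.

# All orderings of 1..n (tiny n only).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n))[-i][sub], nrow(sub), n - 1L))
  }))
}

# Exhaustive permutation null for the rank product on a complete n x m table:
# enumerate every joint assignment of within-replicate ranks, compute each
# protein's rank product, and return for each observed rp value the exact
# expected false-positive count and its exact per-permutation SD (for scaling
# Monte-Carlo tolerances).
exhaustive_rp_null <- function(n, m, observed_rp) {
  perms <- all_permutations(n)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), m)))
  per_assignment <- apply(idx, 1, function(row) {
    ranks <- sapply(row, function(i) perms[i, ])  # n x m ranks
    apply(ranks, 1, function(r) exp(mean(log(r))))
  })  # n x n_assignments matrix of rp values
  t(vapply(observed_rp, function(x) {
    counts <- colSums(per_assignment <= x + 1e-12)
    c(e_fp = mean(counts), sd_fp = stats::sd(counts))
  }, c(e_fp = 0, sd_fp = 0)))
}

# Brute-force hypergeometric upper tail: enumerate all size-n_hits subsets of
# a universe of size N containing K annotated items; P(overlap >= a).
bruteforce_hyper_upper <- function(a, n_hits, K, N) {
  sets <- utils::combn(N, n_hits)
  annotated <- seq_len(K)
  mean(apply(sets, 2, function(s) sum(s %in% annotated) >= a))
}

# Independently-coded running-sum enrichment score (weight 0): walk the
# ranked list; +1/K on a member, -1/(N-K) otherwise; return the extreme.
oracle_es_w0 <- function(n, member_idx) {
  k <- length(member_idx)
  path <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (i %in% member_idx) 1 / k else -1 / (n - k)
    path[i] <- acc
  }
  path[which.max(abs(path))]
}

# Exhaustive GSEA p (weight 0): all placements of a k-member set in an
# n-long ranking; p = fraction with same-sign |ES| at least the observed.
exhaustive_gsea_p <- function(n, member_idx) {
  obs <- oracle_es_w0(n, member_idx)
  placements <- utils::combn(n, length(member_idx))
  null_es <- apply(placements, 2, function(ix) oracle_es_w0(n, ix))
  mean(sign(null_es) == sign(obs) & abs(null_es) >= abs(obs) - 1e-12)
}

# Closed-form Weibull median.
weibull_median <- function(shape, scale) scale * log(2)^(1 / shape)
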