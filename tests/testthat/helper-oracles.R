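# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths they validate.

# Naive triple-loop topological overlap.
tom_oracle <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  k <- rowSums(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# Pairwise double-loop soft-threshold adjacency.
adjacency_oracle <- function(x, beta) {
  n <- nrow(x)
  a <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) a[i, j] <- abs(cor(x[i, ], x[j, ]))^beta
  a
}

# Upper-tail hypergeometric by direct summation of the pmf.
hyper_upper_oracle <- function(overlap, set_size, universe_size, n_hits) {
  ks <- overlap:min(set_size, n_hits)
  sum(choose(set_size, ks) * choose(universe_size - set_size, n_hits - ks)) /
    choose(universe_size, n_hits)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins and summing those no more probable than observed
# (with the conventional relative-error guard against float ties).
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definition: p_(i) * n / i, cumulative
# minimum from the largest rank down.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Two-group log-rank statistic by explicit risk-set arithmetic.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g); n0 <- sum(at_risk & !g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    nn <- n1 + n0
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    if (nn > 1)
      v <- v + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  o_minus_e^2 / v
}

standardize_vec_oracle <- function(x) (x - mean(x)) / sd(x)

# Small cohort configurations reused across test files.
tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_genes = 60L, module_sizes = c(20L, 15L),
                   n_background_genes = 25L,
                   samples_per_group = c(AN = 4L, CNM = 8L,
                                         CWM = 8L, CLM = 8L),
                   celltype_module_map = list(CAF = 1L, myeloid = 2L),
                   seed = seed)
  defaults[names(args)] <- args  # plain replacement, no list merging
  do.call(cohort_config, defaults)
}

null_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, trait_effects = list(),
              celltype_module_map = list(), ...)
}

# Exact-correlation block expression: k "modules" whose per-block factor
# profiles have exactly the sample correlation matrix R (via orthonormal
# polynomial contrasts), each block being noiseless copies of its factor.
exact_cor_blocks <- function(R, block_size = 5L, n_samples = 12L) {
  k <- nrow(R)
  P <- stats::poly(seq_len(n_samples), degree = k)  # orthonormal, mean 0
  fac <- P %*% chol(R)                               # sample cor exactly R
  expr <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rep(fac[, i], each = block_size), nrow = block_size) *
      seq(1, 2, length.out = block_size)))           # scaled copies
  rownames(expr) <- sprintf("B%d_g%d", rep(seq_len(k), each = block_size),
                            rep(seq_len(block_size), k))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  partition <- stats::setNames(rep(paste0("GM", seq_len(k)),
                                   each = block_size), rownames(expr))
  list(expr = expr, partition = partition, factors = fac)
}
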