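# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each statistic from its definition with plain
# loops / set arithmetic and stay independent of the package code paths.

# Running-sum enrichment score, step by step over the whole ranking.
brute_es <- function(gene_set, ranking, weight_p) {
  n <- length(ranking)
  hit <- names(ranking) %in% gene_set
  nh <- sum(hit)
  stopifnot(nh > 0L, nh < n)
  w <- abs(ranking)^weight_p
  tw <- sum(w[hit])
  # running sum as P_hit(i) - P_miss(i); the hit CDF uses cumulative weight
  # fractions so exact ties with the implementation are decided identically
  p_hit <- if (tw > 0) cumsum(ifelse(hit, w, 0)) / tw
           else cumsum(hit) / nh
  p_miss <- cumsum(!hit) / (n - nh)
  rs <- p_hit - p_miss
  mx <- max(rs)
  mn <- min(0, min(rs))
  if (mx >= -mn) mx else mn
}

# Definitional BH: adj_i = min over j with p_(j) >= p_(i) of n * p_(j) / j.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) n * p[o][j] / j, numeric(1))
    adj_sorted[i] <- min(1, min(cand))
  }
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# Pearson correlation from first principles.
brute_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
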