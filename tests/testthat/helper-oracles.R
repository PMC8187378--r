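# Independent oracles used by the unit and acceptance tests.  These are
# deliberately brute-force / reference-library implementations, separate
# from the code paths they check.

# Benjamini-Hochberg by the raw step-up definition: q_i is the smallest
# over thresholds t >= p_i of m * t / #{p <= t}, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(m * cand / vapply(cand, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Fisher's exact two-sided p for a 2x2 table by full hypergeometric
# enumeration with the "no more probable" rule.
fisher_2x2_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# all partitions of n items into exactly k blocks (restricted growth strings)
partitions_k <- function(n, k) {
  res <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      if (mx == k) res[[length(res) + 1L]] <<- a
      return()
    }
    for (v in seq_len(min(mx + 1L, k))) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  res
}

# ward.D objective: sum over clusters of within-cluster pairwise
# dissimilarity / (2 * size), treating the input as squared distances
ward_objective <- function(d, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) s <- s + sum(d[idx, idx]) / (2 * length(idx))
  }
  s
}

# separated two-or-three-blob instance in the plane; greedy Ward provably
# recovers the optimal partition only on separable geometries
blob_instance <- function(seed, n = NULL, k = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:8, 1)
  if (is.null(k)) k <- sample(2:3, 1)
  repeat {
    cent <- matrix(stats::rnorm(k * 2, sd = 4), k)
    if (k == 1 || min(stats::dist(cent)) >= 3) break
  }
  z <- sample(rep_len(seq_len(k), n))
  x <- cent[z, , drop = FALSE] + matrix(stats::rnorm(n * 2, sd = 0.5), n)
  d <- as.matrix(stats::dist(x))^2
  dimnames(d) <- list(paste0("i", seq_len(n)), paste0("i", seq_len(n)))
  list(d = d, k = k, n = n)
}

# log-rank chi-square by explicit per-event-time tabulation (independent
# of the package's vectorised bookkeeping); reference check for small n
logrank_tabulate <- function(time, event, group) {
  lv <- sort(unique(as.character(group)))
  G <- length(lv)
  OE <- numeric(G); V <- matrix(0, G, G)
  for (t in sort(unique(time[event == 1]))) {
    n_t <- sum(time >= t); d_t <- sum(time == t & event == 1)
    n_g <- sapply(lv, function(g) sum(time >= t & group == g))
    d_g <- sapply(lv, function(g) sum(time == t & event == 1 & group == g))
    OE <- OE + d_g - n_g * d_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n_t - d_t) / (n_t - 1) *
        (diag(n_g / n_t, G) - tcrossprod(n_g / n_t))
  }
  i <- seq_len(G - 1)
  if (sum(abs(OE)) < 1e-12) return(0)
  drop(t(OE[i]) %*% solve(V[i, i, drop = FALSE], OE[i]))
}
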