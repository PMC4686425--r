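# Independent brute-force oracles used across test files.

# Position-weighted score by an explicit per-pixel loop.
oracle_weighted_score <- function(intensity, weight_top = 100,
                                  weight_bottom = 0) {
  n <- length(intensity)
  total <- 0
  for (i in seq_len(n)) {
    w <- weight_top + (weight_bottom - weight_top) * (i - 1) / (n - 1)
    total <- total + w * intensity[i]
  }
  total
}

# Per-pixel maximum over z by explicit loops.
oracle_max_project <- function(arr3d) {
  d <- dim(arr3d)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    out[y, x] <- max(out[y, x], arr3d[z, y, x])
  out
}

# Fisher p-values by looping over every admissible table at fixed
# margins, with stats::dhyper as the independent pmf.
oracle_fisher <- function(a, b, c, d,
                          alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  K <- a + b; n <- a + c; N <- a + b + c + d
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- stats::dhyper(support, K, N - K, n)
  p_obs <- pmf[support == a]
  switch(alternative,
    greater = sum(pmf[support >= a]),
    less = sum(pmf[support <= a]),
    two_sided = sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

# Jaccard overlap of two 0-based half-open intervals.
jaccard_interval <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- max(e1, e2) - min(s1, s2)
  inter / uni
}
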