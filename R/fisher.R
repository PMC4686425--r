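# Exact binomial coefficient: exact integer arithmetic in double
# precision while every intermediate stays below 2^53, with a log-space
# fallback for large margins (no overflow up to N = 10,000 and beyond).
choose_exact <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  if (k == 0) return(1)
  acc <- 1
  for (i in seq_len(k)) {
    nxt <- acc * (n - k + i) / i  # exactly divisible at each step
    if (!is.finite(nxt) || nxt > 2^53) return(exp(lchoose(n, k)))
    acc <- nxt
  }
  acc
}

#' Hypergeometric probability mass by exact enumeration
#'
#' `P(X = k)` for the number of "successes" `k` drawn in a sample of size
#' `n` without replacement from a population of `N` items of which `K`
#' are successes: `choose(K, k) * choose(N - K, n - k) / choose(N, n)`.
#' Built from exact integer combinatorics (log-space above 2^53), as the
#' kernel beneath [fisher_exact()].
#'
#' @param k Observed successes in the sample (vectorized).
#' @param K Successes in the population.
#' @param n Sample size.
#' @param N Population size.
#' @return Probabilities, zero outside the support
#'   `max(0, n - (N - K)) <= k <= min(K, n)`.
#' @examples
#' hypergeom_pmf(7, K = 7, n = 10, N = 30)
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  if (any(c(K, n, N) < 0) || K > N || n > N)
    param_error("Inconsistent margins: need 0 <= K <= N and 0 <= n <= N.")
  vapply(k, function(ki) {
    if (ki < 0 || ki > n || ki != floor(ki)) return(0)
    num1 <- choose_exact(K, ki)
    num2 <- choose_exact(N - K, n - ki)
    den <- choose_exact(N, n)
    if (num1 == 0 || num2 == 0) return(0)
    # recompute fully in log space if any piece fell back
    if (num1 > 2^53 || num2 > 2^53 || den > 2^53)
      exp(lchoose(K, ki) + lchoose(N - K, n - ki) - lchoose(N, n))
    else num1 * num2 / den
  }, numeric(1))
}

as_contingency <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L)))
      param_error("Contingency table must be 2x2.")
    table <- as.vector(t(table))  # row-major: a, b, c, d
  }
  if (length(table) != 4L || any(table < 0) || any(table != floor(table)))
    param_error("Need four non-negative integer counts (a, b, c, d).")
  if (sum(table) == 0) param_error("At least one margin must be positive.")
  as.integer(table)
}

#' Fisher's exact test for a 2x2 table by hypergeometric enumeration
#'
#' Exact inference for clone-count style tables, e.g. rows = construct
#' (non-phosphorylatable AA vs phosphomimetic DD/EE), columns = outcome
#' (retained the mutation vs reverted to wild type). The p-value is
#' computed by enumerating every admissible table at the observed
#' margins:
#'
#' * `greater` / `less`: tail sums of the hypergeometric pmf of the
#'   top-left cell;
#' * `two_sided`: the minimum-likelihood rule — the sum of
#'   probabilities of all tables no more probable than the observed one
#'   (with `1e-7` relative slack on the comparison, the dominant
#'   software convention).
#'
#' @param table 2x2 matrix, data frame, or length-4 vector
#'   `c(a, b, c, d)` in row-major order.
#' @param alternative `"greater"` (default: the association is in the
#'   direction of the top-left cell), `"less"`, or `"two_sided"`. The
#'   default is directional because, for tables whose extreme cell is 0,
#'   one- and two-sided values coincide; both are easily obtained.
#' @return A one-row tibble: the four counts, `alternative` and
#'   `p_value` (always in `(0, 1]`).
#' @examples
#' # 7/10 clones retained a benign mutation; 0/20 retained a lethal one
#' fisher_exact(c(7, 3, 0, 20))
#' @export
fisher_exact <- function(table,
                         alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  tb <- as_contingency(table)
  a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
  K <- a + b        # row-1 total
  n <- a + cc       # column-1 total
  N <- a + b + cc + d
  support <- max(0L, n - (N - K)):min(K, n)
  pmf <- hypergeom_pmf(support, K, n, N)
  p_obs <- pmf[support == a]
  p <- switch(alternative,
    greater = sum(pmf[support >= a]),
    less = sum(pmf[support <= a]),
    two_sided = sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  )
  tibble(a = a, b = b, c = cc, d = d,
         alternative = alternative, p_value = min(p, 1))
}

#' Batch Fisher's exact tests for a table of 2x2 counts
#'
#' @param data Tibble with integer columns `a`, `b`, `c`, `d` (row-major
#'   cells) and any annotation columns.
#' @param alternative Passed to [fisher_exact()].
#' @param bound Optional numeric vector (recycled) of claimed p-value
#'   bounds; adds a logical `meets_bound` column (`p_value < bound`).
#' @return `data` with `p_value` (and optionally `meets_bound`)
#'   appended.
#' @examples
#' viability_fisher(tibble::tibble(
#'   comparison = c("AA vs DD", "AA vs EE"),
#'   a = 7, b = 3, c = 0, d = c(20, 12)),
#'   bound = c(1e-4, 1e-3))
#' @export
viability_fisher <- function(data,
                             alternative = c("greater", "less", "two_sided"),
                             bound = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(data), all(c("a", "b", "c", "d") %in% names(data)))
  p <- purrr::map_dbl(seq_len(nrow(data)), function(i)
    fisher_exact(c(data$a[i], data$b[i], data$c[i], data$d[i]),
                 alternative)$p_value)
  out <- dplyr::mutate(as_tibble(data), alternative = alternative,
                       p_value = p)
  if (!is.null(bound)) {
    out$bound <- rep_len(bound, nrow(out))
    out$meets_bound <- out$p_value < out$bound
  }
  out
}
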