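# Exact statistics: two-sided Fisher exact test for 2x2 tables and the
# Mann-Whitney (Wilcoxon rank-sum) test. Both are implemented here rather
# than delegated, because the conventions matter for reproducing published
# clinical p-values: the Fisher p sums all point probabilities not exceeding
# the observed one (with a small relative tolerance for ties), and the
# Mann-Whitney normal approximation applies the tie correction with no
# continuity correction. Base-R equivalents serve as cross-checks in the
# test suite.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the point probabilities that do not exceed the
#' observed table's probability (relative tolerance 1e-7 for ties). This is
#' the two-sided convention of standard clinical software.
#'
#' @param tab a 2x2 matrix of non-negative counts, or the count `a` with
#'   `b`, `c`, `d` supplied separately (row = group, column = feature
#'   present/absent).
#' @param b,c,d remaining cells when `tab` is given as a single count.
#' @return two-sided p-value in `(0, 1]`. A table with an empty row or
#'   column margin carries no information and returns 1.
#' @examples
#' fisher_exact_2x2(matrix(c(6, 0, 3, 7), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  } else {
    a <- tab
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    tmerep_error("2x2 table cells must be non-negative integers",
                 "tmerep_argument_error")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  d_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

# Exact null distribution of the rank-sum W of the first group: number of
# n1-subsets of ranks {1..N} with each possible sum, by dynamic programming
# over the items. Returns probabilities indexed by W = min_sum:max_sum.
ranksum_distribution <- function(n1, n2) {
  N <- n1 + n2
  min_w <- n1 * (n1 + 1) / 2
  max_w <- n1 * (2 * N - n1 + 1) / 2
  # counts[k + 1, s + 1] = number of k-subsets of processed ranks summing to s
  counts <- matrix(0, nrow = n1 + 1, ncol = max_w + 1)
  counts[1, 1] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, n1)
    for (k in kmax:1) {
      s <- (r):(max_w)
      counts[k + 1, s + 1] <- counts[k + 1, s + 1] + counts[k, s - r + 1]
    }
  }
  probs <- counts[n1 + 1, (min_w:max_w) + 1]
  probs <- probs / sum(probs)
  list(w = min_w:max_w, p = probs)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test for a location difference between two independent samples.
#' With combined `n <= 20` and no ties the p-value is exact, from the full
#' null distribution of the rank sum (two-sided as twice the smaller tail,
#' capped at 1). Otherwise the tie-corrected normal approximation is used,
#' without continuity correction. Degenerate data (all values tied) give
#' p = 1.
#'
#' @param x,y numeric vectors, one per group (each non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   `NULL` selects it when `length(x) + length(y) <= 20` and there are no
#'   ties.
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p.value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y))
    tmerep_error("both groups must be non-empty and free of NA",
                 "tmerep_argument_error")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- if (is.null(exact)) (N <= 20 && !has_ties) else exact
  if (use_exact && has_ties)
    tmerep_error("exact Mann-Whitney requires tie-free data",
                 "tmerep_argument_error")
  if (use_exact) {
    dist <- ranksum_distribution(n1, n2)
    lower <- sum(dist$p[dist$w <= W])
    upper <- sum(dist$p[dist$w >= W])
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  tie_sizes <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = U, p.value = 1, method = "normal"))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(statistic = U, p.value = 2 * stats::pnorm(-abs(z)), method = "normal")
}
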