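#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Pearson chi-square test (no continuity correction, as is standard for
#' goodness-of-fit) of observed mutant/non-mutant F2 counts against an
#' expected segregation ratio, by default the 1:3 mutant:other ratio of a
#' monogenic recessive trait.
#'
#' @param n_mutant Number of mutant-phenotype F2 individuals.
#' @param n_total Total F2 individuals.
#' @param ratio Expected `(mutant, other)` ratio pair; scale-invariant, so
#'   `c(1, 3)` and `c(2, 6)` are equivalent.
#' @return A list with `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' segregation_chisq(15, 69)  # statistic 0.39, p 0.53
#' @export
segregation_chisq <- function(n_mutant, n_total, ratio = c(1, 3)) {
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(length(ratio) == 2, all(ratio > 0), n_mutant >= 0,
            n_mutant <= n_total)
  ct <- suppressWarnings(
    chisq.test(c(n_mutant, n_total - n_mutant), p = ratio / sum(ratio)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

# exact null distribution of the rank sum of x via the shift (network)
# algorithm on doubled midranks; returns P(S <= s) and P(S >= s)
.exact_ranksum_tails <- function(r2, nx, s2) {
  total <- sum(r2)
  # ways[k + 1, s + 1] = number of nx-subsets... built incrementally
  ways <- matrix(0, nrow = nx + 1, ncol = total + 1)
  ways[1, 1] <- 1
  for (r in r2) {
    for (k in nx:1) {
      if (r == 0) next
      ways[k + 1, (r + 1):(total + 1)] <-
        ways[k + 1, (r + 1):(total + 1)] + ways[k, 1:(total - r + 1)]
    }
  }
  counts <- ways[nx + 1, ]
  n_comb <- sum(counts)
  p_le <- sum(counts[seq_len(s2 + 1)]) / n_comb
  p_ge <- sum(counts[(s2 + 1):(total + 1)]) / n_comb
  c(p_le = p_le, p_ge = p_ge)
}

#' Wilcoxon rank-sum test with exact enumeration
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. Ties receive midranks.
#' When the combined sample size is at most `exact_max_n`, the p-value is
#' exact: the permutation distribution of the rank sum over all
#' `choose(n_x + n_y, n_x)` group assignments is enumerated (via a
#' shift-algorithm convolution), and the two-sided p doubles the smaller tail
#' probability of rank sums at least as extreme, capped at 1. For larger
#' samples a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y Numeric measurement vectors, both non-empty.
#' @param exact_max_n Largest combined sample size for exact enumeration.
#' @return A list with `statistic` (the rank sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal approximation"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y); n <- nx + ny
  all_vals <- c(x, y)
  ranks <- rank(all_vals)  # midranks for ties
  s <- sum(ranks[seq_len(nx)])

  if (length(unique(all_vals)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = s, p_value = 1, method = "degenerate"))
  }

  if (n <= exact_max_n) {
    r2 <- sort(as.integer(round(2 * ranks)))
    tails <- .exact_ranksum_tails(r2, nx, as.integer(round(2 * s)))
    p <- min(1, 2 * min(tails))
    return(list(statistic = s, p_value = p, method = "exact"))
  }

  mu <- nx * (n + 1) / 2
  ties <- table(ranks)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  delta <- s - mu
  z <- (delta - sign(delta) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = s, p_value = p, method = "normal approximation")
}

#' Per-group summary statistics with pairwise rank-sum tests
#'
#' Summarizes grouped measurements as n / mean / sample SD (n - 1 denominator)
#' and computes pairwise two-sided p-values with [wilcoxon_rank_sum()]. With a
#' single group, only the summaries are returned; groups with fewer than two
#' observations are summarized but excluded from testing.
#'
#' @param measurements Named list of numeric vectors, one entry per group.
#' @return A list with `summary` (`data.frame`: `group`, `n`, `mean`, `sd`)
#'   and `comparisons` (`data.frame`: `group1`, `group2`, `p_value`; absent
#'   pairs if untestable).
#' @export
summary_table <- function(measurements) {
  stopifnot(is.list(measurements), length(measurements) >= 1,
            !is.null(names(measurements)))
  groups <- names(measurements)
  summary <- data.frame(
    group = groups,
    n = vapply(measurements, length, integer(1)),
    mean = vapply(measurements, mean, numeric(1)),
    sd = vapply(measurements, sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  comparisons <- data.frame(group1 = character(), group2 = character(),
                            p_value = numeric(), stringsAsFactors = FALSE)
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      if (length(measurements[[g1]]) < 2 || length(measurements[[g2]]) < 2)
        next
      w <- wilcoxon_rank_sum(measurements[[g1]], measurements[[g2]])
      comparisons <- rbind(comparisons, data.frame(
        group1 = g1, group2 = g2, p_value = w$p_value,
        stringsAsFactors = FALSE))
    }
  }
  list(summary = summary, comparisons = comparisons)
}
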