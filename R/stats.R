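#' Rank-based group comparisons
#'
#' The nonparametric comparison layer used throughout the analyses:
#' Mann-Whitney U for two groups, Kruskal-Wallis H across multiple
#' attempts/groups, and Spearman rank correlation, all two-tailed, with
#' Bonferroni adjustment applied within declared comparison families.
#' Results are returned as one-row \code{comparison} tibbles that stack
#' into report tables.
#'
#' @name rank_tests
NULL

comparison_row <- function(test, statistic, p_value, n, extra = list()) {
  tibble::tibble(test = test, statistic = statistic,
                 p_value = p_value, n = paste(n, collapse = ","),
                 adjusted_p = NA_real_, !!!extra)
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums and reported as \code{min(U1, U2)} (the
#' conventional small-U). The two-tailed p-value is exact (full enumeration
#' of group labelings) when the combined sample size is at most 16 and
#' there are no ties; otherwise the normal approximation with tie
#' correction is used.
#'
#' @param group_a,group_b numeric vectors (nonempty).
#' @param exact_max combined-n ceiling for the exact test, default 16.
#' @return a one-row \code{comparison} tibble with \code{test},
#'   \code{statistic} (U), \code{p_value}, \code{n}, \code{adjusted_p}.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, complete separation
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 16) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty", call. = FALSE)
  n1 <- length(group_a); n2 <- length(group_b)
  rk <- rank(c(group_a, group_b))
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (n1 + n2) <= exact_max && !ties
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = FALSE)$p.value)
  comparison_row("mann_whitney_u", u, p, c(n1, n2),
                 list(exact = use_exact))
}

#' Kruskal-Wallis H test
#'
#' Rank-based one-way comparison across groups (tie-corrected H statistic,
#' chi-squared p-value).
#'
#' @param groups list of numeric vectors (each nonempty).
#' @return a one-row \code{comparison} tibble (statistic = H, df recorded).
#' @export
kruskal_wallis_h <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!lengths(groups))) stop("all groups must be nonempty", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  comparison_row("kruskal_wallis_h", unname(kt$statistic), kt$p.value,
                 lengths(groups), list(df = unname(kt$parameter)))
}

#' Spearman rank correlation
#'
#' Midrank-based rho; exact two-tailed p by permutation reference when
#' n <= 7 and there are no ties, otherwise the t approximation.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return a one-row \code{comparison} tibble (statistic = rho).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- length(x) <= 7 && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact))
  comparison_row("spearman_rho", unname(ct$estimate), ct$p.value,
                 length(x), list(exact = use_exact))
}

#' Bonferroni adjustment within a comparison family
#'
#' Fills \code{adjusted_p = min(1, m * p)} for the m rows of a stacked
#' comparison table, recording the family size. Never decreases a p-value.
#'
#' @param comparisons tibble of stacked \code{comparison} rows.
#' @return the tibble with \code{adjusted_p} and \code{family_m} set.
#' @export
bonferroni_family <- function(comparisons) {
  m <- nrow(comparisons)
  comparisons$adjusted_p <- pmin(1, comparisons$p_value * m)
  comparisons$family_m <- m
  comparisons
}
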