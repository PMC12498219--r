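#' Spearman rank correlation with t-approximation p-value
#'
#' Computes the Pearson correlation of midranks; the two-sided p-value uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees
#' of freedom, which handles ties (midranks) naturally.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing values
#'   are dropped.
#' @return list of class `vhit_test` with `statistic` (r), `p_value`,
#'   `method = "spearman"`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop_input("need >= 3 complete pairs of equal length")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_input("undefined correlation: one input is constant")
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(statistic = r, p_value = p, method = "spearman", n = n),
            class = "vhit_test")
}

#' Mann-Whitney U test
#'
#' U counts the pairs (a_i, b_j) with a_i > b_j, plus half the ties
#' (computed via midranks). P-values: exact (null permutation distribution,
#' via the Wilcoxon rank-sum distribution) when both samples have at most
#' `exact_limit` observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. A zero
#' z-statistic yields p = 1.
#'
#' @param a,b numeric vectors, non-empty.
#' @param exact_limit maximum per-group size for the exact method.
#' @return list of class `vhit_test` with `statistic` (U for sample `a`),
#'   `p_value`, `method = "mann_whitney"`, `exact`.
#' @export
mann_whitney_test <- function(a, b, exact_limit = 20L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (!na || !nb) stop_input("both samples must be non-empty")
  all_r <- rank(c(a, b))
  u <- sum(all_r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && na <= exact_limit && nb <= exact_limit
  mu <- na * nb / 2
  if (exact) {
    p <- if (u == mu) 1 else if (u < mu) {
      2 * stats::pwilcox(u, na, nb)
    } else {
      2 * (1 - stats::pwilcox(u - 1, na, nb))
    }
    p <- min(1, p)
  } else {
    tie_tab <- table(c(a, b))
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    if (u == mu || sigma2 == 0) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = u, p_value = p, method = "mann_whitney",
                 exact = exact), class = "vhit_test")
}

#' Chi-square or Fisher's exact test for a 2x2 table
#'
#' Uses Fisher's exact test (hypergeometric enumeration, two-sided by the
#' point-probability rule: sum all tables whose probability does not exceed
#' that of the observed table) whenever any expected cell count is below 5,
#' and the 1-df chi-square test otherwise (no continuity correction by
#' default). The reported odds-ratio estimate is the sample cross-product
#' ratio.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param correct apply the Yates continuity correction to the chi-square
#'   statistic.
#' @param force_fisher always use Fisher's exact test.
#' @return list of class `vhit_test` with `statistic` (X^2 or the observed
#'   count in cell \[1,1\]), `p_value`, `method`, `odds_ratio`.
#' @export
contingency_test <- function(table, correct = FALSE, force_fisher = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    stop_input("`table` must be a 2x2 matrix of nonnegative integer counts")
  }
  n <- sum(tab)
  if (n == 0) stop_input("all-zero table")
  expd <- outer(rowSums(tab), colSums(tab)) / n
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (force_fisher || any(expd < 5)) {
    # condition on the margins; k = count in cell [1,1]
    m <- sum(tab[1, ]); mm <- sum(tab[2, ]); k1 <- sum(tab[, 1])
    supp <- max(0, k1 - mm):min(m, k1)
    probs <- stats::dhyper(supp, m, mm, k1)
    p_obs <- stats::dhyper(tab[1, 1], m, mm, k1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
    method <- "fisher_exact"
    statistic <- tab[1, 1]
  } else {
    d <- abs(tab - expd) - if (correct) 0.5 else 0
    d <- pmax(d, 0)
    statistic <- sum(d^2 / expd)
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "chi_square"
  }
  structure(list(statistic = statistic, p_value = p, method = method,
                 odds_ratio = or), class = "vhit_test")
}

#' @export
print.vhit_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}
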