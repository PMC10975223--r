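# Relative tolerance used when comparing point probabilities for the
# two-sided "as extreme or more extreme" rule; identical to the convention
# in standard exact-test implementations.
TIE_TOL <- 1e-7

as_count_matrix <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("counts must be finite numbers", call. = FALSE)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
    stop("counts must be non-negative integers", call. = FALSE)
  m <- round(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("a contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  m
}

check_margins <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: every row and column margin must be positive",
         call. = FALSE)
  invisible(m)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability ("Fisher-Irwin") two-sided convention: conditional on
#' both margins, the p-value sums the hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed table
#' (relative tie tolerance 1e-7).
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts with
#'   positive margins.
#' @return the two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(16, 11, 9, 2), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  m <- check_margins(as_count_matrix(table))
  if (nrow(m) != 2 || ncol(m) != 2)
    stop("fisher_exact_two_sided expects a 2x2 table", call. = FALSE)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  support <- lo:hi
  d <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, c2, r1)
  p <- sum(d[d <= p_obs * (1 + TIE_TOL)])
  min(max(p, .Machine$double.xmin), 1)
}

# Visit every r x c table with the given margins; calls visit(cells, logp)
# where logp is the multivariate hypergeometric log probability. Allocation
# is recursive by rows with remaining-column-margin bounds; probabilities in
# log space. Stops with an error beyond `guard` tables.
enumerate_margin_tables <- function(rs, cs, visit, guard = 1e7) {
  r <- length(rs); cc <- length(cs)
  logconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
  count <- 0L
  rec <- function(i, rem, lacc) {
    if (i == r) {
      count <<- count + 1L
      if (count > guard)
        stop("enumeration guard exceeded (more than ", format(guard),
             " tables)", call. = FALSE)
      visit(lacc - sum(lgamma(rem + 1)))
      return(invisible())
    }
    alloc <- function(j, left, la) {
      if (j == cc) {
        if (left <= rem[cc]) {
          row <- row_buf[[i]]; row[cc] <- left
          row_buf[[i]] <<- row
          rem2 <- rem - row_buf[[i]]
          rec(i + 1L, rem2, la - lgamma(left + 1))
        }
        return(invisible())
      }
      upper <- min(left, rem[j])
      for (x in 0:upper) {
        row <- row_buf[[i]]; row[j] <- x
        row_buf[[i]] <<- row
        alloc(j + 1L, left - x, la - lgamma(x + 1))
      }
    }
    alloc(1L, rs[i], lacc)
  }
  row_buf <- replicate(r, numeric(cc), simplify = FALSE)
  rec(1L, cs, logconst)
  invisible(count)
}

table_log_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Freeman-Halton exact test for an r x c table
#'
#' Exact generalization of [fisher_exact_two_sided()] to r x c tables: all
#' tables with the observed margins are enumerated and the multivariate
#' hypergeometric probabilities of those no more probable than the observed
#' table (relative tie tolerance 1e-7) are summed. On a 2x2 input this
#' reduces exactly to the two-sided Fisher test.
#'
#' @param table r x c matrix of non-negative integer counts, positive margins.
#' @param guard upper bound on the number of enumerated tables.
#' @return p-value in (0, 1].
#' @examples
#' freeman_halton_exact(matrix(c(8, 1, 14, 3, 5, 7), 3, byrow = TRUE))
#' @export
freeman_halton_exact <- function(table, guard = 1e7) {
  m <- check_margins(as_count_matrix(table))
  lp_obs <- table_log_prob(m)
  cut <- lp_obs + log1p(TIE_TOL)
  p <- 0
  enumerate_margin_tables(rowSums(m), colSums(m), function(lp) {
    if (lp <= cut) p <<- p + exp(lp)
  }, guard = guard)
  min(max(p, .Machine$double.xmin), 1)
}

#' Pearson chi-squared test for an r x c table
#'
#' `X2 = sum((O - E)^2 / E)` with `df = (r - 1)(c - 1)` and an upper-tail
#' chi-squared p-value; no continuity correction by default (`correct = TRUE`
#' applies the Yates correction, 2x2 only), so the statistic is reproducible
#' from the textbook formula.
#'
#' @inheritParams freeman_halton_exact
#' @param correct apply the Yates continuity correction (2x2 tables only).
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  m <- check_margins(as_count_matrix(table))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  dev <- abs(m - E)
  if (correct) {
    if (nrow(m) != 2 || ncol(m) != 2)
      stop("the Yates correction applies to 2x2 tables only", call. = FALSE)
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Group comparisons for continuous data
#'
#' Standard two-group and k-group comparisons as used in clinical cohort
#' descriptions: two-tailed t test, Mann-Whitney (Wilcoxon rank-sum),
#' Kruskal-Wallis followed by pairwise Mann-Whitney comparisons with
#' Bonferroni's inequality (pairwise p multiplied by the number of
#' comparisons, capped at 1), and Spearman rank correlation.
#'
#' @param values numeric outcome vector.
#' @param group_labels grouping vector; for `method = "spearman"` a second
#'   numeric variable of the same length.
#' @param method one of `"t_test"`, `"mann_whitney"`,
#'   `"kruskal_wallis_bonferroni"`, `"spearman"`.
#' @return list with `statistic`, `p`, and for the Kruskal-Wallis route a
#'   `pairwise` named vector of Bonferroni-adjusted p-values.
#' @export
compare_continuous_groups <- function(values, group_labels,
                                      method = c("t_test", "mann_whitney",
                                                 "kruskal_wallis_bonferroni",
                                                 "spearman")) {
  method <- match.arg(method)
  if (length(values) != length(group_labels))
    stop("values and group_labels must have equal length", call. = FALSE)
  if (method == "spearman") {
    y <- as.numeric(group_labels)
    if (stats::sd(values) == 0 || stats::sd(y) == 0)
      stop("rank correlation is undefined for constant input", call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(values, y, method = "spearman"))
    return(list(statistic = unname(ct$estimate), p = ct$p.value))
  }
  g <- factor(group_labels)
  if (any(table(g) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (method %in% c("t_test", "mann_whitney") && nlevels(g) != 2)
    stop("two-group methods require exactly 2 groups", call. = FALSE)
  if (method == "t_test") {
    tt <- stats::t.test(values ~ g, alternative = "two.sided")
    return(list(statistic = unname(tt$statistic), p = tt$p.value))
  }
  if (method == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(values ~ g,
                                              alternative = "two.sided"))
    return(list(statistic = unname(wt$statistic), p = wt$p.value))
  }
  if (nlevels(g) < 2) stop("at least 2 groups required", call. = FALSE)
  kw <- stats::kruskal.test(values, g)
  pairs <- utils::combn(levels(g), 2)
  n_comp <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    sel <- g %in% pr
    min(1, n_comp * suppressWarnings(
      stats::wilcox.test(values[sel] ~ droplevels(g[sel]))$p.value))
  })
  names(pw) <- apply(pairs, 2, paste, collapse = " vs ")
  list(statistic = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}
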