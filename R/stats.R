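#' One-way analysis of variance from closed forms
#'
#' Classical fixed-effects one-way ANOVA computed directly from the between-
#' and within-group sums of squares, so the arithmetic is transparent and
#' testable against hand computation.  The F statistic is the ratio of the
#' between to the within mean square; its p-value comes from the F
#' distribution with (k - 1, N - k) degrees of freedom.  When the group
#' means are exactly equal the statistic is 0 and p is 1, even if the
#' within-group variance is also degenerate.
#'
#' @param data Data frame with one observation per row.
#' @param value,group Names of the value and grouping columns (defaults
#'   `"value"`, `"group"`).
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p.value`, `ss_between`, `ss_within`, `ms_within`, `n_groups`, `n_obs`.
#' @examples
#' d <- tibble::tibble(
#'   group = rep(c("a", "b", "c"), each = 3),
#'   value = c(1, 2, 3, 2, 3, 4, 6, 7, 8)
#' )
#' oneway_anova(d)
#' @export
oneway_anova <- function(data, value = "value", group = "group") {
  g <- check_groups(data, value, group)
  k <- length(g)
  n_i <- lengths(g)
  n_tot <- sum(n_i)
  grand <- sum(unlist(g)) / n_tot
  means <- purrr::map_dbl(g, mean)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(purrr::map_dbl(g, function(v) sum((v - mean(v))^2)))
  dfb <- k - 1
  dfw <- n_tot - k
  if (ssb == 0) {
    f_stat <- 0
    p <- 1
  } else {
    msw <- ssw / dfw
    f_stat <- (ssb / dfb) / msw
    p <- pf(f_stat, dfb, dfw, lower.tail = FALSE)
  }
  tibble(
    statistic = f_stat, df_between = dfb, df_within = dfw, p.value = p,
    ss_between = ssb, ss_within = ssw, ms_within = ssw / dfw,
    n_groups = k, n_obs = n_tot
  )
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All pairwise mean comparisons on the pooled ANOVA error term, with
#' familywise-adjusted p-values from the studentized range distribution.
#' For a pair (i, j) the statistic is
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MS_W / 2)(1/n_i + 1/n_j)}}
#' (the Tukey-Kramer standard error for unbalanced groups), referred to the
#' studentized range with k groups and the within-group degrees of freedom.
#'
#' @inheritParams oneway_anova
#' @param conf_level Familywise confidence level for significance flags.
#' @return A tibble with one row per group pair: `group1`, `group2`, `diff`
#'   (mean of `group2` minus mean of `group1`), `se`, `q`, `p.adj`,
#'   `significant` (at `1 - conf_level`).
#' @examples
#' d <- tibble::tibble(
#'   group = rep(c("Pi", "MPn"), each = 3),
#'   value = c(27.1, 26.8, 27.3, 48.0, 47.9, 48.2)
#' )
#' tukey_hsd(d)
#' @export
tukey_hsd <- function(data, value = "value", group = "group",
                      conf_level = 0.95) {
  g <- check_groups(data, value, group)
  k <- length(g)
  n_i <- lengths(g)
  dfw <- sum(n_i) - k
  msw <- sum(purrr::map_dbl(g, function(v) sum((v - mean(v))^2))) / dfw
  means <- purrr::map_dbl(g, mean)
  nm <- names(g)
  pairs <- utils::combn(seq_len(k), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_i) {
    i <- pairs[1, c_i]
    j <- pairs[2, c_i]
    diff <- unname(means[j] - means[i])
    se <- unname(sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j])))
    q <- if (se == 0) {
      if (diff == 0) 0 else Inf
    } else {
      abs(diff) / se
    }
    p <- if (is.infinite(q)) 0 else ptukey(q, k, dfw, lower.tail = FALSE)
    tibble(
      group1 = nm[i], group2 = nm[j], diff = diff, se = se, q = q,
      p.adj = p, significant = p <= 1 - conf_level
    )
  })
}

check_groups <- function(data, value, group) {
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` needs columns `%s` and `%s`.", value, group))
  }
  v <- data[[value]]
  if (any(!is.finite(v))) abort("values must be finite.")
  g <- split(v, factor(data[[group]], levels = unique(data[[group]])))
  if (length(g) < 2) abort("at least 2 groups are required.")
  if (any(lengths(g) < 2)) abort("every group needs at least 2 values.")
  g
}

#' Two-proportion test via the 2x2 chi-square
#'
#' Compares two binomial proportions x1/n1 and x2/n2 with the classical 2x2
#' chi-square statistic, by default with the Yates continuity correction
#' (each |observed - expected| cell deviation reduced by 0.5, never below
#' 0).  This is the chi-square form of the two-proportion z-test
#' (z-squared equals the uncorrected chi-square).  One-sided p-values halve
#' the chi-square tail when the observed direction matches the alternative
#' and take the complement otherwise.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two samples.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param continuity Apply the Yates correction (default `TRUE`).
#' @return A `prop_test_result` with `chi2`, `df = 1`, `p`, the input
#'   counts, sample proportions and the conventions used.
#' @examples
#' two_proportion_test(14, 219, 1, 187, alternative = "greater")
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                alternative = c("two.sided", "greater", "less"),
                                continuity = TRUE) {
  alternative <- match.arg(alternative)
  for (v in list(x1 = x1, n1 = n1, x2 = x2, n2 = n2)) check_nonneg(v, "count")
  if (n1 <= 0 || n2 <= 0) abort("`n1` and `n2` must be positive.")
  if (x1 > n1 || x2 > n2) abort("successes cannot exceed trials.")
  obs <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  dev <- abs(obs - expected)
  if (continuity) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  p_two <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  p <- switch(alternative,
    two.sided = p_two,
    greater = if (p1 >= p2) p_two / 2 else 1 - p_two / 2,
    less = if (p1 <= p2) p_two / 2 else 1 - p_two / 2
  )
  structure(
    list(
      x1 = x1, n1 = n1, x2 = x2, n2 = n2, estimate = c(p1 = p1, p2 = p2),
      chi2 = chi2, df = 1L, p = p, alternative = alternative,
      continuity = continuity
    ),
    class = "prop_test_result"
  )
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf(
    "<prop_test_result> %d/%d vs %d/%d (%.3g vs %.3g)\n",
    x$x1, x$n1, x$x2, x$n2, x$estimate[1], x$estimate[2]
  ))
  cat(sprintf(
    "  chi2 = %.4g, df = %d, p = %.6g (%s%s)\n",
    x$chi2, x$df, x$p, x$alternative,
    if (x$continuity) ", Yates-corrected" else ""
  ))
  invisible(x)
}

#' Tidy a two-proportion test
#'
#' @param x A [two_proportion_test()] result.
#' @param ... Unused.
#' @return A one-row tibble with the counts, proportions, statistic and
#'   p-value.
#' @export
tidy.prop_test_result <- function(x, ...) {
  tibble(
    x1 = x$x1, n1 = x$n1, x2 = x$x2, n2 = x$n2,
    p1 = unname(x$estimate[1]), p2 = unname(x$estimate[2]),
    statistic = x$chi2, df = x$df, p.value = x$p,
    alternative = x$alternative, continuity = x$continuity
  )
}
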