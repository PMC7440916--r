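# Group-comparison statistics and the end-to-end report.

#' Two-group (or paired) comparison with Bonferroni adjustment
#'
#' Dispatches to the test used for each comparison family: Wilcoxon
#' rank-sum for unpaired group differences, Wilcoxon signed-rank for
#' paired within-cell differences, Fisher's exact test for proportions
#' (pass `c(successes, failures)` per group), and Kruskal-Wallis for
#' slope distributions.  All tests are two-sided.
#'
#' @param values_a,values_b Numeric samples (counts for `"fisher"`).
#' @param test One of `"wrs"`, `"signed_rank"`, `"fisher"`,
#'   `"kruskal_wallis"`, `"anova"`.
#' @param paired Paired samples (only meaningful for `"signed_rank"`,
#'   which implies it).
#' @param n_family Number of simultaneous comparisons in the family;
#'   the adjusted p is `min(1, p * n_family)`.
#' @param parameter Optional label for the compared quantity.
#' @return A `group_comparison` list: `parameter`, `test`, `statistic`,
#'   `p_raw`, `p_bonferroni`, `n`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("wrs", "signed_rank", "fisher",
                                    "kruskal_wallis", "anova"),
                           paired = FALSE, n_family = 1,
                           parameter = NA_character_) {
  test <- match.arg(test)
  if (!length(values_a) || !length(values_b))
    stop_invalid("empty group")
  res <- switch(test,
    wrs = {
      h <- stats::wilcox.test(values_a, values_b, exact = FALSE)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    signed_rank = {
      h <- stats::wilcox.test(values_a, values_b, paired = TRUE,
                              exact = FALSE)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    fisher = {
      tab <- rbind(values_a, values_b)
      if (!all(dim(tab) == c(2, 2)))
        stop_invalid("fisher test needs c(successes, failures) per group")
      h <- stats::fisher.test(tab)
      list(statistic = unname(h$estimate), p = h$p.value)
    },
    kruskal_wallis = {
      h <- stats::kruskal.test(list(values_a, values_b))
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    anova = {
      p <- responsiveness_anova(list(values_a, values_b))
      list(statistic = NA_real_, p = p)
    })
  structure(list(parameter = parameter, test = test,
                 statistic = res$statistic, p_raw = res$p,
                 p_bonferroni = min(1, res$p * n_family),
                 n = c(length(values_a), length(values_b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, p = %.3g (Bonferroni %.3g)\n",
              x$parameter, x$test, x$p_raw, x$p_bonferroni))
  invisible(x)
}

#' Linear correlation of a shape parameter with an index
#'
#' Ordinary least squares of `y` on `x`; reports R-squared, the F-test
#' p-value and the slope.  With `loo = TRUE` a leave-one-out table of
#' R-squared values quantifies sensitivity to single (possibly
#' high-leverage) points.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @param loo Also compute leave-one-out R-squared values.
#' @return List with `r_squared`, `p`, `slope` (and `loo_r_squared`).
#' @export
linear_corr <- function(x, y, loo = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("need >= 3 finite points")
  if (stats::var(x) == 0) stop_invalid("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  out <- list(r_squared = sm$r.squared, p = unname(p),
              slope = unname(stats::coef(fit)[2]))
  if (loo)
    out$loo_r_squared <- vapply(seq_along(x), function(i)
      summary(stats::lm(y[-i] ~ x[-i]))$r.squared, numeric(1))
  out
}

#' Percent change between two group means
#'
#' `100 * (b - a) / a`; used for the worked examples comparing naive and
#' experienced preferred-direction response means.
#'
#' @param a Reference (naive) value.
#' @param b Comparison (experienced) value.
#' @export
percent_increase <- function(a, b) {
  check_scalar(a, "a")
  if (a == 0) stop_invalid("reference value must be nonzero")
  100 * (b - a) / a
}
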