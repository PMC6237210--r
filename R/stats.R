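#' Group summary: mean and SD
#'
#' @param values Numeric vector, nonempty.
#' @param group_name Label for the group.
#' @return One-row tibble: `group`, `n`, `mean`, `sd`, `sd_defined`. The
#'   sample (n - 1) standard deviation is reported; for a single value it is
#'   0 with `sd_defined = FALSE`.
#' @export
#' @examples
#' summarize_group(c(2, 4, 6), "untreated")
summarize_group <- function(values, group_name = "group") {
  if (length(values) == 0L) abort("`values` must be nonempty.")
  tibble::tibble(
    group = group_name,
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2L) sd(values) else 0,
    sd_defined = length(values) >= 2L
  )
}

#' Two-tailed two-sample t test
#'
#' Welch's t test by default; the pooled-variance (Student) variant is
#' available by flag. The significance call at alpha = 0.05 is reported
#' alongside the statistic, not baked into it.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param alpha Significance level reported in `tidy()`/`print()`
#'   (default 0.05).
#' @return An object of class `osteo_ttest` (see [tidy.osteo_ttest()]).
#' @export
#' @examples
#' tt <- two_tailed_t_test(c(10, 11, 12, 13), c(20, 21, 22, 23),
#'                         variant = "pooled")
#' tidy(tt)
two_tailed_t_test <- function(group_a, group_b,
                              variant = c("welch", "pooled"),
                              alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 values for a t test.")
  }
  ht <- t.test(group_a, group_b,
    alternative = "two.sided", var.equal = variant == "pooled"
  )
  structure(
    list(
      t_statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = length(group_a), n_b = length(group_b),
      variant = variant, alpha = alpha
    ),
    class = "osteo_ttest"
  )
}

#' @export
print.osteo_ttest <- function(x, ...) {
  cat(sprintf(
    "Two-tailed %s t test: t = %.4g, df = %.4g, p = %.4g (%s at alpha = %g)\n",
    x$variant, x$t_statistic, x$df, x$p_value,
    if (x$p_value < x$alpha) "significant" else "not significant", x$alpha
  ))
  invisible(x)
}

#' Tidy a two-sample t-test result
#' @param x An `osteo_ttest`.
#' @param ... Unused.
#' @return One-row tibble: group means and sizes, `t_statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
tidy.osteo_ttest <- function(x, ...) {
  tibble::tibble(
    mean_a = x$mean_a, mean_b = x$mean_b,
    n_a = x$n_a, n_b = x$n_b,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    significant = x$p_value < x$alpha
  )
}

#' @rdname tidy.osteo_ttest
#' @export
glance.osteo_ttest <- function(x, ...) {
  tibble::tibble(
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    variant = x$variant
  )
}

#' Pairwise comparisons of a measurement against a reference group
#'
#' Runs [two_tailed_t_test()] of every non-reference group against the
#' reference and binds the tidied rows. Designed to sit at the end of a
#' pipe over a per-cell or per-movie results table.
#'
#' @param data A data frame.
#' @param value Column (tidy-select) holding the measurement.
#' @param group Column holding the group labels.
#' @param reference Reference group label (default `"untreated"`).
#' @param variant Passed to [two_tailed_t_test()].
#' @return Tibble with one row per comparison: `comparison`, group sizes,
#'   means and SDs, `t_statistic`, `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(data, value, group, reference = "untreated",
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  vals <- dplyr::pull(data, {{ value }})
  grps <- dplyr::pull(data, {{ group }})
  if (!reference %in% grps) {
    abort(sprintf("Reference group '%s' not present in the data.", reference))
  }
  ref_vals <- vals[grps == reference]
  others <- setdiff(unique(grps), reference)
  purrr::map_dfr(others, function(g) {
    gv <- vals[grps == g]
    tt <- tidy(two_tailed_t_test(gv, ref_vals, variant = variant))
    tibble::tibble(
      comparison = paste(g, "vs", reference),
      group = g,
      n = length(gv), mean = mean(gv),
      sd = if (length(gv) >= 2) sd(gv) else 0,
      n_ref = length(ref_vals), mean_ref = mean(ref_vals),
      sd_ref = if (length(ref_vals) >= 2) sd(ref_vals) else 0,
      t_statistic = tt$t_statistic, df = tt$df,
      p_value = tt$p_value, significant = tt$significant
    )
  })
}
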