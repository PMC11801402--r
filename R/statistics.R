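new_cyto_test <- function(test, statistic, df, p_value, alpha,
                          n_per_group) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         alpha = alpha, significant = p_value < alpha,
         n_per_group = n_per_group),
    class = "cyto_test"
  )
}

#' Two-sample Student's t-test
#'
#' Classical equal-variance two-sample t-test, two-sided, with
#' `n_a + n_b - 2` degrees of freedom. The statistical unit is intended to
#' be the per-image (imaging) or per-tube (flow) mean, not pooled per-cell
#' values. If both groups are constant and equal the comparison is vacuous
#' and `p = 1` by convention; constant but unequal groups are an error.
#'
#' @param group_a,group_b Numeric vectors, each `n >= 2`.
#' @param alpha Significance level (default 0.05).
#' @return A `cyto_test` object; see [tidy.cyto_test()].
#' @export
student_t <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs at least 2 observations.")
  }
  df <- length(group_a) + length(group_b) - 2L
  pooled_ss <- sum((group_a - mean(group_a))^2) +
    sum((group_b - mean(group_b))^2)
  if (pooled_ss == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(new_cyto_test("student_t", 0, df, 1, alpha,
                           c(length(group_a), length(group_b))))
    }
    abort("zero pooled variance with unequal means: t statistic undefined.")
  }
  res <- stats::t.test(group_a, group_b, var.equal = TRUE)
  new_cyto_test("student_t", unname(res$statistic), unname(res$parameter),
                res$p.value, alpha, c(length(group_a), length(group_b)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom. With two groups it reduces exactly
#' to the Student's t-test (`F = t^2`, identical p).
#'
#' @param groups A list of numeric vectors (>= 2 groups, each `n >= 2`), or
#'   a data frame with columns `value` and `group`.
#' @param alpha Significance level.
#' @return A `cyto_test` object.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L) abort("need at least 2 groups.")
  if (any(lengths(groups) < 2L)) {
    abort("each group needs at least 2 observations.")
  }
  k <- length(groups)
  n_tot <- sum(lengths(groups))
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (within_ss == 0) {
    mu <- vapply(groups, mean, numeric(1))
    if (max(mu) == min(mu)) {
      return(new_cyto_test("anova_oneway", 0, c(k - 1L, n_tot - k), 1,
                           alpha, lengths(groups)))
    }
    abort("zero within-group variance with unequal means: F undefined.")
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_len(k), lengths(groups)))
  res <- stats::oneway.test(value ~ grp, var.equal = TRUE)
  new_cyto_test("anova_oneway", unname(res$statistic),
                unname(res$parameter), res$p.value, alpha,
                lengths(groups))
}

#' @export
print.cyto_test <- function(x, ...) {
  cat(sprintf(
    "<cyto_test> %s: statistic %.4f, df %s, p = %.4g (%ssignificant at alpha = %g)\n",
    x$test, x$statistic, paste(round(x$df, 2), collapse = ", "), x$p_value,
    if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Tidy a hypothesis-test result
#'
#' @param x A `cyto_test`.
#' @param ... Unused.
#' @return A one-row tibble: `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   `alpha`, `significant`.
#' @export
#' @method tidy cyto_test
tidy.cyto_test <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1L) x$df[2] else NA_real_,
    p_value = x$p_value,
    alpha = x$alpha,
    significant = x$significant
  )
}

#' @rdname tidy.cyto_test
#' @export
#' @method glance cyto_test
glance.cyto_test <- function(x, ...) tidy(x, ...)

#' Per-replicate mean intensities
#'
#' Collapses an event table to one mean intensity per statistical unit —
#' per image for the imaging modality, per tube (`source_id`) for flow.
#' Testing on these replicate means keeps the sample size at the number of
#' images/tubes; testing on pooled per-cell values would inflate
#' significance.
#'
#' @param events Event table with a `source_id` column identifying the
#'   replicate (image or tube).
#' @return A tibble: `modality`, `group`, `source_id`, `mean_8bit`, `n`.
#' @export
replicate_means <- function(events) {
  events |>
    dplyr::group_by(.data$modality, .data$group, .data$source_id) |>
    dplyr::summarise(mean_8bit = mean(.data$intensity_8bit),
                     n = dplyr::n(), .groups = "drop")
}

#' Compare groups within one modality
#'
#' Student's t-test for two groups, one-way ANOVA for three or more, applied
#' to the per-replicate means of one modality.
#'
#' @param means Tibble from [replicate_means()], one modality.
#' @param alpha Significance level.
#' @param bonferroni Divide alpha by the number of comparisons (off by
#'   default; no multiple-testing correction is applied unless requested).
#' @param n_comparisons Number of comparisons for the Bonferroni adjustment.
#' @return A `cyto_test` object.
#' @export
compare_groups <- function(means, alpha = 0.05, bonferroni = FALSE,
                           n_comparisons = 1L) {
  if (bonferroni) alpha <- alpha / n_comparisons
  groups <- split(means$mean_8bit, means$group)
  if (length(groups) == 2L) {
    student_t(groups[[1L]], groups[[2L]], alpha)
  } else {
    anova_oneway(groups, alpha)
  }
}

#' Imaging versus flow concordance report
#'
#' Joins the per-metric relative-change tables of the two modalities on
#' `metric` x `group` and reports, for every key, whether the two modalities
#' agree in sign (a change of exactly zero agrees with anything) and the
#' magnitude ratio `|flow| / |imaging|`. Group-comparison test results can
#' be attached per modality.
#'
#' @param rel_imaging,rel_flow Tibbles from [relative_changes()], one
#'   modality each.
#' @param test_imaging,test_flow Optional `cyto_test` objects.
#' @return A tibble of class `cyto_concordance`: `metric`, `group`,
#'   `control`, `rel_change_imaging_pct`, `rel_change_flow_pct`,
#'   `sign_agree`, `magnitude_ratio`; test results in the `tests` attribute.
#' @export
build_concordance <- function(rel_imaging, rel_flow,
                              test_imaging = NULL, test_flow = NULL) {
  key <- function(x) paste(x$metric, x$group, sep = ":")
  k_i <- key(rel_imaging); k_f <- key(rel_flow)
  missing_in_flow <- setdiff(k_i, k_f)
  missing_in_imaging <- setdiff(k_f, k_i)
  if (length(missing_in_flow) || length(missing_in_imaging)) {
    abort(paste0(
      "metric x group keys differ between modalities; missing in flow: {",
      paste(missing_in_flow, collapse = ", "), "}, missing in imaging: {",
      paste(missing_in_imaging, collapse = ", "), "}"))
  }
  out <- dplyr::inner_join(
    dplyr::select(rel_imaging, dplyr::all_of(c("metric", "group", "control",
                                               "rel_change_pct"))) |>
      dplyr::rename(rel_change_imaging_pct = "rel_change_pct"),
    dplyr::select(rel_flow, dplyr::all_of(c("metric", "group",
                                            "rel_change_pct"))) |>
      dplyr::rename(rel_change_flow_pct = "rel_change_pct"),
    by = c("metric", "group")
  ) |>
    dplyr::mutate(
      sign_agree = .data$rel_change_imaging_pct == 0 |
        .data$rel_change_flow_pct == 0 |
        sign(.data$rel_change_imaging_pct) == sign(.data$rel_change_flow_pct),
      magnitude_ratio = abs(.data$rel_change_flow_pct) /
        abs(.data$rel_change_imaging_pct)
    )
  tests <- list(imaging = test_imaging, flow = test_flow)
  structure(out, tests = tests,
            class = c("cyto_concordance", class(out)))
}

#' @export
#' @method tidy cyto_concordance
tidy.cyto_concordance <- function(x, ...) {
  as_tibble(x)
}

#' @export
#' @method glance cyto_concordance
glance.cyto_concordance <- function(x, ...) {
  tests <- attr(x, "tests")
  tibble(
    n_keys = nrow(x),
    n_sign_agree = sum(x$sign_agree),
    p_imaging = if (!is.null(tests$imaging)) tests$imaging$p_value else NA_real_,
    p_flow = if (!is.null(tests$flow)) tests$flow$p_value else NA_real_
  )
}
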