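#' Tidy a repeated-measures ANOVA
#'
#' @param x A `pacing_rm_anova` from [rm_anova()].
#' @param ... Unused.
#' @return Tibble with one row per stratum (`subjects`, `days`,
#'   `error`): `term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.pacing_rm_anova <- function(x, ...) {
  tibble(
    term = c("subjects", "days", "error"),
    df = c(x$n_subjects - 1, x$df1, x$df2),
    sumsq = c(x$ss_rows, x$ss_cols, x$ss_error),
    meansq = c(x$ms_rows, x$ms_cols, x$ms_error),
    statistic = c(NA, x$f, NA),
    p.value = c(NA, x$p, NA)
  )
}

#' @rdname tidy.pacing_rm_anova
#' @return `glance()`: one-row tibble with `statistic`, `p.value`,
#'   `df`, `df.residual`, `nobs`.
#' @exportS3Method generics::glance
glance.pacing_rm_anova <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, df = x$df1, df.residual = x$df2,
         nobs = x$n_subjects * x$n_days)
}

#' Tidy a between-group ANOVA with LSD post-hoc tests
#'
#' @param x A `pacing_group_anova` from [oneway_anova_lsd()].
#' @param ... Unused.
#' @return `tidy()`: the pairwise LSD table (`group1`, `group2`, `diff`,
#'   `t`, `p_value`).
#' @exportS3Method generics::tidy
tidy.pacing_group_anova <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.pacing_group_anova
#' @return `glance()`: one-row tibble with `statistic`, `p.value`, `df`,
#'   `df.residual`, `eta.squared`.
#' @exportS3Method generics::glance
glance.pacing_group_anova <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p, df = x$df1, df.residual = x$df2,
         eta.squared = x$eta_squared)
}
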