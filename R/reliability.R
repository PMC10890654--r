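#' Pivot one pacing variable into a runners-by-days matrix
#'
#' @param vars_tbl Per-(runner, day) tibble from [pacing_variables()].
#' @param variable Column name of the variable to extract.
#' @param complete_only Drop runners missing any day (default `TRUE`).
#' @return Numeric matrix, runners in rows (rownames = runner ids),
#'   days in columns (colnames = day labels).
#' @export
variable_matrix <- function(vars_tbl, variable, complete_only = TRUE) {
  wide <- vars_tbl |>
    dplyr::select("runner_id", "day", dplyr::all_of(variable)) |>
    tidyr::pivot_wider(names_from = "day", values_from = dplyr::all_of(variable)) |>
    dplyr::arrange(.data$runner_id)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$runner_id
  if (complete_only) mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  mat
}

check_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("Need at least 2 subjects (rows) and 2 days (columns).")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("The measurement matrix must be complete and finite.")
  }
  values
}

#' One-way repeated-measures ANOVA on a subjects-by-days matrix
#'
#' Two-way decomposition with subjects as rows and days as columns
#' (computed through [stats::aov()] on the long form), testing the day
#' effect: `F = MS_days / MS_error` on df `(k - 1, (n - 1)(k - 1))`.
#' No sphericity correction is applied by default.
#'
#' A matrix with zero error variance is degenerate: if the day effect is
#' also zero the test is vacuous (`F = 0`, `p = 1`); otherwise `F` is
#' infinite with `p = 0` and a warning.
#'
#' @param values Numeric matrix, subjects in rows, repeated measurements
#'   (days) in columns; complete cases only.
#' @return A `pacing_rm_anova` object: list with `ss_rows`, `ss_cols`,
#'   `ss_error`, `ms_rows`, `ms_cols`, `ms_error`, `f`, `p`, `df1`,
#'   `df2`, `n_subjects`, `n_days`. Has [tidy()] and [glance()] methods.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3) # F = 12 on df (1, 2)
#' glance(rm_anova(m))
#' @export
rm_anova <- function(values) {
  values <- check_matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    day = factor(rep(seq_len(k), each = n))
  )
  fit <- aov(y ~ subject + day, data = long)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  names(ss) <- c("subject", "day", "error")
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_rows <- ss[["subject"]] / (n - 1)
  ms_cols <- ss[["day"]] / df1
  ms_error <- ss[["error"]] / df2
  if (ms_error <= .Machine$double.eps * max(1, ms_rows, ms_cols)) {
    if (ms_cols <= .Machine$double.eps * max(1, ms_rows)) {
      f <- 0; p <- 1
    } else {
      warn("Zero error variance with a non-zero day effect; F is infinite.")
      f <- Inf; p <- 0
    }
  } else {
    f <- ms_cols / ms_error
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(
      ss_rows = ss[["subject"]], ss_cols = ss[["day"]], ss_error = ss[["error"]],
      ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
      f = f, p = p, df1 = df1, df2 = df2, n_subjects = n, n_days = k
    ),
    class = "pacing_rm_anova"
  )
}

#' @export
print.pacing_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g (%d subjects x %d days)\n",
    x$df1, x$df2, x$f, x$p, x$n_subjects, x$n_days
  ))
  invisible(x)
}

#' Intraclass correlation for test-retest reliability
#'
#' Default form is ICC(3,1): two-way mixed effects, single measures,
#' consistency —
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`. Its
#' 95% CI uses the closed form based on `F = MS_subjects / MS_error`
#' with df `(n - 1, (n - 1)(k - 1))`. `form = "2,1"` gives the two-way
#' random-effects absolute-agreement coefficient ICC(2,1) (point
#' estimate only; its CI has no comparably simple exact form and is
#' returned as `NA`).
#'
#' @inheritParams rm_anova
#' @param form `"3,1"` (default) or `"2,1"`.
#' @param confidence Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `form`, `confidence`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3)
#' icc_reliability(m)$icc # 0.8
#' @export
icc_reliability <- function(values, form = c("3,1", "2,1"),
                            confidence = 0.95) {
  form <- match.arg(form)
  values <- check_matrix(values)
  a <- rm_anova(values)
  n <- a$n_subjects
  k <- a$n_days
  if (form == "3,1") {
    denom <- a$ms_rows + (k - 1) * a$ms_error
    if (denom == 0) abort("ICC undefined: no variance in the matrix.")
    icc <- (a$ms_rows - a$ms_error) / denom
    if (a$ms_error == 0) {
      ci <- c(1, 1)
    } else {
      f_obs <- a$ms_rows / a$ms_error
      alpha <- 1 - confidence
      f_low <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      f_up <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((f_low - 1) / (f_low + k - 1), (f_up - 1) / (f_up + k - 1))
    }
  } else {
    denom <- a$ms_rows + (k - 1) * a$ms_error +
      k * (a$ms_cols - a$ms_error) / n
    if (denom == 0) abort("ICC undefined: no variance in the matrix.")
    icc <- (a$ms_rows - a$ms_error) / denom
    ci <- c(NA_real_, NA_real_)
  }
  list(icc = unname(icc), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
       form = form, confidence = confidence)
}

#' Qualitative ICC reliability band
#'
#' Poor below 0.5, moderate in \[0.5, 0.75), good in \[0.75, 0.9),
#' excellent at 0.9 and above.
#'
#' @param icc ICC value(s).
#' @return Character vector of band labels.
#' @export
icc_interpretation <- function(icc) {
  ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc < 0.9, "good", "excellent")))
}

#' Standard error of measurement
#'
#' `SEM = pooled_sd * sqrt(1 - ICC)`, in the variable's own units. The
#' pooled between-subject sd is taken over all cells after removing the
#' day (column) means, consistent with the consistency-form ICC that a
#' constant day shift should not inflate measurement error.
#'
#' @inheritParams rm_anova
#' @param icc The reliability coefficient to plug in (see
#'   [icc_reliability()]).
#' @return SEM in the units of `values`.
#' @export
sem_measure <- function(values, icc) {
  values <- check_matrix(values)
  if (!is.numeric(icc) || length(icc) != 1L || icc > 1) {
    abort("`icc` must be a single value <= 1.")
  }
  centred <- sweep(values, 2, colMeans(values)) + mean(values)
  pooled_sd <- sd(as.vector(centred))
  pooled_sd * sqrt(1 - icc)
}

#' Typical-error coefficient of variation (percent)
#'
#' Within-subject day-to-day variability expressed as a percent.
#' Values are transformed as `100 * ln(x)`, the repeated-measures ANOVA
#' error term gives the typical error `s = sqrt(MS_error)` on the log
#' scale, and the back-transform `100 * (exp(s / 100) - 1)` returns a
#' percent CV. Variables with any non-positive value (possible for the
#' signed split variables under negative splits) cannot be
#' log-transformed; they fall back to the raw-scale typical error
#' divided by the grand mean, flagged `transform_used = "raw"`.
#'
#' @inheritParams rm_anova
#' @return List with `cv_percent` and `transform_used` (`"log"` or
#'   `"raw"`).
#' @export
typical_error_cv <- function(values) {
  values <- check_matrix(values)
  if (all(values > 0)) {
    a <- rm_anova(100 * log(values))
    s <- sqrt(a$ms_error)
    list(cv_percent = 100 * (exp(s / 100) - 1), transform_used = "log")
  } else {
    a <- rm_anova(values)
    s <- sqrt(a$ms_error)
    list(cv_percent = 100 * s / abs(mean(values)), transform_used = "raw")
  }
}

#' Day-to-day reliability report for all pacing variables
#'
#' Produces one row per variable (mean speed plus the seven pacing
#' variables): per-day mean and sd on the original scale, typical-error
#' CV%, SEM, ICC with its confidence interval and qualitative band, and
#' the repeated-measures ANOVA F and p for a day effect. Only complete
#' runners (present on all days) enter. Variables with zero variance
#' across the whole matrix are flagged degenerate and their reliability
#' statistics returned as `NA`.
#'
#' @param vars_tbl Per-(runner, day) tibble from [pacing_variables()].
#' @param icc_form `"3,1"` (default) or `"2,1"`; see [icc_reliability()].
#' @param confidence Confidence level for the ICC interval.
#' @return A tibble of class `pacing_reliability`, one row per variable:
#'   `variable`, `day<j>_mean`, `day<j>_sd` for each day, `cv_percent`,
#'   `transform_used`, `sem`, `icc`, `icc_ci_low`, `icc_ci_high`,
#'   `icc_band`, `f_stat`, `p_value`, `degenerate`.
#' @export
reliability_report <- function(vars_tbl, icc_form = c("3,1", "2,1"),
                               confidence = 0.95) {
  icc_form <- match.arg(icc_form)
  complete <- vars_tbl |>
    dplyr::group_by(.data$runner_id) |>
    dplyr::filter(dplyr::n() == length(unique(vars_tbl$day))) |>
    dplyr::ungroup()
  vars <- intersect(pacing_variable_names(), names(complete))
  days <- sort(unique(complete$day))

  purrr::map_dfr(vars, function(v) {
    mat <- variable_matrix(complete, v)
    day_stats <- tibble(
      day = days,
      mean = unname(colMeans(mat)),
      sd = unname(apply(mat, 2, sd))
    ) |>
      tidyr::pivot_wider(names_from = "day",
                         values_from = c("mean", "sd"),
                         names_glue = "day{day}_{.value}")
    # a spread at rounding-noise scale is no spread at all
    degenerate <- diff(range(mat)) <= 1e-10 * max(1, abs(mean(mat)))
    if (degenerate) {
      return(dplyr::bind_cols(
        tibble(variable = v), day_stats,
        tibble(cv_percent = NA_real_, transform_used = NA_character_,
               sem = NA_real_, icc = NA_real_, icc_ci_low = NA_real_,
               icc_ci_high = NA_real_, icc_band = NA_character_,
               f_stat = NA_real_, p_value = NA_real_, degenerate = TRUE)
      ))
    }
    te <- typical_error_cv(mat)
    ic <- icc_reliability(mat, form = icc_form, confidence = confidence)
    an <- rm_anova(mat)
    dplyr::bind_cols(
      tibble(variable = v), day_stats,
      tibble(
        cv_percent = te$cv_percent, transform_used = te$transform_used,
        sem = sem_measure(mat, ic$icc),
        icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
        icc_band = icc_interpretation(ic$icc),
        f_stat = an$f, p_value = an$p, degenerate = FALSE
      )
    )
  }) |>
    structure(class = c("pacing_reliability", class(tibble())))
}
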