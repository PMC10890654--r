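#' Fisher Z transformation
#'
#' `atanh(r)`, variance-stabilizing transform applied to per-race
#' regression coefficients before the day-comparison ANOVA. Values at or
#' beyond |r| = 1 are clamped to 0.999999 with a warning.
#'
#' @param r Correlation coefficient(s).
#' @return Fisher-Z value(s), unbounded.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warn("|r| >= 1 clamped to 0.999999 before the Fisher Z transform.")
    r <- pmin(pmax(r, -0.999999), 0.999999)
  }
  atanh(r)
}

#' Classify a pacing profile from its lap-speed correlation
#'
#' The label comes from the Pearson correlation `r` of lap speed against
#' lap index: `r` in \[-0.1, 0.1\] (inclusive) is an even profile,
#' `r < -0.1` a positive profile (slowing over the race), `r > 0.1` a
#' negative profile (speeding up).
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Factor with levels `even`, `positive`, `negative`.
#' @export
classify_profile <- function(r) {
  lab <- ifelse(r < -0.1, "positive", ifelse(r > 0.1, "negative", "even"))
  factor(lab, levels = c("even", "positive", "negative"))
}

#' Pacing profile of one race
#'
#' Ordinary least-squares regression of lap speed on lap index
#' (1..n_laps). The slope and the Pearson correlation `r` summarize the
#' profile; `r` drives the even/positive/negative label (see
#' [classify_profile()]). A record with zero lap-speed variance has no
#' defined correlation: `r` is reported as 0, the label as `even`, and
#' the profile is flagged degenerate.
#'
#' @inheritParams pacing_variable
#' @return A one-row tibble: `slope` ((m/s)/lap), `r`, `z` (Fisher-Z),
#'   `label`, `degenerate`.
#' @export
pacing_profile <- function(lap_times, course = race_course()) {
  v <- lap_speeds(lap_times, course)
  k <- seq_along(v)
  if (var(v) == 0) {
    return(tibble(slope = 0, r = 0, z = 0,
                  label = classify_profile(0), degenerate = TRUE))
  }
  fit <- lm(v ~ k)
  r <- cor(k, v)
  tibble(slope = unname(coef(fit)[2]), r = r, z = fisher_z(r),
         label = classify_profile(r), degenerate = FALSE)
}

#' Pacing profiles for every race in a cohort
#'
#' @inheritParams pacing_variables
#' @return Tibble with one row per (runner, day): `runner_id`, `day`,
#'   `slope`, `r`, `z`, `label`, `degenerate`.
#' @export
pacing_profiles <- function(cohort, course = cohort_course(cohort)) {
  cohort |>
    dplyr::arrange(.data$runner_id, .data$day, .data$lap) |>
    dplyr::group_by(.data$runner_id, .data$day) |>
    dplyr::group_modify(~ pacing_profile(.x$lap_time_s, course)) |>
    dplyr::ungroup()
}

#' Day-to-day consistency of pacing-profile labels
#'
#' Counts, per runner, how many days share the runner's most frequent
#' label, and summarizes the cohort as the fraction of runners with the
#' identical label on all days, on all but one day, and the remainder.
#'
#' @param profiles Per-(runner, day) profile tibble from
#'   [pacing_profiles()]; every runner must have a profile for every day.
#' @return A list with `per_runner` (tibble: `runner_id`, `n_days`,
#'   `modal_label`, `n_modal`) and `summary` (tibble: `frac_all_days`,
#'   `frac_all_but_one`, `frac_other`).
#' @export
profile_consistency <- function(profiles) {
  n_days <- length(unique(profiles$day))
  counts <- profiles |>
    dplyr::count(.data$runner_id, .data$day) |>
    dplyr::count(.data$runner_id)
  if (any(counts$n != n_days)) {
    abort("Every runner must have exactly one profile per day.")
  }
  per_runner <- profiles |>
    dplyr::group_by(.data$runner_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      modal_label = names(which.max(table(.data$label))),
      n_modal = max(table(.data$label)),
      .groups = "drop"
    )
  n <- nrow(per_runner)
  frac_all <- mean(per_runner$n_modal == n_days)
  frac_but_one <- mean(per_runner$n_modal == n_days - 1)
  list(
    per_runner = per_runner,
    summary = tibble(
      n_runners = n,
      frac_all_days = frac_all,
      frac_all_but_one = frac_but_one,
      frac_other = 1 - frac_all - frac_but_one
    )
  )
}

#' Repeated-measures ANOVA on Fisher-Z profile coefficients
#'
#' Tests whether the per-runner regression coefficients (Fisher-Z
#' transformed) differ across days: a one-way repeated-measures ANOVA
#' with runners as subjects and day as the within factor.
#'
#' @param profiles Per-(runner, day) profile tibble from
#'   [pacing_profiles()] (complete runners only).
#' @return A `pacing_rm_anova` object; see [rm_anova()].
#' @export
rm_anova_profiles <- function(profiles) {
  m <- profiles |>
    dplyr::select("runner_id", "day", "z") |>
    tidyr::pivot_wider(names_from = "day", values_from = "z")
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$runner_id
  rm_anova(mat)
}
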