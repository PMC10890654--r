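#' Pacing variables for one race
#'
#' Single-race building blocks for the seven pacing variables plus mean
#' speed. Throughout, `v_k` is the speed of lap `k`, and `v` (the
#' reference) is the race mean speed [race_mean_speed()], i.e. total
#' distance over total time.
#'
#' * `pacing_cv()` — coefficient of variation: `100 * sd(v_k) / v`
#'   (sample sd, n-1 denominator).
#' * `pacing_cs()` — change in mean speed: mean over laps of the signed
#'   percent deviation `100 * (v_k - v) / v`. Because the arithmetic
#'   mean of lap speeds is never below the time-weighted mean, CS is
#'   always >= 0, zero only for an even race.
#' * `pacing_csf()` — change from first-lap speed: mean over all laps
#'   (lap 1 contributing 0) of the percent change relative to lap 1.
#' * `pacing_acs()` — absolute change in mean speed: mean over laps of
#'   `100 * |v_k - v| / v`.
#' * `pacing_range()` — positive range (fastest lap above `v`, percent),
#'   negative range (slowest lap below `v`, percent), and their sum, the
#'   pace range PR.
#' * `pacing_mrs()` — mid-race split: percent speed change between the
#'   two distance halves of the race (boundary at `total_distance / 2`,
#'   interpolated within a lap).
#' * `pacing_32_10()` — percent speed change between the first
#'   `total_distance - 10000` metres and the final 10 km.
#'
#' @section Sign convention:
#' CSF, MRS and 32-10 compare an early segment with a later one. With
#' `sign_convention = "slowdown-positive"` (default) they are computed
#' as (early - late) / early, so a runner who slows — a positive pacing
#' profile, the dominant pattern in recreational marathons — scores
#' positive. `"literal"` flips the sign (late relative to early).
#'
#' @param lap_times Numeric vector of lap times in seconds (one race).
#' @param course A [race_course()].
#' @param sign_convention `"slowdown-positive"` (default) or `"literal"`;
#'   see Details.
#' @return `pacing_cv`, `pacing_cs`, `pacing_csf`, `pacing_acs`,
#'   `pacing_mrs`, `pacing_32_10`: a single percent value.
#'   `pacing_range`: named numeric vector
#'   `c(positive_range, negative_range, pr)`, all in percent.
#' @examples
#' toy <- race_course(total_distance = 3000, n_laps = 3)
#' tt <- 1000 / c(4, 5, 6) # lap speeds 4, 5, 6 m/s
#' pacing_cv(tt, toy)
#' pacing_range(tt, toy)
#' @name pacing_variable
NULL

#' @rdname pacing_variable
#' @export
pacing_cv <- function(lap_times, course = race_course()) {
  v <- lap_speeds(lap_times, course)
  100 * sd(v) / race_mean_speed(lap_times, course)
}

#' @rdname pacing_variable
#' @export
pacing_cs <- function(lap_times, course = race_course()) {
  v <- lap_speeds(lap_times, course)
  vbar <- race_mean_speed(lap_times, course)
  mean(100 * (v - vbar) / vbar)
}

#' @rdname pacing_variable
#' @export
pacing_csf <- function(lap_times, course = race_course(),
                       sign_convention = c("slowdown-positive", "literal")) {
  sign_convention <- match.arg(sign_convention)
  v <- lap_speeds(lap_times, course)
  out <- mean(100 * (v[1] - v) / v[1])
  if (sign_convention == "literal") -out else out
}

#' @rdname pacing_variable
#' @export
pacing_acs <- function(lap_times, course = race_course()) {
  v <- lap_speeds(lap_times, course)
  vbar <- race_mean_speed(lap_times, course)
  mean(100 * abs(v - vbar) / vbar)
}

#' @rdname pacing_variable
#' @export
pacing_range <- function(lap_times, course = race_course()) {
  v <- lap_speeds(lap_times, course)
  vbar <- race_mean_speed(lap_times, course)
  pos <- 100 * (max(v) - vbar) / vbar
  neg <- 100 * (vbar - min(v)) / vbar
  c(positive_range = pos, negative_range = neg, pr = pos + neg)
}

#' @rdname pacing_variable
#' @export
pacing_mrs <- function(lap_times, course = race_course(),
                       sign_convention = c("slowdown-positive", "literal")) {
  sign_convention <- match.arg(sign_convention)
  half <- course$total_distance / 2
  ms1 <- segment_mean_speed(lap_times, 0, half, course)
  ms2 <- segment_mean_speed(lap_times, half, course$total_distance, course)
  out <- 100 * (ms1 - ms2) / ms1
  if (sign_convention == "literal") -out else out
}

#' @rdname pacing_variable
#' @export
pacing_32_10 <- function(lap_times, course = race_course(),
                         sign_convention = c("slowdown-positive", "literal")) {
  sign_convention <- match.arg(sign_convention)
  if (course$total_distance <= 10000) {
    abort("The 32-10 split needs a course longer than 10 km.")
  }
  b <- course$total_distance - 10000
  ms1 <- segment_mean_speed(lap_times, 0, b, course)
  ms2 <- segment_mean_speed(lap_times, b, course$total_distance, course)
  out <- 100 * (ms1 - ms2) / ms1
  if (sign_convention == "literal") -out else out
}

#' All pacing variables for every race in a cohort
#'
#' Computes mean speed and the seven pacing variables for each
#' (runner, day) record. This is the tidy batch entry point the
#' downstream reliability, validity and sensitivity analyses consume.
#'
#' @param cohort A cohort tibble (see [read_split_table()]).
#' @param course A [race_course()]; defaults to the course attached to
#'   `cohort`.
#' @inheritParams pacing_variable
#' @return A tibble with one row per (runner, day) and columns
#'   `runner_id`, `day`, `ms` (m/s), `cv`, `cs`, `csf`, `acs`,
#'   `positive_range`, `negative_range`, `pr`, `mrs`, `split_32_10`
#'   (all percents).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_runners = 4, seed = 1))$cohort
#' pacing_variables(cohort)
#' @export
pacing_variables <- function(cohort, course = cohort_course(cohort),
                             sign_convention = c("slowdown-positive", "literal")) {
  sign_convention <- match.arg(sign_convention)
  cohort |>
    dplyr::arrange(.data$runner_id, .data$day, .data$lap) |>
    dplyr::group_by(.data$runner_id, .data$day) |>
    dplyr::group_modify(function(g, key) {
      tt <- g$lap_time_s
      rng <- pacing_range(tt, course)
      tibble(
        ms = race_mean_speed(tt, course),
        cv = pacing_cv(tt, course),
        cs = pacing_cs(tt, course),
        csf = pacing_csf(tt, course, sign_convention),
        acs = pacing_acs(tt, course),
        positive_range = rng[["positive_range"]],
        negative_range = rng[["negative_range"]],
        pr = rng[["pr"]],
        mrs = pacing_mrs(tt, course, sign_convention),
        split_32_10 = if (course$total_distance > 10000) {
          pacing_32_10(tt, course, sign_convention)
        } else NA_real_
      )
    }) |>
    dplyr::ungroup()
}

# canonical variable order for reports
pacing_variable_names <- function(include_ranges = FALSE) {
  base <- c("ms", "cv", "cs", "csf", "acs", "pr", "mrs", "split_32_10")
  if (include_ranges) {
    append(base, c("positive_range", "negative_range"), after = 5L)
  } else {
    base
  }
}
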