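#' Per-lap speeds of one race
#'
#' @param lap_times Numeric vector of lap times in seconds (one race).
#' @param course A [race_course()].
#' @return Numeric vector of lap speeds in m/s, one per lap.
#' @examples
#' lap_speeds(rep(426.21, 33))
#' @export
lap_speeds <- function(lap_times, course = race_course()) {
  check_lap_times(lap_times, course)
  course$lap_distance / lap_times
}

#' Race mean speed
#'
#' Total distance over total time: the time-weighted (harmonic-style)
#' mean of the lap speeds, which is the speed the finish time implies.
#' It is less than or equal to the arithmetic mean of the lap speeds,
#' with equality only for a perfectly even race.
#'
#' @inheritParams lap_speeds
#' @return Mean race speed in m/s.
#' @examples
#' race_mean_speed(rep(15600 / 33, 33)) # 42195 m in 4:20:00
#' @export
race_mean_speed <- function(lap_times, course = race_course()) {
  check_lap_times(lap_times, course)
  course$total_distance / sum(lap_times)
}

#' Cumulative time at a distance along the race
#'
#' Linearly interpolates within the lap containing `x`, i.e. assumes
#' constant speed within a lap (the finest resolution the split data
#' support).
#'
#' @inheritParams lap_speeds
#' @param x Distance from the start, metres; `0 <= x <= total_distance`.
#' @return Elapsed time in seconds to reach `x`.
#' @export
time_at_distance <- function(lap_times, x, course = race_course()) {
  check_lap_times(lap_times, course)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 0 || x > course$total_distance) {
    abort(sprintf("`x` must be a single distance in [0, %g] metres.",
                  course$total_distance))
  }
  cum_d <- course$lap_distance * seq_len(course$n_laps)
  cum_t <- cumsum(lap_times)
  # piecewise-linear time vs distance through (0, 0) and lap endpoints
  stats::approx(c(0, cum_d), c(0, cum_t), xout = x, ties = "ordered")$y
}

#' Mean speed over a distance segment
#'
#' @inheritParams time_at_distance
#' @param x_start,x_end Segment boundaries in metres,
#'   `0 <= x_start < x_end <= total_distance`.
#' @return Segment mean speed in m/s.
#' @export
segment_mean_speed <- function(lap_times, x_start, x_end,
                               course = race_course()) {
  if (!is.numeric(x_start) || !is.numeric(x_end) ||
      length(x_start) != 1L || length(x_end) != 1L || x_start >= x_end) {
    abort("Need a non-degenerate segment with `x_start < x_end`.")
  }
  t0 <- time_at_distance(lap_times, x_start, course)
  t1 <- time_at_distance(lap_times, x_end, course)
  (x_end - x_start) / (t1 - t0)
}
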