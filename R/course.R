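#' Define a loop race course
#'
#' A course is modeled as `n_laps` equal laps covering `total_distance`
#' metres. The default is the marathon distance run as 33 laps of a
#' ~1279 m loop; laps are treated as exactly `total_distance / n_laps`
#' metres so that all percentage-valued pacing variables, which are
#' ratios of speeds, depend only on the lap times.
#'
#' @param total_distance Total race distance in metres. Default 42195.
#' @param n_laps Number of (equal) laps. Default 33.
#'
#' @return An object of class `race_course`: a list with elements
#'   `total_distance`, `n_laps` and `lap_distance` (metres).
#' @examples
#' marathon <- race_course()
#' marathon$lap_distance # 42195 / 33
#' @export
race_course <- function(total_distance = 42195, n_laps = 33L) {
  if (!is.numeric(total_distance) || length(total_distance) != 1L ||
      !is.finite(total_distance) || total_distance <= 0) {
    abort("`total_distance` must be a single positive number (metres).")
  }
  if (!is.numeric(n_laps) || length(n_laps) != 1L || n_laps < 2 ||
      n_laps != as.integer(n_laps)) {
    abort("`n_laps` must be a single integer >= 2.")
  }
  structure(
    list(
      total_distance = as.numeric(total_distance),
      n_laps = as.integer(n_laps),
      lap_distance = as.numeric(total_distance) / as.integer(n_laps)
    ),
    class = "race_course"
  )
}

#' @export
print.race_course <- function(x, ...) {
  cat(sprintf(
    "<race_course> %g m as %d laps of %.2f m\n",
    x$total_distance, x$n_laps, x$lap_distance
  ))
  invisible(x)
}

# Validate a vector of lap times against a course; used by every
# per-record computation.
check_lap_times <- function(lap_times, course) {
  stopifnot(inherits(course, "race_course"))
  if (!is.numeric(lap_times)) {
    abort("`lap_times` must be numeric (seconds).")
  }
  if (length(lap_times) != course$n_laps) {
    abort(sprintf(
      "Expected %d lap times for this course, got %d.",
      course$n_laps, length(lap_times)
    ))
  }
  if (any(!is.finite(lap_times)) || any(lap_times <= 0)) {
    abort("All lap times must be finite and > 0 seconds.")
  }
  invisible(lap_times)
}
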