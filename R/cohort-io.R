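#' Read a long-format split-time table
#'
#' Reads per-lap split times for a multi-day race from CSV. The single
#' supported dialect is long format with header columns `runner_id`
#' (string), `day` (integer, 1-based), `lap` (integer, 1-based) and
#' `lap_time_s` (seconds). Each (runner, day) must carry contiguous lap
#' indices `1..n_laps`; runner-days that do not are dropped with a
#' warning so one missed chip read never silently corrupts a cohort.
#'
#' @param path Path to the CSV file.
#' @param course A [race_course()]; defines the expected lap count.
#'
#' @return A cohort tibble with columns `runner_id`, `day`, `lap`,
#'   `lap_time_s`, ordered by runner, day, lap, carrying the course as
#'   attribute `"course"`.
#' @seealso [write_split_table()], [complete_runners()]
#' @export
read_split_table <- function(path, course = race_course()) {
  stopifnot(inherits(course, "race_course"))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("runner_id", "day", "lap", "lap_time_s")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Input is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(new_cohort(tibble(runner_id = character(), day = integer(),
                             lap = integer(), lap_time_s = double()),
                      course))
  }

  day <- suppressWarnings(as.integer(raw$day))
  lap <- suppressWarnings(as.integer(raw$lap))
  lap_time_s <- suppressWarnings(as.numeric(raw$lap_time_s))
  bad <- which(is.na(lap_time_s) | lap_time_s <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-numeric or non-positive lap time at data row %d (runner %s, day %s, lap %s).",
      bad[1], raw$runner_id[bad[1]], raw$day[bad[1]], raw$lap[bad[1]]
    ))
  }
  if (anyNA(day) || anyNA(lap) || any(day < 1) || any(lap < 1)) {
    abort("Columns `day` and `lap` must be positive integers (1-based).")
  }

  tbl <- tibble(runner_id = raw$runner_id, day = day, lap = lap,
                lap_time_s = lap_time_s)
  dup <- tbl |> dplyr::count(.data$runner_id, .data$day, .data$lap) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (runner, day, lap) entries, e.g. runner %s day %d lap %d.",
                  dup$runner_id[1], dup$day[1], dup$lap[1]))
  }

  n_laps <- course$n_laps
  keep <- tbl |>
    dplyr::group_by(.data$runner_id, .data$day) |>
    dplyr::filter(dplyr::n() == n_laps && setequal(.data$lap, seq_len(n_laps))) |>
    dplyr::ungroup()
  dropped <- dplyr::anti_join(
    dplyr::distinct(tbl, .data$runner_id, .data$day),
    dplyr::distinct(keep, .data$runner_id, .data$day),
    by = c("runner_id", "day")
  )
  if (nrow(dropped) > 0) {
    warn(sprintf(
      "Dropped %d runner-day(s) without contiguous laps 1..%d: %s.",
      nrow(dropped), n_laps,
      paste(sprintf("%s/day %d", dropped$runner_id, dropped$day), collapse = "; ")
    ))
  }

  keep <- dplyr::arrange(keep, .data$runner_id, .data$day, .data$lap)
  new_cohort(keep, course)
}

#' Write a cohort back to the split-table CSV dialect
#'
#' @param cohort A cohort tibble as returned by [read_split_table()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_table <- function(cohort, path) {
  readr::write_csv(
    dplyr::select(cohort, "runner_id", "day", "lap", "lap_time_s"),
    path
  )
  invisible(path)
}

new_cohort <- function(tbl, course) {
  out <- as_tibble(tbl)
  attr(out, "course") <- course
  out
}

#' Retrieve the course attached to a cohort
#'
#' @param cohort A cohort tibble.
#' @param default Course to fall back on when none is attached.
#' @return A `race_course`.
#' @export
cohort_course <- function(cohort, default = race_course()) {
  attr(cohort, "course") %||% default
}

#' Identify runners present on every race day
#'
#' Evaluation statistics (reliability, validity, sensitivity) use only
#' runners who completed all days; this extracts their ids.
#'
#' @param cohort A cohort tibble.
#' @return Character vector of complete runner ids, sorted.
#' @export
complete_runners <- function(cohort) {
  days <- sort(unique(cohort$day))
  per <- cohort |>
    dplyr::distinct(.data$runner_id, .data$day) |>
    dplyr::count(.data$runner_id)
  sort(per$runner_id[per$n == length(days)])
}
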