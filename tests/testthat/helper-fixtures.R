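# Shared fixtures: tiny toy courses and generators of random race records.

toy_course <- function(d = 1000, n = 3) race_course(total_distance = d * n, n_laps = n)

# lap times that realize the given lap speeds on a course
times_for_speeds <- function(speeds, course) course$lap_distance / speeds

# a random positive record: lognormal lap times around ~8 min
random_lap_times <- function(course = race_course()) {
  exp(rnorm(course$n_laps, mean = log(470), sd = 0.08))
}

# long-format cohort tibble from a named list day -> list(runner -> lap_times)
cohort_from_times <- function(times_by_runner_day, course) {
  rows <- list()
  for (rd in times_by_runner_day) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      runner_id = rd$runner_id, day = rd$day,
      lap = seq_along(rd$lap_times), lap_time_s = rd$lap_times
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "course") <- course
  out
}

# brute-force two-way (subjects x days) sum-of-squares decomposition,
# independent of rm_anova()
brute_force_ss <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  ssr <- k * sum((rowMeans(m) - g)^2)
  ssc <- n * sum((colMeans(m) - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  list(ssr = ssr, ssc = ssc, sse = sse, sst = sst,
       ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
       ms_error = sse / ((n - 1) * (k - 1)))
}
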