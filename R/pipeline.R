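#' Run the full pacing analysis pipeline
#'
#' Reads a split-time CSV (or generates a synthetic cohort), computes
#' the per-race pacing variables, classifies pacing profiles and their
#' day-to-day consistency, and — when at least two days are present —
#' the reliability report, validity and sensitivity correlations and the
#' performance-group comparisons. All results are written as plain CSV
#' (plus a text consistency summary and a JSON run log) into `out_dir`,
#' and returned invisibly as a list. Reruns with the same inputs and
#' seed are byte-identical.
#'
#' @param input Path to a split-time CSV (see [read_split_table()]), or
#'   `NULL` to generate a synthetic cohort.
#' @param synthetic_cfg A [synthetic_config()] used when `input` is
#'   `NULL`.
#' @param out_dir Output directory; created if needed.
#' @param course A [race_course()].
#' @param sign_convention Passed to [pacing_variables()].
#' @param icc_form Passed to [reliability_report()].
#' @param binning,boundaries Passed to [bin_performance_groups()].
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with elements `cohort`, `metrics`,
#'   `profiles`, `consistency`, `reliability`, `validity`,
#'   `sensitivity`, `groups`, `group_comparison`, `run_log`.
#' @export
run_pipeline <- function(input = NULL,
                         synthetic_cfg = synthetic_config(),
                         out_dir = "pacemetrics-report",
                         course = race_course(),
                         sign_convention = "slowdown-positive",
                         icc_form = "3,1",
                         binning = "boundaries",
                         boundaries = c(14477, 16628),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  if (!is.null(input)) {
    cohort <- read_split_table(input, course)
  } else {
    course <- synthetic_cfg$course
    cohort <- generate_cohort(synthetic_cfg)$cohort
    say("Generated synthetic cohort: %d runners x %d days (seed %d).",
        synthetic_cfg$n_runners, synthetic_cfg$n_days, synthetic_cfg$seed)
  }
  if (nrow(cohort) == 0) abort("Empty cohort: nothing to analyse.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  keep <- complete_runners(cohort)
  cohort_c <- dplyr::filter(cohort, .data$runner_id %in% keep)
  cohort_c <- new_cohort(cohort_c, course)
  n_days <- length(unique(cohort_c$day))

  metrics <- pacing_variables(cohort_c, course, sign_convention)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))

  profiles <- pacing_profiles(cohort_c, course)
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))

  consistency <- NULL
  reliability <- NULL
  validity <- NULL
  sensitivity <- NULL
  groups <- NULL
  comparison <- NULL
  notices <- character()

  if (n_days >= 2) {
    consistency <- profile_consistency(profiles)
    z_anova <- rm_anova_profiles(profiles)
    cons_lines <- c(
      sprintf("Complete runners: %d over %d days", length(keep), n_days),
      sprintf("Same profile label on all days: %.1f%%",
              100 * consistency$summary$frac_all_days),
      sprintf("Same profile label on all but one day: %.1f%%",
              100 * consistency$summary$frac_all_but_one),
      sprintf("RM-ANOVA on Fisher-Z coefficients: F(%d, %d) = %.3f, p = %.3f",
              z_anova$df1, z_anova$df2, z_anova$f, z_anova$p)
    )
    writeLines(cons_lines, file.path(out_dir, "consistency.txt"))
    consistency$z_anova <- z_anova

    reliability <- reliability_report(metrics, icc_form = icc_form)
    readr::write_csv(reliability, file.path(out_dir, "reliability.csv"))

    validity <- validity_table(metrics)
    readr::write_csv(validity, file.path(out_dir, "validity.csv"))

    sensitivity <- sensitivity_correlations(metrics)
    readr::write_csv(sensitivity, file.path(out_dir, "sensitivity.csv"))

    groups <- bin_performance_groups(metrics, method = binning,
                                     boundaries = boundaries,
                                     course = course)
    enough <- all(table(groups$group) >= 2) && nlevels(droplevels(groups$group)) >= 2
    if (enough) {
      comparison <- group_comparison_table(metrics, groups)
      readr::write_csv(comparison, file.path(out_dir, "group_comparison.csv"))
    } else {
      notices <- c(notices,
                   "Group comparison skipped: need >= 2 groups with >= 2 runners.")
    }
  } else {
    notices <- c(notices,
                 "Reliability/validity/sensitivity skipped: need >= 2 days.")
    writeLines("Single-day cohort: day-to-day analyses not applicable.",
               file.path(out_dir, "consistency.txt"))
  }
  for (msg in notices) say("%s", msg)

  run_log <- list(
    package_version = as.character(utils::packageVersion("pacemetrics")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input = if (is.null(input)) "synthetic" else input,
    seed = if (is.null(input)) synthetic_cfg$seed else NA,
    synthetic_config = if (is.null(input)) {
      c(unclass(synthetic_cfg)[setdiff(names(synthetic_cfg), "course")],
        list(course = unclass(synthetic_cfg$course)))
    } else NULL,
    course = unclass(course),
    sign_convention = sign_convention,
    icc_form = icc_form,
    binning = binning,
    boundaries = boundaries,
    n_complete_runners = length(keep),
    n_days = n_days,
    notices = notices
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(
    cohort = cohort_c, metrics = metrics, profiles = profiles,
    consistency = consistency, reliability = reliability,
    validity = validity, sensitivity = sensitivity, groups = groups,
    group_comparison = comparison, run_log = run_log
  ))
}
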