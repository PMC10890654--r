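#' Configuration for the synthetic multi-stage cohort generator
#'
#' The defaults emulate the study conditions of a 20-runner, 4-day
#' loop-course marathon cohort: mean race speed about 2.72 +/- 0.32 m/s,
#' within-race lap-speed CV around 6-7%, predominantly positive
#' (slowing) pacing profiles that are stable for a runner across days,
#' small day-to-day effects, more lap-to-lap noise in slower runners,
#' and a modest end spurt.
#'
#' @param n_runners Number of runners (default 20).
#' @param n_days Number of race days (default 4).
#' @param course A [race_course()] (default 33 laps of 42195 m total).
#' @param base_speed_mean,base_speed_sd Mean and sd (m/s) of the
#'   per-runner base speed, drawn once per runner and truncated above
#'   1.0 m/s. Defaults 2.72 and 0.32.
#' @param day_effect_sd SD of the multiplicative day effect (proportion
#'   of base speed), drawn per runner-day. Default 0.01.
#' @param drift_mean,drift_sd Mean and sd of the per-runner linear
#'   speed drift over the race, expressed as the proportional speed
#'   change from start to finish; negative means slowing. Drawn once per
#'   runner and held constant across days (stable individual profiles).
#'   Defaults -0.10 and 0.04.
#' @param lap_noise_cv Lap-to-lap multiplicative noise CV (proportion)
#'   at the cohort mean base speed. Default 0.055.
#' @param speed_noise_coupling Exponent >= 0 coupling noise to slowness:
#'   a runner with base speed `B` gets noise sd
#'   `lap_noise_cv * (base_speed_mean / B)^speed_noise_coupling`, so
#'   slower runners are noisier. 0 switches the coupling off. Default 1.5.
#' @param end_spurt_boost Proportional speed boost over the final laps
#'   (default 0.03).
#' @param end_spurt_laps Number of final laps receiving the boost
#'   (default 2).
#' @param drift_constant_across_days If `FALSE`, the drift is redrawn
#'   every day (null model for profile-consistency testing). Default
#'   `TRUE`.
#' @param seed Integer seed; the same (config, seed) always reproduces
#'   the identical cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_runners = 20L,
                             n_days = 4L,
                             course = race_course(),
                             base_speed_mean = 2.72,
                             base_speed_sd = 0.32,
                             day_effect_sd = 0.01,
                             drift_mean = -0.10,
                             drift_sd = 0.04,
                             lap_noise_cv = 0.055,
                             speed_noise_coupling = 1.5,
                             end_spurt_boost = 0.03,
                             end_spurt_laps = 2L,
                             drift_constant_across_days = TRUE,
                             seed = 1L) {
  stopifnot(
    n_runners >= 1, n_days >= 1, inherits(course, "race_course"),
    course$n_laps >= 3, base_speed_mean > 0, base_speed_sd >= 0,
    day_effect_sd >= 0, drift_sd >= 0, lap_noise_cv >= 0,
    speed_noise_coupling >= 0, end_spurt_boost >= 0,
    end_spurt_laps >= 0, end_spurt_laps <= course$n_laps
  )
  structure(
    list(
      n_runners = as.integer(n_runners), n_days = as.integer(n_days),
      course = course, base_speed_mean = base_speed_mean,
      base_speed_sd = base_speed_sd, day_effect_sd = day_effect_sd,
      drift_mean = drift_mean, drift_sd = drift_sd,
      lap_noise_cv = lap_noise_cv,
      speed_noise_coupling = speed_noise_coupling,
      end_spurt_boost = end_spurt_boost,
      end_spurt_laps = as.integer(end_spurt_laps),
      drift_constant_across_days = isTRUE(drift_constant_across_days),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic multi-stage cohort
#'
#' Lap speeds follow
#' `v = B_r * (1 + delta_rd) * (1 + s_r * (k - (L+1)/2) / L) *
#' (1 + eps_rdk) * spurt_k`
#' where `B_r` is the runner's base speed (normal, truncated above
#' 1 m/s), `delta_rd` a per-day effect, `s_r` the runner's linear drift
#' (constant across days by default), `eps_rdk` lap noise whose sd
#' grows for slower runners when `speed_noise_coupling > 0`, and
#' `spurt_k` multiplies the last `end_spurt_laps` laps by
#' `1 + end_spurt_boost`. Lap times are `lap_distance / v`. Any sampled
#' non-positive speed is redrawn (bounded retries).
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (long tibble: `runner_id`, `day`, `lap`,
#'   `lap_time_s`, course attached) and `truth` (list with `runners` —
#'   per-runner base speed, drift, noise sd and first-order expected
#'   within-race CV — and `day_effects`).
#' @examples
#' out <- generate_cohort(synthetic_config(n_runners = 3, seed = 42))
#' head(out$cohort)
#' out$truth$runners
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  L <- cfg$course$n_laps
  ids <- sprintf("R%02d", seq_len(cfg$n_runners))
  set.seed(cfg$seed)

  base <- vapply(seq_len(cfg$n_runners), function(i) {
    for (try in 1:100) {
      b <- rnorm(1, cfg$base_speed_mean, cfg$base_speed_sd)
      if (b > 1.0) return(b)
    }
    abort("Could not draw a base speed > 1 m/s in 100 tries.")
  }, numeric(1))

  drift <- if (cfg$drift_constant_across_days) {
    matrix(rnorm(cfg$n_runners, cfg$drift_mean, cfg$drift_sd),
           nrow = cfg$n_runners, ncol = cfg$n_days)
  } else {
    matrix(rnorm(cfg$n_runners * cfg$n_days, cfg$drift_mean, cfg$drift_sd),
           nrow = cfg$n_runners, ncol = cfg$n_days)
  }

  day_eff <- matrix(rnorm(cfg$n_runners * cfg$n_days, 0, cfg$day_effect_sd),
                    nrow = cfg$n_runners, ncol = cfg$n_days)

  sigma <- cfg$lap_noise_cv *
    (cfg$base_speed_mean / base)^cfg$speed_noise_coupling

  spurt <- rep(1, L)
  if (cfg$end_spurt_laps > 0) {
    spurt[(L - cfg$end_spurt_laps + 1):L] <- 1 + cfg$end_spurt_boost
  }
  centred_k <- (seq_len(L) - (L + 1) / 2) / L

  rows <- vector("list", cfg$n_runners * cfg$n_days)
  idx <- 1L
  for (r in seq_len(cfg$n_runners)) {
    for (d in seq_len(cfg$n_days)) {
      shape <- base[r] * (1 + day_eff[r, d]) * (1 + drift[r, d] * centred_k) *
        spurt
      eps <- rnorm(L, 0, sigma[r])
      v <- shape * (1 + eps)
      for (try in 1:100) {
        bad <- which(v <= 0)
        if (length(bad) == 0) break
        v[bad] <- shape[bad] * (1 + rnorm(length(bad), 0, sigma[r]))
      }
      if (any(v <= 0)) abort("Could not draw positive lap speeds.")
      rows[[idx]] <- tibble(
        runner_id = ids[r], day = d, lap = seq_len(L),
        lap_time_s = cfg$course$lap_distance / v
      )
      idx <- idx + 1L
    }
  }

  drift_day1 <- drift[, 1]
  truth_runners <- tibble(
    runner_id = ids,
    base_speed = base,
    drift = drift_day1,
    noise_sd = sigma,
    expected_cv = 100 * sqrt(sigma^2 + drift_day1^2 * var_centred_lap(L))
  )
  truth_days <- tibble(
    runner_id = rep(ids, times = cfg$n_days),
    day = rep(seq_len(cfg$n_days), each = cfg$n_runners),
    day_effect = as.vector(day_eff),
    drift = as.vector(drift)
  )

  list(
    cohort = new_cohort(dplyr::bind_rows(rows), cfg$course),
    truth = list(runners = truth_runners, day_effects = truth_days,
                 config = cfg)
  )
}

# population variance of the centred, scaled lap index (k - (L+1)/2)/L
var_centred_lap <- function(L) {
  (L^2 - 1) / (12 * L^2)
}

#' First-order expected within-race CV of a generator configuration
#'
#' Approximates the lap-speed CV a generated race will show, combining
#' the lap-noise CV with the spread induced by the mean linear drift:
#' `100 * sqrt(lap_noise_cv^2 + drift_mean^2 * Var((k - (L+1)/2)/L))`.
#' It ignores the end spurt, the slow-runner noise coupling and the
#' time-weighting of the reference speed, so it is a planning
#' approximation, not an exact moment.
#'
#' @param config A [synthetic_config()].
#' @return Expected within-race CV, percent.
#' @export
expected_within_race_cv <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  100 * sqrt(config$lap_noise_cv^2 +
               config$drift_mean^2 * var_centred_lap(config$course$n_laps))
}

#' Predicted day-to-day ICC of mean race speed under the generator
#'
#' First-order variance-component prediction for the consistency ICC of
#' mean speed: between-runner variance is the base-speed variance;
#' within-runner day-to-day variance combines the day effect and the
#' averaging of lap noise over `L` laps, with a second-order correction
#' for the slow-runner noise coupling:
#' `ICC = sd_B^2 / (sd_B^2 + mu^2 day_sd^2 + mu^2 cv^2 kappa / L)` where
#' `kappa = 1 + c(2c + 1) (sd_B / mu)^2` approximates
#' `E[(mu/B)^(2c)]` for coupling exponent `c`.
#'
#' @param config A [synthetic_config()].
#' @return Predicted ICC in (0, 1).
#' @export
expected_ms_icc <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mu <- config$base_speed_mean
  c2 <- config$speed_noise_coupling
  kappa <- 1 + c2 * (2 * c2 + 1) * (config$base_speed_sd / mu)^2
  between <- config$base_speed_sd^2
  within <- mu^2 * config$day_effect_sd^2 +
    mu^2 * config$lap_noise_cv^2 * kappa / config$course$n_laps
  between / (between + within)
}
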