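test_that("pearson_correlation matches the brute-force formula", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    res <- pearson_correlation(x, y)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_brute, tolerance = 1e-12)
    tstat <- r_brute * sqrt((20 - 2) / (1 - r_brute^2))
    expect_equal(res$p_value, 2 * pt(abs(tstat), 18, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  perfect <- pearson_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("validity table correlates each variable with CV per day", {
  # construct a cohort where ACS is proportional to CV across runners by
  # scaling a single noise pattern per runner
  crs <- race_course()
  set.seed(77)
  pattern <- rnorm(33)
  pattern <- pattern - mean(pattern)
  recs <- list()
  for (r in 1:8) {
    for (d in 1:2) {
      v <- 3 * (1 + 0.01 * r * pattern)
      recs[[paste(r, d)]] <- list(runner_id = sprintf("R%02d", r), day = d,
                                  lap_times = crs$lap_distance / v)
    }
  }
  pv <- pacing_variables(cohort_from_times(recs, crs))
  vt <- validity_table(pv)
  expect_setequal(unique(vt$variable),
                  c("cs", "csf", "acs", "pr", "mrs", "split_32_10"))
  expect_equal(nrow(vt), 6 * 2)
  acs_rows <- vt[vt$variable == "acs", ]
  expect_equal(acs_rows$r, rep(1, 2), tolerance = 1e-4)
  expect_equal(unique(acs_rows$interpretation), "large")
})

test_that("synthetic cohorts show large ACS/PR validity against CV", {
  pv <- pacing_variables(generate_cohort(synthetic_config(seed = 19))$cohort)
  vt <- validity_table(pv)
  strong <- vt[vt$variable %in% c("acs", "pr"), ]
  expect_true(all(strong$r > 0.5))
})

test_that("sensitivity correlations are null without noise-speed coupling", {
  cfg0 <- synthetic_config(speed_noise_coupling = 0, seed = 2)
  pv0 <- pacing_variables(generate_cohort(cfg0)$cohort)
  s0 <- sensitivity_correlations(pv0)
  expect_setequal(unique(s0$variable), c("cv", "acs", "pr"))
  expect_true(all(abs(s0$r) < 0.6)) # no systematic coupling
  cfg1 <- synthetic_config(seed = 2)
  s1 <- sensitivity_correlations(pacing_variables(generate_cohort(cfg1)$cohort))
  expect_true(all(s1$r[s1$variable == "cv"] < 0))
})

test_that("performance binning by boundaries and tertiles", {
  # a runner with mean marathon time 3:46:24 (13584 s) is Fast under the
  # default boundaries 4:01:17 / 4:37:08
  crs <- race_course()
  mk <- function(id, total_s) {
    lapply(1:2, function(d) list(runner_id = id, day = d,
                                 lap_times = rep(total_s / 33, 33)))
  }
  recs <- c(mk("fast", 13584), mk("mid", 15469), mk("slow", 17945))
  pv <- pacing_variables(cohort_from_times(recs, crs))
  g <- bin_performance_groups(pv, method = "boundaries")
  expect_equal(as.character(g$group[g$runner_id == "fast"]), "Fast")
  expect_equal(as.character(g$group[g$runner_id == "mid"]), "Medium")
  expect_equal(as.character(g$group[g$runner_id == "slow"]), "Slow")
  expect_equal(g$mean_time_s[g$runner_id == "fast"], 13584, tolerance = 1e-6)

  # tertiles: 3 runners -> one per group; 20 runners -> sizes 7, 7, 6
  g3 <- bin_performance_groups(pv, method = "tertile")
  expect_equal(as.vector(table(g3$group)), c(1, 1, 1))
  pv20 <- pacing_variables(generate_cohort(synthetic_config(seed = 4))$cohort)
  g20 <- bin_performance_groups(pv20, method = "tertile")
  expect_equal(as.vector(table(g20$group)), c(7, 7, 6))
  # groups are monotone in mean time
  expect_true(all(diff(as.integer(g20$group[order(g20$mean_time_s)])) >= 0))
})

test_that("one-way ANOVA with LSD matches hand decomposition and stats::aov", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("Fast", "Medium", "Slow"), each = 2)
  a <- oneway_anova_lsd(vals, grp)
  # hand oracle: group means 1.5/3.5/5.5, grand 3.5
  # SSB = 2*4 + 0 + 2*4 = 16, SSW = 1.5, MSW = 0.5 -> F = 8/0.5 = 16
  expect_equal(a$f, 16)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 3)
  expect_equal(a$eta_squared, 16 / 17.5)
  ref <- summary(aov(vals ~ factor(grp)))[[1]]
  expect_equal(a$f, ref[["F value"]][1])
  expect_equal(a$p, ref[["Pr(>F)"]][1])
  # eta^2 + SSW/SST = 1 exactly
  expect_equal(a$eta_squared + 1.5 / 17.5, 1)

  # LSD p-values equal unadjusted pooled-sd pairwise t-tests
  ptt <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  expect_equal(a$pairwise$p_value[a$pairwise$group1 == "Fast" &
                                    a$pairwise$group2 == "Medium"],
               ptt["Medium", "Fast"])
  expect_equal(a$pairwise$p_value[a$pairwise$group1 == "Medium" &
                                    a$pairwise$group2 == "Slow"],
               ptt["Slow", "Medium"])
})

test_that("two-group LSD p equals the two-group ANOVA p", {
  set.seed(41)
  vals <- c(rnorm(6, 0), rnorm(5, 1))
  grp <- rep(c("A", "B"), c(6, 5))
  a <- oneway_anova_lsd(vals, grp)
  expect_equal(a$pairwise$p_value, a$p, tolerance = 1e-12)
})

test_that("identical group means give F ~ 0 and eta^2 ~ 0", {
  vals <- c(1, 3, 1, 3, 1, 3)
  grp <- rep(c("A", "B", "C"), each = 2)
  a <- oneway_anova_lsd(vals, grp)
  expect_equal(a$f, 0)
  expect_equal(a$eta_squared, 0)
  expect_error(oneway_anova_lsd(1:5, c("A", "A", "B", "B", "C")),
               ">= 2 members")
})

test_that("group comparison table stacks per-day ANOVAs", {
  pv <- pacing_variables(generate_cohort(synthetic_config(seed = 6))$cohort)
  g <- bin_performance_groups(pv, method = "tertile")
  gc <- group_comparison_table(pv, g)
  expect_equal(nrow(gc), 3 * 4)
  expect_true(all(gc$eta_squared >= 0 & gc$eta_squared <= 1))
  expect_true(all(c("mean_fast", "mean_medium", "mean_slow",
                    "p_fast_vs_medium", "p_fast_vs_slow",
                    "p_medium_vs_slow") %in% names(gc)))
  # slower tertile shows more variability on average (coupling on)
  cv_rows <- gc[gc$variable == "cv", ]
  expect_gt(mean(cv_rows$mean_slow), mean(cv_rows$mean_fast))
})
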