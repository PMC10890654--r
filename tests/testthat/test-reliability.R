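m32 <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3) # subjects x days

test_that("rm_anova reproduces the hand sum-of-squares decomposition", {
  a <- rm_anova(m32)
  # hand oracle: SST 16 = SSR 9 + SSC 6 + SSE 1
  expect_equal(a$ss_rows, 9)
  expect_equal(a$ss_cols, 6)
  expect_equal(a$ss_error, 1)
  expect_equal(a$ms_rows, 4.5)
  expect_equal(a$ms_cols, 6)
  expect_equal(a$ms_error, 0.5)
  expect_equal(a$f, 12)
  expect_equal(a$df1, 1)
  expect_equal(a$df2, 2)
  expect_equal(a$p, pf(12, 1, 2, lower.tail = FALSE))
})

test_that("rm_anova matches a brute-force oracle on random matrices", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:10, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k, 10, 3), n, k)
    a <- rm_anova(m)
    b <- brute_force_ss(m)
    expect_equal(a$ss_rows, b$ssr, tolerance = 1e-9)
    expect_equal(a$ss_cols, b$ssc, tolerance = 1e-9)
    expect_equal(a$ss_error, b$sse, tolerance = 1e-9)
    # sum-of-squares identity
    expect_equal(b$ssr + b$ssc + b$sse, b$sst, tolerance = 1e-9)
    expect_equal(a$f, b$ms_cols / b$ms_error, tolerance = 1e-9)
  }
})

test_that("rm_anova handles degenerate matrices per contract", {
  # identical columns, rows varying: F = 0, p = 1
  m <- matrix(rep(c(1, 2, 3), 2), nrow = 3)
  a <- rm_anova(m)
  expect_equal(a$f, 0)
  expect_equal(a$p, 1)
  # pure column shift with no error: F infinite with warning
  m2 <- cbind(c(1, 2, 3), c(2, 3, 4))
  expect_warning(a2 <- rm_anova(m2), "infinite")
  expect_equal(a2$f, Inf)
  expect_equal(a2$p, 0)
  expect_error(rm_anova(matrix(1, 1, 2)), "at least 2")
})

test_that("ICC(3,1) matches the closed form and its published example shape", {
  ic <- icc_reliability(m32)
  expect_equal(ic$icc, 0.8) # (4.5 - 0.5)/(4.5 + 0.5)
  expect_lte(ic$ci_low, ic$icc)
  expect_gte(ic$ci_high, ic$icc)
  # perfect repeatability: identical columns, subjects differ
  m <- matrix(rep(c(1, 2, 3), 2), nrow = 3)
  expect_equal(icc_reliability(m)$icc, 1)
})

test_that("consistency ICC is invariant to column shifts and scaling", {
  set.seed(17)
  m <- matrix(rnorm(10, 5, 2), 10, 4) + matrix(rnorm(40, 0, 0.5), 10, 4)
  base <- icc_reliability(m)$icc
  shifted <- sweep(m, 2, c(0, 1.3, -0.4, 2), "+")
  expect_equal(icc_reliability(shifted)$icc, base, tolerance = 1e-9)
  expect_equal(icc_reliability(3.7 * m)$icc, base, tolerance = 1e-9)
  # ICC(2,1) penalizes the day shifts instead
  expect_lt(icc_reliability(shifted, form = "2,1")$icc, base)
})

test_that("ICC estimates recover known variance components", {
  # subject + noise model: true ICC = var_s / (var_s + var_e)
  set.seed(23)
  n <- 200; k <- 4
  var_s <- 4; var_e <- 1
  m <- matrix(rnorm(n, 0, sqrt(var_s)), n, k) + matrix(rnorm(n * k, 0, sqrt(var_e)), n, k)
  est <- icc_reliability(m)$icc
  expect_equal(est, var_s / (var_s + var_e), tolerance = 0.05)
})

test_that("SEM follows pooled_sd * sqrt(1 - ICC)", {
  set.seed(3)
  m <- matrix(rnorm(40, 10, 2), 10, 4)
  centred <- sweep(m, 2, colMeans(m)) + mean(m)
  expect_equal(sem_measure(m, 1), 0)
  expect_equal(sem_measure(m, 0), sd(as.vector(centred)))
  expect_equal(sem_measure(m, 0.92), sd(as.vector(centred)) * sqrt(0.08))
  # magnitude check: pooled sd 0.35 at ICC 0.92 gives SEM ~ 0.099
  expect_equal(0.35 * sqrt(1 - 0.92), 0.099, tolerance = 1e-3)
})

test_that("typical-error CV% uses the log path and falls back to raw", {
  # identical columns: no within-subject error at all
  m <- matrix(rep(c(2, 3, 4), 2), nrow = 3)
  te <- typical_error_cv(m)
  expect_equal(te$cv_percent, 0)
  expect_equal(te$transform_used, "log")
  # a pure multiplicative day shift is absorbed by the day effect
  set.seed(29)
  day1 <- runif(10, 2, 3)
  # the zero-error day shift also trips the infinite-F warning downstream
  expect_warning(te2 <- typical_error_cv(cbind(day1, day1 * 1.05)),
                 "infinite")
  expect_equal(te2$cv_percent, 0, tolerance = 1e-10)
  # any non-positive value forces the raw path
  m3 <- matrix(c(1, 2, -3, 2, 3, 4), nrow = 3)
  expect_equal(typical_error_cv(m3)$transform_used, "raw")
  # back-transform formula: s log-units -> 100*(exp(s/100)-1)
  set.seed(31)
  m4 <- matrix(exp(rnorm(40, 1, 0.2)), 10, 4)
  a <- rm_anova(100 * log(m4))
  expect_equal(typical_error_cv(m4)$cv_percent,
               100 * (expm1(sqrt(a$ms_error) / 100)))
})

test_that("reliability_report summarizes each variable on its own row", {
  cfg <- synthetic_config(seed = 8)
  pv <- pacing_variables(generate_cohort(cfg)$cohort)
  rel <- reliability_report(pv)
  expect_equal(rel$variable,
               c("ms", "cv", "cs", "csf", "acs", "pr", "mrs", "split_32_10"))
  expect_true(all(rel$icc_ci_low <= rel$icc & rel$icc <= rel$icc_ci_high,
                  na.rm = TRUE))
  expect_true(all(rel$sem >= 0, na.rm = TRUE))
  expect_true(all(rel$p_value >= 0 & rel$p_value <= 1, na.rm = TRUE))
  expect_true(all(rel$cv_percent >= 0, na.rm = TRUE))
  # per-day mean/sd are on the original scale
  ms_mat <- variable_matrix(pv, "ms")
  expect_equal(rel$day1_mean[rel$variable == "ms"],
               mean(ms_mat[, "1"]), ignore_attr = TRUE)
  expect_equal(rel$day3_sd[rel$variable == "ms"], sd(ms_mat[, "3"]),
               ignore_attr = TRUE)
  # stationary generator: no day effect should be detected for MS
  expect_gt(rel$p_value[rel$variable == "ms"], 0.05)
})

test_that("zero-variance variables are flagged, not silently reported", {
  crs <- race_course()
  tt <- rep(480, 33)
  recs <- list()
  for (r in c("A", "B", "C")) {
    for (d in 1:2) {
      # distinct constant speeds per runner, identical across days
      f <- match(r, c("A", "B", "C"))
      recs[[paste(r, d)]] <- list(runner_id = r, day = d, lap_times = tt * f)
    }
  }
  pv <- pacing_variables(cohort_from_times(recs, crs))
  rel <- reliability_report(pv)
  # all pacing variables are identically zero -> degenerate
  expect_true(all(rel$degenerate[rel$variable != "ms"]))
  expect_false(rel$degenerate[rel$variable == "ms"])
  expect_equal(rel$icc[rel$variable == "ms"], 1)
})
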