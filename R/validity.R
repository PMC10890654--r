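#' Pearson correlation with two-sided p-value
#'
#' Thin tidy wrapper around [stats::cor.test()]; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return One-row tibble: `r`, `p_value`, `n`, `interpretation`
#'   (small < 0.30 <= moderate < 0.50 <= large, on `|r|`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Pearson correlation undefined: zero variance input.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  tibble(r = r, p_value = ct$p.value, n = length(x),
         interpretation = correlation_band(r))
}

correlation_band <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.5, "large",
         ifelse(a >= 0.3, "moderate",
                ifelse(a >= 0.1, "small", "trivial")))
}

#' Concurrent validity: pacing variables against the CV gold standard
#'
#' For each day, correlates each pacing variable (CS, CSF, ACS, PR, MRS,
#' 32-10) across runners with the coefficient of variation, the accepted
#' reference measure of variability.
#'
#' @inheritParams reliability_report
#' @return Tibble: `variable`, `day`, `r`, `p_value`, `n`,
#'   `interpretation`.
#' @export
validity_table <- function(vars_tbl) {
  vars <- intersect(c("cs", "csf", "acs", "pr", "mrs", "split_32_10"),
                    names(vars_tbl))
  correlate_by_day(vars_tbl, vars, reference = "cv")
}

#' Sensitivity: pacing variables against mean race speed
#'
#' For each day, correlates each retained pacing variable across runners
#' with the day's mean race speed. By default only the variables with
#' acceptable reliability (CV, ACS, PR) enter; the poorly reliable
#' split-based variables can be added back via `variables`.
#'
#' @inheritParams reliability_report
#' @param variables Variables to correlate with `ms`; default
#'   `c("cv", "acs", "pr")`.
#' @return Tibble: `variable`, `day`, `r`, `p_value`, `n`,
#'   `interpretation`.
#' @export
sensitivity_correlations <- function(vars_tbl,
                                     variables = c("cv", "acs", "pr")) {
  correlate_by_day(vars_tbl, intersect(variables, names(vars_tbl)),
                   reference = "ms")
}

correlate_by_day <- function(vars_tbl, variables, reference) {
  days <- sort(unique(vars_tbl$day))
  purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(days, function(d) {
      sub <- dplyr::filter(vars_tbl, .data$day == d)
      dplyr::bind_cols(
        tibble(variable = v, day = d),
        pearson_correlation(sub[[v]], sub[[reference]])
      )
    })
  })
}

#' Bin runners into Fast / Medium / Slow performance groups
#'
#' Grouping is by each runner's mean marathon time over all days. The
#' default method cuts at explicit time boundaries (4:01:17 and 4:37:08,
#' the printed ranges separating the three groups in the motivating
#' multi-stage race); a boundary time goes to the faster group. The
#' `"tertile"` method instead ranks runners by mean time and splits them
#' as evenly as possible (extra runners go to the faster groups; ties
#' broken by runner id).
#'
#' @inheritParams reliability_report
#' @param method `"boundaries"` (default) or `"tertile"`.
#' @param boundaries Two increasing cut times in seconds (used by the
#'   boundary method). Defaults to `c(14477, 16628)`, i.e. 4:01:17 and
#'   4:37:08.
#' @param course A [race_course()] used to convert mean speed back to
#'   marathon time.
#' @return Tibble: `runner_id`, `mean_time_s`, `group` (factor Fast <
#'   Medium < Slow).
#' @export
bin_performance_groups <- function(vars_tbl,
                                   method = c("boundaries", "tertile"),
                                   boundaries = c(14477, 16628),
                                   course = race_course()) {
  method <- match.arg(method)
  mean_times <- vars_tbl |>
    dplyr::group_by(.data$runner_id) |>
    dplyr::summarise(mean_time_s = mean(course$total_distance / .data$ms),
                     .groups = "drop") |>
    dplyr::arrange(.data$mean_time_s, .data$runner_id)
  n <- nrow(mean_times)
  if (n < 3) abort("Need at least 3 runners to form 3 groups.")
  if (method == "boundaries") {
    if (length(boundaries) != 2 || diff(boundaries) <= 0) {
      abort("`boundaries` must be two increasing times in seconds.")
    }
    grp <- ifelse(mean_times$mean_time_s <= boundaries[1], "Fast",
                  ifelse(mean_times$mean_time_s <= boundaries[2],
                         "Medium", "Slow"))
  } else {
    base <- n %/% 3
    sizes <- base + (seq_len(3) <= n %% 3)
    grp <- rep(c("Fast", "Medium", "Slow"), times = sizes)
  }
  mean_times$group <- factor(grp, levels = c("Fast", "Medium", "Slow"))
  mean_times
}

#' One-way ANOVA across performance groups with LSD post-hoc tests
#'
#' Between-group one-way ANOVA (via [stats::aov()]) of one value per
#' runner, with eta squared (`SS_between / SS_total`) as effect size and
#' Fisher's least-significant-difference post-hoc comparisons: pairwise
#' t statistics computed from the pooled within-group mean square on its
#' error df, p-values deliberately unadjusted (that is the LSD
#' procedure).
#'
#' @param values Numeric vector, one value per runner.
#' @param groups Factor (or vector) of group labels, same length; every
#'   group needs >= 2 members.
#' @return A `pacing_group_anova` object: list with `f`, `p`, `df1`,
#'   `df2`, `eta_squared`, `group_means` (tibble), `pairwise` (tibble:
#'   `group1`, `group2`, `diff`, `t`, `p_value`). Has [tidy()] and
#'   [glance()] methods.
#' @export
oneway_anova_lsd <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need >= 2 groups with >= 2 members each.")
  }
  d <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = d)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  df <- summary(fit)[[1]][["Df"]]
  ss_between <- ss[1]; ss_within <- ss[2]
  df1 <- df[1]; df2 <- df[2]
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  p <- pf(f, df1, df2, lower.tail = FALSE)
  eta2 <- ss_between / (ss_between + ss_within)

  means <- d |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     sd = sd(.data$y), .groups = "drop") |>
    dplyr::rename(group = "g")

  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    m1 <- means$mean[means$group == pr[1]]
    m2 <- means$mean[means$group == pr[2]]
    n1 <- means$n[means$group == pr[1]]
    n2 <- means$n[means$group == pr[2]]
    tstat <- (m1 - m2) / sqrt(mse * (1 / n1 + 1 / n2))
    tibble(group1 = pr[1], group2 = pr[2], diff = m1 - m2, t = tstat,
           p_value = 2 * pt(abs(tstat), df2, lower.tail = FALSE))
  })

  structure(
    list(f = f, p = p, df1 = df1, df2 = df2, eta_squared = eta2,
         group_means = means, pairwise = pairwise),
    class = "pacing_group_anova"
  )
}

#' @export
print.pacing_group_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, eta^2 = %.3f\n",
              x$df1, x$df2, x$f, x$p, x$eta_squared))
  cat("LSD pairwise comparisons:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' Per-day group comparison table for selected pacing variables
#'
#' Runs [oneway_anova_lsd()] for each (variable, day) cell and stacks
#' the results, mirroring the per-day group-difference analysis of the
#' sensitive variables.
#'
#' @inheritParams reliability_report
#' @param groups Group assignment tibble from [bin_performance_groups()].
#' @param variables Variables to compare across groups.
#' @return Tibble: `variable`, `day`, group means, `f`, `p`,
#'   `eta_squared`, and one LSD p-value column per group pair.
#' @export
group_comparison_table <- function(vars_tbl, groups,
                                   variables = c("cv", "acs", "pr")) {
  days <- sort(unique(vars_tbl$day))
  joined <- dplyr::inner_join(vars_tbl, groups[, c("runner_id", "group")],
                              by = "runner_id")
  purrr::map_dfr(intersect(variables, names(vars_tbl)), function(v) {
    purrr::map_dfr(days, function(d) {
      sub <- dplyr::filter(joined, .data$day == d)
      a <- oneway_anova_lsd(sub[[v]], sub$group)
      means <- setNames(a$group_means$mean,
                        paste0("mean_", tolower(a$group_means$group)))
      lsd <- setNames(
        a$pairwise$p_value,
        paste0("p_", tolower(a$pairwise$group1), "_vs_",
               tolower(a$pairwise$group2))
      )
      dplyr::bind_cols(
        tibble(variable = v, day = d),
        as_tibble(as.list(means)),
        tibble(f = a$f, p = a$p, eta_squared = a$eta_squared),
        as_tibble(as.list(lsd))
      )
    })
  })
}
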