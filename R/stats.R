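# Hypothesis tests and power analysis for group-level summaries: Student and
# Welch two-sample t (from summary statistics or raw data), Mann-Whitney U
# with exact enumeration, one-way ANOVA with exact F tails, Tukey-Kramer HSD,
# and two-sample power / sample-size calculations. All tests are implemented
# from their defining formulas; base R supplies only the distribution tails.

#' Group summary: mean, SEM, n
#'
#' The unit of all between-genotype statistics; figures report groups as
#' mean +/- SEM with n, and the implied sample SD is `sem * sqrt(n)`.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Group size (integer >= 2).
#' @param label Optional group label.
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' group_summary(9.8, 0.4, 18)
group_summary <- function(mean, sem, n, label = NA_character_) {
  check_number(mean, "mean")
  check_number(sem, "sem", lower = 0)
  n <- check_count(n, "n", lower = 2L)
  structure(list(mean = mean, sem = sem, n = n, sd = sem * sqrt(n),
                 label = label),
            class = "group_summary")
}

#' Summarize raw draws into a group summary
#'
#' @param x Numeric vector (n >= 2).
#' @param label Optional label.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x, label = NA_character_) {
  if (length(x) < 2L) abort("Need at least 2 observations.")
  group_summary(mean(x), sd(x) / sqrt(length(x)), length(x), label)
}

new_test_result <- function(statistic, df, p_value, method,
                            warning_flag = NA_character_, extra = list()) {
  structure(c(list(statistic = statistic, df = df,
                   p_value = min(max(p_value, 0), 1), method = method,
                   warning_flag = warning_flag), extra),
            class = "neurofret_test")
}

#' @export
print.neurofret_test <- function(x, ...) {
  cat(sprintf("<%s>\n  statistic = %.6g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p_value))
  if (!is.na(x$warning_flag)) cat("  warning:", x$warning_flag, "\n")
  invisible(x)
}

#' Tidy a test result
#'
#' @param x A `neurofret_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df1`, `df2`, `p_value`, `method`.
#' @method tidy neurofret_test
#' @export
tidy.neurofret_test <- function(x, ...) {
  tibble(statistic = x$statistic,
         df1 = x$df[1],
         df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value, method = x$method)
}

#' @method glance neurofret_test
#' @export
glance.neurofret_test <- function(x, ...) tidy(x, ...)

#' Two-sample t-test from summary statistics
#'
#' Student (pooled variance, df = n1 + n2 - 2) or Welch (Welch-Satterthwaite
#' df) two-sided t-test computed from (mean, SEM, n) triples, matching the
#' raw-data test exactly when the summaries are computed from the raw data.
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sem`, `n`).
#' @param variant `"student"` or `"welch"`.
#' @return A `neurofret_test`.
#' @export
#' @examples
#' ttest_summary(group_summary(9.8, 0.4, 18), group_summary(4.9, 0.3, 18))
ttest_summary <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(a); b <- as_group_summary(b)
  delta <- a$mean - b$mean
  va <- a$sem^2; vb <- b$sem^2  # squared SEMs = s_i^2 / n_i
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "Student two-sample t-test (summary statistics)"
  } else {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch two-sample t-test (summary statistics)"
  }
  if (se == 0) {
    if (delta == 0) return(new_test_result(0, df, 1, method))
    return(new_test_result(sign(delta) * Inf, df, 0, method,
                           "zero variance with unequal means"))
  }
  t <- delta / se
  new_test_result(t, df, 2 * pt(-abs(t), df), method)
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.list(x) && all(c("mean", "sem", "n") %in% names(x))) {
    return(group_summary(x$mean, x$sem, x$n,
                         if (!is.null(x$label)) x$label else NA_character_))
  }
  abort("Expected a group_summary or a list with mean, sem, n.")
}

#' Two-sample t-test on raw data
#'
#' Convenience wrapper: summarizes each sample and calls [ttest_summary()].
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param variant `"student"` or `"welch"`.
#' @return A `neurofret_test`.
#' @export
ttest_raw <- function(x, y, variant = c("student", "welch")) {
  ttest_summary(summarize_group(x), summarize_group(y), variant)
}

#' Mann-Whitney U test
#'
#' U counts pairs with `x > y` (ties count 1/2). For small samples
#' (`min(n) <= exact_limit` by default) the two-sided p-value is computed by
#' full enumeration of all group labelings of the pooled data,
#' `P(|U - n1 n2 / 2| >= |u - n1 n2 / 2|)`; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` decides by sample size.
#' @param exact_limit Largest `min(n)` for which enumeration is the default.
#' @return A `neurofret_test` (statistic = U for the first sample).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, exact = NULL, exact_limit = 8L) {
  if (length(x) < 1L || length(y) < 1L) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (length(unique(pool)) == 1L) {
    return(new_test_result(u_obs, NA_real_, 1, "Mann-Whitney U test",
                           "all observations tied"))
  }
  if (is.null(exact)) exact <- min(n1, n2) <= exact_limit
  if (exact) {
    combs <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact enumeration)"
    return(new_test_result(u_obs, NA_real_, p, method))
  }
  n <- n1 + n2
  ties <- table(pool)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu)
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity correction
  p <- 2 * pnorm(-abs(z))
  new_test_result(u_obs, NA_real_, p,
                  "Mann-Whitney U test (tie-corrected normal approximation)")
}

#' Upper-tail probability of the F distribution
#'
#' @param f Observed F statistic (>= 0).
#' @param d1,d2 Numerator and denominator degrees of freedom (> 0).
#' @return `P(F(d1, d2) >= f)`. For `d1 = 2` this equals the closed form
#'   `(d2 / (d2 + 2 f))^(d2 / 2)`.
#' @export
#' @examples
#' f_tail(44, 2, 55)
f_tail <- function(f, d1, d2) {
  check_number(f, "f", lower = 0)
  check_number(d1, "d1", lower = 0, strict_lower = TRUE)
  check_number(d2, "d2", lower = 0, strict_lower = TRUE)
  pf(f, d1, d2, lower.tail = FALSE)
}

coerce_groups <- function(groups, data, value, group) {
  if (!is.null(data)) {
    data <- as.data.frame(data)
    groups <- split(data[[value]], data[[group]])
  }
  if (!is.list(groups) || length(groups) < 2L) {
    abort("Need at least 2 groups (a list of numeric vectors, or data + column names).")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    abort("Every group needs at least 2 observations.")
  }
  groups
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with df `(k - 1, N - k)`; the p-value is the
#' exact F upper tail from [f_tail()].
#'
#' @param groups A named list of numeric samples; alternatively supply
#'   `data` with `value`/`group` column names.
#' @param data,value,group Optional data-frame interface.
#' @return A `neurofret_test` with `df = c(k - 1, N - k)`.
#' @export
oneway_anova <- function(groups = NULL, data = NULL, value = "value",
                         group = "group") {
  groups <- coerce_groups(groups, data, value, group)
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  means <- vapply(groups, mean, 1)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df <- c(k - 1, N - k)
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(new_test_result(0, df, 1, "one-way ANOVA"))
    }
    return(new_test_result(Inf, df, 0, "one-way ANOVA",
                           "zero within-group variance with unequal means"))
  }
  f <- (ss_between / df[1]) / (ss_within / df[2])
  new_test_result(f, df, f_tail(f, df[1], df[2]), "one-way ANOVA",
                  extra = list(ms_within = ss_within / df[2],
                               group_means = means, group_ns = ns))
}

#' Tukey HSD post hoc comparisons
#'
#' Studentized-range adjusted p-values for every group pair after a one-way
#' ANOVA, with the Tukey-Kramer standard error
#' `sqrt(MS_within / 2 * (1/n_i + 1/n_j))` for unbalanced groups.
#'
#' @inheritParams oneway_anova
#' @return A tibble with one row per pair: `group1`, `group2`, `diff`, `se`,
#'   `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups = NULL, data = NULL, value = "value",
                      group = "group") {
  groups <- coerce_groups(groups, data, value, group)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  an <- oneway_anova(groups)
  k <- length(groups)
  df2 <- an$df[2]
  if (df2 < 1) abort("Pooled within-group df must be >= 1.")
  if (is.null(an$ms_within)) {
    abort("Degenerate ANOVA (zero within-group variance); Tukey HSD undefined.")
  }
  pairs <- combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    d <- mean(groups[[g1]]) - mean(groups[[g2]])
    se <- sqrt(an$ms_within / 2 * (1 / length(groups[[g1]]) +
                                     1 / length(groups[[g2]])))
    q <- abs(d) / se
    tibble(group1 = g1, group2 = g2, diff = d, se = se, q = q,
           p_adj = ptukey(q, k, df2, lower.tail = FALSE))
  })
}

#' Power of the two-sample two-sided t-test
#'
#' Noncentral-t power at equal group size `n`, effect `effect` and common SD
#' `sd`.
#'
#' @param n Per-group sample size (>= 2).
#' @param effect True mean difference.
#' @param sd Common standard deviation (> 0).
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @export
power_two_groups <- function(n, effect, sd, alpha = 0.05) {
  n <- check_count(n, "n", lower = 2L)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  df <- 2 * n - 2
  ncp <- abs(effect) / sd * sqrt(n / 2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
}

#' Sample size for a two-sample comparison
#'
#' Smallest per-group `n` at which the two-sided two-sample t-test reaches
#' the requested power, from the normal-approximation closed form refined by
#' exact noncentral-t evaluation.
#'
#' @param effect True mean difference (non-zero).
#' @param sd Common standard deviation (> 0).
#' @param power Target power (default 0.90).
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @return Integer per-group sample size (>= 2).
#' @export
#' @examples
#' sample_size_two_groups(effect = 2, sd = 1)
sample_size_two_groups <- function(effect, sd, power = 0.90, alpha = 0.05) {
  check_number(effect, "effect")
  if (effect == 0) abort("`effect` must be non-zero: the requested power is unreachable.")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  check_number(power, "power", lower = 0, upper = 1, strict_lower = TRUE)
  if (power >= 1) abort("`power` must be < 1.")
  d <- abs(effect) / sd
  n0 <- ceiling(2 * ((qnorm(1 - alpha / 2) + qnorm(power)) / d)^2)
  n <- max(2L, as.integer(n0))
  while (power_two_groups(n, effect, sd, alpha) < power) n <- n + 1L
  while (n > 2L && power_two_groups(n - 1L, effect, sd, alpha) >= power) n <- n - 1L
  n
}
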