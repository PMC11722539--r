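# Statistics: every test implemented from its formulas, cross-checked
# against base R's independent implementations and closed forms.

test_that("summary-statistics t reproduces the wild-type vs mutant comparison", {
  wt <- group_summary(9.8, 0.4, 18)
  mut <- group_summary(4.9, 0.3, 18)
  res <- ttest_summary(wt, mut, "student")
  expect_equal(res$statistic, 4.9 / sqrt(0.4^2 + 0.3^2), tolerance = 1e-12)
  expect_equal(res$df, 34)
  expect_lt(res$p_value, 1e-4)

  same <- ttest_summary(wt, wt)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary t equals the raw-data t for both variants", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    for (variant in c("student", "welch")) {
      mine <- ttest_summary(summarize_group(x), summarize_group(y), variant)
      ref <- t.test(x, y, var.equal = variant == "student")
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the Welch comparison of the knockout/knockdown lengths lands near 0.14", {
  # SEM rounding and the unreported exact n preclude an exact value; the
  # computed p must bracket the printed one for any n in the stated range
  for (n1 in 18:20) {
    for (n2 in 18:20) {
      p <- ttest_summary(group_summary(5.5, 0.5, n1),
                         group_summary(4.1, 0.7, n2), "welch")$p_value
      expect_gte(p, 0.10)
      expect_lte(p, 0.17)
    }
  }
})

test_that("degenerate zero-variance comparisons flag p = 0", {
  res <- ttest_summary(group_summary(2, 0, 5), group_summary(1, 0, 5))
  expect_equal(res$p_value, 0)
  expect_match(res$warning_flag, "zero variance")
})

test_that("Mann-Whitney exact enumeration matches hand counts and wilcox.test", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)

  expect_equal(mann_whitney(c(2, 5, 9), c(2, 5, 9))$p_value, 1)

  set.seed(4)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    pool <- sample(1:100, n1 + n2)  # tie-free: wilcox.test can be exact
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    mine <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  # with ties wilcox.test cannot enumerate; check against the brute-force
  # pair-counting oracle instead
  set.seed(5)
  for (i in 1:6) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(2:7, 5, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, brute_mwu_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation matches wilcox.test with ties", {
  set.seed(9)
  for (i in 1:10) {
    x <- sample(1:15, 12, replace = TRUE)  # ties guaranteed
    y <- sample(4:18, 14, replace = TRUE)
    mine <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_match(mann_whitney(rnorm(10), rnorm(12))$method, "normal")

  allt <- mann_whitney(rep(3, 9), rep(3, 9))
  expect_equal(allt$p_value, 1)
  expect_match(allt$warning_flag, "tied")
})

test_that("a 3-SD shift is detected by Mann-Whitney in nearly every seed", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    x <- rnorm(10); y <- rnorm(10) + 3
    if (mann_whitney(x, y)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("F tails match the d1 = 2 closed form and the printed legend values", {
  for (f in c(0.5, 2.4, 10, 44, 100)) {
    for (d2 in c(10, 27, 55, 57, 200)) {
      closed <- (d2 / (d2 + 2 * f))^(d2 / 2)
      expect_equal(f_tail(f, 2, d2), closed, tolerance = 1e-12)
    }
  }
  expect_equal(f_tail(0, 3, 20), 1)
  # monotone decreasing in F
  grid <- vapply(seq(0, 50, by = 2.5), f_tail, 1, d1 = 2, d2 = 40)
  expect_true(all(diff(grid) < 0))
  expect_equal(signif(f_tail(44, 2, 55), 2), 3.9e-12)
  expect_equal(round(f_tail(2.4, 2, 57), 1), 0.1)
})

test_that("one-way ANOVA agrees with the lm decomposition", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:10, 1), mean = j / 2))
    names(groups) <- paste0("g", seq_len(k))
    mine <- oneway_anova(groups)
    df <- data.frame(value = unlist(groups),
                     group = rep(names(groups), lengths(groups)))
    ref <- anova(lm(value ~ group, data = df))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$df, c(ref$Df[1], ref$Df[2]))
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  flat <- oneway_anova(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$statistic, 0)
  sep <- oneway_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(sep$p_value, 0)
  expect_match(sep$warning_flag, "zero within-group")
})

test_that("Tukey HSD agrees with TukeyHSD and the two-group t identity", {
  set.seed(31)
  groups <- list(a = rnorm(8, 0), b = rnorm(10, 1), c = rnorm(9, 0.2))
  mine <- tukey_hsd(groups)
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), lengths(groups))))
  ref <- TukeyHSD(aov(value ~ group, data = df))$group
  for (j in seq_len(nrow(mine))) {
    key <- paste(mine$group2[j], mine$group1[j], sep = "-")
    key2 <- paste(mine$group1[j], mine$group2[j], sep = "-")
    row <- if (key %in% rownames(ref)) ref[key, ] else ref[key2, ]
    expect_equal(mine$p_adj[j], unname(row["p adj"]), tolerance = 1e-8)
  }

  # two groups: Tukey p equals the pooled-t p through q = t * sqrt(2)
  two <- list(x = rnorm(7), y = rnorm(9, 0.8))
  tk <- tukey_hsd(two)
  tt <- ttest_raw(two$x, two$y, "student")
  expect_equal(tk$p_adj, tt$p_value, tolerance = 1e-9)
  expect_equal(tk$q, abs(tt$statistic) * sqrt(2), tolerance = 1e-12)

  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$p_adj > 1 - 1e-9))

  # a far-shifted group dominates the pairwise comparisons
  far <- tukey_hsd(list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 10))
  pc <- far$p_adj[far$group1 == "a" & far$group2 == "b"]
  expect_true(all(far$p_adj[far$group2 == "c" | far$group1 == "c"] < pc / 10))
})

test_that("power and sample size match the noncentral-t benchmark", {
  # effect/sd = 2 at 90% power, alpha 0.05: n = 7 per group
  expect_identical(sample_size_two_groups(effect = 2, sd = 1), 7L)
  ref <- power.t.test(delta = 2, sd = 1, power = 0.9)$n
  expect_identical(sample_size_two_groups(2, 1), as.integer(ceiling(ref)))

  # the returned n reaches the target and n - 1 does not
  for (es in c(0.8, 1.2, 2)) {
    n <- sample_size_two_groups(es, 1, power = 0.9)
    expect_gte(power_two_groups(n, es, 1), 0.9)
    if (n > 2L) expect_lt(power_two_groups(n - 1L, es, 1), 0.9)
    expect_equal(power_two_groups(n, es, 1),
                 power.t.test(n = n, delta = es, sd = 1)$power,
                 tolerance = 1e-5)
  }

  # doubling the effect never increases the requirement
  ns <- vapply(c(0.5, 1, 2, 4), sample_size_two_groups, 1L, sd = 1)
  expect_true(all(diff(ns) <= 0))

  expect_error(sample_size_two_groups(0, 1), "non-zero")
})

test_that("p-values are symmetric under group swap and stay in [0, 1]", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(11, 0.5)
    for (variant in c("student", "welch")) {
      a <- ttest_summary(summarize_group(x), summarize_group(y), variant)
      b <- ttest_summary(summarize_group(y), summarize_group(x), variant)
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
      expect_true(a$p_value >= 0 && a$p_value <= 1)
    }
    expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value,
                 tolerance = 1e-12)
  }
})
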