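test_that("mean_ci95 matches the closed form", {
  # constant sample: CI degenerates to the mean
  ci <- mean_ci95(rep(3.5, 6))
  expect_identical(ci$lower, 3.5)
  expect_identical(ci$upper, 3.5)
  # n = 2 sample {0, 2}: mean 1, half-width qt(.975, 1) * sd/sqrt(2)
  ci2 <- mean_ci95(c(0, 2))
  hw <- qt(0.975, 1) * sqrt(2) / sqrt(2)
  expect_equal(ci2$mean, 1)
  expect_equal(ci2$lower, 1 - hw)
  expect_equal(ci2$upper, 1 + hw)
  expect_error(mean_ci95(1), "at least 2")
})

test_that("t-based CI covers the true mean at its nominal rate", {
  withr::local_seed(404)
  hits <- replicate(1000, {
    ci <- mean_ci95(rnorm(7, mean = 2))
    ci$lower <= 2 && 2 <= ci$upper
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("identical samples give a null comparison", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  cmp <- route_and_compare_two(x, x)
  if (cmp$route_taken == "mann_whitney_u") {
    expect_gte(cmp$p_value, 0.99)
  } else {
    expect_equal(cmp$statistic, 0)
    expect_equal(cmp$p_value, 1)
  }
  expect_error(route_and_compare_two(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("routing decisions are recorded and internally consistent", {
  withr::local_seed(8)
  a <- rnorm(10); b <- rnorm(10, 2)
  cmp <- route_and_compare_two(a, b)
  expect_true(all(cmp$normality$shapiro_p > cmp$alpha))
  expect_true(cmp$route_taken %in% c("student_t", "welch_t"))
  expect_false(is.na(cmp$variance_test_p))
  # grossly non-normal data routes to Mann-Whitney
  skewed_a <- exp(rnorm(30, sd = 2)); skewed_b <- exp(rnorm(30, sd = 2)) + 1
  cmp2 <- route_and_compare_two(skewed_a, skewed_b)
  expect_identical(cmp2$route_taken, "mann_whitney_u")
  expect_true(any(cmp2$normality$shapiro_p <= cmp2$alpha))
  # zero-variance groups are flagged and routed nonparametrically
  cmp3 <- route_and_compare_two(rep(1, 5), c(1.2, 1.4, 0.8, 1.1, 0.7))
  expect_true(cmp3$normality$degenerate[1])
  expect_identical(cmp3$route_taken, "mann_whitney_u")
})

test_that("the parametric route is chosen and powered for clear normal shifts", {
  withr::local_seed(2024)
  res <- replicate(200, {
    cmp <- route_and_compare_two(rnorm(7), rnorm(7, 2))
    c(parametric = cmp$route_taken %in% c("student_t", "welch_t"),
      significant = cmp$p_value < 0.05)
  })
  # analytic oracle: power.t.test(n = 7, delta = 2, sd = 1) gives 0.929 for
  # the pure t test, the ceiling for the routed procedure; allow Monte-Carlo
  # noise (binomial sd ~0.018 at 200 replicates)
  expect_gte(mean(res["significant", ]), 0.87)
  expect_gte(mean(res["parametric", ]), 0.80)
})

test_that("Mann-Whitney agrees with exhaustive enumeration at small n", {
  withr::local_seed(15)
  for (rep in 1:10) {
    a <- round(rnorm(sample(4:6, 1)), 4)
    b <- round(rnorm(sample(4:6, 1), 0.8), 4)
    if (anyDuplicated(c(a, b))) next
    ours <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(ours, enum_mw_p(a, b), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis matches the hand rank formula", {
  groups <- list(a = c(2.1, 5.3, 8.8), b = c(1.2, 9.4, 11.0), c = c(0.4, 3.3, 4.1))
  cmp <- route_and_compare_many(
    lapply(groups, function(g) g)  # no ties, clearly non-normal not needed:
  )
  # compute H by hand regardless of the route taken
  x <- unlist(groups); r <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(3 * (tapply(r, rep(names(groups), lengths(groups)), mean) - (N + 1) / 2)^2)
  kw <- kruskal.test(x, factor(rep(names(groups), lengths(groups))))
  expect_equal(unname(kw$statistic), H)
  expect_s3_class(cmp, "group_comparison")
})

test_that("three identical groups yield a null omnibus", {
  x <- c(1.3, 2.2, 3.1, 4.4, 5.2)
  cmp <- route_and_compare_many(list(a = x, b = x, c = x))
  if (cmp$route_taken == "one_way_anova") {
    expect_equal(cmp$statistic, 0, tolerance = 1e-12)
    expect_gte(cmp$p_value, 0.999)
  } else {
    expect_gte(cmp$p_value, 0.99)
  }
  expect_error(route_and_compare_many(list(a = x, b = x)), "at least 3")
})

test_that("Dunn post hoc uses tie-corrected ranks and exact Bonferroni", {
  withr::local_seed(33)
  groups <- list(a = exp(rnorm(8)), b = exp(rnorm(8, 1)), c = exp(rnorm(8, 2)))
  dn <- dunn_test(groups)
  expect_identical(nrow(dn), 3L)
  expect_identical(dn$p_adj, pmin(1, 3 * dn$p_raw))
  expect_true(all(dn$p_adj >= dn$p_raw))
  # z statistic against a direct computation for one pair
  x <- unlist(groups); r <- rank(x); n <- length(x)
  rb <- tapply(r, rep(names(groups), each = 8), mean)
  s2 <- n * (n + 1) / 12
  z_ab <- (rb[["a"]] - rb[["b"]]) / sqrt(s2 * (2 / 8))
  expect_equal(dn$z[dn$comparison == "a - b"], z_ab, tolerance = 1e-12)
})

test_that("the nonparametric multi-group route attaches a Dunn table", {
  withr::local_seed(60)
  groups <- list(a = exp(rnorm(9, sd = 2)), b = exp(rnorm(9, sd = 2)),
                 c = exp(rnorm(9, sd = 2)) + 5)
  cmp <- route_and_compare_many(groups)
  expect_identical(cmp$route_taken, "kruskal_wallis")
  expect_identical(nrow(cmp$posthoc), 3L)
})

test_that("two-way ANOVA detects a planted main effect and adjusts exactly", {
  withr::local_seed(91)
  a <- rep(c("ctl", "les"), each = 12)
  b <- rep(rep(c("ram", "hyp", "bsh"), each = 4), 2)
  y <- rnorm(24) + ifelse(a == "les" & b == "ram", -3, 0) +
    ifelse(a == "les" & b == "hyp", 3, 0)
  cmp <- two_factor_compare(y, a, b)
  expect_identical(cmp$route_taken, "two_way_anova_bonferroni")
  tab <- cmp$anova_table
  expect_lt(tab$p_value[tab$term == "a:b"], 0.05)
  expect_identical(cmp$posthoc$p_adj, pmin(1, nrow(cmp$posthoc) * cmp$posthoc$p_raw))
  expect_error(two_factor_compare(y[1:20], a[1:20], b[1:20]), "cell")
})

test_that("tidy and glance expose broom-style summaries", {
  withr::local_seed(5)
  cmp <- route_and_compare_two(rnorm(7), rnorm(7, 1), names = c("ctl", "mptp"))
  td <- tidy(cmp)
  expect_identical(td$group, c("ctl", "mptp"))
  expect_true(all(td$lower <= td$mean & td$mean <= td$upper))
  gl <- glance(cmp)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("design", "route_taken", "statistic", "p_value") %in% names(gl)))
  expect_gte(gl$p_value, 0); expect_lte(gl$p_value, 1)
})

test_that("the data-frame interface averages replicates per animal first", {
  df <- data.frame(
    value = c(10, 12, 30, 32, 11, 13, 29, 31, 10, 14, 30, 34,
              9, 13, 31, 33, 12, 12, 28, 30),
    group = rep(c("ctl", "les"), 10),
    animal = rep(1:5, each = 4)
  )
  # animals 1..5 each contribute 2 ctl and 2 les stacks
  df$animal <- paste(df$group, rep(rep(1:5, each = 4), length.out = 20))
  cmp <- compare_groups(df, "value", "group", animal = "animal")
  expect_identical(sum(cmp$group_stats$n), 10L)  # 5 animals per group
  expect_s3_class(cmp, "group_comparison")
})
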