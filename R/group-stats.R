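#' Mean with t-based 95% confidence interval
#'
#' @param x Numeric sample with at least 2 values.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `mean`, `lower`, `upper`.
#' @export
mean_ci95 <- function(x, conf_level = 0.95) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) abort("confidence interval requires at least 2 values")
  m <- mean(x)
  se <- stats::sd(x) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble(n = n, mean = m, lower = m - tq * se, upper = m + tq * se)
}

shapiro_p <- function(x) {
  if (length(x) < 3) abort("Shapiro-Wilk needs n >= 3 per group")
  if (stats::sd(x) == 0) return(NA_real_)  # degenerate: flagged, not testable
  stats::shapiro.test(x)$p.value
}

group_stats_tbl <- function(samples) {
  dplyr::bind_rows(lapply(names(samples), function(g) {
    ci <- mean_ci95(samples[[g]])
    dplyr::mutate(ci, group = g, .before = 1)
  }))
}

new_group_comparison <- function(design, route_taken, statistic, p_value,
                                 normality, variance_test_p, group_stats,
                                 posthoc = NULL, anova_table = NULL,
                                 alpha = 0.05) {
  structure(
    list(design = design, route_taken = route_taken, statistic = statistic,
         p_value = p_value, normality = normality,
         variance_test_p = variance_test_p, group_stats = group_stats,
         posthoc = posthoc, anova_table = anova_table, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s design, route: %s\n", x$design, x$route_taken))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  print(x$group_stats)
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Two-group comparison with normality routing
#'
#' Implements the routed two-sample procedure: Shapiro-Wilk on each group at
#' `alpha`; when both pass, an F test compares variances and picks Student's
#' t (equal variances) or Welch's t, both two-tailed; when either group
#' fails normality (or is degenerate with zero variance), the Mann-Whitney U
#' test is used. Every routing decision is recorded in the returned object.
#'
#' @param a,b Numeric samples, each with n >= 3.
#' @param alpha Significance level used for the routing gates (default 0.05).
#' @param names Length-2 group labels.
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
route_and_compare_two <- function(a, b, alpha = 0.05, names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) abort("each sample needs n >= 3")
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  normality <- tibble(group = names, shapiro_p = c(pa, pb),
                      degenerate = c(stats::sd(a) == 0, stats::sd(b) == 0))
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  samples <- stats::setNames(list(a, b), names)

  if (normal) {
    vt <- stats::var.test(a, b)
    if (vt$p.value < alpha) {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      route <- "welch_t"
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      route <- "student_t"
    }
    new_group_comparison("two_group", route, unname(ht$statistic), ht$p.value,
                         normality, vt$p.value, group_stats_tbl(samples),
                         alpha = alpha)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
    new_group_comparison("two_group", "mann_whitney_u", unname(ht$statistic),
                         ht$p.value, normality, NA_real_,
                         group_stats_tbl(samples), alpha = alpha)
  }
}

#' Dunn's multiple-comparison test
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis omnibus, with
#' the tie-corrected variance and Bonferroni adjustment
#' (`p_adj = min(1, m * p)` over the `m = k(k-1)/2` comparisons).
#'
#' @param samples Named list of numeric vectors.
#' @return Tibble: `comparison`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(samples) {
  k <- length(samples)
  if (k < 2) abort("need at least two groups")
  g <- rep(names(samples), lengths(samples))
  x <- unlist(samples, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)[names(samples)]
  ni <- lengths(samples)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  combs <- utils::combn(names(samples), 2)
  m <- ncol(combs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    se <- sqrt(s2 * (1 / ni[[i1]] + 1 / ni[[i2]]))
    z <- (rbar[[i1]] - rbar[[i2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble(comparison = paste(i1, "-", i2), z = unname(z), p_raw = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out
}

#' Multi-group comparison with normality routing
#'
#' Shapiro-Wilk per group at `alpha`; if every group is normal, a one-way
#' ANOVA compares the groups; otherwise Kruskal-Wallis, followed by Dunn's
#' multiple-comparison test with Bonferroni adjustment.
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 3).
#' @param alpha Routing significance level.
#' @return A `group_comparison`.
#' @export
route_and_compare_many <- function(groups, alpha = 0.05) {
  if (length(groups) < 3) abort("need at least 3 groups (use route_and_compare_two)")
  if (any(lengths(groups) < 3)) abort("each group needs n >= 3")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ps <- vapply(groups, shapiro_p, numeric(1))
  normality <- tibble(group = names(groups), shapiro_p = ps,
                      degenerate = vapply(groups, function(x) stats::sd(x) == 0, TRUE))
  normal <- !anyNA(ps) && all(ps > alpha)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  x <- unlist(groups, use.names = FALSE)

  if (normal) {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    new_group_comparison("one_factor", "one_way_anova",
                         tab[["F value"]][1], tab[["Pr(>F)"]][1],
                         normality, NA_real_, group_stats_tbl(groups),
                         alpha = alpha)
  } else {
    kw <- stats::kruskal.test(x, g)
    new_group_comparison("one_factor", "kruskal_wallis",
                         unname(kw$statistic), kw$p.value,
                         normality, NA_real_, group_stats_tbl(groups),
                         posthoc = dunn_test(groups), alpha = alpha)
  }
}

#' Two-way ANOVA with Bonferroni post hoc comparisons
#'
#' Fits `value ~ a * b` (main effects and interaction) and compares the
#' levels of `a` within every level of `b` using the pooled residual
#' variance, Bonferroni-adjusting over all pairwise comparisons
#' (`p_adj = min(1, m * p)`). This is the design used for morphology-class
#' counts across treatments: `a` = treatment, `b` = morphology class.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors of the crossed design (complete, cell
#'   n >= 2).
#' @param alpha Stored significance level.
#' @return A `group_comparison` with `anova_table` (term, df, F, p) and a
#'   `posthoc` tibble; `statistic`/`p_value` report the interaction term.
#' @export
two_factor_compare <- function(values, factor_a, factor_b, alpha = 0.05) {
  a <- factor(factor_a); b <- factor(factor_b)
  x <- as.numeric(values)
  cells <- table(a, b)
  if (any(cells == 0)) abort("design has empty cells")
  if (any(cells < 2)) abort("each cell needs n >= 2")
  fit <- stats::aov(x ~ a * b)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  anova_table <- tibble(
    term = terms, df = tab$Df, sum_sq = tab$`Sum Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`
  )

  # pooled-variance pairwise comparisons of a within each level of b
  mse <- tab$`Mean Sq`[terms == "Residuals"]
  dfe <- tab$Df[terms == "Residuals"]
  rows <- list()
  for (lb in levels(b)) {
    la <- levels(a)
    cmb <- utils::combn(la, 2)
    for (j in seq_len(ncol(cmb))) {
      a1 <- cmb[1, j]; a2 <- cmb[2, j]
      x1 <- x[a == a1 & b == lb]; x2 <- x[a == a2 & b == lb]
      se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
      tstat <- (mean(x1) - mean(x2)) / se
      p <- 2 * stats::pt(-abs(tstat), dfe)
      rows[[length(rows) + 1L]] <- tibble(
        within = lb, comparison = paste(a1, "-", a2),
        estimate = mean(x1) - mean(x2), t = tstat, p_raw = p
      )
    }
  }
  posthoc <- dplyr::bind_rows(rows)
  posthoc$p_adj <- pmin(1, nrow(posthoc) * posthoc$p_raw)

  samples <- split(x, interaction(a, b, sep = ":"))
  inter_row <- which(terms == "a:b")
  new_group_comparison("two_factor", "two_way_anova_bonferroni",
                       anova_table$statistic[inter_row],
                       anova_table$p_value[inter_row],
                       normality = NULL, variance_test_p = NA_real_,
                       group_stats = group_stats_tbl(samples),
                       posthoc = posthoc, anova_table = anova_table,
                       alpha = alpha)
}

#' Data-frame interface to the routed comparisons
#'
#' Splits `data[[value]]` by `data[[group]]` (after optionally averaging
#' replicate rows per animal, the statistical unit) and dispatches to the
#' two-group or multi-group routed procedure by the number of groups.
#'
#' @param data A data frame.
#' @param value,group,animal Column names (strings); `animal` is optional.
#' @param alpha Routing significance level.
#' @return A `group_comparison`.
#' @export
compare_groups <- function(data, value, group, animal = NULL, alpha = 0.05) {
  df <- as.data.frame(data)
  if (!is.null(animal)) {
    agg <- stats::aggregate(df[[value]],
                            by = list(group = df[[group]], animal = df[[animal]]),
                            FUN = mean)
    samples <- split(agg$x, agg$group)
  } else {
    samples <- split(as.numeric(df[[value]]), df[[group]])
  }
  if (length(samples) == 2) {
    route_and_compare_two(samples[[1]], samples[[2]], alpha = alpha,
                          names = names(samples))
  } else {
    route_and_compare_many(samples, alpha = alpha)
  }
}

#' Per-group summary of a comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble of groups with `n`, `mean` and the 95% CI bounds.
#' @export
tidy.group_comparison <- function(x, ...) x$group_stats

#' One-row summary of a comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `design`, `route_taken`, `statistic`, `p_value`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(design = x$design, route_taken = x$route_taken,
         statistic = x$statistic, p_value = x$p_value)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
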