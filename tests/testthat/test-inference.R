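balanced_table <- function(n_per_cell = 3, a = 2, b = 2, seed = 1) {
  withr::with_seed(seed, {
    df <- tidyr::expand_grid(
      A = paste0("a", seq_len(a)), B = paste0("b", seq_len(b)),
      rep = seq_len(n_per_cell)
    )
    df$y <- rnorm(nrow(df))
    df
  })
}

test_that("Type-II SS equals sequential SS on balanced designs", {
  for (seed in 1:5) {
    df <- balanced_table(n_per_cell = 4, a = 3, b = 2, seed = seed)
    fit <- fit_aov(df, "y", c("A", "B"))
    seq_tab <- anova(lm(y ~ A + B + A:B, data = df))
    t2 <- tidy(fit)
    expect_equal(
      t2$sumsq[match(c("A", "B", "A:B"), t2$term)],
      seq_tab$`Sum Sq`[1:3],
      tolerance = 1e-10
    )
  }
})

test_that("one factor with two equal groups reduces to the t test (F = t^2)", {
  df <- data.frame(
    A = rep(c("x", "z"), each = 6),
    y = c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3, 2.0, 1.7, 2.4, 1.9, 2.2, 1.6)
  )
  fit <- fit_aov(df, "y", "A")
  tt <- t.test(y ~ A, data = df, var.equal = TRUE)
  row <- tidy(fit)[tidy(fit)$term == "A", ]
  expect_equal(row$statistic, unname(tt$statistic)^2)
  expect_equal(row$p.value, tt$p.value)
})

test_that("Type-II SS matches the explicit model-comparison oracle when unbalanced", {
  # 2x2 with cell sizes 3/1/2/2
  df <- data.frame(
    A = c("a", "a", "a", "a", "b", "b", "b", "b"),
    B = c("u", "u", "u", "v", "u", "u", "v", "v"),
    y = c(3.1, 2.7, 3.5, 4.2, 1.9, 2.2, 5.1, 4.8)
  )
  fit <- fit_aov(df, "y", c("A", "B"))
  oracle <- naive_typeII_2x2(df, "y")
  t2 <- tidy(fit)
  for (term in c("A", "B", "A:B")) {
    row <- t2[t2$term == term, ]
    expect_equal(row$sumsq, unname(oracle$ss[term]), tolerance = 1e-10)
    expect_equal(row$statistic, unname(oracle$statistic[term]), tolerance = 1e-10)
    expect_equal(row$df, unname(oracle$df[term]))
  }
  expect_equal(t2$df[t2$term == "Residuals"], oracle$df_resid)
})

test_that("Type-II SS is invariant to factor-level ordering", {
  df <- balanced_table(n_per_cell = 2, a = 3, b = 2, seed = 9)
  df$y <- df$y + as.integer(factor(df$A)) # give A a real effect
  base <- tidy(fit_aov(df, "y", c("A", "B")))
  shuffled <- df
  shuffled$A <- factor(shuffled$A, levels = c("a3", "a1", "a2"))
  alt <- tidy(fit_aov(shuffled, "y", c("A", "B")))
  expect_equal(
    base$sumsq[order(base$term)], alt$sumsq[order(alt$term)],
    tolerance = 1e-10
  )
})

test_that("rank-deficient designs error naming the aliased terms", {
  df <- balanced_table(seed = 3)
  df <- df[!(df$A == "a2" & df$B == "b2"), ] # empty cell
  expect_error(fit_aov(df, "y", c("A", "B")), "aliased.*a2.*b2")
  expect_error(fit_aov(df[df$A == "a1", ], "y", c("A", "B")), "fewer than 2")
})

test_that("simple effects run one-way ANOVAs per stratum with Bonferroni over strata", {
  df <- tidyr::expand_grid(
    semester = c("1st", "2nd", "3rd", "4th"),
    department = c("Caldas", "Cauca", "Cesar"),
    rep = 1:4
  )
  withr::with_seed(13, {
    df$r_i <- rnorm(nrow(df), sd = 0.05) +
      ifelse(df$semester == "1st", 0.3 * (df$department == "Cesar"), 0)
  })
  se <- simple_effects(df, "r_i")
  expect_equal(se$stratum, c("1st", "2nd", "3rd", "4th"))
  expect_equal(se$m, rep(4L, 4))
  expect_equal(se$p.adj, pmin(1, se$p.value * 4))

  # per-stratum F agrees with the explicit between/within oracle
  for (s in se$stratum) {
    sub <- df[df$semester == s, ]
    o <- naive_oneway(sub$r_i, sub$department)
    expect_equal(se$statistic[se$stratum == s], o$statistic, tolerance = 1e-10)
    expect_equal(se$p.value[se$stratum == s], o$p.value, tolerance = 1e-10)
  }

  # identical site distributions within a stratum: F ~ 0, not significant
  flat <- df
  flat$r_i <- rep(c(0.5, 0.6, 0.7, 0.8), each = 12) + # varies by semester...
    rep(c(-0.02, 0, 0.02, 0.04), times = 12) # ...and by rep, not by site
  se_flat <- simple_effects(flat, "r_i")
  expect_true(all(abs(se_flat$statistic) < 1e-10))
  expect_false(any(se_flat$significant))

  # a stratum with a single site level is skipped with a warning
  df2 <- df[!(df$semester == "2nd" & df$department != "Caldas"), ]
  expect_warning(se2 <- simple_effects(df2, "r_i"), "skipped")
  expect_equal(nrow(se2), 3L)
})

test_that("pairwise comparisons match the pooled-t oracle and Bonferroni family", {
  df <- tidyr::expand_grid(
    semester = c("1st", "2nd"),
    department = c("Caldas", "Cauca", "Cesar"),
    rep = 1:5
  )
  withr::with_seed(17, df$cv_i <- rnorm(nrow(df), mean = 2, sd = 0.4))
  pw <- pairwise_bonferroni(df, "cv_i")
  expect_equal(nrow(pw), 6L) # 3 pairs x 2 semesters
  expect_equal(unique(pw$m), 6L)
  expect_equal(pw$p.adj, pmin(1, pw$p.value * 6))
  expect_true(all(pw$p.adj >= pw$p.value))

  for (k in seq_len(nrow(pw))) {
    sub <- df[df$semester == pw$stratum[k], ]
    o <- naive_pooled_t(
      sub$cv_i[sub$department == pw$group_a[k]],
      sub$cv_i[sub$department == pw$group_b[k]]
    )
    expect_equal(pw$statistic[k], o$statistic, tolerance = 1e-10)
    expect_equal(pw$p.value[k], o$p.value, tolerance = 1e-10)
    expect_equal(pw$df[k], o$df)
  }

  # adjusted p is monotone in raw p and capped at 1
  expect_true(all(pw$p.adj <= 1))
  ord <- order(pw$p.value)
  expect_true(all(diff(pw$p.adj[ord]) >= -1e-15))

  # groups with < 2 observations are skipped with a warning per comparison
  df3 <- df[!(df$department == "Cesar" & df$rep > 1 & df$semester == "1st"), ]
  w <- testthat::capture_warnings(pw3 <- pairwise_bonferroni(df3, "cv_i"))
  expect_length(w, 2L) # both Cesar pairs in the 1st semester
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(pw3), 4L)
})

test_that("assumption checks report Shapiro and Levene and never gate", {
  # residuals of this two-group fit form a fixed right-skewed sample;
  # p frozen from an independent reference implementation
  df <- data.frame(
    g = rep(c("a", "b"), each = 5),
    y = c(0.1, 0.2, 0.25, 0.3, 0.35, 0.5, 0.9, 1.5, 2.8, 5.0)
  )
  res <- check_assumptions(df, "y", "g")
  expect_equal(res$shapiro_p, 0.09188890091345676, tolerance = 1e-6)
  expect_true(res$shapiro_p >= 0 && res$shapiro_p <= 1)
  expect_true(res$levene_p >= 0 && res$levene_p <= 1)

  # identical groups: Levene statistic is exactly 0
  same <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  expect_equal(check_assumptions(same, "y", "g")$levene_f, 0)

  expect_error(
    check_assumptions(data.frame(g = c("a", "a", "b"), y = rep(1, 3)), "y", "g"),
    "constant"
  )
})

test_that("event medians are computed per grouping and overall", {
  df <- tibble::tibble(
    department = c("Caldas", "Caldas", "Cesar", "Cesar", "Cesar"),
    semester = c("1st", "1st", "1st", "1st", "3rd"),
    accession = c("A1", "A2", "A1", "A2", "A1"),
    event = c(2, 2, 15, 3, 7)
  )
  s <- event_summary(df)
  expect_equal(
    s$by_site_semester$median_event[s$by_site_semester$department == "Caldas"], 2
  )
  # median of {2, 2, 15} is 2; sort-and-pick oracle for grouped medians
  expect_equal(median(c(2, 2, 15)), 2)
  expect_equal(
    s$by_site_semester$median_event[s$by_site_semester$department == "Cesar" &
      s$by_site_semester$semester == "1st"],
    sort(c(15, 3))[1] / 2 + sort(c(15, 3))[2] / 2
  )
  expect_equal(s$overall$median_event, 3)

  single <- event_summary(df[1, ])
  expect_equal(single$overall$median_event, 2)
})
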