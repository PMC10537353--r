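# Independent naive reimplementations used as oracles. These deliberately
# avoid the code paths they check: ranks and moments are written out as
# explicit sums, Type-II sums of squares as explicit full/reduced model
# comparisons.

# mid-ranks by explicit counting: rank = (#smaller) + (1 + #equal) / 2
naive_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

# Pearson on mid-ranks via explicit sums
naive_spearman <- function(x, y) {
  rx <- naive_midranks(x)
  ry <- naive_midranks(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

naive_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  s / m
}

# synchrony: mean |rho| over all unordered pairs, undefined pairs dropped
naive_ri <- function(grid) {
  n <- nrow(grid)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- naive_spearman(grid[i, ], grid[j, ])
      if (!is.na(r)) vals <- c(vals, abs(r))
    }
  }
  if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
}

naive_cvi <- function(grid) {
  mean(vapply(seq_len(nrow(grid)), function(i) naive_cv(grid[i, ]), numeric(1)))
}

# random small calendar with >= 2 flowering plants (counts 0..max_count)
random_small_calendar <- function(max_plants = 4, max_weeks = 6, max_count = 3) {
  repeat {
    np <- sample(2:max_plants, 1)
    nw <- sample(3:max_weeks, 1)
    grid <- matrix(sample(0:max_count, np * nw, replace = TRUE), nrow = np)
    if (all(rowSums(grid) > 0)) {
      return(floral_calendar(grid))
    }
  }
}

# Type-II SS for y ~ A + B + A:B by explicit model comparison:
# SS(term) = RSS(model with every term not containing it) - RSS(+ term)
naive_typeII_2x2 <- function(df, response) {
  rss <- function(fml) sum(residuals(lm(fml, data = df))^2)
  f <- function(s) stats::as.formula(paste(response, "~", s))
  full <- lm(f("A + B + A:B"), data = df)
  mse <- sum(residuals(full)^2) / df.residual(full)
  ss <- c(
    A = rss(f("B")) - rss(f("A + B")),
    B = rss(f("A")) - rss(f("A + B")),
    `A:B` = rss(f("A + B")) - rss(f("A + B + A:B"))
  )
  dfs <- c(
    A = nlevels(factor(df$A)) - 1,
    B = nlevels(factor(df$B)) - 1
  )
  dfs <- c(dfs, `A:B` = unname(dfs["A"] * dfs["B"]))
  list(ss = ss, df = dfs, statistic = (ss / dfs) / mse,
    df_resid = df.residual(full), mse = mse
  )
}

# one-way ANOVA by explicit between/within sums of squares
naive_oneway <- function(y, g) {
  g <- as.character(g)
  groups <- unique(g)
  grand <- mean(y)
  ss_between <- sum(vapply(groups, function(k) {
    length(y[g == k]) * (mean(y[g == k]) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(k) {
    sum((y[g == k] - mean(y[g == k]))^2)
  }, numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, p.value = pf(f, df1, df2, lower.tail = FALSE))
}

# pooled-variance two-sample t by explicit formulas
naive_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2,
    p.value = 2 * pt(-abs(t), na + nb - 2)
  )
}
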