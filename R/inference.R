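#' Factorial analysis of variance with Type-II sums of squares
#'
#' Fits a fixed-effects linear model for one phenological descriptor and
#' computes the ANOVA table with Type-II sums of squares: each term's SS is
#' the drop in residual SS when the term is added to the model containing
#' every other term that does not contain it. For balanced designs Type-II
#' and sequential (Type-I) SS coincide; for the unbalanced plant counts
#' typical of field censuses they do not, and Type-II is the convention used
#' here. F statistics are term mean squares over the residual mean square.
#'
#' Rows with a missing response (populations flagged by
#' [descriptor_table()]) are dropped with a message before fitting.
#'
#' @param data Descriptor table (or any data frame).
#' @param response Name of the numeric response column, e.g. `"r_i"` or
#'   `"cv_i"`.
#' @param factors Character vector of factor column names (each must have at
#'   least 2 levels in the data).
#' @param interactions `TRUE` for all two-way interactions (default),
#'   `FALSE` for main effects only, or a character vector of explicit
#'   interaction terms such as `"department:semester"`.
#' @param alpha Significance threshold recorded on the result (default
#'   0.005, a conservative level guarding against false positives across
#'   several separately modelled responses).
#' @return An object of class `floracal_aov`; see [tidy()] and [glance()]
#'   for tabular views, `$fit` for the underlying `lm`.
#' @export
fit_aov <- function(data, response, factors,
                    interactions = TRUE, alpha = 0.005) {
  stopifnot(is.character(response), length(response) == 1L)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("column(s) not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data)[, c(response, factors)]
  n_na <- sum(is.na(df[[response]]))
  if (n_na > 0L) {
    message(sprintf("dropping %d row(s) with missing %s", n_na, response))
    df <- df[!is.na(df[[response]]), , drop = FALSE]
  }
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) {
      abort(sprintf("factor `%s` has fewer than 2 levels", f))
    }
  }

  int_terms <- if (isTRUE(interactions)) {
    if (length(factors) > 1L) {
      utils::combn(factors, 2L, paste, collapse = ":")
    } else {
      character(0)
    }
  } else if (is.character(interactions)) {
    interactions
  } else {
    character(0)
  }
  rhs <- paste(c(factors, int_terms), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lm(fml, data = df)

  if (fit$rank < ncol(stats::model.matrix(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(sprintf(
      "rank-deficient design; aliased coefficient(s): %s",
      paste(aliased, collapse = ", ")
    ))
  }
  if (stats::df.residual(fit) < 1L) {
    abort("no residual degrees of freedom; the model is saturated")
  }

  a2 <- car::Anova(fit, type = 2)
  tab <- tibble::tibble(
    term = rownames(a2),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`
  )
  structure(
    list(
      table = tab,
      fit = fit,
      response = response,
      factors = factors,
      interactions = int_terms,
      ss_type = "II",
      alpha = alpha,
      n_dropped = n_na,
      nobs = nrow(df)
    ),
    class = "floracal_aov"
  )
}

#' @export
print.floracal_aov <- function(x, ...) {
  cat(sprintf(
    "Type-%s ANOVA of %s (~ %s), n = %d, alpha = %g\n",
    x$ss_type, x$response,
    paste(c(x$factors, x$interactions), collapse = " + "), x$nobs, x$alpha
  ))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Three-factor screening model for a descriptor
#'
#' Convenience wrapper fitting the screening model with the three main
#' effects site, semester and accession and their two-way interactions,
#' Type-II SS. In the two-step workflow one first checks whether accession
#' (and its interactions) shows any evidence of effect; if not, the analysis
#' proceeds with the two-factor site-by-semester model ([fit_aov()] with
#' `factors = c(site, semester)`). The decision to drop accession is left to
#' the analyst -- this function only fits and reports.
#'
#' @inheritParams fit_aov
#' @param site,semester,accession Names of the three factor columns.
#' @return A `floracal_aov`.
#' @export
three_factor_screen <- function(data, response,
                                site = "department",
                                semester = "semester",
                                accession = "accession",
                                alpha = 0.005) {
  fit_aov(data, response,
    factors = c(site, semester, accession),
    interactions = TRUE, alpha = alpha
  )
}

#' Simple effects of site within each semester
#'
#' Decomposes a significant site-by-semester interaction: within each level
#' of `within` (each semester), a one-way ANOVA of the response across
#' `across` (the sites) is fitted, and the per-stratum p-values are
#' Bonferroni-adjusted over the number of strata analyzed. Strata with fewer
#' than 2 site levels are skipped with a warning.
#'
#' Callers should check first that the interaction is significant in the
#' two-factor model ([fit_aov()]); this function does not enforce it.
#'
#' @inheritParams fit_aov
#' @param within Stratifying factor (default `"semester"`).
#' @param across Factor whose effect is tested inside each stratum (default
#'   `"department"`).
#' @return A tibble with one row per analyzed stratum: `stratum`, `df1`,
#'   `df2`, `statistic`, `p.value`, `p.adj` (= min(1, m * p)), `m`,
#'   `significant` at `alpha`.
#' @export
simple_effects <- function(data, response,
                           within = "semester", across = "department",
                           alpha = 0.005) {
  df <- as.data.frame(data)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  strata <- sort(unique(as.character(df[[within]])))
  rows <- purrr::map_dfr(strata, function(s) {
    sub <- df[df[[within]] == s, , drop = FALSE]
    sub[[across]] <- factor(sub[[across]])
    if (nlevels(sub[[across]]) < 2L) {
      warn(sprintf("stratum %s = %s has < 2 %s levels; skipped", within, s, across))
      return(NULL)
    }
    fit <- lm(stats::as.formula(paste(response, "~", across)), data = sub)
    a <- anova(fit)
    tibble::tibble(
      stratum = s,
      df1 = a$Df[1L], df2 = a$Df[2L],
      statistic = a$`F value`[1L],
      p.value = a$`Pr(>F)`[1L]
    )
  })
  if (nrow(rows) == 0L) return(rows)
  m <- nrow(rows)
  rows %>%
    dplyr::mutate(
      p.adj = pmin(1, .data$p.value * m),
      m = m,
      significant = .data$p.adj < alpha
    )
}

#' Pairwise site comparisons within semesters, Bonferroni-adjusted
#'
#' All unordered pairs of `group` levels are compared within each level of
#' `within` by a two-sample t test (pooled variance by default, the
#' classical post-ANOVA comparison; Welch available via
#' `var_equal = FALSE`). The Bonferroni family is the full set of
#' comparisons performed in the analysis -- all pairs across all strata --
#' and the family size `m` is reported on every row. Comparisons with fewer
#' than 2 observations in either group are skipped with a warning.
#'
#' @inheritParams simple_effects
#' @param group Factor whose levels are compared pairwise (default
#'   `"department"`).
#' @param var_equal Pooled-variance t test if `TRUE` (default), Welch
#'   otherwise.
#' @return A tibble of class `floracal_comparisons`: `stratum`, `group_a`,
#'   `group_b`, `mean_a`, `mean_b`, `estimate` (a - b), `df`, `statistic`,
#'   `p.value`, `p.adj`, `m`, `significant` at `alpha`.
#' @export
pairwise_bonferroni <- function(data, response,
                                within = "semester", group = "department",
                                alpha = 0.005, var_equal = TRUE) {
  df <- as.data.frame(data)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  strata <- sort(unique(as.character(df[[within]])))
  rows <- purrr::map_dfr(strata, function(s) {
    sub <- df[df[[within]] == s, , drop = FALSE]
    levels_here <- sort(unique(as.character(sub[[group]])))
    if (length(levels_here) < 2L) return(NULL)
    purrr::map_dfr(
      utils::combn(levels_here, 2L, simplify = FALSE),
      function(pair) {
        xa <- sub[[response]][sub[[group]] == pair[1L]]
        xb <- sub[[response]][sub[[group]] == pair[2L]]
        if (length(xa) < 2L || length(xb) < 2L) {
          warn(sprintf(
            "comparison %s vs %s in %s = %s has < 2 observations; skipped",
            pair[1L], pair[2L], within, s
          ))
          return(NULL)
        }
        tt <- stats::t.test(xa, xb, var.equal = var_equal)
        tibble::tibble(
          stratum = s,
          group_a = pair[1L], group_b = pair[2L],
          mean_a = mean(xa), mean_b = mean(xb),
          estimate = mean(xa) - mean(xb),
          df = unname(tt$parameter),
          statistic = unname(tt$statistic),
          p.value = tt$p.value
        )
      }
    )
  })
  if (nrow(rows) == 0L) return(rows)
  m <- nrow(rows)
  out <- rows %>%
    dplyr::mutate(
      p.adj = pmin(1, .data$p.value * m),
      m = m,
      significant = .data$p.adj < alpha
    )
  class(out) <- c("floracal_comparisons", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "var_equal") <- var_equal
  out
}

#' Normality and variance-homogeneity checks for an ANOVA
#'
#' Runs the Shapiro--Wilk test on the residuals of the fitted model and
#' Levene's test of variance homogeneity across the design cells. Both are
#' annotations, not gates: the pipeline reports them (pass when both
#' p > 0.05) and continues either way.
#'
#' @inheritParams fit_aov
#' @param groups Character vector of factor columns whose cell combinations
#'   define the Levene groups.
#' @param center Centering for Levene's test: `"median"` (the robust
#'   Brown--Forsythe variant, default) or `"mean"` (the classical test).
#' @param alpha Threshold for the pass flag (default 0.05).
#' @return A one-row tibble: `shapiro_w`, `shapiro_p`, `levene_f`,
#'   `levene_p`, `pass`, `alpha`.
#' @export
check_assumptions <- function(data, response, groups,
                              center = c("median", "mean"), alpha = 0.05) {
  center <- match.arg(center)
  df <- as.data.frame(data)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  if (nrow(df) < 3L) abort("need at least 3 observations")
  y <- df[[response]]
  if (sd(y) == 0) abort("constant response; assumption tests are undefined")
  cell <- interaction(df[groups], drop = TRUE)
  if (nlevels(cell) < 2L) abort("need at least 2 groups for Levene's test")

  fml <- stats::as.formula(paste(response, "~", paste(groups, collapse = "*")))
  for (g in groups) df[[g]] <- factor(df[[g]])
  fit <- lm(fml, data = df)
  sw <- shapiro.test(stats::residuals(fit))
  lv <- car::leveneTest(y ~ cell, center = if (center == "median") median else mean)
  tibble::tibble(
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    levene_f = lv$`F value`[1L],
    levene_p = lv$`Pr(>F)`[1L],
    pass = sw$p.value > alpha && lv$`Pr(>F)`[1L] > alpha,
    alpha = alpha
  )
}

#' Median flowering-event counts by grouping
#'
#' The event descriptor is analyzed descriptively: medians per
#' site-by-semester cell, per accession, and overall.
#'
#' @param data Descriptor table with an `event` column.
#' @param site,semester,accession Grouping column names.
#' @return A list of three tibbles: `by_site_semester`, `by_accession`,
#'   `overall`.
#' @export
event_summary <- function(data, site = "department", semester = "semester",
                          accession = "accession") {
  if (nrow(data) == 0L) abort("empty descriptor table")
  list(
    by_site_semester = data %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(c(site, semester)))) %>%
      dplyr::summarise(
        median_event = median(.data$event), n = dplyr::n(), .groups = "drop"
      ),
    by_accession = data %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(accession))) %>%
      dplyr::summarise(
        median_event = median(.data$event), n = dplyr::n(), .groups = "drop"
      ),
    overall = tibble::tibble(
      median_event = median(data$event), n = nrow(data)
    )
  )
}
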