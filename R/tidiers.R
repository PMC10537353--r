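#' Tidy a Type-II ANOVA fit
#'
#' @param x A `floracal_aov` from [fit_aov()].
#' @param ... Unused.
#' @return A tibble with one row per model term plus the residual row:
#'   `term`, `sumsq`, `df`, `meansq`, `statistic`, `p.value`.
#' @method tidy floracal_aov
#' @export
tidy.floracal_aov <- function(x, ...) {
  x$table %>%
    dplyr::mutate(meansq = .data$sumsq / .data$df, .after = "df")
}

#' One-row summary of a Type-II ANOVA fit
#'
#' @param x A `floracal_aov` from [fit_aov()].
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`, `nobs`, `n_dropped`, `ss_type`, `alpha`.
#' @method glance floracal_aov
#' @export
glance.floracal_aov <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = stats::df.residual(x$fit),
    nobs = x$nobs,
    n_dropped = x$n_dropped,
    ss_type = x$ss_type,
    alpha = x$alpha
  )
}
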