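#' Classify a flowering series into a Newstrom pattern class
#'
#' Newstrom's taxonomy describes flowering patterns by the frequency of
#' flowering cycles per year: "continual" (flowering with only brief,
#' sporadic pauses), "sub-annual" (more than one cycle per year), "annual"
#' (one main cycle per year) and "supra-annual" (one cycle extending over
#' more than one year). The taxonomy is qualitative; this function makes it
#' operational with explicit, tunable thresholds, which are reported back
#' with the label so a classification is always reproducible from its
#' evidence.
#'
#' Rules, applied to the population weekly bud totals:
#' * a cycle is a maximal run of flowering weeks in which consecutive
#'   flowering weeks are separated by fewer than `cycle_gap` zero weeks;
#' * `none` -- the whole series has no flowering week;
#' * `continual` -- flowering in at least `month_coverage` of the months
#'   (months are consecutive 4-week blocks, as the data model carries week
#'   indices, not calendar dates) and no pause longer than `gap_weeks`;
#'   takes precedence over the cycle-count rules;
#' * `supra-annual` -- a single cycle spanning more than one year;
#' * `annual` -- at most one cycle per year on average;
#' * `sub-annual` -- more than one cycle per year.
#'
#' @param series Numeric vector of weekly population bud totals spanning an
#'   integer number of semesters (at least one year for a meaningful label).
#' @param weeks_per_year Weeks making up one year of the grid (default 52,
#'   i.e. two 26-week semesters).
#' @param gap_weeks Longest pause (consecutive zero weeks) tolerated by the
#'   continual class. Default 4.
#' @param cycle_gap Number of consecutive zero weeks that separates two
#'   cycles. Default 8.
#' @param month_coverage Minimum fraction of months with flowering for the
#'   continual class. Default 0.8.
#' @return A one-row tibble: `label`, `n_cycles`, `cycles_per_year`,
#'   `longest_pause_weeks`, `months_flowering`, `n_months`,
#'   `month_coverage`, plus the thresholds used (`gap_weeks`, `cycle_gap`,
#'   `min_month_coverage`).
#' @export
#' @examples
#' year <- c(rep(0, 8), rep(5, 6), rep(0, 38)) # one 6-week bloom per year
#' classify_newstrom(rep(year, 2))$label # "annual"
classify_newstrom <- function(series,
                              weeks_per_year = 52,
                              gap_weeks = 4,
                              cycle_gap = 8,
                              month_coverage = 0.8) {
  if (anyNA(series) || any(series < 0)) {
    abort("series must be non-negative and NA-free")
  }
  if (gap_weeks <= 0 || cycle_gap <= 0) abort("thresholds must be positive")
  n_weeks <- length(series)
  n_years <- n_weeks / weeks_per_year

  flowering <- series > 0
  evidence <- function(label, n_cycles, longest_pause, span_max) {
    months <- split(flowering, ceiling(seq_len(n_weeks) / 4))
    months_flowering <- sum(purrr::map_lgl(months, any))
    tibble::tibble(
      label = label,
      n_cycles = n_cycles,
      cycles_per_year = if (n_years > 0) n_cycles / n_years else NA_real_,
      longest_pause_weeks = longest_pause,
      months_flowering = months_flowering,
      n_months = length(months),
      month_coverage = months_flowering / length(months),
      gap_weeks = gap_weeks,
      cycle_gap = cycle_gap,
      min_month_coverage = month_coverage
    )
  }

  if (n_weeks == 0L || !any(flowering)) {
    return(evidence("none", 0L, n_weeks, 0L))
  }

  runs <- rle(flowering)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  zero_runs <- runs$lengths[!runs$values]
  # interior pauses split cycles; edge zeros only count toward pauses
  interior <- !runs$values &
    seq_along(runs$values) > 1L &
    seq_along(runs$values) < length(runs$values)
  longest_pause <- if (length(zero_runs)) max(zero_runs) else 0L

  # group flowering runs into cycles: an interior zero run >= cycle_gap
  # starts a new cycle
  flowering_idx <- which(runs$values)
  cycle_id <- integer(length(flowering_idx))
  current <- 1L
  for (k in seq_along(flowering_idx)) {
    if (k > 1L) {
      between <- seq(flowering_idx[k - 1L] + 1L, flowering_idx[k] - 1L)
      gap <- sum(runs$lengths[between])
      if (gap >= cycle_gap) current <- current + 1L
    }
    cycle_id[k] <- current
  }
  n_cycles <- max(cycle_id)
  spans <- purrr::map_int(seq_len(n_cycles), function(cy) {
    members <- flowering_idx[cycle_id == cy]
    ends[max(members)] - starts[min(members)] + 1L
  })

  ev <- evidence("pending", n_cycles, longest_pause, max(spans))
  label <- if (ev$month_coverage >= month_coverage && longest_pause <= gap_weeks) {
    "continual"
  } else if (n_cycles == 1L && max(spans) > weeks_per_year) {
    "supra-annual"
  } else if (ev$cycles_per_year <= 1) {
    "annual"
  } else {
    "sub-annual"
  }
  ev$label <- label
  ev
}

#' Flowering-period labels for a multi-year week grid
#'
#' Years alternate a 26-week FP I semester (November--April) and a 26-week
#' FP II semester (May--October); this builds the per-week period labels for
#' [flowering_period_share()].
#'
#' @param n_years Number of years.
#' @param weeks_per_semester Weeks per semester (default 26).
#' @return Character vector of length `n_years * 2 * weeks_per_semester`.
#' @export
fp_labels <- function(n_years = 1, weeks_per_semester = 26) {
  rep(rep(c("FP I", "FP II"), each = weeks_per_semester), times = n_years)
}

#' Share of total flowering in each flowering period
#'
#' Splits a year's bud totals between the two flowering periods FP I
#' (November--April) and FP II (May--October). At low northern latitudes
#' most coffee flowering falls in FP II; above about 4 degrees N the heavier
#' blooms shift to FP I -- the shares quantify where a series sits on that
#' gradient.
#'
#' @param series Numeric vector of weekly bud totals.
#' @param periods Character vector of `"FP I"` / `"FP II"` labels, one per
#'   week (see [fp_labels()]).
#' @return A one-row tibble with `share_fp1`, `share_fp2` and `total_buds`.
#'   Shares sum to 1; both are `NA` (with a warning) when the series has no
#'   buds at all.
#' @export
#' @examples
#' flowering_period_share(c(1, 0, 9, 0), c("FP I", "FP I", "FP II", "FP II"))
flowering_period_share <- function(series, periods = fp_labels()) {
  if (length(series) != length(periods)) {
    abort("`series` and `periods` must have the same length")
  }
  if (!all(periods %in% c("FP I", "FP II"))) {
    abort("`periods` must be 'FP I' or 'FP II'")
  }
  total <- sum(series)
  if (total <= 0) {
    warn("series has no buds; flowering-period shares are undefined")
    return(tibble::tibble(
      share_fp1 = NA_real_, share_fp2 = NA_real_, total_buds = 0
    ))
  }
  s1 <- sum(series[periods == "FP I"])
  share_fp1 <- s1 / total
  tibble::tibble(
    share_fp1 = share_fp1,
    share_fp2 = 1 - share_fp1, # complements sum to 1 exactly
    total_buds = total
  )
}
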