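#' Spearman rank correlation between two weekly count series
#'
#' Rank correlation with mid-rank (average) treatment of ties, the standard
#' Spearman convention. This is the pairwise building block of the flowering
#' synchrony descriptor; no p-value is attached.
#'
#' @param x,y Numeric vectors of equal length (at least 3 weeks).
#' @return The correlation in \[-1, 1\], or `NA` when either series has zero
#'   variance (constant counts), in which case the correlation is undefined
#'   and the caller decides the policy.
#' @export
#' @examples
#' spearman_rho(c(0, 0, 3, 10, 0), c(0, 0, 5, 2, 0)) # 0.875
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("series must have equal length")
  if (length(x) < 3L) abort("series must have length >= 3")
  if (anyNA(x) || anyNA(y)) abort("series must not contain NA")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Flowering synchrony among individuals
#'
#' Synchrony (`r_i`) of a population is the average of the absolute values of
#' all pairwise Spearman correlations between the individuals' weekly
#' bud-count series. The absolute value is taken per pair before averaging,
#' so two plants flowering in perfectly opposite weeks are maximally
#' "synchronized" in the sense of sharing temporal structure; `r_i` lies in
#' \[0, 1\].
#'
#' Pairs whose correlation is undefined (a constant series) are dropped from
#' the average and reported in `n_pairs_dropped` rather than being imputed as
#' 0 or 1. After [drop_nonflowering()] such pairs are rare: they require a
#' plant flowering with equal counts every single week.
#'
#' @param cal A [floral_calendar] with at least 2 plants (apply
#'   [drop_nonflowering()] first).
#' @return A one-row tibble: `r_i`, `n_plants`, `n_pairs_used`,
#'   `n_pairs_dropped`. `r_i` is `NA` when every pair is undefined.
#' @export
synchrony_ri <- function(cal) {
  stopifnot(inherits(cal, "floral_calendar"))
  grid <- cal$counts
  n <- nrow(grid)
  if (n < 2L) {
    abort(sprintf(
      "synchrony requires >= 2 flowering plants (calendar has %d)", n
    ))
  }
  pairs <- combn(n, 2L)
  rhos <- purrr::map_dbl(
    seq_len(ncol(pairs)),
    function(k) spearman_rho(grid[pairs[1L, k], ], grid[pairs[2L, k], ])
  )
  used <- !is.na(rhos)
  tibble::tibble(
    r_i = if (any(used)) mean(abs(rhos[used])) else NA_real_,
    n_plants = n,
    n_pairs_used = sum(used),
    n_pairs_dropped = sum(!used)
  )
}

#' Coefficient of variation of one plant's weekly counts
#'
#' Standard deviation of the weekly series divided by its mean. The default
#' uses the sample standard deviation (denominator `n - 1`); the population
#' convention (denominator `n`) is available as a switch since the field is
#' not unanimous. A plant flowering in a single week out of `n` has
#' CV = sqrt(n) under the sample convention.
#'
#' @param x Numeric vector of weekly counts, length >= 2, mean > 0.
#' @param denominator `"n-1"` (sample sd, default) or `"n"` (population sd).
#' @return The coefficient of variation (dimensionless, >= 0).
#' @export
#' @examples
#' individual_cv(c(2, 0, 6, 0)) # sqrt(2)
individual_cv <- function(x, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (length(x) < 2L) abort("series must have length >= 2")
  m <- mean(x)
  if (m <= 0) {
    abort("mean must be > 0 (all-zero plants should be excluded upstream)")
  }
  s <- sd(x)
  if (denominator == "n") {
    n <- length(x)
    s <- s * sqrt((n - 1) / n)
  }
  s / m
}

#' Intraindividual temporal variability of flowering
#'
#' `CV_i` of a population is the arithmetic mean over its plants of each
#' plant's coefficient of variation of weekly bud counts across the semester
#' ([individual_cv()]). High values indicate heterogeneous, spiky flowering
#' (few high-amplitude weeks among many zero weeks); low values indicate an
#' even spread of buds across the weeks.
#'
#' @param cal A [floral_calendar] with at least 1 flowering plant.
#' @inheritParams individual_cv
#' @return The mean coefficient of variation (scalar, >= 0).
#' @export
temporal_variability_cvi <- function(cal, denominator = c("n-1", "n")) {
  stopifnot(inherits(cal, "floral_calendar"))
  denominator <- match.arg(denominator)
  if (nrow(cal$counts) < 1L) {
    abort("temporal variability requires >= 1 flowering plant")
  }
  mean(apply(cal$counts, 1L, individual_cv, denominator = denominator))
}

#' Number of flowering events of a population
#'
#' A flowering event is a week of the semester in which the accession showed
#' at least one flower bud, regardless of which individual carried it: the
#' number of week columns with a positive population total.
#'
#' @param cal A [floral_calendar].
#' @return Integer count of flowering weeks, in `[0, n_weeks]`.
#' @export
count_events <- function(cal) {
  stopifnot(inherits(cal, "floral_calendar"))
  if (nrow(cal$counts) == 0L) return(0L)
  sum(colSums(cal$counts) > 0)
}

#' Compute the descriptor table for a set of floral calendars
#'
#' Applies [drop_nonflowering()] to each calendar and assembles the response
#' table for inference: one row per population with the three phenological
#' descriptors (`r_i`, `cv_i`, `event`) alongside the grouping labels and the
#' pair bookkeeping from [synchrony_ri()]. Populations on which a descriptor
#' is undefined (fewer than 2 flowering plants, or no usable pairs) are kept
#' as flagged rows with `NA` descriptors and a reason in `note` -- never
#' silently dropped.
#'
#' @param cals A calendar tibble from [read_bud_counts()] /
#'   [simulate_study()], a list of [floral_calendar] objects, or a single
#'   calendar.
#' @inheritParams individual_cv
#' @return A tibble ordered by (department, semester, accession) with columns
#'   `department`, `semester`, `flowering_period`, `accession`, `size_class`,
#'   `r_i`, `cv_i`, `event`, `n_plants`, `n_pairs_used`, `n_pairs_dropped`,
#'   `n_removed`, `note`.
#' @export
descriptor_table <- function(cals, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  cal_list <- as_calendar_list(cals)
  rows <- purrr::map_dfr(cal_list, function(cal) {
    cal <- suppressWarnings(drop_nonflowering(cal))
    base <- tibble::tibble(
      department = cal$department,
      semester = cal$semester,
      flowering_period = cal$flowering_period,
      accession = cal$accession,
      size_class = cal$size_class,
      n_removed = cal$n_removed
    )
    n_flowering <- nrow(cal$counts)
    if (n_flowering < 2L) {
      return(dplyr::mutate(base,
        r_i = NA_real_, cv_i = NA_real_,
        event = count_events(cal),
        n_plants = n_flowering, n_pairs_used = 0L, n_pairs_dropped = 0L,
        note = sprintf("only %d flowering plant(s)", n_flowering)
      ))
    }
    sync <- synchrony_ri(cal)
    dplyr::mutate(base,
      r_i = sync$r_i,
      cv_i = temporal_variability_cvi(cal, denominator = denominator),
      event = count_events(cal),
      n_plants = sync$n_plants,
      n_pairs_used = sync$n_pairs_used,
      n_pairs_dropped = sync$n_pairs_dropped,
      note = if (is.na(sync$r_i)) "all pairs undefined" else NA_character_
    )
  })
  if (nrow(rows) == 0L) return(rows)
  rows %>%
    dplyr::arrange(.data$department, .data$semester, .data$accession) %>%
    dplyr::relocate(
      "department", "semester", "flowering_period", "accession", "size_class",
      "r_i", "cv_i", "event", "n_plants", "n_pairs_used", "n_pairs_dropped",
      "n_removed", "note"
    )
}

#' Write a descriptor table to CSV
#'
#' @param descriptors Tibble from [descriptor_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  readr::write_csv(descriptors, path, progress = FALSE)
  invisible(path)
}
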