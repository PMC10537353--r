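#' Construct a floral calendar
#'
#' A floral calendar is the unit on which phenological descriptors are
#' computed: a dense plants-by-weeks grid of non-negative integer flower-bud
#' counts for one (department, semester, accession) population, together with
#' its grouping labels. Weeks in which a plant showed no buds are stored as
#' zeros.
#'
#' @param counts Integer matrix, plants in rows and weeks in columns. Row
#'   names identify plants; missing row names are filled with `p1, p2, ...`.
#' @param department,accession Character grouping labels.
#' @param semester One of `"1st"`, `"2nd"`, `"3rd"`, `"4th"`. The flowering
#'   period is derived from it: 1st/3rd belong to FP I (November--April),
#'   2nd/4th to FP II (May--October).
#' @param size_class Plant stature class, conventionally `"LS"` (long size,
#'   tall) or `"SS"` (short size).
#'
#' @return An object of class `floral_calendar`.
#' @seealso [read_bud_counts()], [drop_nonflowering()], [descriptor_table()]
#' @export
#' @examples
#' cal <- floral_calendar(
#'   matrix(c(0, 2, 5, 0, 1, 3, 4, 0), nrow = 2, byrow = TRUE),
#'   department = "Caldas", semester = "1st", accession = "CU1812"
#' )
#' count_events(cal)
floral_calendar <- function(counts,
                            department = "site",
                            semester = "1st",
                            accession = "acc",
                            size_class = "SS") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(is.na(counts))) abort("counts must not contain NA")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(counts != floor(counts))) abort("counts must be integers")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("p", seq_len(nrow(counts)))
  }
  colnames(counts) <- NULL
  structure(
    list(
      counts = counts,
      department = as.character(department),
      semester = as.character(semester),
      flowering_period = semester_to_period(as.character(semester)),
      accession = as.character(accession),
      size_class = as.character(size_class),
      n_weeks = ncol(counts),
      n_removed = 0L,
      all_zero = all(counts == 0) && nrow(counts) > 0L
    ),
    class = "floral_calendar"
  )
}

#' @export
print.floral_calendar <- function(x, ...) {
  cat(sprintf(
    "<floral_calendar> %s / %s (%s) / %s [%s]: %d plants x %d weeks, %d buds\n",
    x$department, x$semester, x$flowering_period, x$accession, x$size_class,
    nrow(x$counts), x$n_weeks, sum(x$counts)
  ))
  if (x$n_removed > 0L) {
    cat(sprintf("  (%d non-flowering plant(s) removed)\n", x$n_removed))
  }
  invisible(x)
}

#' @export
dim.floral_calendar <- function(x) dim(x$counts)

#' Turn a floral calendar back into long-format records
#'
#' The inverse of [read_bud_counts()] for a single calendar: one row per
#' plant and week, including the zero weeks, so that writing and re-reading a
#' calendar reproduces the grid exactly.
#'
#' @param x A `floral_calendar`.
#' @param ... Unused.
#' @return A tibble with columns `department`, `semester`, `accession`,
#'   `size_class`, `plant_id`, `week`, `count`.
#' @method as_tibble floral_calendar
#' @export
as_tibble.floral_calendar <- function(x, ...) {
  grid <- x$counts
  tibble::tibble(
    department = x$department,
    semester = x$semester,
    accession = x$accession,
    size_class = x$size_class,
    plant_id = rep(rownames(grid), each = ncol(grid)),
    week = rep(seq_len(ncol(grid)), times = nrow(grid)),
    count = as.integer(t(grid))
  )
}

BUD_COUNT_COLUMNS <- c(
  "department", "semester", "accession", "size_class",
  "plant_id", "week", "count"
)

validate_bud_records <- function(df, n_weeks) {
  missing_cols <- setdiff(BUD_COUNT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  row_id <- seq_len(nrow(df))
  bad <- function(cond) row_id[which(cond)]

  not_count <- bad(is.na(df$count) | df$count < 0 | df$count != floor(df$count))
  if (length(not_count) > 0L) {
    abort(sprintf(
      "count must be a non-negative integer; offending row(s): %s",
      paste(utils::head(not_count, 5L), collapse = ", ")
    ))
  }
  bad_week <- bad(is.na(df$week) | df$week < 1 | df$week > n_weeks |
    df$week != floor(df$week))
  if (length(bad_week) > 0L) {
    abort(sprintf(
      "week must be an integer in [1, %d]; offending row(s): %s",
      n_weeks, paste(utils::head(bad_week, 5L), collapse = ", ")
    ))
  }
  key <- paste(df$department, df$semester, df$accession, df$plant_id, df$week,
    sep = "\r"
  )
  dup <- row_id[duplicated(key)]
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate (department, semester, accession, plant_id, week) key; offending row(s): %s",
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(df)
}

#' Zero-fill sparse weekly records into a plants-by-weeks grid
#'
#' Census files typically record only the weeks in which buds were seen;
#' weeks without flower buds are treated as zeros. This expands per-plant
#' (week, count) pairs into the dense grid descriptors are computed on.
#'
#' @param records Data frame with columns `plant_id`, `week`, `count`.
#' @param n_weeks Number of weeks in the flowering semester (grid width).
#' @return An integer matrix with one row per plant (in first-appearance
#'   order) and exactly `n_weeks` columns; unobserved weeks are 0.
#' @export
#' @examples
#' zero_fill(
#'   data.frame(plant_id = "a", week = c(1, 3), count = c(4, 2)),
#'   n_weeks = 4
#' )
zero_fill <- function(records, n_weeks) {
  n_weeks <- stopifnot_scalar_count(n_weeks, "n_weeks", min = 1L)
  if (any(records$week > n_weeks)) {
    abort(sprintf(
      "week index exceeds n_weeks = %d (max observed: %d)",
      n_weeks, max(records$week)
    ))
  }
  if (any(records$week < 1)) abort("week index must be >= 1")
  plants <- unique(as.character(records$plant_id))
  grid <- matrix(0, nrow = length(plants), ncol = n_weeks,
    dimnames = list(plants, NULL)
  )
  grid[cbind(
    match(as.character(records$plant_id), plants),
    as.integer(records$week)
  )] <- records$count
  storage.mode(grid) <- "double"
  grid
}

#' Read a long-format flower-bud census into floral calendars
#'
#' Reads a CSV of weekly flower-bud counts (one row per plant and week;
#' header `department,semester,accession,size_class,plant_id,week,count`),
#' validates it, and groups the records into one [floral_calendar] per
#' (department, semester, accession) population. Unrecorded weeks are
#' zero-filled, and the flowering period (FP I / FP II) is derived from the
#' semester label.
#'
#' Validation failures -- a missing column, a negative or non-integer count,
#' a week outside `[1, n_weeks]`, or a duplicated (plant, week) key within a
#' population -- raise an error naming the offending data row(s).
#'
#' @param path Path to the CSV file (or a data frame already in that layout).
#' @param n_weeks Number of weeks per flowering semester; defaults to 26
#'   (a six-month November--April or May--October semester).
#' @return A tibble with one row per population: grouping-label columns plus
#'   a `calendar` list-column of [floral_calendar] objects, ordered by
#'   (department, semester, accession).
#' @export
read_bud_counts <- function(path, n_weeks = 26) {
  n_weeks <- stopifnot_scalar_count(n_weeks, "n_weeks", min = 1L)
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_bud_records(df, n_weeks)
  semester_to_period(unique(df$semester)) # validates labels

  df %>%
    dplyr::group_by(.data$department, .data$semester, .data$accession) %>%
    dplyr::group_modify(function(g, key) {
      size_class <- unique(g$size_class)
      if (length(size_class) > 1L) {
        abort(sprintf(
          "population %s/%s/%s mixes size classes: %s",
          key$department, key$semester, key$accession,
          paste(size_class, collapse = ", ")
        ))
      }
      cal <- floral_calendar(
        zero_fill(g, n_weeks),
        department = key$department, semester = key$semester,
        accession = key$accession, size_class = size_class
      )
      tibble::tibble(
        flowering_period = cal$flowering_period,
        size_class = size_class,
        calendar = list(cal)
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$department, .data$semester, .data$accession) %>%
    dplyr::relocate(
      "department", "semester", "flowering_period", "accession", "size_class"
    )
}

#' Write floral calendars as a long-format census CSV
#'
#' @param cals A calendar tibble from [read_bud_counts()], a list of
#'   [floral_calendar] objects, or a single calendar.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bud_counts <- function(cals, path) {
  long <- purrr::map_dfr(as_calendar_list(cals), as_tibble.floral_calendar)
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

# Accept the nested tibble, a bare list, or a single calendar.
as_calendar_list <- function(cals) {
  if (inherits(cals, "floral_calendar")) return(list(cals))
  if (is.data.frame(cals)) {
    if (!"calendar" %in% names(cals)) {
      abort("expected a `calendar` list-column (as returned by read_bud_counts())")
    }
    return(cals$calendar)
  }
  if (is.list(cals)) return(cals)
  abort("cannot interpret `cals` as floral calendars")
}

#' Remove plants that never flowered in the semester
#'
#' Individuals that did not flower during a semester carry no information
#' about synchrony or within-plant variability and are excluded before
#' descriptors are computed. The number of removed plants is kept on the
#' calendar (`$n_removed`), and a calendar whose plants were all zero comes
#' back empty with its `all_zero` flag set (plus a warning).
#'
#' The operation is idempotent: applying it twice changes nothing.
#'
#' @param cal A [floral_calendar].
#' @return The calendar with all-zero plant rows removed.
#' @export
drop_nonflowering <- function(cal) {
  stopifnot(inherits(cal, "floral_calendar"))
  keep <- rowSums(cal$counts) > 0
  removed <- sum(!keep)
  cal$counts <- cal$counts[keep, , drop = FALSE]
  cal$n_removed <- cal$n_removed + as.integer(removed)
  cal$all_zero <- nrow(cal$counts) == 0L && cal$n_removed > 0L
  if (cal$all_zero && removed > 0L) {
    warn(sprintf(
      "calendar %s/%s/%s: no plant flowered; calendar is empty",
      cal$department, cal$semester, cal$accession
    ))
  }
  cal
}
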