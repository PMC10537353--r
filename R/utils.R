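# Small shared helpers. Nothing here is exported.

# Round half away from zero at `digits` decimals. Base round() rounds half to
# even, which disagrees with the printed climate means (e.g. 16.45 -> 16.5);
# the small epsilon guards against 28.35 being stored as 28.34999....
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Semesters 1st/3rd fall in FP I (November-April), 2nd/4th in FP II
# (May-October).
SEMESTER_LEVELS <- c("1st", "2nd", "3rd", "4th")

semester_to_period <- function(semester) {
  if (!all(semester %in% SEMESTER_LEVELS)) {
    bad <- setdiff(unique(semester), SEMESTER_LEVELS)
    abort(sprintf(
      "unknown semester label(s): %s (expected %s)",
      paste(bad, collapse = ", "), paste(SEMESTER_LEVELS, collapse = ", ")
    ))
  }
  ifelse(semester %in% c("1st", "3rd"), "FP I", "FP II")
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
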