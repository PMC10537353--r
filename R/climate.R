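# Built-in climate fixture: per-semester weather summaries for the four
# Colombian study departments (Cesar = northern, Caldas and Quindio =
# central, Cauca = southern coffee zone), as published for the census
# period. One caveat is preserved as-is: the source prints the daylength
# column (accumulated light hours) with W m^-2 units, an inconsistency we
# store without correcting.

CLIMATE_VARIABLES <- c(
  "temp_mean", "temp_max", "temp_min",
  "insolation", "daylength", "rainfall", "days_rain"
)

# printed precision per variable: 1 decimal for temperatures, integers
# for the accumulated/count variables
climate_digits <- function(variable) {
  if (variable %in% c("temp_mean", "temp_max", "temp_min")) 1L else 0L
}

climate_file <- function(which = c("semesters", "means")) {
  which <- match.arg(which)
  system.file("extdata", paste0("climate_", which, ".csv"),
    package = "floracal", mustWork = TRUE
  )
}

#' Semester climate summaries of the four study departments
#'
#' Returns the built-in table of per-semester climate conditions at the four
#' experimental stations: mean/maximum/minimum air temperature (degrees C),
#' accumulated daily insolation (W m^-2), accumulated light hours
#' (daylength), accumulated rainfall (mm) and number of days with rain, for
#' each of the four flowering semesters. 16 records: 4 departments x 4
#' semesters.
#'
#' @param department Optional department filter (`"Cesar"`, `"Caldas"`,
#'   `"Quindio"`, `"Cauca"`); an unknown department is an error.
#' @return A tibble with columns `department`, `semester` and the seven
#'   climate variables.
#' @export
#' @examples
#' load_climate_table("Cesar")$rainfall
load_climate_table <- function(department = NULL) {
  tab <- readr::read_csv(climate_file("semesters"),
    show_col_types = FALSE, progress = FALSE
  )
  if (!is.null(department)) {
    if (!department %in% tab$department) {
      abort(sprintf(
        "unknown department '%s'; available: %s",
        department, paste(unique(tab$department), collapse = ", ")
      ))
    }
    tab <- tab[tab$department == department, , drop = FALSE]
  }
  tab
}

#' Published departmental climate means
#'
#' The departmental "Mean" summary rows as published, one per department.
#' [climate_semester_means()] recomputes these from the semester rows.
#'
#' @return A tibble with `department` and the seven climate variables.
#' @export
climate_published_means <- function() {
  readr::read_csv(climate_file("means"), show_col_types = FALSE, progress = FALSE)
}

#' Recompute a departmental climate mean from the semester records
#'
#' Arithmetic mean of the four semester values of one variable, rounded
#' half away from zero to the published precision (one decimal for the
#' temperatures, integers for insolation, daylength, rainfall and days with
#' rain). With half-away-from-zero rounding every recomputed mean matches
#' the published summary row exactly.
#'
#' @param department One of the four departments.
#' @param variable One of `temp_mean`, `temp_max`, `temp_min`, `insolation`,
#'   `daylength`, `rainfall`, `days_rain`.
#' @param round Round to the published precision (default `TRUE`); set
#'   `FALSE` for the raw arithmetic mean.
#' @return A single number.
#' @export
#' @examples
#' climate_semester_means("Cesar", "rainfall") # 1090
climate_semester_means <- function(department, variable, round = TRUE) {
  if (!variable %in% CLIMATE_VARIABLES) {
    abort(sprintf(
      "unknown variable '%s'; available: %s",
      variable, paste(CLIMATE_VARIABLES, collapse = ", ")
    ))
  }
  tab <- load_climate_table(department)
  m <- mean(tab[[variable]])
  if (round) round_half_up(m, climate_digits(variable)) else m
}
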