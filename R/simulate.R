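#' Regime parameters for the stochastic flowering-calendar generator
#'
#' A regime is a phenomenological description of how a population flowers in
#' one semester: a schedule of population-level event weeks, a per-plant
#' participation probability for each event, Gaussian timing jitter, and a
#' lognormal amplitude model. It deliberately carries no climate mechanism;
#' it is the minimal generative model that reproduces the pulsed, zero-heavy
#' weekly count series seen in flower-bud censuses.
#'
#' For each plant `i` and event `e`: the plant participates with probability
#' `participation`; its event week is the scheduled week plus rounded
#' `Normal(0, jitter_sd)` jitter, clamped to `[1, n_weeks]` (semesters do not
#' wrap); its bud count is `round(s_i * m_e * eps)` with plant scale
#' `s_i ~ LogNormal(0, plant_scale_sigma)` shared across the semester, event
#' magnitude `m_e ~ LogNormal(amplitude_mu, amplitude_sigma)` shared across
#' plants, and multiplicative noise `eps ~ LogNormal(0, noise_sd)`. Counts
#' landing on the same week are summed. Rounding is half away from zero.
#'
#' @param n_weeks Weeks per semester (default 26).
#' @param event_weeks Integer vector of scheduled event weeks in
#'   `[1, n_weeks]`.
#' @param participation Probability in \[0, 1\] that a plant joins an event.
#' @param jitter_sd Timing jitter standard deviation in weeks (>= 0).
#' @param amplitude_mu,amplitude_sigma Log-scale mean and sd of event
#'   magnitudes.
#' @param plant_scale_sigma Log-scale sd of the per-plant multiplier.
#' @param noise_sd Log-scale sd of per-count noise; 0 switches noise off.
#' @param active_periods Flowering periods in which the regime produces
#'   buds; semesters of an inactive period yield all-zero calendars (the
#'   annual pattern flowers only in FP I).
#' @return A `regime_params` list.
#' @seealso [regime_preset()], [simulate_calendar()]
#' @export
regime_params <- function(n_weeks = 26,
                          event_weeks,
                          participation = 1,
                          jitter_sd = 0,
                          amplitude_mu = log(50),
                          amplitude_sigma = 0.5,
                          plant_scale_sigma = 0.5,
                          noise_sd = 0.1,
                          active_periods = c("FP I", "FP II")) {
  n_weeks <- stopifnot_scalar_count(n_weeks, "n_weeks", min = 1L)
  event_weeks <- sort(unique(as.integer(event_weeks)))
  if (length(event_weeks) == 0L) abort("need at least one event week")
  if (any(event_weeks < 1L | event_weeks > n_weeks)) {
    abort(sprintf("event_weeks must lie in [1, %d]", n_weeks))
  }
  if (participation < 0 || participation > 1) {
    abort("participation must be in [0, 1]")
  }
  if (jitter_sd < 0 || amplitude_sigma < 0 || plant_scale_sigma < 0 ||
    noise_sd < 0) {
    abort("sd parameters must be >= 0")
  }
  if (!all(active_periods %in% c("FP I", "FP II")) ||
    length(active_periods) == 0L) {
    abort("active_periods must be a subset of {'FP I', 'FP II'}")
  }
  structure(
    list(
      n_weeks = n_weeks, event_weeks = event_weeks,
      participation = participation, jitter_sd = jitter_sd,
      amplitude_mu = amplitude_mu, amplitude_sigma = amplitude_sigma,
      plant_scale_sigma = plant_scale_sigma, noise_sd = noise_sd,
      active_periods = active_periods
    ),
    class = "regime_params"
  )
}

#' Flowering-regime presets for the Colombian coffee zones
#'
#' Three named parameterizations spanning the observed range of flowering
#' behaviour:
#' * `"annual-north"` -- the northern-zone (Cesar-like) annual pattern: two
#'   high-amplitude, tightly synchronized events one month apart, flowering
#'   confined to FP I semesters;
#' * `"continual-central"` -- the central-zone (Caldas/Quindio-like)
#'   continual pattern: fifteen lower-amplitude events spread over the
#'   whole semester, moderate jitter, in both flowering periods;
#' * `"continual-south"` -- the southern-zone (Cauca-like) continual
#'   pattern: seven events with low jitter, reflecting the higher synchrony
#'   of the cooler site.
#'
#' @param name One of `"annual-north"`, `"continual-central"`,
#'   `"continual-south"`.
#' @return A [regime_params()] object.
#' @export
#' @examples
#' length(regime_preset("annual-north")$event_weeks) # 2
regime_preset <- function(name) {
  presets <- list(
    "annual-north" = regime_params(
      event_weeks = c(9, 13),
      participation = 0.95, jitter_sd = 0.6,
      amplitude_mu = log(150), amplitude_sigma = 0.6,
      plant_scale_sigma = 0.5, noise_sd = 0.1,
      active_periods = "FP I"
    ),
    "continual-central" = regime_params(
      event_weeks = round_half_up(seq(1, 26, length.out = 15)),
      participation = 0.8, jitter_sd = 1.0,
      amplitude_mu = log(30), amplitude_sigma = 0.5,
      plant_scale_sigma = 0.5, noise_sd = 0.1
    ),
    "continual-south" = regime_params(
      event_weeks = round_half_up(seq(2, 25, length.out = 7)),
      participation = 0.85, jitter_sd = 0.5,
      amplitude_mu = log(60), amplitude_sigma = 0.5,
      plant_scale_sigma = 0.5, noise_sd = 0.1
    )
  )
  if (!name %in% names(presets)) {
    abort(sprintf(
      "unknown preset '%s'; valid presets: %s",
      name, paste(names(presets), collapse = ", ")
    ))
  }
  presets[[name]]
}

# Draw one plants x weeks grid using the *current* RNG state. All public
# entry points seed via withr::with_seed so no global state leaks.
sim_grid <- function(regime, n_plants, active = TRUE) {
  grid <- matrix(0, nrow = n_plants, ncol = regime$n_weeks,
    dimnames = list(paste0("p", seq_len(n_plants)), NULL)
  )
  if (!active) return(grid)
  s_i <- rlnorm(n_plants, 0, regime$plant_scale_sigma)
  m_e <- rlnorm(length(regime$event_weeks), regime$amplitude_mu,
    regime$amplitude_sigma
  )
  for (e in seq_along(regime$event_weeks)) {
    takes_part <- rbinom(n_plants, 1L, regime$participation) == 1L
    jitter <- round(rnorm(n_plants, 0, regime$jitter_sd))
    eps <- if (regime$noise_sd > 0) rlnorm(n_plants, 0, regime$noise_sd) else rep(1, n_plants)
    weeks <- pmin(pmax(regime$event_weeks[e] + jitter, 1L), regime$n_weeks)
    counts <- round_half_up(s_i * m_e[e] * eps)
    for (i in which(takes_part)) {
      grid[i, weeks[i]] <- grid[i, weeks[i]] + counts[i]
    }
  }
  grid
}

#' Simulate one semester's floral calendar
#'
#' Draws a plants-by-weeks grid from a flowering regime (see
#' [regime_params()] for the generative model). The same
#' (regime, n_plants, seed) always yields the identical calendar; all
#' randomness flows through the supplied seed and the global RNG state is
#' left untouched.
#'
#' @param regime A [regime_params()] object or a preset name.
#' @param n_plants Number of plants (>= 2; descriptors need pairs).
#' @param seed Integer seed.
#' @param department,semester,accession,size_class Labels attached to the
#'   calendar. If the semester's flowering period is not among the regime's
#'   `active_periods`, the calendar is all zeros.
#' @return A [floral_calendar].
#' @export
simulate_calendar <- function(regime, n_plants, seed,
                              department = "sim", semester = "1st",
                              accession = "acc", size_class = "SS") {
  if (is.character(regime)) regime <- regime_preset(regime)
  stopifnot(inherits(regime, "regime_params"))
  n_plants <- stopifnot_scalar_count(n_plants, "n_plants", min = 2L)
  period <- semester_to_period(semester)
  grid <- withr::with_seed(
    seed,
    sim_grid(regime, n_plants, active = period %in% regime$active_periods)
  )
  floral_calendar(grid,
    department = department, semester = semester,
    accession = accession, size_class = size_class
  )
}

#' Simulate a multi-year population flowering series
#'
#' Concatenates alternating FP I / FP II semesters (26 weeks each) into a
#' year-spanning weekly series of population bud totals, the input expected
#' by [classify_newstrom()] and [flowering_period_share()]. Regimes whose
#' `active_periods` exclude FP II (the annual pattern) are silent in those
#' semesters.
#'
#' @inheritParams simulate_calendar
#' @param n_years Number of years (2 semesters each).
#' @return A tibble with one row per week: `week` (1-based over the whole
#'   series), `year`, `period` (`"FP I"`/`"FP II"`), `total` (population
#'   weekly bud total).
#' @export
simulate_series <- function(regime, n_plants, seed, n_years = 2) {
  if (is.character(regime)) regime <- regime_preset(regime)
  stopifnot(inherits(regime, "regime_params"))
  n_plants <- stopifnot_scalar_count(n_plants, "n_plants", min = 2L)
  n_years <- stopifnot_scalar_count(n_years, "n_years", min = 1L)
  totals <- withr::with_seed(seed, {
    purrr::map(seq_len(n_years), function(yr) {
      purrr::map(c("FP I", "FP II"), function(period) {
        colSums(sim_grid(regime, n_plants,
          active = period %in% regime$active_periods
        ))
      })
    })
  })
  tibble::tibble(
    week = seq_len(n_years * 2L * regime$n_weeks),
    year = rep(seq_len(n_years), each = 2L * regime$n_weeks),
    period = rep(fp_labels(1, regime$n_weeks), times = n_years),
    total = unlist(totals)
  )
}

#' Define a simulated census study
#'
#' A study design crosses departments (each with its own flowering regime)
#' with four flowering semesters and a set of accessions, with a per-cell
#' number of plants drawn uniformly from `plants_per_cell` -- mirroring
#' field censuses where 5--20 individuals per accession survive to be
#' scored. Optional `effects` inject per-(department, semester) shifts of
#' regime parameters so that power and calibration of the inference stage
#' can be studied against known truth; with no effects and a shared regime,
#' the design is a null.
#'
#' @param regimes Named list mapping department name to a
#'   [regime_params()] object or preset name.
#' @param accessions Character vector of accession labels.
#' @param size_classes Optional named character vector mapping accession to
#'   `"LS"`/`"SS"`; defaults to `"SS"` for all.
#' @param semesters Semester labels (default all four).
#' @param plants_per_cell Integer range `c(min, max)` (default `c(5, 20)`)
#'   or a single fixed count.
#' @param effects Optional tibble with columns `department`, `semester` and
#'   any of `jitter_add`, `amplitude_mu_add`, `participation_add`; matching
#'   cells have those regime parameters shifted (participation is clamped
#'   to \[0, 1\], jitter floored at 0).
#' @return A `study_design` list, to be passed to [simulate_study()].
#' @export
study_design <- function(regimes,
                         accessions = paste0("ACC", 1:5),
                         size_classes = NULL,
                         semesters = c("1st", "2nd", "3rd", "4th"),
                         plants_per_cell = c(5, 20),
                         effects = NULL) {
  if (is.null(names(regimes)) || any(names(regimes) == "")) {
    abort("`regimes` must be a named list (department -> regime)")
  }
  regimes <- purrr::map(regimes, function(r) {
    if (is.character(r)) regime_preset(r) else r
  })
  if (length(plants_per_cell) == 1L) {
    plants_per_cell <- rep(plants_per_cell, 2L)
  }
  if (plants_per_cell[1L] < 2L) {
    abort("plants_per_cell must be >= 2 (descriptors require pairs)")
  }
  semester_to_period(semesters)
  if (is.null(size_classes)) {
    size_classes <- stats::setNames(rep("SS", length(accessions)), accessions)
  }
  if (!is.null(effects)) {
    stopifnot(all(c("department", "semester") %in% names(effects)))
  }
  structure(
    list(
      regimes = regimes, accessions = accessions,
      size_classes = size_classes, semesters = semesters,
      plants_per_cell = as.integer(plants_per_cell), effects = effects
    ),
    class = "study_design"
  )
}

apply_effects <- function(regime, effects, department, semester) {
  if (is.null(effects)) return(regime)
  hit <- effects[effects$department == department &
    effects$semester == semester, , drop = FALSE]
  if (nrow(hit) == 0L) return(regime)
  if (nrow(hit) > 1L) abort("multiple effect rows for one (department, semester)")
  if ("jitter_add" %in% names(hit)) {
    regime$jitter_sd <- max(0, regime$jitter_sd + hit$jitter_add)
  }
  if ("amplitude_mu_add" %in% names(hit)) {
    regime$amplitude_mu <- regime$amplitude_mu + hit$amplitude_mu_add
  }
  if ("participation_add" %in% names(hit)) {
    regime$participation <- min(1, max(0, regime$participation + hit$participation_add))
  }
  regime
}

#' Simulate a full census study
#'
#' Generates one [floral_calendar] per (department, semester, accession)
#' cell of a [study_design()], together with a truth table of the realized
#' generating parameters for each cell so that descriptor estimates can be
#' compared against what generated them. The same (design, seed) always
#' reproduces the identical study.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A list with `calendars` (nested tibble in the layout of
#'   [read_bud_counts()]) and `truth` (one row per cell: labels, n_plants
#'   and the regime parameters after effect injection).
#' @export
simulate_study <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  cells <- tidyr::expand_grid(
    department = names(design$regimes),
    semester = design$semesters,
    accession = design$accessions
  )
  withr::with_seed(seed, {
    out <- purrr::pmap(cells, function(department, semester, accession) {
      regime <- apply_effects(
        design$regimes[[department]], design$effects, department, semester
      )
      n_plants <- if (design$plants_per_cell[1L] == design$plants_per_cell[2L]) {
        design$plants_per_cell[1L]
      } else {
        sample(design$plants_per_cell[1L]:design$plants_per_cell[2L], 1L)
      }
      period <- semester_to_period(semester)
      grid <- sim_grid(regime, n_plants,
        active = period %in% regime$active_periods
      )
      cal <- floral_calendar(grid,
        department = department, semester = semester,
        accession = accession,
        size_class = unname(design$size_classes[accession])
      )
      truth <- tibble::tibble(
        department = department, semester = semester, accession = accession,
        n_plants = n_plants,
        n_events = length(regime$event_weeks),
        participation = regime$participation,
        jitter_sd = regime$jitter_sd,
        amplitude_mu = regime$amplitude_mu,
        active = period %in% regime$active_periods
      )
      list(cal = cal, truth = truth)
    })
    calendars <- cells %>%
      dplyr::mutate(
        flowering_period = semester_to_period(.data$semester),
        size_class = unname(design$size_classes[.data$accession]),
        calendar = purrr::map(out, "cal")
      ) %>%
      dplyr::relocate(
        "department", "semester", "flowering_period", "accession", "size_class"
      )
    list(
      calendars = calendars,
      truth = purrr::map_dfr(out, "truth")
    )
  })
}
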