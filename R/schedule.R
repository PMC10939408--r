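# Weekly schedules, simulation units and the simulation parameter grid.
# Days of the week are integers 1 (Monday) .. 7 (Sunday); the week clock runs
# in minutes from Monday 00:00 and every session starts at minute 0 of its
# scheduled day.

#' Weekly dialysis schedule
#'
#' A schedule is the set of week days on which dialysis sessions are run,
#' together with the day on which kinetic blood samples are drawn
#' (`labdayofwk`). The lab day must be a dialysis day, so that the
#' interdialytic interval preceding the sampled session is well defined.
#'
#' @param days Integer vector, a subset of `1:7` (1 = Monday), the dialysis
#'   days. Duplicates are an error.
#' @param labdayofwk Integer, the blood-sampling day; must be one of `days`.
#'   Defaults to the first dialysis day.
#'
#' @return An object of class `weekly_schedule` with elements `days`
#'   (sorted), `labdayofwk` and `frequency` (number of sessions per week).
#' @examples
#' weekly_schedule(c(1, 3, 5), labdayofwk = 1)
#' @seealso [parse_schedule()] for the compact digit-string form.
#' @export
weekly_schedule <- function(days, labdayofwk = days[1]) {
  days <- as.integer(days)
  if (length(days) < 1L || length(days) > 7L)
    stop("a schedule must have between 1 and 7 dialysis days")
  if (any(is.na(days)) || any(days < 1L | days > 7L))
    stop("dialysis days must be integers between 1 (Monday) and 7 (Sunday)")
  if (anyDuplicated(days))
    stop("duplicate dialysis days in schedule")
  days <- sort(days)
  labdayofwk <- as.integer(labdayofwk)
  if (length(labdayofwk) != 1L || is.na(labdayofwk) || !(labdayofwk %in% days))
    stop("labdayofwk must be one of the dialysis days")
  structure(
    list(days = days, labdayofwk = labdayofwk, frequency = length(days)),
    class = "weekly_schedule"
  )
}

#' Parse a digit-string schedule
#'
#' Schedules are conventionally written as a string of unique digits, e.g.
#' `"135"` for Monday/Wednesday/Friday, three sessions a week.
#'
#' @param sequence Character scalar of unique digits in `1..7`.
#' @param labdayofwk Blood-sampling day; must be one of the digits.
#' @return A [weekly_schedule()].
#' @examples
#' parse_schedule("135", 1)
#' @export
parse_schedule <- function(sequence, labdayofwk) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 1L)
    stop("sequence must be a non-empty digit string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% as.character(1:7)))
    stop("schedule digits must all be in 1..7")
  weekly_schedule(as.integer(chars), labdayofwk)
}

#' @export
print.weekly_schedule <- function(x, ...) {
  cat(sprintf("Weekly schedule: days %s (%d/week), lab day %d\n",
              paste(x$days, collapse = ""), x$frequency, x$labdayofwk))
  invisible(x)
}

#' Interdialytic intervals of a schedule
#'
#' Gaps (minutes) between the end of one session and the start of the next,
#' ordered so that the first entry is the interval preceding the lab-day
#' session. Under the session-clock convention (sessions start at minute 0 of
#' their day) a gap is `1440 * day_difference - Td` of the preceding session.
#' The gaps plus the session durations always close the 10080-minute week.
#'
#' @param schedule A [weekly_schedule()].
#' @param Td Session length(s) in minutes, recycled to the number of sessions.
#' @return Numeric vector of gaps (minutes), first entry before the lab day.
#' @examples
#' interdialytic_intervals(parse_schedule("135", 1), Td = 150)
#' @export
interdialytic_intervals <- function(schedule, Td) {
  stopifnot(inherits(schedule, "weekly_schedule"))
  f <- schedule$frequency
  Td <- rep_len(as.numeric(Td), f)
  if (any(Td <= 0)) stop("Td must be positive")
  days <- schedule$days
  prev <- c(f, seq_len(f - 1L))[seq_len(f)]
  ddays <- days - days[prev]
  ddays[ddays <= 0] <- ddays[ddays <= 0] + 7L
  gaps <- 1440 * ddays - Td[prev]
  if (any(gaps < 0))
    stop("session length exceeds an interdialytic interval")
  k <- match(schedule$labdayofwk, days)
  ord <- ((seq_len(f) + k - 2L) %% f) + 1L
  gaps[ord]
}

#' Simulation unit: a (schedule, lab-day) pair
#'
#' The unit of the simulation plan: coefficients of the simplified stdKt/V
#' formula are derived separately for every combination of treatment schedule
#' and blood-sampling day.
#'
#' @param schedule A [weekly_schedule()].
#' @return Object of class `simulation_unit` with `schedule` and a unique
#'   `id` of the form `"<digits>-<labday>"`.
#' @export
simulation_unit <- function(schedule) {
  stopifnot(inherits(schedule, "weekly_schedule"))
  id <- paste0(paste(schedule$days, collapse = ""), "-", schedule$labdayofwk)
  structure(list(schedule = schedule, id = id), class = "simulation_unit")
}

#' @export
print.simulation_unit <- function(x, ...) {
  cat(sprintf("Simulation unit %s (%d sessions/week)\n",
              x$id, x$schedule$frequency))
  invisible(x)
}

# Canonical day patterns, one per weekly frequency. 135 and 12345 follow
# common clinical usage; 14 and 1357 give maximal even spacing; frequencies
# 6 and 7 are forced.
.canonical_patterns <- c("1", "14", "135", "1357", "12345", "123456", "1234567")

#' Canonical simulation units
#'
#' The seven practical units used for the simplified coefficient table: one
#' schedule per weekly frequency 1..7, all with blood sampling on Monday
#' (`labdayofwk = 1`).
#'
#' @return List of 7 [simulation_unit()] objects, ordered by frequency.
#' @examples
#' length(canonical_units())
#' @export
canonical_units <- function() {
  lapply(.canonical_patterns, function(p) simulation_unit(parse_schedule(p, 1L)))
}

#' Default configuration for the extended unit list
#'
#' Day patterns per weekly frequency and admissible lab days. The default is
#' an approximation of a full realistic plan: a few common patterns per
#' frequency, with every dialysis day admissible as lab day.
#'
#' @return A list with elements `patterns` (list of digit strings per
#'   frequency `"1"`..`"7"`) and `labdays` (`"all"` or a list of integer
#'   vectors parallel to `patterns`).
#' @export
default_unit_config <- function() {
  list(
    patterns = list(
      `1` = "1",
      `2` = c("14", "15"),
      `3` = c("135", "146", "246"),
      `4` = c("1357", "1346"),
      `5` = c("12345", "13457"),
      `6` = c("123456", "123457"),
      `7` = "1234567"
    ),
    labdays = "all"
  )
}

#' Extended simulation-unit list
#'
#' Expands a configuration of day patterns and admissible lab days into a
#' deduplicated list of simulation units. The default configuration is an
#' approximation of a comprehensive plan covering realistic schedule /
#' lab-day combinations; the exact count depends on the configuration.
#'
#' @param config A configuration as returned by [default_unit_config()].
#' @return List of unique [simulation_unit()] objects.
#' @examples
#' length(extended_units(list(patterns = list(`3` = "135"), labdays = "all")))
#' @export
extended_units <- function(config = default_unit_config()) {
  stopifnot(is.list(config), !is.null(config$patterns))
  units <- list()
  for (freq in names(config$patterns)) {
    pats <- config$patterns[[freq]]
    for (j in seq_along(pats)) {
      p <- pats[[j]]
      days <- as.integer(strsplit(as.character(p), "")[[1L]])
      lds <- if (identical(config$labdays, "all")) days
             else intersect(as.integer(config$labdays[[freq]][[j]]), days)
      for (ld in lds) {
        u <- simulation_unit(weekly_schedule(days, ld))
        units[[u$id]] <- u
      }
    }
  }
  unname(units)
}

#' Simulation parameter grid for one unit
#'
#' The full-factorial parameter grid simulated for a unit when deriving its
#' coefficients: residual kidney clearance (Kru), dialyser clearance (Kd),
#' urea generation rate (G) and session length (Td) are crossed while the
#' urea distribution volume, blood and dialysate flows and the weekly
#' ultrafiltration volume are held fixed. The default axes give
#' 4 x 5 x 6 x 4 = 480 points; weekly UF is 10 L except for once-weekly
#' schedules, where 1 L is used for realism.
#'
#' Iteration order is deterministic: Kru varies slowest, then Kd, then G,
#' with Td innermost.
#'
#' @param unit A [simulation_unit()].
#' @param Kru,Kd,G,Td Axis values (mL/min, mL/min, mg/min, min).
#' @param V Fixed urea distribution volume, mL.
#' @param Qb,Qd Fixed blood / dialysate flow rates, mL/min (informational).
#' @param weekly_uf Weekly ultrafiltration volume, mL. Default 10000, or
#'   1000 for a once-weekly unit.
#' @return Object of class `parameter_grid`: list with `unit`, `fixed`,
#'   `axes` and `points` (a data frame with one row per grid point).
#' @examples
#' g <- build_parameter_grid(canonical_units()[[5]])
#' nrow(g$points)
#' @export
build_parameter_grid <- function(unit,
                                 Kru = c(0, 2, 4, 6),
                                 Kd = seq(100, 200, by = 25),
                                 G = seq(2.78, 9.76, length.out = 6),
                                 Td = c(120, 150, 180, 200),
                                 V = 35000, Qb = 350, Qd = 180,
                                 weekly_uf = NULL) {
  stopifnot(inherits(unit, "simulation_unit"))
  for (ax in list(Kru, Kd, G, Td))
    if (length(ax) < 1L || any(!is.finite(ax))) stop("empty or non-finite grid axis")
  if (any(Kru < 0) || any(Kd < 0) || any(G < 0) || any(Td <= 0))
    stop("invalid axis values")
  if (is.null(weekly_uf))
    weekly_uf <- if (unit$schedule$frequency == 1L) 1000 else 10000
  pts <- expand.grid(Td = Td, G = G, Kd = Kd, Kru = Kru,
                     KEEP.OUT.ATTRS = FALSE)
  pts <- pts[, c("Kru", "Kd", "G", "Td")]
  rownames(pts) <- NULL
  structure(
    list(unit = unit,
         fixed = list(V = V, Qb = Qb, Qd = Qd, weekly_uf = weekly_uf),
         axes = list(Kru = Kru, Kd = Kd, G = G, Td = Td),
         points = pts),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("Parameter grid for unit %s: %d points (V = %g L, weekly UF = %g L)\n",
              x$unit$id, nrow(x$points), x$fixed$V / 1000,
              x$fixed$weekly_uf / 1000))
  invisible(x)
}

#' Export a parameter grid as a plain table
#'
#' One row per grid point with the unit id and all fixed parameters attached,
#' suitable for CSV export.
#'
#' @param grid A [build_parameter_grid()] result.
#' @return A data frame.
#' @export
grid_table <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  cbind(
    data.frame(unit_id = grid$unit$id,
               V = grid$fixed$V, Qb = grid$fixed$Qb, Qd = grid$fixed$Qd,
               weekly_uf = grid$fixed$weekly_uf),
    grid$points
  )
}
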