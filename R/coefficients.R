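# Coefficients of the simplified stdKt/V formula
#   stdKt/V = a + b * KRUn + c * eKt/V
# derived per simulation unit by OLS over the simulated parameter grid, and
# the canonical published constants for the seven Monday-lab-day units.

# Canonical constants, one row per weekly frequency (lab day Monday).
.CANONICAL <- data.frame(
  frequency = 1:7,
  unit_id = paste0(c("1", "14", "135", "1357", "12345", "123456", "1234567"),
                   "-1"),
  a = c(0.126, 0.234, 0.324, 0.471, 0.358, 0.565, 0.827),
  b = c(0.288, 0.288, 0.288, 0.288, 0.289, 0.289, 0.289),
  c = c(0.543, 1.201, 1.781, 2.335, 3.098, 3.604, 4.089),
  stringsAsFactors = FALSE
)

.coefficient_set <- function(unit_id, a, b, c, fit_r2 = NA_real_,
                             n_points = NA_integer_, provenance = "derived") {
  structure(
    list(unit_id = unit_id, a = a, b = b, c = c,
         fit_r2 = fit_r2, n_points = n_points, provenance = provenance),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("Coefficients [%s] %s: a = %.3f, b = %.3f, c = %.3f",
              x$provenance, x$unit_id, x$a, x$b, x$c))
  if (!is.na(x$fit_r2))
    cat(sprintf(" (R2 = %.4f, n = %d)", x$fit_r2, x$n_points))
  cat("\n")
  invisible(x)
}

#' Canonical coefficients for a weekly frequency
#'
#' The published (a, b, c) constants of the simplified formula for the
#' seven Monday-lab-day units, one per treatment frequency 1..7 sessions a
#' week. These constants are what the prescription engine uses by default.
#'
#' @param frequency Integer in 1..7.
#' @return A `coefficient_set`.
#' @examples
#' canonical_coefficients(5)
#' @export
canonical_coefficients <- function(frequency) {
  frequency <- as.integer(frequency)
  if (length(frequency) != 1L || is.na(frequency) ||
      frequency < 1L || frequency > 7L)
    stop("frequency must be an integer between 1 and 7")
  row <- .CANONICAL[frequency, ]
  .coefficient_set(row$unit_id, row$a, row$b, row$c, provenance = "canonical")
}

#' Canonical coefficient table
#'
#' All seven canonical coefficient rows as a data frame (class
#' `coefficient_table`), ordered by frequency.
#'
#' @return Data frame with columns `frequency`, `unit_id`, `a`, `b`, `c`.
#' @examples
#' coefficient_table()
#' @export
coefficient_table <- function() {
  structure(.CANONICAL, class = c("coefficient_table", "data.frame"),
            provenance = "canonical")
}

#' Fit the simplified formula to simulated grid responses
#'
#' Ordinary least squares of `stdktv` on `kru` and `ektv` with intercept —
#' the regression that defines (a, b, c) for one simulation unit. On the
#' derivation grid the distribution volume is fixed at 35 L, so Kru and
#' normalized Kru coincide and the fitted `b` applies to KRUn.
#'
#' @param data Data frame with columns `stdktv`, `kru`, `ektv`.
#' @param unit_id Identifier stored in the result.
#' @return A `coefficient_set` with in-sample `fit_r2` and `n_points`.
#' @examples
#' d <- expand.grid(kru = 0:3, ektv = c(0.4, 0.6, 0.8))
#' d$stdktv <- 0.5 + 0.3 * d$kru + 2 * d$ektv
#' fit_coefficients(d, "toy")
#' @export
fit_coefficients <- function(data, unit_id = "unit") {
  stopifnot(all(c("stdktv", "kru", "ektv") %in% names(data)))
  if (nrow(data) < 3L) stop("at least 3 points are required")
  fit <- stats::lm(stdktv ~ kru + ektv, data = data)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: Kru and/or eKt/V do not vary over the grid")
  .coefficient_set(unit_id,
                   a = unname(cf["(Intercept)"]),
                   b = unname(cf["kru"]),
                   c = unname(cf["ektv"]),
                   fit_r2 = summary(fit)$r.squared,
                   n_points = nrow(data))
}

#' Derive formula coefficients for one simulation unit
#'
#' Simulates every point of the unit's parameter grid with the two-pool
#' weekly-cycle model, takes the weekly stdKt/V and the lab-day session
#' eKt/V at each point, and fits the simplified linear formula by OLS.
#'
#' @param unit A [simulation_unit()].
#' @param grid Parameter grid; defaults to the unit's standard 480-point
#'   grid from [build_parameter_grid()].
#' @param dt RK4 step, minutes.
#' @param data Optional pre-simulated grid responses (a data frame from
#'   [simulate_grid()]); when supplied the simulation step is skipped.
#' @return A `coefficient_set`.
#' @examples
#' \donttest{
#' derive_coefficients(canonical_units()[[5]])
#' }
#' @export
derive_coefficients <- function(unit, grid = build_parameter_grid(unit),
                                dt = 1, data = NULL) {
  stopifnot(inherits(unit, "simulation_unit"))
  if (is.null(data)) data <- simulate_grid(grid, dt = dt)
  if (!all(data$converged))
    stop("some grid points failed to converge")
  fit_coefficients(
    data.frame(stdktv = data$stdktv, kru = data$Kru, ektv = data$ektv_lab),
    unit_id = unit$id
  )
}

#' Derive a full coefficient table
#'
#' Runs [derive_coefficients()] for a list of units (by default the seven
#' canonical Monday-lab-day units) and assembles the rows into a
#' `coefficient_table`.
#'
#' @param units List of [simulation_unit()] objects.
#' @param dt RK4 step, minutes.
#' @param ... Passed to [build_parameter_grid()] (axis overrides).
#' @return A `coefficient_table` data frame with fit diagnostics.
#' @export
derive_coefficient_table <- function(units = canonical_units(), dt = 1, ...) {
  rows <- lapply(units, function(u) {
    cs <- derive_coefficients(u, grid = build_parameter_grid(u, ...), dt = dt)
    data.frame(frequency = u$schedule$frequency, unit_id = cs$unit_id,
               a = cs$a, b = cs$b, c = cs$c, fit_r2 = cs$fit_r2,
               n_points = cs$n_points, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$frequency), ]
  rownames(tab) <- NULL
  structure(tab, class = c("coefficient_table", "data.frame"),
            provenance = "derived")
}

#' Compare a derived coefficient table with the canonical constants
#'
#' Per-frequency coefficient deltas (derived minus canonical) and the
#' maximum discrepancy between the two formulas' predicted stdKt/V over a
#' fixed evaluation lattice covering the derivation grid's response range
#' (KRUn 0, 2, 4, 6 mL/min; eKt/V 0.3 to 1.1).
#'
#' @param derived A `coefficient_table` covering all 7 frequencies.
#' @param krun,ektv Evaluation lattice axes.
#' @return List with `deltas` (data frame of `d_a`, `d_b`, `d_c` per
#'   frequency), `max_abs_delta` and `max_pred_discrepancy` (v/wk).
#' @export
compare_to_canonical <- function(derived,
                                 krun = c(0, 2, 4, 6),
                                 ektv = seq(0.3, 1.1, by = 0.2)) {
  stopifnot(is.data.frame(derived))
  canon <- .CANONICAL
  if (!all(canon$frequency %in% derived$frequency))
    stop("derived table must cover all 7 frequencies")
  derived <- derived[match(canon$frequency, derived$frequency), ]
  deltas <- data.frame(
    frequency = canon$frequency,
    d_a = derived$a - canon$a,
    d_b = derived$b - canon$b,
    d_c = derived$c - canon$c
  )
  lattice <- expand.grid(krun = krun, ektv = ektv)
  disc <- 0
  for (i in seq_len(7)) {
    p_d <- derived$a[i] + derived$b[i] * lattice$krun + derived$c[i] * lattice$ektv
    p_c <- canon$a[i] + canon$b[i] * lattice$krun + canon$c[i] * lattice$ektv
    disc <- max(disc, max(abs(p_d - p_c)))
  }
  list(deltas = deltas,
       max_abs_delta = max(abs(as.matrix(deltas[, -1]))),
       max_pred_discrepancy = disc)
}

#' Export a coefficient table as JSON
#'
#' @param table A `coefficient_table`.
#' @param path File to write; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written.
#' @export
write_coefficients_json <- function(table, path = NULL) {
  stopifnot(is.data.frame(table))
  payload <- list(
    format = "ureadose/coefficients",
    version = "1.0",
    provenance = attr(table, "provenance") %||% "unknown",
    software_version = as.character(utils::packageVersion("ureadose")),
    rows = table
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
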