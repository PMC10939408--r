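# Prescription engine: required per-session dose and minimum treatment
# frequency to meet a weekly standard Kt/V target, from the simplified
# formula stdKt/V = a + b * KRUn + c * eKt/V.

#' Normalize residual kidney clearance to a 35 L distribution volume
#'
#' The formula's coefficient on residual clearance refers to a patient with
#' a typical urea distribution volume of 35 L; for other volumes the
#' normalized clearance `KRUn = Kru / V * 35` is used in its place.
#'
#' @param Kru Residual kidney urea clearance, mL/min (blood water).
#' @param V Urea distribution volume, litres.
#' @return KRUn in mL/min per 35 L.
#' @examples
#' normalize_kru(2, 30)
#' @export
normalize_kru <- function(Kru, V) {
  if (any(V <= 0)) stop("V must be positive")
  if (any(Kru < 0)) stop("Kru must be non-negative")
  Kru / V * 35
}

.coef_abc <- function(coeffs) {
  if (inherits(coeffs, "coefficient_set"))
    return(list(a = coeffs$a, b = coeffs$b, c = coeffs$c))
  if (is.list(coeffs) && all(c("a", "b", "c") %in% names(coeffs)))
    return(list(a = coeffs$a, b = coeffs$b, c = coeffs$c))
  stop("coeffs must be a coefficient_set or a list with a, b, c")
}

#' Predicted standard Kt/V from the simplified formula
#'
#' `stdKt/V = a + b * KRUn + c * eKt/V` for one coefficient set.
#'
#' @param coeffs A `coefficient_set` (see [canonical_coefficients()]) or a
#'   list with elements `a`, `b`, `c`.
#' @param KRUn Normalized residual clearance, mL/min per 35 L (>= 0).
#' @param ektv Per-session equilibrated Kt/V (>= 0).
#' @return Predicted stdKt/V, volumes/week.
#' @examples
#' stdktv_formula(canonical_coefficients(5), normalize_kru(2, 30), 0.6)
#' @export
stdktv_formula <- function(coeffs, KRUn, ektv) {
  k <- .coef_abc(coeffs)
  if (any(KRUn < 0) || any(ektv < 0)) stop("KRUn and ektv must be non-negative")
  k$a + k$b * KRUn + k$c * ektv
}

#' Required per-session eKt/V to reach a stdKt/V target
#'
#' Solves the simplified formula for the dose:
#' `eKt/V_req = (target - a - b * KRUn) / c`, floored at 0. A zero
#' requirement means the residual kidney clearance alone meets the target
#' at that frequency (`renal_sufficient`).
#'
#' @inheritParams stdktv_formula
#' @param target Weekly stdKt/V target, volumes/week (default 2.3).
#' @return Named list with `ektv_req` and logical `renal_sufficient`.
#' @examples
#' ektv_required(canonical_coefficients(6), KRUn = 0)
#' @export
ektv_required <- function(coeffs, KRUn, target = 2.3) {
  k <- .coef_abc(coeffs)
  if (k$c <= 0) stop("coefficient c must be positive")
  if (any(KRUn < 0)) stop("KRUn must be non-negative")
  if (target <= 0) stop("target must be positive")
  raw <- (target - k$a - k$b * KRUn) / k$c
  list(ektv_req = pmax(raw, 0), renal_sufficient = raw <= 0)
}

#' Minimum KRUn at which a frequency meets the target at a capped dose
#'
#' The cut-off residual clearance above which a given treatment frequency
#' achieves the stdKt/V target without exceeding the per-session dose cap:
#' `(target - a - c * cap) / b`, floored at 0.
#'
#' @inheritParams stdktv_formula
#' @param ektv_cap Per-session eKt/V cap (default 0.7, the study-population
#'   mean dose).
#' @param target Weekly stdKt/V target, volumes/week.
#' @return KRUn cut-off, mL/min per 35 L.
#' @examples
#' krun_cutoff(canonical_coefficients(1)) # once-weekly needs KRUn > ~6
#' @export
krun_cutoff <- function(coeffs, ektv_cap = 0.7, target = 2.3) {
  k <- .coef_abc(coeffs)
  if (k$b <= 0) stop("coefficient b must be positive")
  if (ektv_cap <= 0) stop("ektv_cap must be positive")
  max((target - k$a - k$c * ektv_cap) / k$b, 0)
}

#' Prescribe the minimum treatment frequency
#'
#' Evaluates the required per-session eKt/V at every allowed frequency and
#' returns the smallest frequency whose requirement does not exceed the
#' dose cap, together with the full per-frequency table. When no frequency
#' is feasible under the cap, the highest allowed frequency is returned
#' flagged infeasible. The `minimum_stdktv` floor (default 2.1) is carried
#' for reporting only; the prescription is driven by `target_stdktv`.
#'
#' @param Kru Residual kidney urea clearance, mL/min (blood water).
#' @param V Urea distribution volume, litres.
#' @param target_stdktv Weekly stdKt/V target (default 2.3 v/wk).
#' @param minimum_stdktv Minimum acceptable delivered stdKt/V (reported,
#'   not used for selection).
#' @param ektv_cap Per-session eKt/V considered deliverable (default 0.7).
#' @param allowed_frequencies Subset of 1..7 to consider.
#' @param table Coefficient table (default the canonical constants).
#' @return Object of class `prescription` with `frequency`, `ektv_req`,
#'   `stdktv_predicted`, `renal_sufficient`, `feasible`, `KRUn` and
#'   `per_frequency_table`.
#' @examples
#' prescribe_frequency(Kru = 2, V = 30)
#' @export
prescribe_frequency <- function(Kru, V = 35,
                                target_stdktv = 2.3, minimum_stdktv = 2.1,
                                ektv_cap = 0.7, allowed_frequencies = 1:7,
                                table = coefficient_table()) {
  stopifnot(length(Kru) == 1L, length(V) == 1L)
  allowed_frequencies <- sort(unique(as.integer(allowed_frequencies)))
  if (length(allowed_frequencies) == 0L ||
      any(allowed_frequencies < 1L | allowed_frequencies > 7L))
    stop("allowed_frequencies must be a non-empty subset of 1..7")
  if (target_stdktv < minimum_stdktv)
    stop("target_stdktv must be at least minimum_stdktv")
  KRUn <- normalize_kru(Kru, V)

  rows <- lapply(allowed_frequencies, function(fr) {
    k <- table[table$frequency == fr, ]
    if (nrow(k) != 1L) stop(sprintf("no coefficient row for frequency %d", fr))
    req <- ektv_required(k, KRUn, target_stdktv)
    data.frame(frequency = fr, ektv_req = req$ektv_req,
               renal_sufficient = req$renal_sufficient,
               feasible = req$ektv_req <= ektv_cap)
  })
  tab <- do.call(rbind, rows)
  pick <- which(tab$feasible)[1L]
  feasible <- !is.na(pick)
  if (!feasible) pick <- nrow(tab)
  fr <- tab$frequency[pick]
  krow <- table[table$frequency == fr, ]
  structure(
    list(frequency = fr,
         ektv_req = tab$ektv_req[pick],
         stdktv_predicted = stdktv_formula(krow, KRUn, tab$ektv_req[pick]),
         renal_sufficient = tab$renal_sufficient[pick],
         feasible = feasible,
         KRUn = KRUn, Kru = Kru, V = V,
         target_stdktv = target_stdktv, minimum_stdktv = minimum_stdktv,
         ektv_cap = ektv_cap,
         per_frequency_table = tab),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("Prescription for Kru = %.2f mL/min, V = %.1f L (KRUn = %.2f):\n",
              x$Kru, x$V, x$KRUn))
  print(x$per_frequency_table, digits = 4, row.names = FALSE)
  if (x$feasible) {
    if (x$renal_sufficient)
      cat(sprintf("-> %d session(s)/week; residual kidney clearance alone meets stdKt/V %.1f\n",
                  x$frequency, x$target_stdktv))
    else
      cat(sprintf("-> %d session(s)/week at eKt/V >= %.3f (predicted stdKt/V %.2f)\n",
                  x$frequency, x$ektv_req, x$stdktv_predicted))
  } else {
    cat(sprintf("-> no allowed frequency reaches stdKt/V %.1f under the eKt/V cap %.2f; showing %d/week\n",
                x$target_stdktv, x$ektv_cap, x$frequency))
  }
  invisible(x)
}

#' Prescription graph data
#'
#' Required per-session eKt/V as a function of normalized residual
#' clearance, one affine decreasing line per treatment frequency (clamped
#' at 0 once the residual kidney meets the target alone). This is the
#' construction behind the graphical prescription aid.
#'
#' @param table Coefficient table (default canonical).
#' @param krun_max Upper end of the KRUn axis, mL/min per 35 L.
#' @param step KRUn grid step (> 0).
#' @param target Weekly stdKt/V target, v/wk.
#' @return Data frame (class `prescription_graph`) with columns
#'   `frequency`, `KRUn`, `ektv_req`.
#' @examples
#' g <- prescription_graph()
#' head(g)
#' @export
prescription_graph <- function(table = coefficient_table(), krun_max = 8,
                               step = 0.1, target = 2.3) {
  if (step <= 0) stop("step must be positive")
  krun <- seq(0, krun_max, by = step)
  rows <- lapply(table$frequency, function(fr) {
    k <- table[table$frequency == fr, ]
    data.frame(frequency = fr, KRUn = krun,
               ektv_req = ektv_required(k, krun, target)$ektv_req)
  })
  structure(do.call(rbind, rows),
            class = c("prescription_graph", "data.frame"),
            target = target)
}

#' Plot the prescription graph
#'
#' @param x A [prescription_graph()] data frame.
#' @param ektv_cap Horizontal reference line (set `NULL` to omit).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot.prescription_graph <- function(x, ektv_cap = 0.7, ...) {
  freqs <- sort(unique(x$frequency))
  graphics::plot(NA, xlim = range(x$KRUn), ylim = c(0, max(x$ektv_req) * 1.05),
                 xlab = "KRUn (mL/min per 35 L)",
                 ylab = "required eKt/V per session", ...)
  for (i in seq_along(freqs)) {
    d <- x[x$frequency == freqs[i], ]
    graphics::lines(d$KRUn, d$ektv_req, col = i, lwd = 2)
  }
  if (!is.null(ektv_cap)) graphics::abline(h = ektv_cap, lty = 2)
  graphics::legend("topright", legend = paste0(freqs, "/wk"),
                   col = seq_along(freqs), lwd = 2, cex = 0.8)
  invisible(x)
}
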