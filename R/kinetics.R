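# Patient kinetic parameters and per-session dialysis prescriptions.

#' Patient kinetic parameters
#'
#' Physiological parameters of one modelled patient for the two-pool
#' variable-volume urea kinetic model. The urea distribution volume
#' `V_total` is the post-dialysis ("dry") volume; it is split into an
#' extracellular pool (fraction `ecf_fraction`, default 1/3) that receives
#' generation, fluid intake, ultrafiltration and all clearances, and an
#' intracellular pool of constant volume coupled through the
#' intercompartmental clearance `Kc`. The default `Kc` of 500 mL/min for a
#' 35 L patient, scaled proportionally to `V_total`, is the package's
#' standard two-pool closure: it is calibrated so that the model's
#' post-dialysis rebound reproduces the established
#' `eKt/V = spKt/V * Td/(Td + 35)` relation over clinical session lengths
#' (see the package vignette).
#'
#' @param V_total Urea distribution volume, mL (> 0).
#' @param Kru Residual kidney urea clearance, mL/min of blood water (>= 0).
#' @param G Urea nitrogen generation rate, mg/min (>= 0).
#' @param ecf_fraction Extracellular fraction of `V_total`, in (0, 1).
#' @param Kc Intercompartmental urea clearance, mL/min (> 0).
#' @return Object of class `patient_kinetics`.
#' @examples
#' patient_kinetics(V_total = 35000, Kru = 2, G = 6)
#' @export
patient_kinetics <- function(V_total, Kru = 0, G = 0,
                             ecf_fraction = 1 / 3,
                             Kc = 500 * V_total / 35000) {
  stopifnot(is.numeric(V_total), length(V_total) == 1L)
  if (!is.finite(V_total) || V_total <= 0) stop("V_total must be positive")
  if (!is.finite(Kru) || Kru < 0) stop("Kru must be non-negative")
  if (!is.finite(G) || G < 0) stop("G must be non-negative")
  if (!is.finite(ecf_fraction) || ecf_fraction <= 0 || ecf_fraction >= 1)
    stop("ecf_fraction must lie strictly between 0 and 1")
  if (!is.finite(Kc) || Kc <= 0) stop("Kc must be positive")
  structure(
    list(V_total = as.numeric(V_total), Kru = as.numeric(Kru),
         G = as.numeric(G), ecf_fraction = as.numeric(ecf_fraction),
         Kc = as.numeric(Kc)),
    class = "patient_kinetics"
  )
}

#' @export
print.patient_kinetics <- function(x, ...) {
  cat(sprintf(
    "Patient kinetics: V = %.1f L, Kru = %.2f mL/min, G = %.2f mg/min, Kc = %.0f mL/min (ECF %.2f)\n",
    x$V_total / 1000, x$Kru, x$G, x$Kc, x$ecf_fraction))
  invisible(x)
}

#' Per-session dialysis prescription
#'
#' Operating parameters of one dialysis session. `Qb` and `Qd` are
#' informational; a warning (not an error) is emitted when the stated
#' dialyser clearance exceeds the smaller of the two flows, which is
#' physically implausible for urea.
#'
#' @param Kd Effective dialyser urea clearance, mL/min (>= 0).
#' @param Td Session length, min (> 0).
#' @param UF_volume Fluid removed this session, mL (>= 0). In weekly-cycle
#'   simulations the per-session removal is re-derived from the weekly
#'   ultrafiltration so that the cycle is exactly periodic; see
#'   [simulate_weekly_cycle()].
#' @param Qb,Qd Blood / dialysate flow rates, mL/min.
#' @return Object of class `session_rx`.
#' @examples
#' session_rx(Kd = 160, Td = 150)
#' @export
session_rx <- function(Kd, Td, UF_volume = 0, Qb = 350, Qd = 180) {
  if (!is.finite(Kd) || Kd < 0) stop("Kd must be non-negative")
  if (!is.finite(Td) || Td <= 0) stop("Td must be positive")
  if (!is.finite(UF_volume) || UF_volume < 0) stop("UF_volume must be non-negative")
  if (!is.finite(Qb) || Qb <= 0 || !is.finite(Qd) || Qd <= 0)
    stop("Qb and Qd must be positive")
  if (Kd > min(Qb, Qd))
    warning(sprintf("Kd (%g mL/min) exceeds min(Qb, Qd) = %g mL/min",
                    Kd, min(Qb, Qd)))
  structure(
    list(Kd = as.numeric(Kd), Td = as.numeric(Td),
         UF_volume = as.numeric(UF_volume),
         Qb = as.numeric(Qb), Qd = as.numeric(Qd)),
    class = "session_rx"
  )
}

#' @export
print.session_rx <- function(x, ...) {
  cat(sprintf("Session: Kd = %g mL/min, Td = %g min, UF = %g mL (Qb %g, Qd %g)\n",
              x$Kd, x$Td, x$UF_volume, x$Qb, x$Qd))
  invisible(x)
}
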