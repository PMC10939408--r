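# Dose metrics: variable-volume single-pool Kt/V inversion and the
# formula-based clinical estimators used when only pre/post BUN is known.

# Closed-form concentration after a session of the variable-volume
# single-pool model: V(t) shrinks linearly from V_pre to V_post, total loss
# coefficient lam = K + Kru + intake, generation G. Used to invert the
# observed concentration drop for the clearance K.
.vvsp_conc <- function(K, C0, Td, V_pre, V_post, G, Kru, intake) {
  lam <- K + Kru + intake
  B <- (V_pre - V_post) / Td
  if (lam < 1e-14) {
    Tint <- if (abs(B) > 1e-12) log(V_pre / V_post) / B else Td / V_pre
    return(C0 + G * Tint)
  }
  shrink <- if (abs(B) > 1e-12) (V_post / V_pre)^(lam / B)
            else exp(-lam * Td / V_pre)
  G / lam + (C0 - G / lam) * shrink
}

.vvsp_ktv <- function(C0, C1, Td, V_pre, V_post, G = 0, Kru = 0,
                      intake = 0, tol = 1e-10) {
  if (C0 <= 0) return(0)
  fk <- function(K) .vvsp_conc(K, C0, Td, V_pre, V_post, G, Kru, intake) - C1
  if (fk(0) <= 0) return(0)  # no positive clearance explains the change
  hi <- 100
  while (fk(hi) > 0 && hi < 1e7) hi <- hi * 10
  if (fk(hi) > 0) stop("single-pool clearance inversion failed to bracket a root")
  K <- stats::uniroot(fk, c(0, hi), tol = tol)$root
  K * Td / V_post
}

#' Kt/V from a concentration drop (variable-volume single pool)
#'
#' Finds the dialyser clearance `K` whose variable-volume single-pool
#' session — volume shrinking linearly from `V_pre` to `V_post`, generation
#' `G`, residual clearance `Kru` and continuous fluid intake — reproduces
#' the observed pre-to-post concentration change, and returns
#' `K * Td / V_post`. With the post-dialysis extracellular concentration
#' this yields spKt/V; with the equilibrated (mass-average) concentration
#' it yields eKt/V. The root is bracketed and solved by [stats::uniroot()]
#' to a tolerance of 1e-10; a session whose concentration does not fall is
#' assigned dose 0.
#'
#' @param C0,C1 Pre- and post-dialysis concentrations, mg/mL.
#' @param Td Session length, min.
#' @param V_pre,V_post Total urea distribution volume at session start and
#'   end, mL.
#' @param G Urea generation rate, mg/min.
#' @param Kru Residual kidney urea clearance, mL/min.
#' @param intake Continuous fluid intake rate during the session, mL/min.
#' @return The dimensionless Kt/V (0 when no drop occurred).
#' @examples
#' vvsp_ktv(C0 = 1, C1 = exp(-1), Td = 200, V_pre = 35000, V_post = 35000)
#' @export
vvsp_ktv <- function(C0, C1, Td, V_pre, V_post, G = 0, Kru = 0, intake = 0) {
  stopifnot(C0 >= 0, C1 >= 0, Td > 0, V_pre > 0, V_post > 0)
  .vvsp_ktv(C0, C1, Td, V_pre, V_post, G, Kru, intake)
}

#' Single-pool Kt/V from pre/post BUN (second-generation estimator)
#'
#' The standard bedside estimator of spKt/V from the post/pre BUN ratio,
#' session length and ultrafiltration:
#' `spKt/V = -log(R - 0.008 t) + (4 - 3.5 R) * UF / W`, with `t` in hours.
#'
#' @param R Post/pre BUN ratio, in (0, 1).
#' @param Td Session length, minutes.
#' @param UF Ultrafiltration volume, litres.
#' @param W Post-dialysis body weight, kg.
#' @return Estimated spKt/V.
#' @examples
#' spktv_daugirdas(R = 0.3, Td = 240, UF = 2, W = 70)
#' @export
spktv_daugirdas <- function(R, Td, UF = 0, W) {
  stopifnot(length(R) == length(Td) || length(R) == 1L || length(Td) == 1L)
  if (any(R <= 0 | R >= 1)) stop("R must lie strictly between 0 and 1")
  if (any(W <= 0)) stop("W must be positive")
  if (any(UF < 0)) stop("UF must be non-negative")
  th <- Td / 60
  arg <- R - 0.008 * th
  if (any(arg <= 0))
    stop("R - 0.008 t <= 0: ratio too small for this session length")
  -log(arg) + (4 - 3.5 * R) * UF / W
}

#' Equilibrated Kt/V from single-pool Kt/V
#'
#' Converts spKt/V to eKt/V with either the rate equation
#' (`eKt/V = spKt/V - 0.6 spKt/V / t_h + 0.03`, `t_h` in hours) or the
#' Tattersall correction (`eKt/V = spKt/V * Td / (Td + 35)`). Negative
#' results are floored at 0.
#'
#' @param spktv Single-pool Kt/V (>= 0).
#' @param Td Session length, minutes (> 0).
#' @param method `"rate_equation"` (default) or `"tattersall"`.
#' @return Estimated eKt/V.
#' @examples
#' ektv_from_spktv(1.4, 240, "rate_equation")
#' ektv_from_spktv(1.4, 240, "tattersall")
#' @export
ektv_from_spktv <- function(spktv, Td, method = c("rate_equation", "tattersall")) {
  method <- match.arg(method)
  if (any(Td <= 0)) stop("Td must be positive")
  if (any(spktv < 0)) stop("spktv must be non-negative")
  e <- switch(method,
              rate_equation = spktv - 0.6 * spktv / (Td / 60) + 0.03,
              tattersall = spktv * Td / (Td + 35))
  e[spktv == 0] <- 0
  pmax(e, 0)
}

#' Residual kidney urea clearance from an interdialytic urine collection
#'
#' Excreted urea nitrogen mass divided by the collection time and the mean
#' serum urea nitrogen concentration expressed in blood water (plasma-water
#' factor 0.93), matching the convention that Kru values used with kinetic
#' formulas are blood-water clearances.
#'
#' @param urine_volume Collected urine volume, litres.
#' @param urine_ureaN Urine urea nitrogen concentration, mg/dL.
#' @param collection Collection duration, minutes.
#' @param serum_start,serum_end Serum urea nitrogen at the start and end of
#'   the collection, mg/dL; their arithmetic mean is used.
#' @param plasma_water Plasma-to-plasma-water conversion factor.
#' @return Kru in mL/min of blood water.
#' @examples
#' kru_from_urine(1.2, 600, 1440, 60, 60) # ~7.75 mL/min
#' @export
kru_from_urine <- function(urine_volume, urine_ureaN, collection,
                           serum_start, serum_end, plasma_water = 0.93) {
  if (any(urine_volume < 0)) stop("urine_volume must be non-negative")
  if (any(collection <= 0)) stop("collection must be positive")
  if (any(urine_ureaN < 0)) stop("urine_ureaN must be non-negative")
  mean_serum <- (serum_start + serum_end) / 2     # mg/dL
  if (any(mean_serum <= 0)) stop("mean serum concentration must be positive")
  excreted <- urine_volume * 10 * urine_ureaN     # L * 10 dL/L * mg/dL = mg
  bw_conc <- mean_serum / 100 / plasma_water      # mg/mL of blood water
  (excreted / collection) / bw_conc
}
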