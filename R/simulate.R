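# Two-pool variable-volume weekly-cycle simulator.
#
# The model: urea nitrogen is distributed over an extracellular pool
# (volume Ve, concentration Ce) and an intracellular pool (constant volume
# Vi, concentration Ci) coupled by the intercompartmental clearance Kc.
# Generation G, fluid intake (continuous, weekly_uf/10080 mL/min),
# ultrafiltration and the clearances Kd (dialytic phases only) and Kru all
# act on the extracellular pool. Because fluid leaves at the extracellular
# concentration and intake carries no urea, the concentration-form dynamics
# are
#     dVe/dt = r - Qf
#     dCe/dt = (G + Kc (Ci - Ce) - (Kd + Kru + r) Ce) / Ve
#     dCi/dt = Kc (Ce - Ci) / Vi
# with Qf > 0 only during dialysis. Each session removes exactly the fluid
# accumulated since the previous session, so the post-dialysis volume
# returns to V_total and the weekly cycle is exactly periodic.
#
# The dynamics are linear in (Ce, Ci), so the map carrying the state over
# one week is affine: x(week) = Phi x(0) + psi. The periodic steady state
# is the fixed point x* = (I - Phi)^{-1} psi, assembled from one propagation
# of two basis initial conditions plus the inhomogeneous (G-driven) column.
# A brute-force fixed-point iteration is retained as a cross-check.
#
# Integration is fixed-step RK4 (default dt = 1 min). The explicit scheme
# is stable for physiological Kc; columns whose Kc exceeds `kc_collapse`
# are integrated exactly in the single-pool limit (one pool on the total
# volume), which is the Kc -> infinity solution of the same mass balance.

.WEEK_MIN <- 10080

# Standard two-pool closure: intercompartmental clearance scaled to the
# distribution volume, calibrated so the model's post-dialysis rebound
# reproduces the established eKt/V = spKt/V * Td/(Td + 35) relation over
# clinical session lengths.
.default_kc <- function(V_total) 500 * V_total / 35000

# Weekly standard Kt/V, the guideline's operational definition: the
# fixed-volume weekly-clearance formula evaluated at the per-session
# equilibrated dose e, session length t (min) and frequency N,
#   S = 10080 (1 - exp(-e)) / t / [ (1 - exp(-e))/e + 10080/(N t) - 1 ],
# divided by the ultrafiltration correction (1 - 0.74/N * UFweek/V) and
# with the continuous residual kidney clearance credited in full,
# + Kru * 10080 / V.
.stdktv_fixed_volume <- function(ektv, Td, n_per_week) {
  s <- numeric(length(ektv))
  pos <- ektv > 0
  e <- ektv[pos]; t <- Td[pos]; N <- n_per_week[pos]
  s[pos] <- (10080 * (1 - exp(-e)) / t) /
    ((1 - exp(-e)) / e + 10080 / (N * t) - 1)
  s
}

# Timeline of one week for a set of dialysis days and session lengths.
.week_timeline <- function(days, Td) {
  f <- length(days)
  Td <- rep_len(as.numeric(Td), f)
  if (any(Td <= 0)) stop("Td must be positive")
  start <- (days - 1) * 1440
  end <- start + Td
  if (f > 1L && any(start[-1L] < end[-f])) stop("sessions overlap")
  if (end[f] > .WEEK_MIN) stop("last session runs past the end of the week")
  prev_end <- c(end[f] - .WEEK_MIN, end[-f])
  gap <- start - prev_end
  if (any(gap < 0)) stop("session length exceeds an interdialytic interval")
  list(f = f, days = days, Td = Td, start = start, end = end, gap = gap)
}

# RK4 integration of one phase of constant (kd, qf) for all columns.
# st: list(Ve, Ce, Ci, Rm); pp: list(r, G, Kru, Kc, Vi); kd, qf: vectors.
.integrate_phase <- function(st, len, kd, qf, pp, dt) {
  Ve <- st$Ve; Ce <- st$Ce; Ci <- st$Ci; Rm <- st$Rm
  r <- pp$r; G <- pp$G; Kru <- pp$Kru; Kc <- pp$Kc; Vi <- pp$Vi
  lam <- kd + Kru + r      # concentration-form loss coefficient
  rem <- kd + Kru + qf     # mass-removal coefficient (diffusive + convective)
  dVe <- r - qf            # constant within the phase
  n <- max(1L, as.integer(ceiling(len / dt - 1e-9)))
  hlast <- len - (n - 1L) * dt
  for (i in seq_len(n)) {
    h <- if (i < n) dt else hlast
    k1e <- (G + Kc * (Ci - Ce) - lam * Ce) / Ve
    k1i <- Kc * (Ce - Ci) / Vi
    Veh <- Ve + 0.5 * h * dVe
    Ce2 <- Ce + 0.5 * h * k1e; Ci2 <- Ci + 0.5 * h * k1i
    k2e <- (G + Kc * (Ci2 - Ce2) - lam * Ce2) / Veh
    k2i <- Kc * (Ce2 - Ci2) / Vi
    Ce3 <- Ce + 0.5 * h * k2e; Ci3 <- Ci + 0.5 * h * k2i
    k3e <- (G + Kc * (Ci3 - Ce3) - lam * Ce3) / Veh
    k3i <- Kc * (Ce3 - Ci3) / Vi
    Ve1 <- Ve + h * dVe
    Ce4 <- Ce + h * k3e; Ci4 <- Ci + h * k3i
    k4e <- (G + Kc * (Ci4 - Ce4) - lam * Ce4) / Ve1
    k4i <- Kc * (Ce4 - Ci4) / Vi
    Rm <- Rm + h / 6 * rem * (Ce + 2 * Ce2 + 2 * Ce3 + Ce4)
    Ce <- Ce + h / 6 * (k1e + 2 * k2e + 2 * k3e + k4e)
    Ci <- Ci + h / 6 * (k1i + 2 * k2i + 2 * k3i + k4i)
    Ve <- Ve1
  }
  list(Ve = Ve, Ce = Ce, Ci = Ci, Rm = Rm)
}

# Propagate all columns over one week, recording the state immediately
# before and after every session. Kd, Qf are f x m matrices.
.propagate_week <- function(tl, st, pp, Kd, Qf, dt) {
  f <- tl$f
  pre <- vector("list", f)
  post <- vector("list", f)
  zero <- rep(0, length(st$Ce))
  t <- 0
  for (s in seq_len(f)) {
    if (tl$start[s] > t) {
      st <- .integrate_phase(st, tl$start[s] - t, zero, zero, pp, dt)
      t <- tl$start[s]
    }
    pre[[s]] <- st
    st <- .integrate_phase(st, tl$Td[s], Kd[s, ], Qf[s, ], pp, dt)
    t <- tl$end[s]
    post[[s]] <- st
  }
  if (t < .WEEK_MIN)
    st <- .integrate_phase(st, .WEEK_MIN - t, zero, zero, pp, dt)
  list(final = st, pre = pre, post = post)
}

# Periodic steady state of the weekly cycle for m parameter columns sharing
# one (days, Td) timeline.
#
# pars: list of length-m vectors V_total, ecf, Kc, Kru, G, weekly_uf and an
# f x m matrix Kd. Returns per-point steady-state session concentrations,
# dose metrics and mass-balance diagnostics.
.solve_cycle <- function(days, Td, pars, dt = 1,
                         method = c("affine", "iterate", "transient"),
                         conc_init = 1, kc_collapse = 1e4,
                         max_weeks = 200L, tol = 1e-10) {
  method <- match.arg(method)
  tl <- .week_timeline(days, Td)
  f <- tl$f
  m <- length(pars$V_total)
  Kd <- matrix(pars$Kd, nrow = f, ncol = m)
  V_total <- pars$V_total
  ecf <- rep_len(pars$ecf, m)
  Kc <- rep_len(pars$Kc, m)
  Kru <- rep_len(pars$Kru, m)
  G <- rep_len(pars$G, m)
  weekly_uf <- rep_len(pars$weekly_uf, m)
  if (any(weekly_uf < 0)) stop("weekly_uf must be non-negative")

  r <- weekly_uf / .WEEK_MIN
  # single-pool collapse for very large Kc (exact Kc -> Inf limit; explicit
  # RK4 would otherwise be unstable for the stiff exchange term)
  sp <- Kc >= kc_collapse
  Vi <- ifelse(sp, 1e-6, (1 - ecf) * V_total)
  Ve_base <- V_total - Vi
  Kc_eff <- ifelse(sp, 0, Kc)
  # session UF rates: each session removes the fluid accumulated since the
  # previous session end plus the intake during the session itself
  Qf <- matrix(0, f, m)
  for (s in seq_len(f)) Qf[s, ] <- r * (tl$gap[s] + tl$Td[s]) / tl$Td[s]
  Ve0 <- Ve_base + r * (.WEEK_MIN - tl$end[f])

  pp1 <- list(r = r, G = G, Kru = Kru, Kc = Kc_eff, Vi = Vi)

  if (method == "affine") {
    # three columns per point: two homogeneous basis states and the
    # G-driven inhomogeneous state
    idx <- rep(seq_len(m), each = 3L)
    which3 <- rep(1:3, m)
    pp <- lapply(pp1, function(v) v[idx])
    pp$G <- ifelse(which3 == 3L, G[idx], 0)
    st0 <- list(Ve = Ve0[idx],
                Ce = as.numeric(which3 == 1L),
                Ci = as.numeric(which3 == 2L),
                Rm = rep(0, 3L * m))
    wk <- .propagate_week(tl, st0, pp, Kd[, idx, drop = FALSE],
                          Qf[, idx, drop = FALSE], dt)
    i1 <- which(which3 == 1L); i2 <- which(which3 == 2L); i3 <- which(which3 == 3L)
    p11 <- wk$final$Ce[i1]; p12 <- wk$final$Ce[i2]
    p21 <- wk$final$Ci[i1]; p22 <- wk$final$Ci[i2]
    psi_e <- wk$final$Ce[i3]; psi_i <- wk$final$Ci[i3]

    xce <- xci <- numeric(m)
    a11 <- 1 - p11; a12 <- -p12; a21 <- -p21; a22 <- 1 - p22
    det2 <- a11 * a22 - a12 * a21
    for (j in seq_len(m)) {
      if (sp[j]) {
        # intracellular column is an inert dummy in collapse mode
        if (a11[j] < 1e-12) {
          if (abs(psi_e[j]) < 1e-14) { xce[j] <- conc_init; xci[j] <- conc_init }
          else .stop_unbounded(Kd[, j], Kru[j])
        } else {
          xce[j] <- psi_e[j] / a11[j]
          xci[j] <- xce[j]
        }
      } else if (abs(det2[j]) < 1e-12) {
        if (max(abs(psi_e[j]), abs(psi_i[j])) < 1e-14) {
          xce[j] <- conc_init; xci[j] <- conc_init
        } else .stop_unbounded(Kd[, j], Kru[j])
      } else {
        xce[j] <- (a22[j] * psi_e[j] - a12[j] * psi_i[j]) / det2[j]
        xci[j] <- (a11[j] * psi_i[j] - a21[j] * psi_e[j]) / det2[j]
      }
    }
    weeks <- 1L
  } else if (method == "transient") {
    # one week from a uniform starting concentration; no steady state sought
    xce <- rep(conc_init, m); xci <- rep(conc_init, m)
    weeks <- 0L
  } else {
    xce <- rep(conc_init, m); xci <- rep(conc_init, m)
    weeks <- 0L
    repeat {
      wk <- .propagate_week(tl, list(Ve = Ve0, Ce = xce, Ci = xci, Rm = rep(0, m)),
                            pp1, Kd, Qf, dt)
      weeks <- weeks + 1L
      nce <- wk$final$Ce; nci <- wk$final$Ci
      scale <- max(abs(nce), abs(nci), 1e-12)
      delta <- max(abs(nce - xce), abs(nci - xci)) / scale
      xce <- nce; xci <- nci
      if (delta < tol) break
      if (weeks >= max_weeks)
        stop(sprintf(
          "weekly cycle did not reach a periodic steady state after %d weeks (last relative change %.3e)",
          weeks, delta))
    }
  }

  # one recorded pass from the steady state
  wk <- .propagate_week(tl, list(Ve = Ve0, Ce = xce, Ci = xci, Rm = rep(0, m)),
                        pp1, Kd, Qf, dt)
  pre_ce <- sapply(wk$pre, `[[`, "Ce"); pre_ci <- sapply(wk$pre, `[[`, "Ci")
  pre_ve <- sapply(wk$pre, `[[`, "Ve")
  post_ce <- sapply(wk$post, `[[`, "Ce"); post_ci <- sapply(wk$post, `[[`, "Ci")
  post_ve <- sapply(wk$post, `[[`, "Ve")
  dim(pre_ce) <- dim(pre_ci) <- dim(pre_ve) <- c(m, f)
  dim(post_ce) <- dim(post_ci) <- dim(post_ve) <- c(m, f)
  if (any(sp)) {          # report the single pool's concentration for both
    pre_ci[sp, ] <- pre_ce[sp, ]
    post_ci[sp, ] <- post_ce[sp, ]
  }
  Vi_m <- matrix(Vi, m, f)
  pre_eq <- (pre_ve * pre_ce + Vi_m * pre_ci) / (pre_ve + Vi_m)
  post_eq <- (post_ve * post_ce + Vi_m * post_ci) / (post_ve + Vi_m)

  removed <- wk$final$Rm
  expected <- G * .WEEK_MIN
  mbe <- if (method == "transient") rep(NA_real_, m)
         else ifelse(expected > 0,
                     abs(removed - expected) / expected,
                     abs(removed) / pmax(V_total * pmax(xce, 0), 1))

  # session doses via variable-volume single-pool inversion
  spktv <- ektv <- matrix(0, m, f)
  n_warn <- 0L
  for (s in seq_len(f)) {
    Vpre <- pre_ve[, s] + Vi
    for (j in seq_len(m)) {
      if (Kd[s, j] <= 0) next
      c0 <- pre_ce[j, s]
      if (c0 <= 1e-14) next
      sk <- .vvsp_ktv(c0, post_ce[j, s], tl$Td[s], Vpre[j], V_total[j],
                      G[j], Kru[j], r[j])
      ek <- .vvsp_ktv(c0, post_eq[j, s], tl$Td[s], Vpre[j], V_total[j],
                      G[j], Kru[j], r[j])
      if (sk == 0 || ek == 0) n_warn <- n_warn + 1L
      spktv[j, s] <- sk
      ektv[j, s] <- ek
    }
  }
  if (n_warn > 0L)
    warning(sprintf(
      "%d session(s) showed no concentration drop despite Kd > 0; dose reported as 0",
      n_warn))

  mean_pre_eq <- rowMeans(pre_eq)
  stdktv <- stdktv_gotch <- numeric(m)
  if (method == "transient") {
    stdktv <- stdktv_gotch <- rep(NA_real_, m)
  } else {
    pos <- G > 0
    if (any(pos & mean_pre_eq <= 0))
      stop("internal inconsistency: G > 0 with zero mean pre-dialysis concentration")
    stdktv_gotch[pos] <- G[pos] / mean_pre_eq[pos] * .WEEK_MIN / V_total[pos]
    e_bar <- rowMeans(ektv)
    uf_corr <- 1 - 0.74 / f * weekly_uf / V_total
    stdktv <- .stdktv_fixed_volume(e_bar, rep(mean(tl$Td), m), rep(f, m)) /
      uf_corr + Kru * .WEEK_MIN / V_total
  }

  list(m = m, f = f, days = tl$days, Td = tl$Td, gap = tl$gap,
       pre_ce = pre_ce, pre_ci = pre_ci, pre_eq = pre_eq, pre_ve = pre_ve,
       post_ce = post_ce, post_ci = post_ci, post_eq = post_eq,
       spktv = spktv, ektv = ektv, stdktv = stdktv,
       stdktv_gotch = stdktv_gotch,
       removed = removed, mass_balance_error = mbe,
       converged = if (method == "transient") rep(NA, m)
                   else mbe < 1e-3 | expected == 0,
       weeks = weeks, x_star = cbind(Ce = xce, Ci = xci))
}

.stop_unbounded <- function(kd_col, kru) {
  if (all(kd_col <= 0) && kru <= 0)
    stop("unbounded accumulation: G > 0 with no dialytic or renal clearance; no periodic steady state exists")
  stop("weekly cycle map is singular; no periodic steady state found")
}

#' Simulate one week of dialysis at periodic steady state
#'
#' Solves the two-pool variable-volume urea kinetic model over a repeating
#' weekly schedule and returns the periodic steady state: pre- and
#' post-dialysis concentrations for every session, the single-pool and
#' equilibrated session doses (spKt/V, eKt/V), and the weekly standard
#' Kt/V. The reported `stdktv` is the guideline's operational definition —
#' the fixed-volume weekly-clearance formula evaluated at the simulated
#' equilibrated dose, divided by the ultrafiltration correction
#' `1 - 0.74/N * UFweek/V` and with the continuous residual clearance
#' credited in full (`+ Kru * 10080 / V`). The classical
#' generation-over-mean-pre-dialysis-concentration (peak-concentration)
#' variant is reported alongside as `stdktv_gotch`; see the package
#' vignette for why the two differ and which one the coefficient table
#' refers to. Fluid intake is continuous at `weekly_uf / 10080` mL/min and each
#' session removes exactly the fluid accumulated since the previous one, so
#' the post-dialysis volume returns to the patient's dry `V_total` and the
#' cycle is exactly periodic.
#'
#' `method = "affine"` exploits the linearity of the concentration dynamics:
#' two basis initial conditions and the generation-driven solution are
#' propagated over one week and the fixed point of the resulting affine map
#' is solved directly. `method = "iterate"` repeats weekly propagation until
#' the start-of-week state stabilises (relative tolerance 1e-10, at most
#' `max_weeks` weeks); it is slower and exists as an independent
#' cross-check of the affine solution. `method = "transient"` propagates a
#' single week from the uniform starting concentration `conc_init` without
#' seeking a steady state (useful for initial-value checks); its `stdktv`,
#' `converged` and `mass_balance_error` are `NA`.
#'
#' @param patient A [patient_kinetics()] object.
#' @param schedule A [weekly_schedule()].
#' @param rx A [session_rx()] applied to every session, or a list of one per
#'   dialysis day.
#' @param weekly_uf Weekly ultrafiltration volume, mL. Defaults to the sum
#'   of the sessions' `UF_volume`.
#' @param dt RK4 integration step, minutes.
#' @param method `"affine"` (direct fixed point, default), `"iterate"` or
#'   `"transient"`.
#' @param conc_init Initial/degenerate concentration, mg/mL. Used as the
#'   iteration start and as the reported state in the fully degenerate case
#'   (no clearance, no generation), where any constant concentration is a
#'   steady state.
#' @param max_weeks,tol Iteration controls for `method = "iterate"`.
#' @param kc_collapse Kc threshold (mL/min) above which the model is
#'   integrated in its exact single-pool limit.
#' @return Object of class `weekly_cycle`: list with `sessions` (data frame
#'   of per-session day, gap, pre/post concentrations and doses), `stdktv`,
#'   `stdktv_gotch`, `weekly_removed_mass` (mg), `weeks_iterated`,
#'   `converged`, `mass_balance_error`, `labday_index`, plus the inputs.
#' @examples
#' pt <- patient_kinetics(V_total = 35000, Kru = 2, G = 6)
#' sched <- parse_schedule("135", 1)
#' cyc <- simulate_weekly_cycle(pt, sched, session_rx(Kd = 180, Td = 180),
#'                              weekly_uf = 10000)
#' cyc$stdktv
#' @export
simulate_weekly_cycle <- function(patient, schedule, rx, weekly_uf = NULL,
                                  dt = 1,
                                  method = c("affine", "iterate", "transient"),
                                  conc_init = 1, max_weeks = 200L,
                                  tol = 1e-10, kc_collapse = 1e4) {
  stopifnot(inherits(patient, "patient_kinetics"),
            inherits(schedule, "weekly_schedule"))
  method <- match.arg(method)
  f <- schedule$frequency
  if (inherits(rx, "session_rx")) rx <- rep(list(rx), f)
  if (!is.list(rx) || length(rx) != f ||
      !all(vapply(rx, inherits, logical(1), "session_rx")))
    stop("rx must be a session_rx or a list with one session_rx per dialysis day")
  Kd <- vapply(rx, `[[`, numeric(1), "Kd")
  Td <- vapply(rx, `[[`, numeric(1), "Td")
  if (is.null(weekly_uf))
    weekly_uf <- sum(vapply(rx, `[[`, numeric(1), "UF_volume"))

  pars <- list(V_total = patient$V_total, ecf = patient$ecf_fraction,
               Kc = patient$Kc, Kru = patient$Kru, G = patient$G,
               weekly_uf = weekly_uf, Kd = matrix(Kd, ncol = 1))
  sol <- .solve_cycle(schedule$days, Td, pars, dt = dt, method = method,
                      conc_init = conc_init, kc_collapse = kc_collapse,
                      max_weeks = max_weeks, tol = tol)
  sessions <- data.frame(
    day = sol$days,
    gap_before = sol$gap,
    Td = sol$Td,
    Kd = Kd,
    pre_conc_equilibrated = sol$pre_eq[1, ],
    pre_conc_extracellular = sol$pre_ce[1, ],
    post_conc_extracellular = sol$post_ce[1, ],
    post_conc_equilibrated = sol$post_eq[1, ],
    spktv = sol$spktv[1, ],
    ektv = sol$ektv[1, ]
  )
  structure(
    list(sessions = sessions,
         stdktv = sol$stdktv[1],
         stdktv_gotch = sol$stdktv_gotch[1],
         weekly_removed_mass = sol$removed[1],
         weeks_iterated = sol$weeks,
         converged = sol$converged[1],
         mass_balance_error = sol$mass_balance_error[1],
         labday_index = match(schedule$labdayofwk, schedule$days),
         patient = patient, schedule = schedule,
         weekly_uf = weekly_uf, dt = dt, method = method),
    class = "weekly_cycle"
  )
}

#' @export
print.weekly_cycle <- function(x, ...) {
  cat(sprintf("Weekly cycle at periodic steady state (%d sessions/week, %s solver)\n",
              nrow(x$sessions), x$method))
  print(x$sessions[, c("day", "pre_conc_equilibrated", "post_conc_equilibrated",
                       "spktv", "ektv")], digits = 4)
  cat(sprintf("stdKt/V = %.3f v/wk; mass balance error %.2e; converged: %s\n",
              x$stdktv, x$mass_balance_error, x$converged))
  invisible(x)
}

#' Standard Kt/V of a simulated weekly cycle
#'
#' Recomputes the weekly standard Kt/V from a simulated cycle using the
#' operational definition: the fixed-volume weekly-clearance formula at the
#' mean equilibrated session dose, divided by the ultrafiltration
#' correction `1 - 0.74/N * UFweek/V`, plus the fully credited continuous
#' residual clearance `Kru * 10080 / V_total`. With no dialytic clearance
#' and Kru > 0 this reduces to `Kru * 10080 / V_total`, the
#' continuous-clearance limit (equivalently, a target of 2.3 v/wk at
#' V = 35 L corresponds to a continuous clearance of
#' `2.3 * 35000 / 10080 ~ 8` mL/min).
#'
#' The classical peak-concentration variant (generation over mean
#' equilibrated pre-dialysis concentration) is available as
#' `gotch = TRUE`; it is not additive in Kru and is reported for
#' comparison only.
#'
#' @param result A `weekly_cycle` from [simulate_weekly_cycle()].
#' @param patient The [patient_kinetics()] used (defaults to the one stored
#'   in `result`).
#' @param gotch Return the peak-concentration variant instead.
#' @return Standard Kt/V in volumes/week.
#' @export
compute_stdktv <- function(result, patient = result$patient, gotch = FALSE) {
  stopifnot(inherits(result, "weekly_cycle"))
  if (!isTRUE(result$converged))
    stop("weekly cycle did not converge; stdKt/V undefined")
  if (patient$G == 0) return(0)
  if (gotch) {
    cbar <- mean(result$sessions$pre_conc_equilibrated)
    if (cbar <= 0)
      stop("internal inconsistency: G > 0 with zero mean pre-dialysis concentration")
    return(patient$G / cbar * .WEEK_MIN / patient$V_total)
  }
  f <- nrow(result$sessions)
  uf_corr <- 1 - 0.74 / f * result$weekly_uf / patient$V_total
  .stdktv_fixed_volume(mean(result$sessions$ektv),
                       mean(result$sessions$Td), f) / uf_corr +
    patient$Kru * .WEEK_MIN / patient$V_total
}

#' Simulate every point of a parameter grid
#'
#' Runs the weekly-cycle simulator at each grid point of a simulation unit
#' and reports the weekly stdKt/V together with the lab-day session doses.
#' Points sharing a session length are propagated together as columns of
#' one batched integration.
#'
#' @param grid A [build_parameter_grid()] object.
#' @param dt RK4 step, minutes.
#' @param method Steady-state solver, see [simulate_weekly_cycle()].
#' @return A data frame: the grid point parameters plus `stdktv`,
#'   `ektv_lab`, `spktv_lab`, `converged` and `mass_balance_error`.
#' @examples
#' \donttest{
#' g <- build_parameter_grid(canonical_units()[[3]])
#' head(simulate_grid(g))
#' }
#' @export
simulate_grid <- function(grid, dt = 1, method = "affine") {
  stopifnot(inherits(grid, "parameter_grid"))
  sched <- grid$unit$schedule
  lab <- match(sched$labdayofwk, sched$days)
  pts <- grid$points
  out <- data.frame(pts,
                    stdktv = NA_real_, stdktv_gotch = NA_real_,
                    ektv_lab = NA_real_,
                    spktv_lab = NA_real_, converged = NA,
                    mass_balance_error = NA_real_)
  for (td in unique(pts$Td)) {
    sel <- which(pts$Td == td)
    m <- length(sel)
    pars <- list(V_total = rep(grid$fixed$V, m),
                 ecf = 1 / 3,
                 Kc = .default_kc(grid$fixed$V),
                 Kru = pts$Kru[sel], G = pts$G[sel],
                 weekly_uf = grid$fixed$weekly_uf,
                 Kd = matrix(rep(pts$Kd[sel], each = sched$frequency),
                             nrow = sched$frequency))
    sol <- .solve_cycle(sched$days, rep(td, sched$frequency), pars,
                        dt = dt, method = method)
    out$stdktv[sel] <- sol$stdktv
    out$stdktv_gotch[sel] <- sol$stdktv_gotch
    out$ektv_lab[sel] <- sol$ektv[, lab]
    out$spktv_lab[sel] <- sol$spktv[, lab]
    out$converged[sel] <- sol$converged
    out$mass_balance_error[sel] <- sol$mass_balance_error
  }
  out
}

#' Serialise a weekly-cycle result as JSON
#'
#' Versioned JSON serialisation of a [simulate_weekly_cycle()] result.
#'
#' @param result A `weekly_cycle` object.
#' @param path File to write; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_cycle_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "weekly_cycle"))
  payload <- list(
    format = "ureadose/weekly_cycle",
    version = "1.0",
    schedule = list(days = result$schedule$days,
                    labdayofwk = result$schedule$labdayofwk),
    patient = unclass(result$patient),
    weekly_uf = result$weekly_uf,
    sessions = result$sessions,
    stdktv = result$stdktv,
    weekly_removed_mass = result$weekly_removed_mass,
    weeks_iterated = result$weeks_iterated,
    converged = result$converged,
    mass_balance_error = result$mass_balance_error
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
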