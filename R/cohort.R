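# Seeded synthetic session cohort emulating the marginal moment structure
# of a home-haemodialysis population, plus the validation pipeline that
# runs on it: formula-vs-simulator agreement and the delivered-vs-
# prescribed treatment-frequency comparison.

# Truncated-normal sampling by inverse CDF; deterministic under set.seed.
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.tnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location adjustment so the *truncated* mean equals the target mean.
.tnorm_location <- function(target, sd, lower, upper) {
  stats::uniroot(function(mu) .tnorm_mean(mu, sd, lower, upper) - target,
                 interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

.rtnorm_matched <- function(n, target, sd, lower, upper) {
  mu <- .tnorm_location(target, sd, lower, upper)
  .rtnorm(n, mu, sd, lower, upper)
}

#' Specification of a synthetic session cohort
#'
#' Marginal moments (mean, SD) and physiologic truncation bounds for each
#' session-level variable, the weekly-frequency mix, and the urine-producing
#' fraction. Defaults emulate the moment structure of a prevalent
#' home-haemodialysis population treated with low-dialysate-flow devices:
#' blood flow 343 +/- 26.2 mL/min, dialysate flow 185 +/- 18 mL/min,
#' session length 152 +/- 13.1 min, post-dialysis weight 73.6 +/- 18.3 kg,
#' ultrafiltration 1.0 +/- 0.63 L/session, per-session eKt/V
#' 0.677 +/- 0.163, distribution volume 33.0 +/- 9.03 L; most sessions are
#' anuric, with residual clearance 4.0 +/- 3.0 mL/min in the urine-producing
#' minority; delivered frequencies 3..7 per week in proportions
#' 5:13:49:127:37.
#'
#' Variables are drawn independently (the emulated population is described
#' by marginal moments only) from truncated normals whose location is
#' adjusted so the truncated mean equals the target mean.
#'
#' @param n_sessions Number of sessions to generate.
#' @param seed Integer seed; the generated table is a pure function of the
#'   spec including the seed.
#' @param moments Named list of `c(mean, sd, lower, upper)` per variable:
#'   `Qb`, `Qd`, `Td`, `post_weight`, `UF_session`, `V`, `ektv`, `G`, `Kru`.
#' @param frequency_weights Weights over 3..7 sessions/week (normalised
#'   internally).
#' @param urine_fraction Probability that a session's patient produces
#'   urine (non-zero Kru).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sessions = 231L, seed = 1L,
                        moments = list(
                          Qb = c(343, 26.2, 250, 450),
                          Qd = c(185, 18, 130, 300),
                          Td = c(152, 13.1, 90, 240),
                          post_weight = c(73.6, 18.3, 35, 140),
                          UF_session = c(1.0, 0.63, 0, 4),
                          V = c(33.0, 9.03, 15, 60),
                          ektv = c(0.677, 0.163, 0.25, 1.3),
                          G = c(6.27, 1.75, 2.78, 9.76),
                          Kru = c(4.0, 3.0, 0.5, 15)
                        ),
                        frequency_weights = c(`3` = 5, `4` = 13, `5` = 49,
                                              `6` = 127, `7` = 37),
                        urine_fraction = 20 / 231) {
  n_sessions <- as.integer(n_sessions)
  if (is.na(n_sessions) || n_sessions < 0L) stop("n_sessions must be >= 0")
  for (nm in names(moments)) {
    m <- moments[[nm]]
    if (length(m) != 4L || m[2L] <= 0 || m[3L] >= m[4L] ||
        m[1L] <= m[3L] || m[1L] >= m[4L])
      stop(sprintf("infeasible moment specification for %s", nm))
  }
  w <- frequency_weights / sum(frequency_weights)
  if (any(w < 0)) stop("frequency weights must be non-negative")
  structure(
    list(n_sessions = n_sessions, seed = as.integer(seed),
         moments = moments, frequency_weights = w,
         urine_fraction = urine_fraction),
    class = "cohort_spec"
  )
}

#' Generate a synthetic session cohort
#'
#' Draws one row per session: treatment schedule (canonical day pattern for
#' the drawn frequency, Monday lab day), session length, flows, weights,
#' ultrafiltration, distribution volume, residual clearance (zero for the
#' anuric majority) and generation rate. The dialyser clearance is
#' back-computed from a drawn per-session eKt/V via the Tattersall relation
#' and the single-pool identity `Kd = spKt/V * V / Td`; draws implying
#' `Kd > Qd` (impossible with a low dialysate flow) are rejected and
#' redrawn. Session lengths are rounded to whole minutes.
#'
#' The same spec (including seed) always yields the identical table.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per session, in the session-CSV dialect
#'   (see [read_sessions()]) plus kinetic-truth columns `V_L`, `Kru`,
#'   `G_mgmin`, `UF_L_session`, `weekly_uf_L`, `ektv_drawn`, `frequency`.
#' @examples
#' head(generate_cohort(cohort_spec(n_sessions = 5, seed = 42)))
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_sessions
  mom <- spec$moments
  empty <- data.frame(
    patient_id = character(0), schedule = character(0),
    labdayofwk = integer(0), frequency = integer(0), Td_min = numeric(0),
    Qb = numeric(0), Qd = numeric(0), Kd = numeric(0),
    pre_weight_kg = numeric(0), post_weight_kg = numeric(0),
    UF_L_session = numeric(0), weekly_uf_L = numeric(0),
    V_L = numeric(0), Kru = numeric(0), G_mgmin = numeric(0),
    ektv_drawn = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(old(), add = TRUE)

  draw <- function(nm, k = n) {
    m <- mom[[nm]]
    .rtnorm_matched(k, m[1L], m[2L], m[3L], m[4L])
  }
  Qb <- draw("Qb")
  Qd <- draw("Qd")
  Td <- round(draw("Td"))
  post_w <- draw("post_weight")
  uf <- draw("UF_session")
  V <- draw("V")
  G <- draw("G")
  has_urine <- stats::runif(n) < spec$urine_fraction
  Kru <- ifelse(has_urine, draw("Kru"), 0)

  freqs <- as.integer(names(spec$frequency_weights))
  frequency <- sample(freqs, n, replace = TRUE, prob = spec$frequency_weights)
  patterns <- .canonical_patterns[frequency]

  # eKt/V drawn, Kd back-computed; redraw where the implied Kd exceeds Qd
  ektv <- draw("ektv")
  kd_from <- function(e) e * (Td + 35) / Td * (V * 1000) / Td
  Kd <- kd_from(ektv)
  for (it in 1:100) {
    bad <- which(Kd > Qd)
    if (length(bad) == 0L) break
    ektv[bad] <- draw("ektv", length(bad))
    Kd[bad] <- kd_from(ektv)[bad]
  }
  if (length(bad <- which(Kd > Qd)) > 0L) {  # give up gracefully: cap at Qd
    Kd[bad] <- Qd[bad]
    ektv[bad] <- Kd[bad] * Td[bad] / (V[bad] * 1000) * Td[bad] / (Td[bad] + 35)
  }

  data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    schedule = patterns,
    labdayofwk = 1L,
    frequency = frequency,
    Td_min = Td,
    Qb = Qb, Qd = Qd, Kd = Kd,
    pre_weight_kg = post_w + uf,  # 1 L of fluid ~ 1 kg
    post_weight_kg = post_w,
    UF_L_session = uf,
    weekly_uf_L = uf * frequency,
    V_L = V, Kru = Kru, G_mgmin = G,
    ektv_drawn = ektv,
    stringsAsFactors = FALSE
  )
}

# Save/restore RNG state so cohort generation does not disturb the caller's
# random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Write a cohort to CSV
#'
#' Deterministic CSV serialisation (fixed 15-significant-digit formatting,
#' no row names): the same cohort always produces a byte-identical file.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  num <- vapply(cohort, is.numeric, logical(1))
  out <- cohort
  out[num] <- lapply(cohort[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session CSV
#'
#' Reads a clinical or synthetic session table. Required columns:
#' `patient_id`, `schedule`, `labdayofwk`, `Td_min`, `Qb`, `Qd`. Optional:
#' `Kd`, `pre_BUN`, `post_BUN`, `pre_weight_kg`, `post_weight_kg`,
#' `urine_volume_L`, `urine_ureaN_mgdl`, `collection_min` and the
#' kinetic-truth columns written by [write_cohort_csv()].
#'
#' @param path CSV file path.
#' @return Data frame with `schedule` as character.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(schedule = "character"))
  need <- c("patient_id", "schedule", "labdayofwk", "Td_min", "Qb", "Qd")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  df
}

#' Formula-based dose work-up of clinical sessions
#'
#' For sessions with measured pre/post BUN, computes the estimator-based
#' doses (spKt/V from the second-generation formula, eKt/V from the rate
#' equation or Tattersall correction), residual clearance from the urine
#' collection when present, normalized KRUn (volume from the
#' Watson-weight-free `V_L` column when present, else 0.58 x post weight),
#' and the minimum-frequency prescription for each session.
#'
#' @param sessions Data frame from [read_sessions()].
#' @param ektv_method Estimator for eKt/V, see [ektv_from_spktv()].
#' @param ... Passed to [prescribe_frequency()] (targets, cap, table).
#' @return The input with columns `spktv_est`, `ektv_est`, `Kru_est`,
#'   `KRUn`, `prescribed_frequency`, `prescribed_ektv_req` appended.
#' @export
analyze_sessions <- function(sessions, ektv_method = "rate_equation", ...) {
  n <- nrow(sessions)
  has_bun <- all(c("pre_BUN", "post_BUN") %in% names(sessions))
  sp <- rep(NA_real_, n); ek <- rep(NA_real_, n)
  if (has_bun) {
    ok <- which(is.finite(sessions$pre_BUN) & is.finite(sessions$post_BUN) &
                sessions$post_BUN > 0 & sessions$post_BUN < sessions$pre_BUN)
    if (length(ok)) {
      R <- sessions$post_BUN[ok] / sessions$pre_BUN[ok]
      ufl <- if ("pre_weight_kg" %in% names(sessions))
        pmax(sessions$pre_weight_kg[ok] - sessions$post_weight_kg[ok], 0)
      else rep(0, length(ok))
      sp[ok] <- spktv_daugirdas(R, sessions$Td_min[ok], ufl,
                                sessions$post_weight_kg[ok])
      ek[ok] <- ektv_from_spktv(sp[ok], sessions$Td_min[ok], ektv_method)
    }
  }
  kru <- rep(0, n)
  if (all(c("urine_volume_L", "urine_ureaN_mgdl", "collection_min") %in%
          names(sessions)) && has_bun) {
    uok <- which(is.finite(sessions$urine_volume_L) &
                 sessions$urine_volume_L > 0)
    if (length(uok))
      kru[uok] <- kru_from_urine(sessions$urine_volume_L[uok],
                                 sessions$urine_ureaN_mgdl[uok],
                                 sessions$collection_min[uok],
                                 sessions$pre_BUN[uok], sessions$post_BUN[uok])
  } else if ("Kru" %in% names(sessions)) {
    kru <- sessions$Kru
  }
  V_L <- if ("V_L" %in% names(sessions)) sessions$V_L
         else 0.58 * sessions$post_weight_kg
  krun <- normalize_kru(kru, V_L)
  presc <- lapply(seq_len(n), function(i) {
    prescribe_frequency(Kru = kru[i], V = V_L[i], ...)
  })
  sessions$spktv_est <- sp
  sessions$ektv_est <- ek
  sessions$Kru_est <- kru
  sessions$KRUn <- krun
  sessions$prescribed_frequency <- vapply(presc, `[[`, numeric(1), "frequency")
  sessions$prescribed_ektv_req <- vapply(presc, `[[`, numeric(1), "ektv_req")
  sessions
}

# Simulate every cohort session to periodic steady state, batched by
# (schedule, Td). Returns stdktv_sim and lab-day ektv_sim per session.
.simulate_cohort <- function(cohort, dt = 1) {
  n <- nrow(cohort)
  stdktv <- ektv <- spktv <- mbe <- rep(NA_real_, n)
  conv <- rep(NA, n)
  key <- paste(cohort$schedule, cohort$Td_min)
  for (k in unique(key)) {
    sel <- which(key == k)
    sched <- parse_schedule(cohort$schedule[sel[1L]],
                            cohort$labdayofwk[sel[1L]])
    lab <- match(sched$labdayofwk, sched$days)
    m <- length(sel)
    V <- cohort$V_L[sel] * 1000
    pars <- list(V_total = V, ecf = 1 / 3, Kc = .default_kc(V),
                 Kru = cohort$Kru[sel], G = cohort$G_mgmin[sel],
                 weekly_uf = cohort$weekly_uf_L[sel] * 1000,
                 Kd = matrix(rep(cohort$Kd[sel], each = sched$frequency),
                             nrow = sched$frequency))
    sol <- .solve_cycle(sched$days,
                        rep(cohort$Td_min[sel[1L]], sched$frequency),
                        pars, dt = dt)
    stdktv[sel] <- sol$stdktv
    ektv[sel] <- sol$ektv[, lab]
    spktv[sel] <- sol$spktv[, lab]
    conv[sel] <- sol$converged
    mbe[sel] <- sol$mass_balance_error
  }
  data.frame(stdktv_sim = stdktv, ektv_sim = ektv, spktv_sim = spktv,
             converged = conv, mass_balance_error = mbe)
}

#' Agreement of the simplified formula with the kinetic simulator
#'
#' Simulates each cohort session to its weekly periodic steady state (the
#' reference), evaluates the simplified formula
#' `a + b * KRUn + c * eKt/V` with the same lab-day eKt/V (the comparator),
#' and summarises agreement by Bland-Altman statistics, regression against
#' the reference and a paired t test. Differences are formula minus
#' simulator.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param table Coefficient table used by the formula (default canonical).
#' @param dt RK4 step, minutes.
#' @return List with `report` (an `agreement_report`), `data` (per-session
#'   simulated and formula stdKt/V), and `anuric_report` (agreement on the
#'   anuric subset, `NULL` when it is too small).
#' @export
evaluate_agreement <- function(cohort, table = coefficient_table(), dt = 1) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  sim <- .simulate_cohort(cohort, dt = dt)
  krun <- normalize_kru(cohort$Kru, cohort$V_L)
  idx <- match(cohort$frequency, table$frequency)
  if (any(is.na(idx)))
    stop("coefficient table lacks rows for some cohort frequencies")
  formula_std <- table$a[idx] + table$b[idx] * krun + table$c[idx] * sim$ektv_sim
  data <- cbind(cohort[, c("patient_id", "frequency")],
                KRUn = krun, sim,
                stdktv_formula = formula_std)
  report <- .agreement_report(sim$stdktv_sim, formula_std)
  anuric <- which(cohort$Kru == 0)
  anuric_report <- if (length(anuric) >= 3L)
    .agreement_report(sim$stdktv_sim[anuric], formula_std[anuric])
  else NULL
  list(report = report, data = data, anuric_report = anuric_report)
}

#' Delivered versus prescribed treatment frequency
#'
#' Applies the minimum-frequency prescription rule to every cohort session
#' and compares the prescribed weekly frequencies with the delivered ones:
#' per-frequency counts, means +/- SD and a paired t test.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param target_stdktv,ektv_cap Prescription parameters, see
#'   [prescribe_frequency()].
#' @param table Coefficient table (default canonical).
#' @return List with `counts` (7 x 2 matrix of delivered / prescribed
#'   session counts), `delivered_mean`, `delivered_sd`, `prescribed_mean`,
#'   `prescribed_sd`, `paired_t` and the per-session `prescribed` vector.
#' @export
frequency_reduction_report <- function(cohort, target_stdktv = 2.3,
                                       ektv_cap = 0.7,
                                       table = coefficient_table()) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  prescribed <- vapply(seq_len(nrow(cohort)), function(i) {
    prescribe_frequency(Kru = cohort$Kru[i], V = cohort$V_L[i],
                        target_stdktv = target_stdktv, ektv_cap = ektv_cap,
                        table = table)$frequency
  }, numeric(1))
  counts <- rbind(
    delivered = tabulate(cohort$frequency, nbins = 7L),
    prescribed = tabulate(prescribed, nbins = 7L)
  )
  colnames(counts) <- as.character(1:7)
  list(counts = counts,
       delivered_mean = mean(cohort$frequency),
       delivered_sd = stats::sd(cohort$frequency),
       prescribed_mean = mean(prescribed),
       prescribed_sd = stats::sd(prescribed),
       paired_t = paired_t(cohort$frequency, prescribed),
       prescribed = prescribed)
}
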