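test_that("KRUn normalisation rescales to the 35 L reference volume", {
  expect_equal(normalize_kru(2, 30), 2 / 30 * 35, tolerance = 1e-12)
  expect_equal(normalize_kru(4, 35), 4)
  expect_error(normalize_kru(3, 0), "V must be positive")
  expect_error(normalize_kru(-1, 30), "Kru")
})

test_that("the simplified formula reproduces the worked dose predictions", {
  # 5/week patient: Kru 2 mL/min at V 30 L, eKt/V 0.6 -> 2.89 v/wk
  got <- stdktv_formula(canonical_coefficients(5), normalize_kru(2, 30), 0.6)
  expect_equal(got, 2.89, tolerance = 0.005)

  # 3/week at KRUn 2, eKt/V 0.7
  expect_equal(stdktv_formula(canonical_coefficients(3), 2, 0.7),
               0.324 + 0.288 * 2 + 1.781 * 0.7, tolerance = 1e-12)

  # zero dose, anuric: the intercept alone
  expect_equal(stdktv_formula(canonical_coefficients(4), 0, 0), 0.471)
})

test_that("required dose solves the formula for the target and clamps at zero", {
  r6 <- ektv_required(canonical_coefficients(6), KRUn = 0)
  expect_equal(r6$ektv_req, (2.3 - 0.565) / 3.604, tolerance = 1e-12)
  expect_false(r6$renal_sufficient)

  r5 <- ektv_required(canonical_coefficients(5), KRUn = 0)
  expect_equal(r5$ektv_req, 0.6268, tolerance = 5e-4)

  r1 <- ektv_required(canonical_coefficients(1), KRUn = 8)
  expect_equal(r1$ektv_req, 0)
  expect_true(r1$renal_sufficient)
})

test_that("formula and required dose are exact inverses when unclamped", {
  for (fr in 1:7) {
    k <- canonical_coefficients(fr)
    for (krun in seq(0, 6, by = 1.5)) {
      req <- ektv_required(k, krun, target = 2.3)
      if (!req$renal_sufficient)
        expect_equal(stdktv_formula(k, krun, req$ektv_req), 2.3,
                     tolerance = 1e-12)
    }
  }
})

test_that("required dose is non-increasing in KRUn and in frequency", {
  # The frequency ordering holds over the clinically relevant range; above
  # KRUn ~ 5 the published 4/week and 5/week rows cross because the
  # intercepts are not monotone in frequency (a drops from 0.471 to 0.358).
  krun <- seq(0, 5, by = 0.5)
  prev <- NULL
  for (fr in 1:7) {
    k <- canonical_coefficients(fr)
    req <- ektv_required(k, seq(0, 8, by = 0.5))$ektv_req
    expect_true(all(diff(req) <= 1e-12))           # non-increasing in KRUn
    req5 <- ektv_required(k, krun)$ektv_req
    if (!is.null(prev)) expect_true(all(req5 <= prev + 1e-12))
    prev <- req5
  }
})

test_that("KRUn cut-offs at the 0.7 dose cap match the published rule of thumb", {
  co <- vapply(1:4, function(fr) krun_cutoff(canonical_coefficients(fr)),
               numeric(1))
  expect_equal(co[1], (2.3 - 0.126 - 0.543 * 0.7) / 0.288, tolerance = 1e-12)
  expect_equal(co, c(6.229, 4.255, 2.532, 0.675), tolerance = 1e-3)
  # once a week needs KRUn > 6; twice >= 4; thrice >= 2; four times >= ~1
  expect_gte(co[1], 6); expect_gte(co[2], 4); expect_gte(co[3], 2)
  expect_gte(co[4], 0.675)
})

test_that("minimum-frequency selection walks the feasibility table", {
  p1 <- prescribe_frequency(Kru = 7, V = 35)
  expect_equal(p1$frequency, 1L)
  expect_equal(p1$ektv_req, 0.2910, tolerance = 5e-4)
  expect_true(p1$feasible)

  p5 <- prescribe_frequency(Kru = 0, V = 35)
  expect_equal(p5$frequency, 5L)
  expect_equal(p5$ektv_req, 0.6268, tolerance = 5e-4)
  # 4/week would need more than the 0.7 cap
  tab <- p5$per_frequency_table
  expect_gt(tab$ektv_req[tab$frequency == 4], 0.7)

  p4 <- prescribe_frequency(Kru = 2.5, V = 35)
  expect_equal(p4$frequency, 4L)
  expect_equal(p4$ektv_req, 0.4750, tolerance = 5e-4)

  # predicted stdKt/V meets the target whenever feasible
  for (kru in c(0, 2, 5, 9)) {
    p <- prescribe_frequency(Kru = kru, V = 35)
    expect_gte(p$stdktv_predicted, 2.3 - 1e-9)
    expect_equal(p$ektv_req == 0, p$renal_sufficient)
  }

  # infeasible under a restricted frequency set
  pinf <- prescribe_frequency(Kru = 0, V = 35, allowed_frequencies = c(1, 2))
  expect_false(pinf$feasible)
  expect_equal(pinf$frequency, 2L)
})

test_that("prescription graph lines are affine in KRUn with slope -b/c", {
  g <- prescription_graph(step = 0.1)
  for (fr in 1:7) {
    k <- canonical_coefficients(fr)
    d <- g[g$frequency == fr, ]
    pre_clamp <- d$ektv_req > 0
    slopes <- diff(d$ektv_req[pre_clamp]) / diff(d$KRUn[pre_clamp])
    if (length(slopes) > 1)
      expect_equal(slopes[-length(slopes)],
                   rep(-k$b / k$c, length(slopes) - 1), tolerance = 1e-9)
    expect_true(all(d$ektv_req >= 0))
  }
  # at KRUn = 0 required dose decreases strictly with frequency
  at0 <- g$ektv_req[g$KRUn == 0][order(unique(g$frequency))]
  expect_true(all(diff(at0) < 0))
  # the once-weekly line crosses the 0.7 cap at its cut-off
  d1 <- g[g$frequency == 1 & g$ektv_req > 0, ]
  cross <- stats::approx(d1$ektv_req, d1$KRUn, xout = 0.7)$y
  expect_equal(cross, krun_cutoff(canonical_coefficients(1)), tolerance = 1e-6)

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(g))
})
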