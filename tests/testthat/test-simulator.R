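test_that("null dynamics leave concentrations constant with zero stdKt/V", {
  p <- patient_kinetics(35000, Kru = 0, G = 0)
  cyc <- simulate_weekly_cycle(p, parse_schedule("135", 1), rx(Kd = 0, Td = 150),
                               weekly_uf = 0, conc_init = 0.8)
  expect_equal(cyc$sessions$pre_conc_equilibrated, rep(0.8, 3))
  expect_equal(cyc$sessions$post_conc_equilibrated, rep(0.8, 3))
  expect_equal(cyc$stdktv, 0)
  expect_equal(cyc$mass_balance_error, 0)
  expect_true(cyc$converged)
})

test_that("the single-pool limit reproduces the analytic exponential decay", {
  # Kc -> infinity, no UF, no generation: C(t) = C0 exp(-Kd t / V), so one
  # session with Kd Td / V = 1 drops the concentration to exp(-1)
  p <- patient_kinetics(35000, Kru = 0, G = 0, Kc = 1e9)
  cyc <- simulate_weekly_cycle(p, weekly_schedule(1), rx(Kd = 175, Td = 200),
                               weekly_uf = 0, method = "transient",
                               conc_init = 1)
  ratio <- cyc$sessions$post_conc_extracellular / cyc$sessions$pre_conc_extracellular
  expect_equal(ratio, exp(-1), tolerance = 1e-4)
  expect_equal(cyc$sessions$spktv, 1, tolerance = 1e-3)
  expect_equal(cyc$sessions$ektv, 1, tolerance = 1e-3)
  # equilibrated and extracellular coincide when there is one pool
  expect_equal(cyc$sessions$spktv, cyc$sessions$ektv, tolerance = 1e-9)
})

test_that("weekly mass balance closes at periodic steady state across the grid", {
  d <- simulate_grid(small_grid(canonical_units()[[5]]))
  expect_true(all(d$converged))
  expect_true(all(d$mass_balance_error < 1e-3))
  # rebound ordering: equilibrated dose below single-pool dose everywhere
  expect_true(all(d$ektv_lab < d$spktv_lab))
  cyc <- simulate_weekly_cycle(typical_patient(Kru = 2), parse_schedule("135", 1),
                               rx(Kd = 160, Td = 180), weekly_uf = 10000)
  expect_equal(cyc$weekly_removed_mass, 6 * 10080, tolerance = 1e-3)
})

test_that("with no dialytic clearance stdKt/V reduces to the continuous renal dose", {
  p <- patient_kinetics(35000, Kru = 2, G = 6)
  cyc <- simulate_weekly_cycle(p, parse_schedule("135", 1), rx(Kd = 0, Td = 150),
                               weekly_uf = 0)
  expect_equal(cyc$stdktv, 2 * 10080 / 35000, tolerance = 1e-9)
  expect_equal(cyc$stdktv_gotch, 2 * 10080 / 35000, tolerance = 1e-6)
  expect_equal(cyc$sessions$spktv, rep(0, 3))
  expect_equal(cyc$sessions$ektv, rep(0, 3))
})

test_that("generation without any clearance is rejected as unbounded", {
  p <- patient_kinetics(35000, Kru = 0, G = 6)
  expect_error(
    simulate_weekly_cycle(p, parse_schedule("135", 1), rx(Kd = 0, Td = 150),
                          weekly_uf = 0),
    "unbounded accumulation")
})

test_that("affine fixed-point and brute-force iteration agree to 1e-8", {
  cases <- list(
    list(sched = "135", Kru = 0, Kd = 180, Td = 180, uf = 10000),
    list(sched = "12345", Kru = 4, Kd = 120, Td = 150, uf = 10000),
    list(sched = "1", Kru = 2, Kd = 200, Td = 200, uf = 1000)
  )
  for (cs in cases) {
    p <- typical_patient(Kru = cs$Kru)
    s <- parse_schedule(cs$sched, 1)
    a <- simulate_weekly_cycle(p, s, rx(cs$Kd, cs$Td), weekly_uf = cs$uf)
    b <- simulate_weekly_cycle(p, s, rx(cs$Kd, cs$Td), weekly_uf = cs$uf,
                               method = "iterate")
    for (col in c("pre_conc_equilibrated", "post_conc_extracellular",
                  "post_conc_equilibrated"))
      expect_equal(a$sessions[[col]], b$sessions[[col]], tolerance = 1e-8)
    expect_true(b$weeks_iterated <= 200)
  }
})

test_that("stdKt/V increases with Kd, Td, Kru and treatment frequency", {
  u <- canonical_units()[[3]]
  kd <- simulate_grid(build_parameter_grid(u, Kru = 2, Kd = c(120, 160, 200),
                                           G = 6, Td = 150))$stdktv
  expect_true(all(diff(kd) > 0))
  td <- simulate_grid(build_parameter_grid(u, Kru = 2, Kd = 150, G = 6,
                                           Td = c(120, 150, 180, 200)))$stdktv
  expect_true(all(diff(td) > 0))
  kru <- simulate_grid(build_parameter_grid(u, Kru = c(0, 2, 4, 6), Kd = 150,
                                            G = 6, Td = 150))$stdktv
  expect_true(all(diff(kru) > 0))
  fq <- vapply(c(2, 4, 6), function(k) {
    simulate_grid(build_parameter_grid(canonical_units()[[k]], Kru = 2,
                                       Kd = 150, G = 6, Td = 150,
                                       weekly_uf = 10000))$stdktv
  }, numeric(1))
  expect_true(all(diff(fq) > 0))
})

test_that("renal clearance is credited additively in stdKt/V", {
  u <- canonical_units()[[5]]
  d <- simulate_grid(build_parameter_grid(u, Kru = c(0, 2, 4, 6), Kd = 150,
                                          G = 6, Td = 150))
  extra <- d$stdktv - d$stdktv[1]
  expect_equal(extra, d$Kru * 10080 / 35000, tolerance = 0.03)
})

test_that("compute_stdktv reproduces the stored weekly metrics", {
  p <- typical_patient(Kru = 3)
  cyc <- simulate_weekly_cycle(p, parse_schedule("12345", 1),
                               rx(Kd = 160, Td = 150), weekly_uf = 10000)
  expect_equal(compute_stdktv(cyc), cyc$stdktv, tolerance = 1e-12)
  expect_equal(compute_stdktv(cyc, gotch = TRUE), cyc$stdktv_gotch,
               tolerance = 1e-12)
  expect_true(cyc$stdktv > 0 && cyc$stdktv_gotch > 0)
})

test_that("weekly cycle results serialise to versioned JSON", {
  p <- typical_patient(Kru = 1)
  cyc <- simulate_weekly_cycle(p, parse_schedule("135", 1),
                               rx(Kd = 160, Td = 150), weekly_uf = 6000)
  path <- withr::local_tempfile(fileext = ".json")
  write_cycle_json(cyc, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$format, "ureadose/weekly_cycle")
  expect_equal(back$stdktv, cyc$stdktv, tolerance = 1e-12)
  expect_equal(nrow(back$sessions), 3L)
})
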