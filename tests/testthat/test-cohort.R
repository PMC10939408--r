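test_that("cohort generation is deterministic and bounded", {
  expect_equal(nrow(generate_cohort(cohort_spec(n_sessions = 0))), 0L)

  a <- generate_cohort(cohort_spec(n_sessions = 60, seed = 9))
  b <- generate_cohort(cohort_spec(n_sessions = 60, seed = 9))
  expect_identical(a, b)
  other <- generate_cohort(cohort_spec(n_sessions = 60, seed = 10))
  expect_false(identical(a, other))

  expect_true(all(a$V_L >= 15 & a$V_L <= 60))
  expect_true(all(a$Td_min >= 90 & a$Td_min <= 240))
  expect_true(all(a$Kru >= 0))
  expect_true(all(a$Kd <= a$Qd + 1e-9))      # low-dialysate-flow constraint
  expect_true(all(a$frequency %in% 3:7))
  expect_true(all(a$labdayofwk == 1L))

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, f1)
  write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_sessions(f1)
  expect_equal(nrow(back), 60L)
  expect_type(back$schedule, "character")
})

test_that("large-sample moments match the emulated population", {
  co <- generate_cohort(cohort_spec(n_sessions = 5000, seed = 7))
  targets <- list(Qb = c("Qb", 343, 26.2), Qd = c("Qd", 185, 18),
                  Td = c("Td_min", 152, 13.1), V = c("V_L", 33.0, 9.03))
  for (tg in targets) {
    m <- mean(co[[tg[1]]])
    se <- as.numeric(tg[3]) / sqrt(5000)
    expect_lt(abs(m - as.numeric(tg[2])), 3 * se)
  }
  # urine-producing minority near its nominal fraction
  p <- 20 / 231
  frac <- mean(co$Kru > 0)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
  # residual clearance centred near 4 mL/min among urine producers
  expect_equal(mean(co$Kru[co$Kru > 0]), 4.0, tolerance = 0.5)
})

test_that("every generated session is simulable with plausible doses", {
  co <- generate_cohort(cohort_spec(n_sessions = 30, seed = 3))
  ag <- evaluate_agreement(co)
  expect_true(all(ag$data$converged))
  expect_true(all(ag$data$ektv_sim > 0 & ag$data$ektv_sim < 2))
  expect_true(all(ag$data$mass_balance_error < 1e-3))
})

test_that("agreement reporting separates the anuric stratum", {
  co <- generate_cohort(cohort_spec(n_sessions = 40, seed = 5))
  ag <- evaluate_agreement(co)
  expect_s3_class(ag$report, "agreement_report")
  anuric <- co$Kru == 0
  if (sum(anuric) >= 3) {
    expect_equal(ag$anuric_report$n, sum(anuric))
    expect_equal(ag$anuric_report$mean_diff,
                 mean(ag$data$stdktv_formula[anuric] -
                        ag$data$stdktv_sim[anuric]),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_agreement(generate_cohort(cohort_spec(0))), "empty")
})

test_that("frequency prescription collapses anuric cohorts to five sessions a week", {
  co <- generate_cohort(cohort_spec(n_sessions = 25, seed = 2))
  co$Kru <- 0
  fr <- frequency_reduction_report(co)
  expect_true(all(fr$prescribed == 5))
  expect_equal(sum(fr$counts["prescribed", ]), 25)

  # abundant residual clearance brings everyone to once a week
  co$Kru <- 7 * co$V_L / 35        # KRUn = 7 for every session
  fr7 <- frequency_reduction_report(co)
  expect_true(all(fr7$prescribed == 1))

  # minimisation never increases frequency for a deliverable-dose cohort
  co2 <- generate_cohort(cohort_spec(n_sessions = 60, seed = 21))
  fr2 <- frequency_reduction_report(co2)
  expect_lte(fr2$prescribed_mean, fr2$delivered_mean)
})

test_that("clinical CSV work-up computes estimator doses and recommendations", {
  sess <- data.frame(
    patient_id = c("A", "B"), schedule = c("135", "12345"),
    labdayofwk = 1L, Td_min = c(240, 150), Qb = 350, Qd = 180,
    pre_BUN = c(60, 55), post_BUN = c(18, 30),
    pre_weight_kg = c(72, 71), post_weight_kg = c(70, 70),
    urine_volume_L = c(1.2, NA), urine_ureaN_mgdl = c(600, NA),
    collection_min = c(1440, NA), stringsAsFactors = FALSE
  )
  out <- analyze_sessions(sess)
  expect_equal(out$spktv_est[1],
               spktv_daugirdas(18 / 60, 240, 2, 70), tolerance = 1e-12)
  expect_equal(out$Kru_est[1], kru_from_urine(1.2, 600, 1440, 60, 18),
               tolerance = 1e-12)
  expect_equal(out$Kru_est[2], 0)
  expect_true(all(out$prescribed_frequency %in% 1:7))
})
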