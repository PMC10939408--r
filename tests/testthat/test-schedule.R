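test_that("digit-string schedules parse with a validated lab day", {
  s <- parse_schedule("135", 1)
  expect_equal(s$days, c(1L, 3L, 5L))
  expect_equal(s$frequency, 3L)
  expect_equal(s$labdayofwk, 1L)

  expect_equal(parse_schedule("1234567", 1)$frequency, 7L)
  expect_equal(parse_schedule("531", 5)$days, c(1L, 3L, 5L))

  expect_error(parse_schedule("135", 2), "labdayofwk")
  expect_error(parse_schedule("113", 1), "duplicate")
  expect_error(parse_schedule("089", 8), "1..7")
  expect_error(weekly_schedule(integer(0)), "between 1 and 7")
})

test_that("interdialytic intervals follow the session-clock convention and close the week", {
  g <- interdialytic_intervals(parse_schedule("135", 1), Td = 150)
  expect_equal(g[1], 3 * 1440 - 150)   # weekend gap precedes the Monday lab day
  expect_equal(g[-1], c(2 * 1440 - 150, 2 * 1440 - 150))

  daily <- interdialytic_intervals(parse_schedule("1234567", 1), Td = 150)
  expect_equal(daily, rep(1440 - 150, 7))

  for (seq in c("1", "14", "135", "1357", "12345", "123456", "1234567")) {
    for (td in c(120, 200)) {
      s <- parse_schedule(seq, as.integer(substr(seq, 1, 1)))
      gaps <- interdialytic_intervals(s, td)
      expect_equal(sum(gaps) + s$frequency * td, 10080)
    }
  }

  # lab-day rotation: first gap always precedes the lab-day session
  s <- parse_schedule("135", 3)
  expect_equal(interdialytic_intervals(s, 150)[1], 2 * 1440 - 150)
})

test_that("canonical units cover frequencies 1..7 with Monday lab day", {
  units <- canonical_units()
  expect_length(units, 7L)
  expect_equal(vapply(units, function(u) u$schedule$frequency, integer(1)), 1:7)
  expect_equal(units[[3]]$id, "135-1")
  expect_equal(units[[5]]$id, "12345-1")
  expect_true(all(vapply(units, function(u) u$schedule$labdayofwk, integer(1)) == 1L))
})

test_that("extended unit lists expand patterns x lab days without duplicates", {
  only_canonical <- list(
    patterns = as.list(setNames(c("1", "14", "135", "1357", "12345",
                                  "123456", "1234567"), as.character(1:7))),
    labdays = lapply(1:7, function(i) list(1L))
  )
  names(only_canonical$labdays) <- as.character(1:7)
  expect_length(extended_units(only_canonical), 7L)

  three <- extended_units(list(patterns = list(`3` = "135"), labdays = "all"))
  expect_length(three, 3L)
  expect_setequal(vapply(three, `[[`, character(1), "id"),
                  c("135-1", "135-3", "135-5"))

  ids <- vapply(extended_units(), `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("the default parameter grid has 480 points with the stated axes", {
  g <- build_parameter_grid(canonical_units()[[5]])
  expect_equal(nrow(g$points), 480L)
  expect_equal(g$axes$Kru, c(0, 2, 4, 6))
  expect_equal(g$axes$Kd, c(100, 125, 150, 175, 200))
  expect_equal(g$axes$G, c(2.78, 4.176, 5.572, 6.968, 8.364, 9.76),
               tolerance = 1e-12)
  expect_equal(g$axes$Td, c(120, 150, 180, 200))
  expect_equal(g$fixed$weekly_uf, 10000)

  g1 <- build_parameter_grid(canonical_units()[[1]])
  expect_equal(g1$fixed$weekly_uf, 1000)

  g0 <- build_parameter_grid(canonical_units()[[5]], Kru = 0)
  expect_equal(nrow(g0$points), 120L)
  expect_error(build_parameter_grid(canonical_units()[[5]], Kd = numeric(0)),
               "axis")
})

test_that("grid iteration order is deterministic with Kru outermost", {
  g <- build_parameter_grid(canonical_units()[[3]])
  h <- build_parameter_grid(canonical_units()[[3]])
  expect_identical(g$points, h$points)
  expect_equal(g$points$Kru[1:120], rep(0, 120))     # Kru slowest
  expect_equal(g$points$Td[1:4], c(120, 150, 180, 200))  # Td innermost
  tab <- grid_table(g)
  expect_equal(tab$unit_id[1], "135-1")
  expect_equal(nrow(tab), 480L)
})
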