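test_that("stress CSV parsing maps device codes and detects formats", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,stress",
               "2020-01-06T00:03:00Z,42",
               "2020-01-06T00:00:00Z,-1",
               "2020-01-06T00:06:00Z,-2",
               "2020-01-06T00:09:00Z,0"), f)
  s <- parse_stress_csv(f)
  expect_s3_class(s, "stress_series")
  expect_identical(s$missing_code, c("insufficient", "observed", "activity", "observed"))
  expect_identical(s$values, c(NA, 42, NA, 0))
  expect_identical(format(s$time[1], "%H:%M", tz = "UTC"), "00:00")  # sorted

  # Unix epoch seconds, including the epoch origin itself
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,stress", "0,10", "180,20"), f2)
  s2 <- parse_stress_csv(f2)
  expect_identical(format(s2$time[1], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   "1970-01-01T00:00:00Z")
})

test_that("malformed exports are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,stress", "2020-01-06T00:00:00Z,101"), f)
  expect_error(parse_stress_csv(f), "outside \\[0,100\\]")
  writeLines(c("timestamp,stress", "not-a-time,50"), f)
  expect_error(parse_stress_csv(f), "unparseable timestamp at row 1")
  writeLines(c("timestamp,stress",
               "2020-01-06T00:00:00Z,50", "2020-01-06T00:00:00Z,51"), f)
  expect_error(parse_stress_csv(f), "duplicate")
  writeLines("timestamp,stress", f)
  expect_error(parse_stress_csv(f), "empty")
  writeLines(c("zeit,stresswert", "2020-01-06T00:00:00Z,50"), f)
  expect_error(parse_stress_csv(f), "not found")
  s <- parse_stress_csv(f, column_map = c(timestamp = "zeit", stress = "stresswert"))
  expect_identical(s$values, 50)
})

test_that("grid regularization fills gaps, is idempotent, rejects misalignment", {
  t0 <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")
  slots <- c(0, 1, 2, 4, 5, 6, 7, 8, 9)             # slot 3 absent
  s <- stress_series(t0 + slots * 180, rep(50, 9), rep("observed", 9))
  r <- regularize_grid(s)
  expect_length(r, 10)
  expect_identical(r$missing_code[4], "absent")
  expect_true(is.na(r$values[4]))
  expect_identical(regularize_grid(r), r)            # idempotent
  expect_identical(r$values[-4], s$values)

  bad <- stress_series(t0 + c(0, 180, 270), c(1, 2, 3), rep("observed", 3))
  expect_error(regularize_grid(bad), "not aligned.*row 3")
})

test_that("14 days of aligned 3-min rows regularize to 6720 slots", {
  sim <- simulate_stress_series(regime_spec(0, 20, 0.5),
                                missing = missingness_spec(0.05, 1, 5, 0.05),
                                n_days = 14, noise_sd = 5, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stress_csv(sim$series, f)
  r <- regularize_grid(parse_stress_csv(f, patient_id = "sim"))
  expect_length(r, 6720)
})

test_that("write -> parse -> regularize round-trips a series", {
  sim <- simulate_stress_series(regime_spec(0, 20, 0.5),
                                missing = missingness_spec(0.1, 2, 5, 0.05),
                                n_days = 2, noise_sd = 5, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stress_csv(sim$series, f)
  back <- regularize_grid(parse_stress_csv(f, patient_id = sim$series$patient_id))
  # trailing absent epochs cannot round-trip (no final row); compare the
  # covered window
  n <- length(back)
  expect_identical(back$values, sim$series$values[seq_len(n)])
  expect_identical(back$missing_code, sim$series$missing_code[seq_len(n)])
  expect_identical(back$time, sim$series$time[seq_len(n)])
})

test_that("wear report counts records and applies the strict 50% rule", {
  code <- c(rep("observed", 30), rep("insufficient", 5), rep("activity", 5),
            rep("absent", 20))
  s <- make_series(rep(40, 60), code = code)
  wr <- wear_report(s)
  expect_equal(wr$n_slots, 60)
  expect_equal(wr$n_observed + wr$n_insufficient + wr$n_activity + wr$n_absent, 60)
  expect_equal(wr$wear_fraction, 40 / 60)
  expect_true(wr$suitable)

  half <- make_series(rep(40, 60), code = c(rep("observed", 30), rep("absent", 30)))
  expect_false(wear_report(half)$suitable)           # exactly 0.5 is not enough
  none <- make_series(rep(40, 10), code = rep("absent", 10))
  expect_equal(wear_report(none)$wear_fraction, 0)
  expect_false(wear_report(none)$suitable)
})

test_that("stress categories follow the device bands", {
  expect_equal(as.character(categorize_stress(c(0, 25, 26, 50, 51, 75, 76, 100))),
               c("rest", "rest", "low", "low", "medium", "medium", "high", "high"))
  expect_error(categorize_stress(101), "outside")
  expect_error(categorize_stress(NA_real_), "missing")
})

test_that("modeling view collapses all missing categories without imputing", {
  code <- c("observed", "insufficient", "activity", "absent", "observed")
  s <- make_series(c(10, NA, NA, NA, 20), code = code)
  mv <- modeling_view(s)
  expect_identical(mv$missing_code, c("observed", "missing", "missing",
                                      "missing", "observed"))
  expect_identical(mv$values, s$values)
  full <- make_series(c(10, 20, 30))
  expect_identical(modeling_view(full)$values, full$values)
  # count bookkeeping on a large masked series
  sim <- simulate_stress_series(regime_spec(0, 20, 0.5),
                                missing = missingness_spec(0.1, 2, 5, 0.02),
                                n_days = 14, noise_sd = 5, seed = 6)
  mv2 <- modeling_view(sim$series)
  n_missing <- sum(mv2$missing_code == "missing")
  expect_equal(sum(mv2$missing_code == "observed"), 6720 - n_missing)
  expect_equal(n_missing, sum(sim$truth$missing_mask != "observed"))
})

test_that("Excel serial conversion uses the 25569-day offset", {
  t0 <- as.POSIXct("1970-01-01 00:00:00", tz = "UTC")
  expect_equal(excel_serial(t0), 25569)
  expect_equal(excel_serial(t0 + 86400 * 2 + 43200), 25571.5)
})
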