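test_that("recordings survive a CSV write/read round trip", {
  p <- quick_participant(seed = 2)
  rec <- p$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, data.frame(participant_id = rec$participant_id,
                                          mass_kg = rec$mass_kg,
                                          sex = rec$sex,
                                          stopwatch_s = rec$stopwatch_s))
  expect_equal(back$fz_raw, rec$fz_raw, tolerance = 1e-9)
  expect_equal(back$sampling_rate_hz, rec$sampling_rate_hz, tolerance = 1e-6)
  expect_equal(back$mass_kg, rec$mass_kg)
})

test_that("sampling rate is inferred from the time column and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,fz_n", "0.000,700.0", "0.005,700.0"), path)
  rec <- read_recording(path, list(participant_id = "A", mass_kg = 70))
  expect_equal(rec$sampling_rate_hz, 200)

  writeLines(c("time_s,fz_n", "0.01,1", "0.005,2", "0.02,3"), path)
  expect_error(read_recording(path, list(participant_id = "A", mass_kg = 70)),
               "increasing")
  writeLines(c("time_s,fz_n", "0,1", "0.005,2", "0.02,3"), path)
  expect_error(read_recording(path, list(participant_id = "A", mass_kg = 70)),
               "constant sampling interval")
  writeLines(c("time_s,fz_n"), path)
  expect_error(read_recording(path, list(participant_id = "A", mass_kg = 70)),
               "fewer than 2")
  writeLines(c("t,f", "0,1", "1,2"), path)
  expect_error(read_recording(path, list(participant_id = "A", mass_kg = 70)),
               "must contain columns")
  writeLines(c("time_s,fz_n", "0.000,700.0", "0.005,700.0"), path)
  expect_error(read_recording(path, list(participant_id = "A", mass_kg = 70,
                                         sampling_rate_hz = 100)),
               "disagrees")
})

test_that("metadata joining by participant id works and fails loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,fz_n", "0.000,700.0", "0.005,700.0"), path)
  md <- data.frame(participant_id = c("A", "B"), mass_kg = c(70, 80))
  rec <- read_recording(path, md, participant_id = "B")
  expect_equal(rec$mass_kg, 80)
  expect_error(read_recording(path, md), "participant_id required")
  expect_error(read_recording(path, md, participant_id = "C"),
               "does not identify")
})

test_that("body-weight normalization divides by m*g and is linear", {
  rec <- crt_recording("A", 200, rep(735.75, 10), mass_kg = 75)
  expect_equal(normalize_bodyweight(rec)$values, rep(1, 10))
  rec0 <- crt_recording("A", 200, c(0, 0), mass_kg = 75)
  expect_equal(normalize_bodyweight(rec0)$values, c(0, 0))
  rec2 <- crt_recording("A", 200, rep(735.75, 10), mass_kg = 150)
  expect_equal(normalize_bodyweight(rec2)$values,
               normalize_bodyweight(rec)$values / 2)
  expect_error(crt_recording("A", 200, 1:10, mass_kg = 0), "positive")
})

test_that("peak normalization scales the maximum to one and is idempotent", {
  r <- normalize_peak(c(1, 2, 4))
  expect_equal(r$values, c(0.25, 0.5, 1))
  expect_equal(normalize_peak(r)$values, r$values)
  expect_error(normalize_peak(c(-2, -1)), "positive maximum")
  set.seed(31)
  for (i in 1:100) {
    amp <- amp_arch1 + rnorm(4, 0, 0.05)
    cyc <- synth_cycle(amp, runif(1, 1.5, 3), 200, noise_sd = 0.01)
    expect_identical(max(normalize_peak(as.numeric(cyc))$values), 1)
  }
})

test_that("integer downsampling keeps every factor-th sample", {
  expect_equal(downsample_series(1:10, 3), c(1, 4, 7, 10))
  expect_equal(downsample_series(1:10, 1), 1:10)
  expect_error(downsample_series(1:10, 2.5), "positive integer")
})

test_that("a cohort directory round-trips through cohort.csv and per-participant files", {
  coh <- synth_cohort(cohort_config(n_per_archetype = c(2, 1), seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  md <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(md), 3)
  rec <- read_recording(file.path(dir, paste0(md$participant_id[1], ".csv")),
                        md, participant_id = md$participant_id[1])
  expect_equal(rec$fz_raw, coh$recordings[[1]]$fz_raw, tolerance = 1e-9)
})
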