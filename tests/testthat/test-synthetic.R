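test_that("default archetypes carry the calibrated phase-force and duration parameters", {
  a <- default_archetypes()
  expect_equal(a[[1]]$stab_mean, 0.39)
  expect_equal(a[[2]]$stab_mean, 0.69)
  expect_equal(a[[1]]$seatoff_mean, 1.16)
  expect_equal(a[[1]]$stopwatch_mean_s, 9.84)
  expect_equal(a[[1]]$stopwatch_sd_s, 1.41)
  expect_equal(a[[2]]$stopwatch_mean_s, 12.59)
  expect_equal(a[[2]]$stopwatch_sd_s, 2.47)
  expect_equal(a[[2]]$stand_sd, 0.067)
})

test_that("archetype validation rejects incoherent parameter sets", {
  expect_error(crt_archetype("x", 0.5, -0.1, 1.2, 0.1, 0.4, 0.1, 1.0, 0.1,
                             10, 1), ">= 0")
  expect_error(crt_archetype("x", 0.5, 0.1, 0.9, 0.1, 0.4, 0.1, 1.0, 0.1,
                             10, 1), "seatoff_mean > 1")
  expect_error(crt_archetype("x", 0.5, 0.1, 1.2, 0.1, 0.4, 0.1, 1.0, 0.1,
                             10, 1, sit_baseline = 1.2), "sit_baseline")
})

test_that("noise-free cycles place landmark amplitudes as the phase extrema", {
  cyc <- synth_cycle(amp_arch1, duration_s = 2.3, rate = 200)
  lm <- attr(cyc, "landmarks")
  n <- length(cyc)
  expect_true(all(diff(lm$idx) > 0))
  # seat-off is the maximum of the sit-to-stand part of the cycle
  expect_equal(max(cyc[1:floor(0.6 * n)]), amp_arch1[["seatoff"]])
  # stabilization dip is the minimum between seat-off and the landing
  so <- lm$idx[lm$name == "seatoff"]
  sd_ <- lm$idx[lm$name == "sitdown"]
  expect_equal(min(cyc[so:sd_]), amp_arch1[["stab"]])
  expect_equal(cyc[lm$idx], lm$value)
  expect_length(cyc, round(2.3 * 200))
})

test_that("cycle synthesis is seeded-deterministic and validates inputs", {
  set.seed(10); a <- synth_cycle(amp_arch1, 2, 200, noise_sd = 0.01)
  set.seed(10); b <- synth_cycle(amp_arch1, 2, 200, noise_sd = 0.01)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(synth_cycle(amp_arch1, -1, 200), "positive")
  expect_error(synth_cycle(amp_arch1, 2, 0), "positive")
  expect_error(synth_cycle(c(unload = 0.5), 2, 200), "must name")
})

test_that("participant-level amplitude draws converge to the archetype means", {
  set.seed(123)
  a1 <- default_archetypes()[[1]]
  draws <- t(replicate(10000, crtclust:::draw_amplitudes(a1)))
  # coherence redraws perturb archetype-1 means by well under 0.005
  expect_lt(abs(mean(draws[, "stab"]) - 0.39), 0.01)
  expect_lt(abs(mean(draws[, "unload"]) - 0.50), 0.01)
  expect_lt(abs(mean(draws[, "seatoff"]) - 1.16), 0.01)
  expect_lt(abs(mean(draws[, "stand"]) - 1.04), 0.01)
})

test_that("a participant is five cycles between rest pads with a coherent truth channel", {
  p <- quick_participant(arch_id = 1, seed = 4)
  rec <- p$recording; tr <- p$truth
  cfg <- cohort_config()
  expect_length(tr$cycle_start_idx, 5)
  expect_equal(tr$test_end_idx - tr$test_start_idx, sum(tr$cycle_lengths))
  pad <- round(cfg$rest_pad_s * rec$sampling_rate_hz)
  expect_length(rec$fz_raw, 2 * pad + sum(tr$cycle_lengths))
  expect_true(all(diff(tr$landmarks$idx[tr$landmarks$cycle == 2]) > 0))
  # stopwatch-to-GRF relation within the configured residual spread
  expect_lt(abs(tr$t_grf_s - (0.89 * tr$t_stopwatch_s + 2.86)), 4 * 0.3)
})

test_that("zero within-participant scale gives five identical cycle amplitude sets", {
  p <- quick_participant(arch_id = 2, seed = 9, noise_sd = 0, within = 0)
  amps <- do.call(rbind, p$truth$cycle_amplitudes)
  expect_equal(apply(amps, 2, function(v) max(v) - min(v)),
               c(unload = 0, seatoff = 0, stab = 0, stand = 0))
})

test_that("cohorts are sized, labeled, reproducible and bounded", {
  cfg <- cohort_config(n_per_archetype = c(3, 4), seed = 77)
  c1 <- synth_cohort(cfg)
  c2 <- synth_cohort(cfg)
  expect_length(c1$recordings, 7)
  labs <- vapply(c1$truth, `[[`, "", "archetype_label")
  expect_equal(sum(labs == "archetype_1"), 3)
  ids <- vapply(c1$recordings, `[[`, "", "participant_id")
  expect_false(any(duplicated(ids)))
  expect_identical(c1$recordings, c2$recordings)
  # bounded in [0, 2] a.u. at default noise
  for (i in seq_along(c1$recordings)) {
    bw <- normalize_bodyweight(c1$recordings[[i]])$values
    expect_true(all(is.finite(bw)))
    expect_true(all(bw > 0 & bw < 2))
  }
  tiny <- synth_cohort(cohort_config(n_per_archetype = c(1, 1)))
  expect_length(tiny$recordings, 2)
})

test_that("default cohort counts match the study population", {
  cfg <- cohort_config()
  expect_equal(cfg$n_per_archetype, c(72L, 100L))
  expect_equal(cfg$sampling_rate_hz, 200)
  expect_equal(cfg$grf_slope, 0.89)
  expect_equal(cfg$grf_intercept, 2.86)
})
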