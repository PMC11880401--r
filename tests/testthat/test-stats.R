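test_that("chair-rise scores reproduce the duration bands", {
  expect_equal(guralnik_score(11.19), 4L)
  expect_equal(guralnik_score(11.20), 3L)
  expect_equal(guralnik_score(12.0), 3L)
  expect_equal(guralnik_score(13.69), 3L)
  expect_equal(guralnik_score(13.70), 2L)
  expect_equal(guralnik_score(16.69), 2L)
  expect_equal(guralnik_score(16.70), 1L)
  expect_equal(guralnik_score(60.0), 1L)
  expect_equal(guralnik_score(61.0), 0L)
  expect_equal(guralnik_score(NA, unable = TRUE), 0L)
  # durations inside the printed band gaps round half-up to 2 decimals
  expect_equal(guralnik_score(11.194), 4L)
  expect_equal(guralnik_score(11.195), 3L)
  expect_error(guralnik_score(-1), "positive")
})

test_that("the score is a monotone non-increasing step function of duration", {
  grid <- seq(0.01, 70, by = 0.01)
  s <- guralnik_score(grid)
  expect_true(all(diff(s) <= 0))
  expect_equal(sort(unique(s)), 0:4)
})

test_that("Mann-Whitney p-values match exact enumeration for small groups", {
  set.seed(55)
  for (rep in 1:8) {
    x <- rnorm(sample(4:8, 1))
    y <- rnorm(sample(4:8, 1), mean = sample(c(0, 1.5), 1))
    got <- compare_clusters(list(v = c(x, y)),
                            rep(1:2, c(length(x), length(y))))$p_value
    expect_equal(got, mw_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("cluster comparison is symmetric, sane on equal groups, and flags degeneracy", {
  set.seed(66)
  x <- rnorm(40); y <- x
  res <- compare_clusters(list(v = c(x, y)), rep(1:2, each = 40))
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)
  a <- rnorm(30); b <- rnorm(35, 2)
  p1 <- compare_clusters(list(v = c(a, b)), rep(1:2, c(30, 35)))$p_value
  p2 <- compare_clusters(list(v = c(b, a)), rep(1:2, c(35, 30)))$p_value
  expect_equal(p1, p2)
  dg <- compare_clusters(list(v = c(rep(1, 5), rnorm(5))), rep(1:2, each = 5))
  expect_true(dg$degenerate)
  expect_error(compare_clusters(list(v = rnorm(4)), c(1, 1, 2, 2)), ">= 3")
})

test_that("Mann-Whitney has power at the stabilization effect size (small-scale check)", {
  set.seed(77)
  hits <- replicate(60, {
    x <- rnorm(72, 0.39, 0.16); y <- rnorm(100, 0.69, 0.13)
    suppressWarnings(stats::wilcox.test(x, y)$p.value) < 0.01
  })
  expect_gte(mean(hits), 0.99)
})

test_that("duration regression recovers an exact linear relation and is stable", {
  t_sw <- seq(7, 18, by = 0.5)
  t_grf <- 0.89 * t_sw + 2.86
  # (suppressed warning: lm flags the residual-free exact fit)
  fit <- suppressWarnings(duration_regression(t_sw, t_grf))
  expect_equal(fit$slope, 0.89, tolerance = 1e-10)
  expect_equal(fit$intercept_s, 2.86, tolerance = 1e-10)
  # duplicating the dataset leaves the fit unchanged
  fit2 <- suppressWarnings(duration_regression(rep(t_sw, 2), rep(t_grf, 2)))
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept_s, fit$intercept_s)
  expect_error(duration_regression(rep(10, 5), rnorm(5)), "constant")
  expect_error(duration_regression(1:2, 1:2), "at least 3")
})

test_that("regression over synthetic truth recovers the generating relation", {
  coh <- synth_cohort(cohort_config(n_per_archetype = c(40, 60), seed = 101))
  tsw <- vapply(coh$truth, `[[`, 0, "t_stopwatch_s")
  tg <- vapply(coh$truth, `[[`, 0, "t_grf_s")
  fit <- duration_regression(tsw, tg)
  expect_lt(abs(fit$slope - 0.89), 3 * fit$slope_se)
  expect_lt(abs(fit$intercept_s - 2.86), 3 * fit$intercept_se)
})

test_that("consistency table categorizes label patterns and rows sum to one", {
  full <- matrix(1, 4, 5)
  ct <- consistency_table(full)
  expect_equal(ct$all[ct$cluster == "total"], 1)
  m <- rbind(c(1, 2, 2, 2, 2),
             c(2, 2, 2, 2, 2),
             c(1, 1, 1, 2, 1))
  ct2 <- consistency_table(m)
  r1 <- ct2[ct2$cluster == "1", ]
  expect_equal(r1$only_first, 0.5)   # participant (1,2,2,2,2)
  expect_equal(r1$four, 0.5)         # participant (1,1,1,2,1)
  set.seed(88)
  for (i in 1:50) {
    mm <- matrix(sample(1:2, 5 * 20, TRUE), 20, 5)
    ct3 <- consistency_table(mm)
    sums <- rowSums(ct3[, c("all", "four", "three", "two", "only_first")])
    expect_equal(unname(sums), rep(1, nrow(ct3)), tolerance = 1e-9)
  }
  expect_error(consistency_table(matrix(1, 3, 4)), "5 cycle labels")
})

test_that("cohort summaries report per-cluster structure and flag tiny cohorts", {
  meta <- data.frame(participant_id = sprintf("P%d", 1:12),
                     cluster = rep(1:2, each = 6),
                     sex = rep(c("m", "f"), 6),
                     mass_kg = rnorm(12, 75, 5),
                     stopwatch_s = c(rnorm(6, 9.8, 0.5), rnorm(6, 12.6, 0.5)),
                     t_grf_s = rnorm(12, 12, 1))
  set.seed(3)
  phase <- data.frame(participant_id = meta$participant_id,
                      unload = rnorm(12, 0.5, 0.05),
                      seatoff = rnorm(12, 1.16, 0.05),
                      stab = c(rnorm(6, 0.39, 0.05), rnorm(6, 0.69, 0.05)),
                      stand = rnorm(12, 1.02, 0.05))
  s <- cohort_summary(meta, phase)
  expect_equal(unname(c(s$cluster_sizes)), c(6L, 6L))
  expect_equal(nrow(s$phase_comparison), 4)
  expect_true(s$phase_comparison$p_value[3] <
              s$phase_comparison$p_value[2])  # stab separates, seatoff not
  one <- cohort_summary(meta[1, ], phase[1, ])
  expect_true(one$population$single_participant)
  expect_equal(one$durations$stopwatch_sd, 0)
})
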