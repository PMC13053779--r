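test_that("unit-time fit is origin-constrained least squares", {
  # two exactly proportional points
  expect_equal(fit_unit_time(arm_calibration(c(2, 4), c(102.98, 205.96))),
               51.49, tolerance = 1e-12)
  # a single point fixes the slope directly
  expect_equal(fit_unit_time(arm_calibration(1, 60)), 60)
  # the four reference points are nearly, not exactly, proportional:
  # the fit reconciles the slightly slow 1 Gy point with the rest
  u <- fit_unit_time(arm_reference_calibration())
  expect_gte(u, 51.49)
  expect_lte(u, 51.59)
  expect_equal(u, 51.49118, tolerance = 1e-6)
  expect_error(arm_calibration(numeric(0), numeric(0)), "calibration")
  expect_error(arm_calibration(-1, 60), "dose_gy")
})

test_that("dwell time scales linearly with target dose", {
  expect_equal(dwell_time_for_dose(8, 51.49), 411.92)
  expect_equal(dwell_time_for_dose(0, 51.49), 0)
  expect_equal(dwell_time_for_dose(6, 51.49), 308.94)
  expect_error(dwell_time_for_dose(-1, 51.49), "dose_gy")
})

test_that("dose rate from a dose/dwell pair is 60 * dose / dwell", {
  expect_equal(round(dose_rate_from_dwell(1, 51.59), 3), 1.163)
  expect_equal(dose_rate_from_dwell(1, 60), 1)
  expect_equal(round(dose_rate_from_dwell(4, 205.96), 3), 1.165)
  expect_error(dose_rate_from_dwell(1, 0), "dwell_s")
})

test_that("schedules cover each column group once with proportional dwells", {
  sched <- build_schedule(c(0, 2, 4, 8), 51.49)
  expect_equal(sched$dwell_s, c(0, 102.98, 205.96, 411.92))
  expect_equal(sum(sched$dwell_s), 720.86)
  expect_equal(sched$col_start, c(1, 7, 13, 19))
  expect_equal(sched$col_end, c(6, 12, 18, 24))
  expect_true(all(build_schedule(c(0, 0, 0), 51.49, n_cols = 24)$dwell_s == 0))
  one <- build_schedule(1, 51.59, n_cols = 24)
  expect_equal(sum(one$dwell_s), 51.59)
})

test_that("noiseless scheduling then delivery is a round-trip identity", {
  targets <- c(0, 2, 4, 8)
  u <- fit_unit_time(arm_reference_calibration())
  sched <- build_schedule(targets, u)
  dm <- simulate_delivery(sched, rate_gy_per_min = 60 / u)
  per_col_group <- rep(targets, each = 6)
  for (r in unique(dm$row)) {
    expect_equal(dm$dose_gy[dm$row == r], per_col_group, tolerance = 1e-12)
  }
})

test_that("shielding scales delivered dose by the transmission factor", {
  sched <- build_schedule(6, 51.49, n_cols = 24)
  shield <- matrix(FALSE, 16, 24)
  shield[4:9, 2:7] <- TRUE
  dm <- simulate_delivery(sched, 60 / 51.49, shield = shield,
                          shield_transmission = 1 / 6)
  open <- dm$dose_gy[!shield[cbind(dm$row, dm$col)]]
  blocked <- dm$dose_gy[shield[cbind(dm$row, dm$col)]]
  expect_equal(unique(round(open, 10)), 6)
  expect_equal(unique(round(blocked, 10)), 1)
  dm0 <- simulate_delivery(sched, 60 / 51.49, shield = shield,
                           shield_transmission = 0)
  expect_true(all(dm0$dose_gy[shield[cbind(dm0$row, dm0$col)]] == 0))
})

test_that("delivery noise produces the expected dispersion", {
  sched <- build_schedule(4, 51.49, n_cols = 24)
  dm <- simulate_delivery(sched, 60 / 51.49, n_rows = 42,
                          noise_sd = 0.02, seed = 11)
  expect_gte(nrow(dm), 1000)
  cv <- 100 * sd(dm$dose_gy) / mean(dm$dose_gy)
  expect_gt(cv, 1.5)
  expect_lt(cv, 2.5)
  # same seed reproduces the map exactly
  dm2 <- simulate_delivery(sched, 60 / 51.49, n_rows = 42,
                           noise_sd = 0.02, seed = 11)
  expect_identical(dm, dm2)
})

test_that("delivered dose is monotone in dwell time at fixed rate", {
  dwells <- sort(runif(20, 0, 500))
  doses <- purrr::map_dbl(dwells, function(t) {
    sched <- tibble::tibble(step = 1L, col_start = 1L, col_end = 24L,
                            target_gy = NA_real_, dwell_s = t)
    simulate_delivery(sched, 1.163)$dose_gy[1]
  })
  expect_true(all(diff(doses) >= 0))
})

test_that("delivery statistics summarise reproducibility", {
  same <- delivery_stats(rep(1.16, 5), dwell_s = 60)
  expect_equal(same$cv_percent, 0)
  lin <- delivery_stats(tibble::tibble(dwell_s = c(60, 120, 240, 480),
                                       dose_gy = c(1, 2, 4, 8)))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$mean_rate_gy_per_min, 1)
  uni <- delivery_stats(c(1.16, 1.17, 1.16), dwell_s = 60)
  expect_equal(uni$cv_percent, 0.4962896, tolerance = 1e-6)
  expect_true(is.na(uni$r_squared))
  expect_error(delivery_stats(c(0, 0, 0), dwell_s = 60), "undefined")
  expect_error(delivery_stats(1.16, dwell_s = 60), "at least 2")
})

test_that("delivery quality degrades gracefully to ideal as noise vanishes", {
  u <- 51.49
  sched <- build_schedule(c(2, 4, 6, 8), u)
  for (noise in c(0.05, 0.005)) {
    dm <- simulate_delivery(sched, 60 / u, noise_sd = noise, seed = 5)
    meas <- tibble::tibble(
      dwell_s = rep(sched$dwell_s, each = 16 * 6),
      dose_gy = dm$dose_gy[order(dm$col)]
    )
    stats_n <- delivery_stats(meas)
    if (noise == 0.05) r2_noisy <- stats_n$r_squared else {
      expect_gt(stats_n$r_squared, r2_noisy)
      expect_gt(stats_n$r_squared, 0.999)
    }
  }
})
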