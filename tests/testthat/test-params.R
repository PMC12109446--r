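test_that("cycle segmentation forms HS-TO-HS triples and skips malformed runs", {
  ev <- tibble::tibble(event = c("HS", "TO", "HS"), time_s = c(0, 0.76, 1.18))
  cyc <- segment_cycles(ev)
  expect_equal(nrow(cyc), 1)
  expect_equal(unlist(cyc[1, ]), c(hs_start = 0, to = 0.76, hs_end = 1.18))
  expect_equal(attr(cyc, "n_skipped"), 0L)

  # missing TO between two HS: that interval is skipped and counted
  ev2 <- tibble::tibble(
    event = c("HS", "HS", "TO", "HS"),
    time_s = c(0, 1.2, 1.9, 2.4)
  )
  cyc2 <- segment_cycles(ev2)
  expect_equal(nrow(cyc2), 1)
  expect_equal(attr(cyc2, "n_skipped"), 1L)

  # fewer than two heel strikes -> empty
  expect_equal(nrow(segment_cycles(
    tibble::tibble(event = c("HS", "TO"), time_s = c(0, 0.7))
  )), 0)
})

test_that("six simulated cycles yield five complete same-foot cycles", {
  rec <- simulate_recording(gait_profile(n_cycles = 6, seed = 2))
  cyc <- segment_cycles(rec$events)
  expect_equal(nrow(cyc), 5)
  expect_equal(attr(cyc, "n_skipped"), 0L)
})

test_that("per-cycle parameters satisfy the timing identities exactly", {
  cyc <- tibble::tibble(hs_start = 0, to = 0.76, hs_end = 1.18)
  p <- compute_parameters(cyc)
  expect_equal(p$stride_time_s, 1.18)
  expect_equal(p$stance_time_s, 0.76)
  expect_equal(p$swing_time_s, 0.42)
  expect_equal(p$stance_phase_pct, 100 * 0.76 / 1.18) # 64.41%
  expect_equal(p$stance_phase_pct + p$swing_phase_pct, 100)
  expect_equal(p$cadence_spm * p$stride_time_s, 120)

  # symmetric cycle -> both phases 50%
  sym <- compute_parameters(tibble::tibble(hs_start = 0, to = 0.6, hs_end = 1.2))
  expect_equal(sym$stance_phase_pct, 50)
  expect_equal(sym$swing_phase_pct, 50)

  expect_error(
    compute_parameters(tibble::tibble(hs_start = 0, to = 0, hs_end = 1)),
    "hs_start < to < hs_end"
  )
})

test_that("trial means average per-cycle values and count cycles", {
  cyc <- tibble::tibble(
    hs_start = c(0, 1.2), to = c(0.7, 1.95), hs_end = c(1.2, 2.5)
  )
  per <- compute_parameters(cyc, per_cycle = TRUE)
  tot <- compute_parameters(cyc)
  expect_equal(nrow(per), 2)
  expect_equal(tot$stride_time_s, mean(per$stride_time_s))
  expect_equal(tot$stance_phase_pct, mean(per$stance_phase_pct))
  expect_equal(tot$n_cycles, 2)
})

test_that("stride-length model predicts linearly with clipping", {
  m <- stride_length_model(0.5, 0.85)
  expect_equal(predict(m, 0.834), 0.5 + 0.85 * 0.834)
  expect_equal(predict(m, -10), 0.2)  # clipped below
  expect_equal(predict(m, 100), 2.5)  # clipped above
})

test_that("OLS calibration recovers exact and noisy coefficients", {
  f <- seq(0.6, 1.1, length.out = 24)
  exact <- tibble::tibble(
    stride_frequency_hz = f,
    stride_length_m = 0.5 + 0.6 * f
  )
  fit <- fit_stride_length_model(exact)
  expect_equal(fit$intercept_m, 0.5, tolerance = 1e-9)
  expect_equal(fit$slope_m_per_hz, 0.6, tolerance = 1e-9)

  set.seed(77)
  f2 <- runif(200, 0.6, 1.1)
  noisy <- tibble::tibble(
    stride_frequency_hz = f2,
    stride_length_m = 0.5 + 0.6 * f2 + rnorm(200, 0, 0.05)
  )
  fit2 <- fit_stride_length_model(noisy)
  est <- tidy(fit2)
  expect_lt(abs(est$estimate[1] - 0.5) / est$std.error[1], 3)
  expect_lt(abs(est$estimate[2] - 0.6) / est$std.error[2], 3)

  one_freq <- tibble::tibble(stride_frequency_hz = rep(0.8, 5),
                             stride_length_m = runif(5))
  expect_error(fit_stride_length_model(one_freq), "distinct")
})

test_that("recording-level parameters carry metadata and recover the profile", {
  rec <- simulate_recording(
    gait_profile(cadence_spm = 100, stance_fraction = 0.6, seed = 12),
    subject_id = "S042", age_group = "60-69"
  )
  row <- recording_parameters(rec)
  expect_equal(row$subject_id, "S042")
  expect_equal(row$task, "STW")
  expect_equal(row$cadence_spm, 100, tolerance = 0.05)
  expect_equal(row$stance_phase_pct, 60, tolerance = 2)
  expect_equal(row$n_cycles, 5)
})

test_that("stronger dual-task perturbation monotonically slows the cohort", {
  mean_params <- function(task) {
    p <- cohort_parameters(simulate_cohort(8, tasks = task, seed = 31))
    c(cadence = mean(p$cadence_spm), speed = mean(p$walking_speed_mps))
  }
  stw <- mean_params("STW")
  vft <- mean_params("VFT")
  expect_lt(vft["cadence"], stw["cadence"])
  expect_lt(vft["speed"], stw["speed"])
})
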