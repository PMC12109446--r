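test_that("noise-free recording has the exact prescribed geometry", {
  rec <- clean_recording(seed = 1)
  # cadence 100 -> stride 1.2 s; 6 cycles at 50 Hz -> 360 samples
  expect_equal(nrow(rec$signals), ceiling(6 * 1.2 * 50))
  expect_equal(sum(rec$events$event == "HS"), 6)
  expect_equal(sum(rec$events$event == "TO"), 6)
  expect_equal(mean(rec$signals$stance), 0.6, tolerance = 0.02)
  # stride time between consecutive heel strikes is exact without jitter
  hs <- rec$events$time_s[rec$events$event == "HS"]
  expect_equal(diff(hs), rep(1.2, 5), tolerance = 1e-12)
  # stance intervals occupy the stance fraction of each stride
  to <- rec$events$time_s[rec$events$event == "TO"]
  expect_equal(to - hs, rep(0.72, 6), tolerance = 1e-12)
  expect_true(all(diff(rec$signals$time) - 1 / 50 < 1e-12))
})

test_that("same profile and seed reproduce the recording bitwise", {
  p <- gait_profile(cadence_spm = 97.3, asymmetry = 0.03, seed = 99)
  r1 <- simulate_recording(p)
  r2 <- simulate_recording(p)
  expect_identical(r1$signals, r2$signals)
  expect_identical(r1$events, r2$events)
})

test_that("invalid profiles are rejected", {
  expect_error(gait_profile(cadence_spm = 0), "positive")
  expect_error(gait_profile(stance_fraction = 1), "between 0 and 1")
  expect_error(gait_profile(stance_fraction = 0), "between 0 and 1")
  expect_error(gait_profile(n_cycles = 0), "whole number")
  expect_error(gait_profile(noise_sd = -1), ">= 0")
})

test_that("stance trace and true events are mutually consistent", {
  for (s in c(2, 7, 13)) {
    rec <- simulate_recording(gait_profile(
      cadence_spm = 95 + s, stance_fraction = 0.62, asymmetry = 0.03,
      seed = s
    ))
    got <- extract_events(rec$signals$stance, fs_hz = rec$fs_hz, t0 = 0)
    tru <- dplyr::arrange(rec$events, time_s)
    expect_equal(nrow(got), nrow(tru))
    expect_equal(got$event, tru$event)
    # reconstructed time is the true time quantized up to the sample grid
    quantized <- ceiling(tru$time_s * rec$fs_hz - 1e-9) / rec$fs_hz
    expect_equal(got$time_s, quantized, tolerance = 1e-12)
  }
})

test_that("empirical stance fraction converges with the number of cycles", {
  short <- simulate_recording(gait_profile(n_cycles = 4, seed = 3))
  long <- simulate_recording(gait_profile(n_cycles = 120, seed = 3))
  expect_lt(abs(mean(long$signals$stance) - 0.6),
            abs(mean(short$signals$stance) - 0.6) + 0.01)
  expect_equal(mean(long$signals$stance), 0.6, tolerance = 0.005)
})

test_that("excluded channels stay low-variance across seeds", {
  for (s in 1:8) {
    rec <- simulate_recording(gait_profile(seed = s))
    v <- vapply(c("Ax", "Ay", "Az", "Gx", "Gy", "Gz", "Yaw", "Pitch", "Roll"),
                function(ch) var(rec$signals[[ch]]), numeric(1))
    informative <- v[c("Ax", "Ay", "Gy", "Gz", "Yaw", "Roll")]
    excluded <- v[c("Az", "Gx", "Pitch")]
    expect_true(all(excluded <= 0.1 * min(informative)),
                label = sprintf("variance ratio holds for seed %d", s))
  }
})

test_that("dual-task perturbation slows gait in the expected direction", {
  p <- gait_profile(seed = 4)
  stw <- simulate_recording(p, task = "STW")
  vft <- simulate_recording(p, task = "VFT")
  expect_gt(nrow(vft$signals), nrow(stw$signals)) # slower -> longer trial
  expect_gt(mean(vft$signals$stance), mean(stw$signals$stance))
})

test_that("cohort generation stratifies, allocates and reproduces", {
  coh <- simulate_cohort(6, seed = 1)
  m <- cohort_manifest(coh)
  expect_equal(nrow(m), 6)
  expect_equal(sort(unique(m$age_group)),
               c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79"))

  alloc <- c(22L, 25L, 25L, 29L, 26L, 23L)
  coh150 <- simulate_cohort(150, age_allocation = alloc, seed = 2)
  counts <- table(cohort_manifest(coh150)$age_group)
  expect_equal(as.integer(counts[c("20-29", "30-39", "40-49",
                                   "50-59", "60-69", "70-79")]), alloc)

  again <- simulate_cohort(6, seed = 1)
  expect_identical(
    purrr::map(coh, "signals"), purrr::map(again, "signals")
  )

  expect_error(simulate_cohort(0), ">= 1")
  expect_error(simulate_cohort(3, cadence_range = c(110, 90)), "range")
  expect_error(simulate_cohort(3, age_allocation = c(1, 1, 1, 1, 0, 0)),
               "sum")
})

test_that("multi-condition cohorts record each speed and task", {
  coh <- simulate_cohort(2, speeds = c("low", "normal", "high"),
                         tasks = c("STW", "VFT"), seed = 5)
  m <- cohort_manifest(coh)
  expect_equal(nrow(m), 12)
  expect_equal(nrow(dplyr::distinct(m, subject_id, speed_condition, task)), 12)
})

test_that("recording CSV round trip preserves signals and quantized events", {
  rec <- simulate_recording(gait_profile(seed = 8, asymmetry = 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path, fs_hz = rec$fs_hz)
  expect_equal(as.data.frame(back$signals), as.data.frame(rec$signals),
               tolerance = 1e-9)
  got <- back$events
  quantized <- ceiling(sort(rec$events$time_s) * 50 - 1e-9) / 50
  expect_equal(sort(got$time_s), quantized, tolerance = 1e-9)

  evpath <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(rec$events, evpath)
  expect_equal(read_events_csv(evpath), rec$events, tolerance = 1e-12)
})
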