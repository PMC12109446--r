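test_that("binarization thresholds and debounces as specified", {
  # 20 ms spike at 50 Hz is below the 100 ms floor and gets absorbed
  expect_equal(binarize_trace(c(0.1, 0.9, 0.1), fs_hz = 50), c(0L, 0L, 0L))
  expect_equal(binarize_trace(rep(0.7, 10), fs_hz = 50), rep(1L, 10))
  clean <- rep(c(0, 1, 0), each = 10)
  expect_equal(binarize_trace(clean, fs_hz = 50), as.integer(clean))
  # a 3-sample blip inside a long stance flips to stance
  blip <- c(rep(1, 10), 0, 0, 0, rep(1, 10))
  expect_equal(binarize_trace(blip, fs_hz = 50), rep(1L, 23))
  expect_error(binarize_trace(c(0.5, 1.2)), "within")
  expect_error(binarize_trace(c(0.5, -0.1)), "within")
})

test_that("event extraction matches the worked example and edge cases", {
  ev <- extract_events(c(0, 0, 1, 1, 1, 0, 0), fs_hz = 50, t0 = 0)
  expect_equal(ev$event, c("HS", "TO"))
  expect_equal(ev$time_s, c(0.04, 0.10))
  expect_equal(nrow(extract_events(rep(1, 20))), 0)
  expect_equal(nrow(extract_events(rep(0, 20))), 0)
  expect_error(extract_events(c(0, 2, 1)), "0 and 1")
  # t0 offsets every timestamp
  ev2 <- extract_events(c(0, 1), fs_hz = 50, t0 = 1.5)
  expect_equal(ev2$time_s, 1.5 + 0.02)
})

test_that("vectorized extraction equals the brute-force scan on random strings", {
  set.seed(123)
  for (i in 1:200) {
    b <- sample(0:1, sample(2:60, 1), replace = TRUE)
    expect_identical(extract_events(b, fs_hz = 50, t0 = 0),
                     scan_events_oracle(b, fs_hz = 50, t0 = 0))
  }
})

test_that("extraction recovers the simulator's ground truth within a sample", {
  rec <- simulate_recording(gait_profile(seed = 17, asymmetry = 0.02))
  got <- extract_events(rec$signals$stance, fs_hz = 50)
  tru <- dplyr::arrange(rec$events, time_s)
  expect_equal(got$event, tru$event)
  expect_true(all(abs(got$time_s - tru$time_s) <= 1 / 50 + 1e-12))
})

test_that("matching scores identical, offset and jittered event sets", {
  ref <- tibble::tibble(event = c("HS", "TO", "HS"), time_s = c(1, 1.6, 2.2))
  perfect <- match_events(ref, ref)
  expect_equal(perfect$summary$mae_ms, c(0, 0))
  expect_equal(perfect$unmatched_reference, 0)
  expect_equal(perfect$spurious_predicted, 0)

  one <- match_events(
    tibble::tibble(event = "HS", time_s = 1.00),
    tibble::tibble(event = "HS", time_s = 1.04)
  )
  expect_equal(one$summary$mae_ms[one$summary$event == "HS"], 40)

  # +/- one sample of jitter on simulator events stays within 20 ms
  rec <- simulate_recording(gait_profile(seed = 23))
  tru <- rec$events
  set.seed(23)
  jit <- dplyr::mutate(tru, time_s = time_s + sample(c(-1, 1), dplyr::n(),
                                                    replace = TRUE) / 50)
  rep <- match_events(tru, jit)
  expect_true(all(rep$summary$mae_ms <= 20 + 1e-9))
  expect_equal(rep$unmatched_reference, 0)
})

test_that("kinds never cross-match and far events stay unmatched", {
  ref <- tibble::tibble(event = c("HS", "TO"), time_s = c(1.0, 1.01))
  pred <- tibble::tibble(event = c("TO", "HS"), time_s = c(1.0, 1.01))
  rep <- match_events(ref, pred)
  expect_equal(rep$matches$event, c("HS", "TO"))
  expect_equal(rep$matches$abs_error_ms, c(10, 10))

  far <- match_events(
    tibble::tibble(event = "HS", time_s = 1),
    tibble::tibble(event = "HS", time_s = 2)
  )
  expect_equal(nrow(far$matches), 0)
  expect_equal(far$unmatched_reference, 1)
  expect_equal(far$spurious_predicted, 1)
})

test_that("MAE is symmetric under role swap for equal-size unique-gap sets", {
  set.seed(5)
  ref <- tibble::tibble(event = "HS", time_s = sort(runif(6, 0, 10)))
  pred <- dplyr::mutate(ref, time_s = time_s + runif(6, -0.08, 0.08))
  a <- match_events(ref, pred)$summary
  b <- match_events(pred, ref)$summary
  expect_equal(a$mae_ms, b$mae_ms, tolerance = 1e-12)
})

test_that("detect_events composes the oracle path end to end", {
  rec <- preprocess_recording(simulate_recording(gait_profile(seed = 31)))
  ev <- detect_events(oracle_model(40), rec)
  # events after the warm-up window are the quantized truth
  tru <- rec$events[rec$events$time_s >= rec$signals$time[41], ]
  rep <- match_events(tru, ev)
  expect_true(all(rep$summary$mae_ms <= 20 + 1e-9, na.rm = TRUE))
  expect_equal(rep$unmatched_reference, 0)
})
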