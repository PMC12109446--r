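test_that("Kalman filter fixes constants and tracks exactly as r shrinks", {
  expect_equal(kalman_smooth(c(5, 5, 5, 5), q = 0.01, r = 1), c(5, 5, 5, 5))
  expect_equal(kalman_smooth(rep(-2.5, 20), q = 100, r = 1e-6), rep(-2.5, 20))
  x <- sin(1:30)
  expect_equal(kalman_smooth(x, q = 1, r = 1e-14), x, tolerance = 1e-10)
})

test_that("Kalman filter reduces variance and matches the recursion oracle", {
  x <- rep(c(0, 1), 25)
  y <- kalman_smooth(x, q = 0.01, r = 1)
  expect_lt(var(y), var(x))
  expect_equal(y, kalman_oracle(x, 0.01, 1), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:5) {
    n <- sample(2:1000, 1)
    x <- rnorm(n)
    q <- runif(1, 1e-4, 1)
    r <- runif(1, 1e-3, 2)
    expect_equal(kalman_smooth(x, q, r), kalman_oracle(x, q, r),
                 tolerance = 1e-12)
  }
})

test_that("Kalman filter rejects bad input", {
  expect_error(kalman_smooth(c(1, NA, 2), 0.1, 0.1), "non-finite")
  expect_error(kalman_smooth(1:5, q = 0, r = 1), "positive")
  expect_error(kalman_smooth(1:5, q = 1, r = -1), "positive")
})

test_that("low-pass passes the band, blocks the stopband, keeps DC exact", {
  t <- seq(0, 4, by = 1 / 50)
  slow <- sin(2 * pi * 1 * t)
  fast <- sin(2 * pi * 20 * t)
  y_slow <- lowpass(slow, cutoff_hz = 10, order = 4, fs_hz = 50)
  y_fast <- lowpass(fast, cutoff_hz = 10, order = 4, fs_hz = 50)
  expect_equal(length(y_slow), length(slow))
  expect_gt(tone_amplitude(y_slow, 1, t), 0.99)   # < 1% attenuation
  expect_lt(tone_amplitude(y_fast, 20, t), 0.10)  # > 90% attenuation
  expect_equal(lowpass(rep(5, 100), 10, 4, 50), rep(5, 100), tolerance = 1e-9)
  expect_error(lowpass(slow, cutoff_hz = 25, fs_hz = 50), "Nyquist")
  expect_error(lowpass(slow, cutoff_hz = 30, fs_hz = 50), "Nyquist")
})

test_that("zero-phase filtering does not shift a gait-band tone", {
  t <- seq(0, 4, by = 1 / 50)
  x <- sin(2 * pi * 2 * t)
  y <- lowpass(x, 10, 4, 50)
  lag <- which.max(stats::ccf(y, x, lag.max = 5, plot = FALSE)$acf) - 6
  expect_equal(lag, 0)
})

test_that("channel exclusion keeps order and rejects nonsense", {
  rec <- clean_recording()
  kept <- select_channels(rec)
  expect_equal(setdiff(names(kept$signals), c("time", "stance")),
               c("Ax", "Ay", "Gy", "Gz", "Yaw", "Roll"))
  same <- select_channels(rec, excluded = character(0))
  expect_identical(same$signals, rec$signals)
  expect_error(select_channels(rec, excluded = c("Az", "Qx")), "Unknown")
  expect_error(
    select_channels(rec, excluded = c("Ax", "Ay", "Az", "Gx", "Gy", "Gz",
                                      "Yaw", "Pitch", "Roll")),
    "every channel"
  )
})

test_that("full preprocessing preserves length, drops channels, smooths", {
  rec <- simulate_recording(gait_profile(seed = 10))
  pre <- preprocess_recording(rec)
  expect_equal(nrow(pre$signals), nrow(rec$signals))
  expect_identical(pre$signals$time, rec$signals$time)
  expect_identical(pre$signals$stance, rec$signals$stance)
  expect_equal(setdiff(names(pre$signals), c("time", "stance")),
               c("Ax", "Ay", "Gy", "Gz", "Yaw", "Roll"))
  # the zero-phase low-pass is idempotent on already-smooth signals: its
  # passband gain is ~1, so a second application barely changes RMS (the
  # causal Kalman stage, by contrast, is a contraction on every pass)
  for (ch in c("Ax", "Ay", "Gy")) {
    x <- pre$signals[[ch]]
    y <- lowpass(x, 10, 4, 50)
    expect_lt(abs(sqrt(mean(y^2)) - sqrt(mean(x^2))) / sqrt(mean(x^2)), 0.01)
  }
})

test_that("channel statistics standardize a recording", {
  recs <- list(simulate_recording(gait_profile(seed = 1)),
               simulate_recording(gait_profile(seed = 2)))
  st <- channel_stats(recs)
  expect_equal(nrow(st), 9)
  z <- apply_channel_stats(recs[[1]], st)
  pooled <- c(recs[[1]]$signals$Ax, recs[[2]]$signals$Ax)
  expect_equal(mean((pooled - st$mean[st$channel == "Ax"]) /
                      st$sd[st$channel == "Ax"]), 0, tolerance = 1e-10)
  expect_false(identical(z$signals$Ax, recs[[1]]$signals$Ax))
})
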