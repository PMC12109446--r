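test_that("paired t test handles identity, shifts and degenerate cases", {
  a <- c(1.1, 1.3, 0.9, 1.2)
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  # constant nonzero shift with zero difference variance: documented
  # convention p -> 0
  shifted <- paired_ttest(a + 0.5, a)
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p, 0)
  expect_true(shifted$significant)

  # agrees with stats::t.test in the regular case
  set.seed(1)
  b <- a + rnorm(4, 0.3, 0.1)
  ours <- paired_ttest(b, a)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)

  expect_error(paired_ttest(1:3, 1:4), "same length")
  expect_error(paired_ttest(1, 2), "two pairs")
})

test_that("t statistic flips sign and p is unchanged when roles swap", {
  set.seed(2)
  a <- rnorm(10, 1)
  b <- rnorm(10, 1.2)
  ab <- paired_ttest(a, b)
  ba <- paired_ttest(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("task comparison pairs subjects and covers all eight parameters", {
  dt <- dual_task_experiment(n_subjects = 8, seed = 9)
  cmp <- dt$comparison
  expect_equal(nrow(cmp), 8)
  expect_setequal(cmp$parameter,
                  c("cadence_spm", "stride_time_s", "stance_phase_pct",
                    "swing_phase_pct", "stance_time_s", "swing_time_s",
                    "stride_length_m", "walking_speed_mps"))
  expect_true(all(cmp$n == 8))
  # directions: dual task lowers cadence/speed and raises stance share
  get <- function(p) cmp$mean_diff[cmp$parameter == p]
  expect_gt(get("cadence_spm"), 0)
  expect_gt(get("walking_speed_mps"), 0)
  expect_lt(get("stance_phase_pct"), 0)

  holm <- compare_tasks(dt$parameters, adjust = "holm")
  expect_true(all(holm$p >= cmp$p - 1e-15))
})

test_that("Bland-Altman summaries match the closed-form oracle", {
  ba <- bland_altman(c(1.02, 2.01, 2.98), c(1.00, 2.00, 3.00))
  d <- c(0.02, 0.01, -0.02)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))

  # identical vectors: zero bias and collapsed limits
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)

  # the two-point worked example {+20, -20} ms
  two <- bland_altman(c(1.02, 1.98), c(1.00, 2.00))
  expect_equal(two$bias, 0)
  expect_equal(two$loa_upper, 1.96 * sd(c(0.02, -0.02)))

  expect_error(bland_altman(1, 1), "two pairs")
  expect_error(bland_altman(1:3, 1:4), "same length")
})

test_that("grouped Bland-Altman reports per-group and pooled rows", {
  set.seed(3)
  ref <- runif(30, 0, 10)
  det <- ref + rnorm(30, 0.01, 0.02)
  grp <- rep(c("low", "normal", "high"), each = 10)
  ba <- bland_altman(det, ref, group = grp)
  expect_setequal(ba$group, c("low", "normal", "high", "(pooled)"))
  pooled <- ba[ba$group == "(pooled)", ]
  expect_equal(pooled$bias, mean(det - ref), tolerance = 1e-12)
  expect_equal(pooled$n, 30)
})
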