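test_that("window splitting respects the 20 ms boundary rule", {
  sp <- data.frame(trial = c(1, 1, 2), time_ms = c(10, 19.999, 5))
  w <- split_windows(sp, n_trials = 2)
  expect_equal(w$rate_mean[w$window == "late"], 0)
  expect_gt(w$rate_mean[w$window == "early"], 0)
  # a spike at exactly 20 ms counts as late
  w2 <- split_windows(data.frame(trial = 1, time_ms = 20), n_trials = 1)
  expect_equal(w2$rate_mean[w2$window == "late"], 1 / 0.08)
  expect_equal(w2$rate_mean[w2$window == "early"], 0)
  expect_error(split_windows(sp, 2, trial_end_ms = 50),
               class = "scmsi_window_error")
})

test_that("window rates conserve the total spike count", {
  set.seed(81)
  n_trials <- 20
  sp <- data.frame(trial = rep(1:n_trials, each = 10),
                   time_ms = runif(200, 0, 100))
  per <- split_windows(sp, n_trials, per_trial = TRUE)
  counts <- per$rate * ifelse(per$window == "early", 0.02, 0.08)
  expect_equal(sum(counts), nrow(sp))
  # uniform rate: both windows estimate the same underlying rate
  agg <- split_windows(sp, n_trials)
  expect_equal(agg$rate_mean[1], agg$rate_mean[2], tolerance = 0.2)
})

test_that("responsiveness p-values match the count-model tails", {
  # evoked equal to baseline: clearly not significant
  r <- responsiveness_test(total_count = 5, n_trials = 30, window_s = 0.08,
                           baseline_rate = 2, theta = 1)
  expect_gt(r$p_value, 0.01)
  expect_false(r$significant)
  # ten-fold response over baseline at 30 trials: detected
  mu <- 2 * 0.08 * 30
  r2 <- responsiveness_test(round(10 * mu), 30, 0.08, 2, theta = 1)
  expect_lt(r2$p_value, 1e-3)
  # closed-form check against the Poisson tail
  expect_equal(responsiveness_test(10, 30, 0.08, 2, theta = 1)$p_value,
               ppois(9, mu, lower.tail = FALSE))
  # overdispersed null uses the moment-matched negative binomial
  expect_equal(responsiveness_test(10, 30, 0.08, 2, theta = 3)$p_value,
               pnbinom(9, size = mu / 2, mu = mu, lower.tail = FALSE))
  expect_equal(responsiveness_test(0, 30, 0.08, 0)$p_value, 1)
})

test_that("monotonicity classification detects peaked tuning and not noise", {
  set.seed(82)
  lv <- c(20, 30, 40, 50)
  # strictly increasing, noiseless
  inc <- data.frame(intensity = rep(lv, each = 5),
                    rate = rep(c(5, 10, 15, 20), each = 5))
  expect_equal(classify_monotonicity(inc)$class, "monotonic")
  # strong mid-intensity peak with 30 trials
  peak <- data.frame(intensity = rep(lv, each = 30),
                     rate = rnorm(120, rep(c(10, 40, 20, 12), each = 30), 6))
  res <- classify_monotonicity(peak)
  expect_equal(res$class, "non_monotonic")
  expect_lt(res$p_min_contrast, 1e-3)
  expect_error(classify_monotonicity(inc[inc$intensity < 40, ]), "3 intensity")
  expect_error(classify_monotonicity(
    data.frame(intensity = lv, rate = 1:4)), "2 trials")
})

test_that("flat tuning is rarely called non-monotonic", {
  set.seed(83)
  calls <- replicate(300, {
    tr <- data.frame(intensity = rep(c(20, 30, 40, 50), each = 30),
                     rate = rnorm(120, 15, 5))
    classify_monotonicity(tr)$class == "non_monotonic"
  })
  expect_lte(mean(calls), 0.02)
})
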