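test_that("populations and trials are bit-identical under the same seed", {
  gt1 <- make_population(6, "mixed", seed = 101)
  gt2 <- make_population(6, "mixed", seed = 101)
  expect_identical(gt1$params, gt2$params)
  d1 <- simulate_trials(gt1, n_trials = 10, seed = 102)
  d2 <- simulate_trials(gt2, n_trials = 10, seed = 102)
  expect_identical(d1, d2)
  expect_false(identical(d1, simulate_trials(gt1, n_trials = 10, seed = 103)))
})

test_that("generated tables satisfy the response-table invariants", {
  gt <- make_population(3, "AM", seed = 104)
  d <- simulate_trials(gt, n_trials = 12, seed = 105)
  expect_silent(validate_responses(d))
  expect_equal(as.vector(table(d$neuron_id)), rep(336L, 3))  # 168 per window
  expect_true(all(d$R_obs >= 0 & d$sigma_obs >= 0))
  expect_true(all(d$n_trials == 12))
  # every neuron has all 168 non-redundant late patterns exactly once
  late <- d[d$window == "late" & d$neuron_id == "n001", ]
  key <- paste(late$phi_V, late$phi_A, late$I_V, late$I_A)
  expect_equal(length(unique(key)), 168)
})

test_that("scenario classes control the modulation weights", {
  lin <- make_population(10, "linear", seed = 106)
  expect_true(all(lin$params$alpha == 1))
  expect_equal(lin$variant, "L")
  am <- make_population(10, "AM", seed = 107)
  expect_true(all(am$params$alpha >= 1.5 & am$params$alpha <= 10))
  mx <- make_population(100, "mixed", seed = 108)
  tab <- table(mx$params$scenario_class)
  expect_equal(unname(tab["linear"]), 70)
  expect_equal(unname(tab["superlinear"]), 17)
  expect_equal(unname(tab["sublinear"]), 13)
  expect_true(all(mx$params$alpha[mx$params$scenario_class == "linear"] == 1))
})

test_that("the default ground-truth modulation has the expected sign structure", {
  gt <- make_population(5, "AM", seed = 109)
  ph <- gt$params$phi_eff[1]
  expect_gt(modulation_delta(ph, 20, ph, gt$global), 0)
  expect_lt(modulation_delta(ph, 50, ph, gt$global), 0)
})

test_that("simulated counts have the requested mean and dispersion", {
  g <- stimulus_grid()
  np <- neuron_params("m", F_V = setNames(c(30, 30, 30), g$visual_azimuths),
                      F_A = setNames(c(30, 30, 30), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 30, n_A = 2,
                      alpha = 1, phi_eff = 0, b = 5)
  np$theta_true <- 1
  gt <- manual_gt(np, variant = "L")
  d <- simulate_trials(gt, n_trials = 10000, seed = 110, windows = "late",
                       keep_trials = TRUE)
  tr <- attr(d, "trials")
  one <- tr[tr$phi_V == 0 & !is.na(tr$phi_V) & tr$I_V == 0.75 &
              is.na(tr$phi_A), ]
  counts <- one$rate * 0.08
  expect_equal(length(counts), 10000)
  # Poisson: variance over mean within 10%
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)
  # law of large numbers: observed means converge on the model rates
  late <- d[d$R_obs > 0, ]
  pred <- predict_rate(late, np, NULL, "L")
  rel <- abs(late$R_obs - pred$R_model) / pred$R_model
  expect_lt(max(rel[pred$R_model >= 5]), 0.05)
  expect_lt(median(rel), 0.01)
})

test_that("a silent neuron produces all-zero counts and exercises the floor", {
  g <- stimulus_grid()
  np <- neuron_params("z", F_V = setNames(rep(0, 3), g$visual_azimuths),
                      F_A = setNames(rep(0, 3), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 30, n_A = 2,
                      alpha = 1, phi_eff = 0, b = 0)
  np$early_F <- 0
  gt <- manual_gt(np, variant = "L")
  gt$params$b <- 0
  d <- simulate_trials(gt, n_trials = 5, seed = 111)
  expect_true(all(d$R_obs == 0))
  expect_true(all(d$sigma_obs == 0))
  expect_equal(unique(dispersion(d$R_obs, d$sigma_obs)), 1)
})

test_that("RF mapping grids have the documented geometry and recover centers", {
  gt <- make_population(2, "AM", seed = 112)
  rf <- simulate_rf_grids(gt, seed = 113)
  expect_equal(nrow(rf$visual) / 2, 112)
  expect_equal(nrow(rf$auditory) / 2, 85)
  v <- fit_visual_rf(rf$visual[rf$visual$neuron_id == "n001", ])
  expect_equal(unname(v$center["azimuth"]), gt$params$phi_eff[1],
               tolerance = 5)
  a <- fit_auditory_rf(rf$auditory[rf$auditory$neuron_id == "n001", ])
  expect_equal(unname(a$center["azimuth"]), gt$params$phi_eff[1],
               tolerance = 8)
})
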