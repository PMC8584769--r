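test_that("dispersion is the SEM-squared to mean ratio with a floor", {
  expect_equal(dispersion(4, 2), 1)
  expect_equal(dispersion(10, 5), 25 / 10)
  expect_equal(dispersion(0, 2), 1)
  expect_equal(dispersion(5, 0), 1)
  expect_equal(dispersion(0, 0, floor = 2.5), 2.5)
})

test_that("deviance terms match the closed form and its zero-rate limit", {
  expect_equal(deviance_term(7, 7, 3), 0)
  expect_equal(deviance_term(10, 20, 2), 10 * (2 - 1 - log(2)))
  expect_equal(deviance_term(0, 5, 1), 10)
  expect_error(deviance_term(1, -1, 1), class = "scmsi_domain_error")
  expect_error(deviance_term(1, 1, 0), class = "scmsi_domain_error")
})

test_that("deviance is non-negative, zero only at equality, linear in 1/theta", {
  set.seed(31)
  R_obs <- runif(200, 0, 50)
  R_model <- runif(200, 0.5, 50)
  th <- runif(200, 0.5, 3)
  t1 <- deviance_term(R_obs, R_model, th)
  expect_true(all(t1 >= 0))
  expect_true(all(t1[abs(R_obs - R_model) > 1e-6] > 0))
  expect_equal(deviance_term(R_obs, R_model, 2 * th), t1 / 2)
})

test_that("degrees of freedom follow the published formulas", {
  expect_equal(degrees_of_freedom(1, "L"), 158)
  expect_equal(degrees_of_freedom(1, "AM"), 148)
  expect_equal(degrees_of_freedom(10, "AM"), 1552)
  expect_equal(degrees_of_freedom(10, "AM"), 156 * 10 - 8)
  expect_equal(degrees_of_freedom(7, "VM"), 156 * 7 - 8)
  expect_equal(degrees_of_freedom(7, "L"), 158 * 7)
  expect_error(degrees_of_freedom(0, "L"))
})

test_that("the goodness-of-fit p-value is the chi-squared upper tail", {
  expect_equal(gof_pvalue(0, 10), 1)
  # numeric-integration oracle for the survival function
  oracle <- integrate(function(x) dchisq(x, 10), 20, Inf)$value
  expect_equal(gof_pvalue(20, 10), oracle, tolerance = 1e-6)
  expect_equal(gof_pvalue(1000, 1000), 0.5, tolerance = 0.02)
})

test_that("total deviance equals an independent plain-loop summation", {
  gt <- make_population(5, "AM", seed = 61)
  d <- simulate_trials(gt, n_trials = 10, seed = 62, windows = "late")
  rep <- total_deviance(d, gt$params, gt$global, "AM")
  # oracle: per-row loop in reversed order with scalar arithmetic
  dl <- d[rev(seq_len(nrow(d))), ]
  D_oracle <- 0
  for (j in seq_len(nrow(dl))) {
    np <- gt$params[gt$params$neuron_id == dl$neuron_id[j], ]
    mu <- predict_rate(dl[j, ], np, gt$global, "AM")$R_model
    th <- if (dl$R_obs[j] > 0 && dl$sigma_obs[j] > 0)
      dl$sigma_obs[j]^2 / dl$R_obs[j] else 1
    D_oracle <- D_oracle + if (dl$R_obs[j] == 0) 2 * mu / th else
      2 * dl$R_obs[j] / th * (mu / dl$R_obs[j] - 1 - log(mu / dl$R_obs[j]))
  }
  expect_equal(rep$D, D_oracle, tolerance = 1e-9)
  expect_equal(sum(rep$per_neuron$D), rep$D)
  expect_equal(rep$df, degrees_of_freedom(5, "AM"))
  expect_equal(rep$outlier_deviance, rep$d_per_df - 1)
})

test_that("a model that reproduces the data exactly has zero deviance", {
  gt <- make_population(3, "AM", seed = 63)
  d <- exact_table(gt)
  rep <- total_deviance(d, gt$params, gt$global, "AM")
  expect_equal(rep$D, 0, tolerance = 1e-10)
  expect_equal(rep$gof_p, 1)
})

test_that("missing pattern rows are reported by neuron", {
  gt <- make_population(2, "AM", seed = 64)
  d <- simulate_trials(gt, n_trials = 5, seed = 65, windows = "late")
  expect_error(total_deviance(d[-13, ], gt$params, gt$global, "AM"),
               "n001", class = "scmsi_missing_patterns")
})
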