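test_that("unisensory initialization recovers sigmoids from noiseless data", {
  g <- stimulus_grid()
  np <- neuron_params("u1", F_V = setNames(c(20, 35, 15), g$visual_azimuths),
                      F_A = setNames(c(25, 10, 30), g$auditory_azimuths),
                      I_V50 = 0.45, n_V = 2.2, I_A50 = 32, n_A = 2.8,
                      alpha = 1, phi_eff = 30, b = 3)
  gt <- manual_gt(np, variant = "L")
  d <- exact_table(gt)
  init <- init_unisensory(d)
  expect_equal(init$I_V50, 0.45, tolerance = 1e-3)
  expect_equal(init$n_V, 2.2, tolerance = 1e-3)
  expect_equal(init$I_A50, 32, tolerance = 1e-3)
  expect_equal(init$n_A, 2.8, tolerance = 1e-3)
  expect_equal(init$F_V[[1]], np$F_V[[1]], tolerance = 1e-3)
  expect_false(init$init_flagged)
  expect_equal(init$phi_eff, 30)     # taken from the phi_eff_init column
  expect_equal(init$alpha, 1.01)     # narrow-phase lower bound
})

test_that("a silent neuron gets minimal defaults and a flag", {
  g <- stimulus_grid()
  np <- neuron_params("flat", F_V = setNames(rep(0, 3), g$visual_azimuths),
                      F_A = setNames(rep(0, 3), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 30, n_A = 2,
                      alpha = 1, phi_eff = 0, b = 0)
  d <- exact_table(manual_gt(np, variant = "L"))
  d$R_obs <- 0; d$sigma_obs <- 0
  init <- init_unisensory(d)
  expect_true(init$init_flagged)
  expect_equal(init$F_V[[1]], setNames(rep(0, 3), g$visual_azimuths))
})

test_that("a visual-only neuron comes back with near-zero auditory drive", {
  g <- stimulus_grid()
  np <- neuron_params("v", F_V = setNames(c(30, 40, 20), g$visual_azimuths),
                      F_A = setNames(rep(0, 3), g$auditory_azimuths),
                      I_V50 = 0.35, n_V = 1.8, I_A50 = 30, n_A = 2,
                      alpha = 1, phi_eff = 0, b = 2)
  init <- init_unisensory(exact_table(manual_gt(np, variant = "L")))
  expect_lt(max(init$F_A[[1]]), 0.5)
  expect_equal(init$I_V50, 0.35, tolerance = 1e-3)
})

test_that("refitting an already optimal neuron leaves the deviance unchanged", {
  fx <- fx_am5()
  prep <- scmsi:::prep_fit_data(fx$data)
  plist <- scmsi:::.params_to_p(fx$fit$params, prep)
  g <- scmsi:::.g_to_vec(fx$fit$global)
  b2 <- scmsi:::phase_bounds(2)
  d0 <- scmsi:::.neuron_dev(prep$neurons[[1]], plist[[1]], g, "AM", 3, 1e-3)
  res <- scmsi:::.fit_neuron(prep$neurons[[1]], plist[[1]], g, "AM", 2, b2,
                             3, 1e-3)
  expect_lte(res$dev, d0 + 1e-6)
  expect_lt(abs(res$dev - d0), 0.5)
})

test_that("a neuron block recovers alpha from noiseless data given the true global", {
  g <- stimulus_grid()
  np <- neuron_params("a", F_V = setNames(c(20, 30, 25), g$visual_azimuths),
                      F_A = setNames(c(15, 25, 20), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 35, n_A = 2.5,
                      alpha = 4, phi_eff = 30, b = 3)
  gt <- manual_gt(np, variant = "AM")
  d <- exact_table(gt)
  prep <- scmsi:::prep_fit_data(d)
  gvec <- scmsi:::.g_to_vec(gt$global)
  b2 <- scmsi:::phase_bounds(2)
  start <- scmsi:::.params_to_p(gt$params, prep)[[1]]
  start[11] <- 1.5  # perturb alpha away from the truth
  res <- scmsi:::.fit_neuron(prep$neurons[[1]], start, gvec, "AM", 2, b2,
                             3, 1e-3, maxit = 500)
  expect_equal(res$p[11], 4, tolerance = 0.01)
})

test_that("with no nonlinearity in the data, alpha stays at its lower bound", {
  g <- stimulus_grid()
  np <- neuron_params("l", F_V = setNames(c(20, 30, 25), g$visual_azimuths),
                      F_A = setNames(c(15, 25, 20), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 35, n_A = 2.5,
                      alpha = 1, phi_eff = 30, b = 3)
  d <- exact_table(manual_gt(np, variant = "L"))
  prep <- scmsi:::prep_fit_data(d)
  gvec <- scmsi:::.g_to_vec(default_global())
  b1 <- scmsi:::phase_bounds(1)
  start <- scmsi:::.params_to_p(np, prep)[[1]]
  start[11] <- 1.01
  res <- scmsi:::.fit_neuron(prep$neurons[[1]], start, gvec, "AM", 1, b1,
                             3, 1e-3, maxit = 500)
  expect_lt(res$p[11], 1.02)
})

test_that("the global deviance profile is flat when every alpha is 1", {
  fx <- fx_lin4()
  d <- exact_table(fx$gt)
  prep <- scmsi:::prep_fit_data(d)
  plist <- scmsi:::.params_to_p(fx$gt$params, prep)
  set.seed(71)
  b1 <- scmsi:::phase_bounds(1)
  devs <- replicate(6, {
    g <- runif(8, b1$global_lower, b1$global_upper)
    scmsi:::.total_dev(prep, plist, g, "AM", 1e-3)
  })
  expect_lt(diff(range(devs)), 1e-9)
})

test_that("the alternating fit is deterministic and monotone", {
  fx <- fx_am5()
  f2 <- alternating_fit(fx$data, "AM", msi_config(n_restarts = 1), seed = 11)
  expect_equal(f2$nll, fx$fit$nll)
  expect_equal(f2$params, fx$fit$params)
  expect_equal(scmsi:::.g_to_vec(f2$global),
               scmsi:::.g_to_vec(fx$fit$global))
  # NLL trace never increases within a phase
  for (ph in unique(fx$fit$trace$phase)) {
    tr <- fx$fit$trace$nll[fx$fit$trace$phase == ph]
    expect_true(all(diff(tr) <= 1e-8))
  }
  # phase 2 starts from phase 1's solution: no NLL jump upward
  expect_lte(min(fx$fit$trace$nll[fx$fit$trace$phase == "phase2"]),
             min(fx$fit$trace$nll[fx$fit$trace$phase == "phase1"]) + 1e-8)
})

test_that("the modulated model never fits worse than the linear model", {
  fx <- fx_am5()
  fl <- alternating_fit(fx$data, "L", msi_config(), seed = 1)
  expect_lte(fx$fit$nll, fl$nll + 0.1)
})

test_that("multi-restart picks the best seed and is monotone in restarts", {
  fx <- fx_am5()
  one <- multi_restart(fx$data, "AM", msi_config(n_restarts = 1), seed = 9)
  expect_equal(one$restart_nlls, one$nll)
  three <- multi_restart(fx$data, "AM", msi_config(), n_restarts = 3, seed = 9)
  expect_lte(three$nll, one$nll + 1e-9)
  expect_equal(three$nll, min(three$restart_nlls))
  expect_equal(three$restart_index,
               which(three$restart_nlls <= min(three$restart_nlls) + 1e-6)[1])
})
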