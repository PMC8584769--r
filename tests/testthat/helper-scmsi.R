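# Shared fixtures: heavier fits are computed once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fx)) assign(name, maker(), envir = .fx)
  get(name, envir = .fx)
}

# small audition-modulated population with a completed fit
fx_am5 <- function() fixture("am5", function() {
  gt <- make_population(5, "AM", seed = 201)
  data <- simulate_trials(gt, n_trials = 30, seed = 202, sem = "true")
  fit <- alternating_fit(data, "AM", msi_config(n_restarts = 1), seed = 11)
  list(gt = gt, data = data, fit = fit)
})

# linear population (all alpha = 1) with trials
fx_lin4 <- function() fixture("lin4", function() {
  gt <- make_population(4, "linear", seed = 301)
  data <- simulate_trials(gt, n_trials = 30, seed = 302, sem = "true")
  list(gt = gt, data = data)
})

# noiseless response table: R_obs set exactly to the model prediction
exact_table <- function(gt, grid = gt$grid, sigma_obs = 1) {
  pats <- patterns(grid)
  purrr::map_dfr(seq_len(nrow(gt$params)), function(i) {
    np <- gt$params[i, ]
    pred <- predict_rate(pats, np, gt$global, gt$variant)
    tibble::tibble(
      neuron_id = np$neuron_id, window = "late",
      phi_V = pred$phi_V, phi_A = pred$phi_A,
      I_V = pred$I_V, I_A = pred$I_A,
      R_obs = pred$R_model, sigma_obs = sigma_obs, n_trials = 30,
      b = np$b, phi_eff_init = np$phi_eff, theta = 1
    )
  })
}

# hand-built ground truth wrapper for custom parameter tables
manual_gt <- function(params, global = default_global(), variant = "AM",
                      grid = stimulus_grid()) {
  if (!"theta_true" %in% names(params)) params$theta_true <- 1
  if (!"early_F" %in% names(params)) params$early_F <- 10
  if (!"early_I50" %in% names(params)) params$early_I50 <- 30
  if (!"early_n" %in% names(params)) params$early_n <- 2
  structure(list(params = params, global = global, variant = variant,
                 scenario = "manual", seed = 0, grid = grid),
            class = "msi_ground_truth")
}
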