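#' Generate a synthetic population with known ground truth
#'
#' Draws per-neuron model parameters emulating a deep-SC population under
#' the factorial visuoauditory design: maximal evoked rates lognormal
#' around 5-40 Hz, intensity-sigmoid parameters inside the narrow-phase
#' boxes, baselines uniform on 1-10 Hz, per-neuron dispersion uniform on
#' 1-3 (typical collicular overdispersion), and effective RF azimuths near
#' the three stimulus locations. Scenarios: `"linear"` sets every
#' `alpha = 1`; `"AM"` / `"VM"` draw modulation weights lognormally within
#' 1.5-10 with the modulation driven by audition / vision; `"mixed"`
#' makes 17% of neurons superlinear-dominant (effective azimuth on a
#' stimulus location), 13% sublinear-dominant (effective azimuth displaced
#' off the excitatory center), and 70% linear. The shared modulation
#' function defaults to the center-surround shape of [default_global()].
#'
#' Each neuron also carries an early-window auditory tuning (monotone
#' sigmoid) so the window-characterization tools can be exercised on the
#' same population.
#'
#' @param n_neurons Population size.
#' @param scenario `"AM"`, `"VM"`, `"linear"`, or `"mixed"`.
#' @param seed Master seed.
#' @param grid The [stimulus_grid()] design.
#' @param global Shared modulation function (truth).
#' @param phi_jitter SD (degrees) of the jitter between a neuron's
#'   effective azimuth and its nearest stimulus location.
#' @return An object of class `msi_ground_truth`: `params` (a
#'   [neuron_params()] tibble with extra columns `theta_true`, `early_F`,
#'   `early_I50`, `early_n`, `scenario_class`), `global`, `variant`,
#'   `seed`.
#' @export
make_population <- function(n_neurons, scenario = c("AM", "linear", "VM", "mixed"),
                            seed = 1, grid = stimulus_grid(),
                            global = default_global(), phi_jitter = 5) {
  scenario <- match.arg(scenario)
  stopifnot(n_neurons >= 1)
  set.seed(seed)
  vis_az <- grid$visual_azimuths
  aud_az <- grid$auditory_azimuths
  classes <- switch(scenario,
    linear = rep("linear", n_neurons),
    AM = rep("modulated", n_neurons),
    VM = rep("modulated", n_neurons),
    mixed = sample(rep(c("superlinear", "sublinear", "linear"),
                       times = pmax(round(n_neurons * c(0.17, 0.13, 0.70)), 0))[
                         seq_len(n_neurons)])
  )
  draw_F <- function(k) pmin(rlnorm(k, meanlog = log(15), sdlog = 0.45), 95)
  params <- purrr::map_dfr(seq_len(n_neurons), function(i) {
    cl <- classes[i]
    home <- sample(aud_az, 1)
    phi_eff <- switch(cl,
      sublinear = home + sample(c(-1, 1), 1) * 60 + rnorm(1, 0, phi_jitter),
      home + rnorm(1, 0, phi_jitter)
    )
    alpha <- if (cl == "linear") 1 else
      pmin(pmax(rlnorm(1, meanlog = log(3), sdlog = 0.5), 1.5), 10)
    mid_IV <- stats::median(grid$visual_intensities[grid$visual_intensities > 0])
    np <- neuron_params(
      neuron_id = sprintf("n%03d", i),
      F_V = setNames(draw_F(length(vis_az)), vis_az),
      F_A = setNames(draw_F(length(aud_az)), aud_az),
      I_V50 = runif(1, 0.6 * mid_IV, 1.4 * mid_IV),
      n_V = runif(1, 1, 3),
      I_A50 = runif(1, 25, 45), n_A = runif(1, 1, 4),
      alpha = alpha, phi_eff = phi_eff,
      b = runif(1, 1, 10)
    )
    np$theta_true <- runif(1, 1, 3)
    np$early_F <- draw_F(1)
    np$early_I50 <- runif(1, 25, 40)
    np$early_n <- runif(1, 2, 4)
    np$scenario_class <- cl
    np
  })
  variant <- switch(scenario, VM = "VM", linear = "L", "AM")
  structure(
    list(params = params, global = global, variant = variant,
         scenario = scenario, seed = seed, grid = grid),
    class = "msi_ground_truth"
  )
}

#' @export
print.msi_ground_truth <- function(x, ...) {
  cat(sprintf("<msi_ground_truth> %d neurons, scenario '%s' (%s variant), seed %d\n",
              nrow(x$params), x$scenario, x$variant, x$seed))
  invisible(x)
}

# gamma-mixed Poisson (negative binomial) counts with mean m, variance theta*m
.rcounts <- function(n, m, theta) {
  if (m <= 0) return(rep(0L, n))
  if (theta <= 1) rpois(n, m)
  else rnbinom(n, size = m / (theta - 1), mu = m)
}

#' Simulate trial firing-rate tables from a ground truth
#'
#' For every (neuron, non-redundant pattern), late-window spike counts
#' over the 80 ms window (20-100 ms) are drawn with mean `rate * 0.08`
#' and variance `theta_true * mean` (gamma-mixed Poisson), where the rate
#' comes from [predict_rate()] under the generating variant. Early-window
#' counts (20 ms) are drawn from each neuron's monotone early auditory
#' sigmoid for auditory-present patterns and from baseline otherwise.
#' Observed means, SEMs and the measured baseline column `b` are computed
#' from the simulated trials; `phi_eff_init` records the true effective
#' azimuth plus location jitter for use as the Phase-1 fixed value.
#'
#' @param gt An [make_population()] ground truth.
#' @param grid Stimulus design (defaults to the one in `gt`).
#' @param n_trials Trials per pattern.
#' @param seed Seed.
#' @param windows Which windows to tabulate.
#' @param init_jitter SD (degrees) of the jitter added to the true
#'   effective azimuth to form `phi_eff_init`.
#' @param keep_trials Also return the per-trial late-window rates (as
#'   attribute `"trials"`)?
#' @param sem `"sample"` computes `sigma_obs` as the empirical SEM of the
#'   simulated trial rates; `"true"` writes the known-dispersion SEM
#'   `sqrt(theta_true * rate / (window * n_trials))` and adds a `theta`
#'   column with the exact rate-unit dispersion, which the likelihood
#'   uses directly — for calibration studies where the dispersion should
#'   not carry sampling noise.
#' @return A response tibble (see [read_responses()] for the schema).
#' @export
simulate_trials <- function(gt, grid = gt$grid, n_trials = 30, seed = 1,
                            windows = c("early", "late"), init_jitter = 0,
                            keep_trials = FALSE, sem = c("sample", "true")) {
  sem <- match.arg(sem)
  stopifnot(inherits(gt, "msi_ground_truth"))
  set.seed(seed)
  pats <- patterns(grid)
  w_late <- 0.08; w_early <- 0.02
  trials_out <- vector("list", nrow(gt$params))
  tab <- purrr::map_dfr(seq_len(nrow(gt$params)), function(i) {
    np <- gt$params[i, ]
    theta <- np$theta_true
    pred <- predict_rate(pats, np, gt$global, gt$variant)
    sim_window <- function(mu_vec, w) {
      rates <- vapply(mu_vec, function(mu) .rcounts(n_trials, mu * w, theta),
                      numeric(n_trials)) / w  # n_trials x n_patterns
      sigma_obs <- if (sem == "sample") {
        apply(rates, 2, sd) / sqrt(n_trials)
      } else {
        # known-dispersion SEM: var(rate) = theta * mu / w
        sqrt(theta * mu_vec / (w * n_trials))
      }
      out <- tibble::tibble(
        phi_V = pred$phi_V, phi_A = pred$phi_A,
        I_V = pred$I_V, I_A = pred$I_A,
        R_obs = colMeans(rates),
        sigma_obs = sigma_obs,
        n_trials = n_trials,
        .rates = lapply(seq_len(ncol(rates)), function(j) rates[, j])
      )
      if (sem == "true") {
        # known dispersion in rate units (sigma_true^2 / mu); Poisson
        # fallback where the true rate is zero
        out$theta <- ifelse(mu_vec > 0, theta / (w * n_trials), 1)
      }
      out
    }
    out <- NULL
    if ("late" %in% windows) {
      late <- sim_window(pred$R_model, w_late)
      late$window <- "late"
      if (keep_trials) {
        trials_out[[i]] <<- late |>
          dplyr::mutate(neuron_id = np$neuron_id) |>
          tidyr::unnest_longer(".rates", values_to = "rate",
                               indices_to = "trial") |>
          dplyr::select("neuron_id", "window", "phi_V", "phi_A", "I_V",
                        "I_A", "trial", "rate")
      }
      out <- late
    }
    if ("early" %in% windows) {
      aud <- !is.na(pats$I_A) & pats$I_A > 0
      mu_early <- np$b + ifelse(aud, np$early_F *
                                  sigmoid(ifelse(aud, pats$I_A, 0),
                                          np$early_I50, np$early_n), 0)
      early <- sim_window(mu_early, w_early)
      early$window <- "early"
      out <- dplyr::bind_rows(out, early)
    }
    out$.rates <- NULL
    out$neuron_id <- np$neuron_id
    out$b <- np$b
    out$phi_eff_init <- np$phi_eff + if (init_jitter > 0)
      rnorm(1, 0, init_jitter) else 0
    dplyr::relocate(out, "neuron_id", "window")
  })
  tab <- validate_responses(tab)
  if (keep_trials) attr(tab, "trials") <- dplyr::bind_rows(trials_out)
  tab
}

#' Simulate receptive-field mapping grids
#'
#' Poisson counts on the visual flashed-spot grid (16 azimuths x 7
#' elevations, 10 degree spacing) from a 2D Gaussian rate surface, and on
#' the auditory virtual-speaker grid (17 azimuths x 5 elevations) from a
#' symmetric Kent rate surface; both surfaces are centered on each
#' neuron's true effective azimuth.
#'
#' @param gt An [make_population()] ground truth.
#' @param seed Seed.
#' @param visual_repeats,auditory_repeats Repeats per grid point.
#' @param visual_sigma True visual RF width (degrees).
#' @param auditory_kappa True Kent concentration.
#' @param amplitude,elevation Peak evoked rate (Hz) and RF elevation
#'   (degrees) shared by all neurons.
#' @param exposure_visual_s,exposure_auditory_s Collection windows (s).
#' @return A list of tibbles `visual` and `auditory` with columns
#'   `neuron_id`, `azimuth`, `elevation`, `count`.
#' @export
simulate_rf_grids <- function(gt, seed = 1, visual_repeats = 12,
                              auditory_repeats = 30, visual_sigma = 15,
                              auditory_kappa = 4, amplitude = 20,
                              elevation = 20, exposure_visual_s = 0.5,
                              exposure_auditory_s = 0.1) {
  stopifnot(inherits(gt, "msi_ground_truth"))
  set.seed(seed)
  vis_grid <- tidyr::expand_grid(azimuth = seq(-75, 75, by = 10),
                                 elevation = seq(-30, 30, by = 10))
  aud_grid <- tidyr::expand_grid(azimuth = seq(-144, 144, by = 18),
                                 elevation = seq(0, 80, by = 20))
  visual <- purrr::map_dfr(seq_len(nrow(gt$params)), function(i) {
    np <- gt$params[i, ]
    rate <- np$b + amplitude *
      exp(-((vis_grid$azimuth - np$phi_eff)^2 +
              (vis_grid$elevation - elevation)^2) / (2 * visual_sigma^2))
    tibble::tibble(neuron_id = np$neuron_id,
                   azimuth = vis_grid$azimuth, elevation = vis_grid$elevation,
                   count = rpois(nrow(vis_grid),
                                 rate * visual_repeats * exposure_visual_s))
  })
  auditory <- purrr::map_dfr(seq_len(nrow(gt$params)), function(i) {
    np <- gt$params[i, ]
    dirs <- .sph_to_unit(aud_grid$azimuth, aud_grid$elevation)
    c0 <- as.vector(.sph_to_unit(np$phi_eff, elevation))
    cosg <- pmin(pmax(drop(dirs %*% c0), -1), 1)
    rate <- np$b + amplitude * exp(auditory_kappa * (cosg - 1))
    tibble::tibble(neuron_id = np$neuron_id,
                   azimuth = aud_grid$azimuth, elevation = aud_grid$elevation,
                   count = rpois(nrow(aud_grid),
                                 rate * auditory_repeats * exposure_auditory_s))
  })
  list(visual = visual, auditory = auditory)
}
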