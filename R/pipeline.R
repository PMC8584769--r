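#' Run the full analysis pipeline on a dataset
#'
#' Simulates (or accepts) a response table, keeps the neurons with a
#' significant late-window unimodal response, fits the linear,
#' audition-modulated, and vision-modulated variants with a shared seed
#' stream, tests per-neuron modulation on the audition-modulated fit, and
#' assembles a comparison report.
#'
#' The responsiveness filter tests, for each neuron, the strongest
#' late-window unimodal response against the measured baseline under the
#' quasi-Poisson null ([responsiveness_test()]), Bonferroni-corrected
#' over the unimodal patterns, at p < 0.001.
#'
#' @param data A response table (from [simulate_trials()] or
#'   [read_responses()]); must carry `b`. If `NULL`, a population is
#'   simulated from `scenario`.
#' @param scenario,n_neurons,n_trials Simulation settings used when
#'   `data` is `NULL`.
#' @param grid The stimulus design.
#' @param config An [msi_config()].
#' @param n_restarts Restarts per modulated variant.
#' @param seed Master seed (simulation and all fits derive from it).
#' @param variants Model variants to fit.
#' @param out_dir Optional directory; when given, writes `responses.csv`,
#'   `params_<variant>.json`, `deviance.csv`, `significance.csv`, and
#'   `delta_grid.csv` there.
#' @return An object of class `msi_comparison`: `fits` (named list of
#'   `msi_fit`), `deviance` (per-variant summary tibble),
#'   `classification` (per-neuron, mutually exclusive labels),
#'   `delta_grid` (modulation-function evaluation grid), `n_dropped`
#'   (non-responsive neurons removed).
#' @export
run_pipeline <- function(data = NULL, scenario = "AM", n_neurons = 20,
                         n_trials = 30, grid = stimulus_grid(),
                         config = msi_config(), n_restarts = 3, seed = 1,
                         variants = c("L", "AM", "VM"), out_dir = NULL) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, length(variants) + 1)
  if (is.null(data)) {
    gt <- make_population(n_neurons, scenario, seed = seeds[1], grid = grid)
    data <- simulate_trials(gt, grid, n_trials = n_trials, seed = seeds[1])
  }
  keep <- responsive_neurons(data, grid)
  n_dropped <- length(unique(data$neuron_id)) - length(keep)
  if (length(keep) == 0) {
    abort("no neuron passes the late-window responsiveness filter; nothing to fit.")
  }
  data_f <- dplyr::filter(data, .data$neuron_id %in% keep)

  fits <- purrr::imap(setNames(as.list(variants), variants), function(v, nm) {
    i <- which(variants == v)
    fit <- multi_restart(data_f, v, config, n_restarts, seed = seeds[i + 1])
    if (v != "L") fit <- estimate_errors(fit, data_f)
    fit
  })
  devs <- purrr::map_dfr(fits, function(f)
    tibble::tibble(variant = f$variant, D = f$deviance$D, df = f$deviance$df,
                   d_per_df = f$deviance$d_per_df,
                   outlier_deviance = f$deviance$outlier_deviance,
                   nll = f$nll, converged = f$converged))

  classification <- NULL
  sig <- NULL
  if ("AM" %in% variants) {
    sig <- test_modulation_significance(fits$AM, grid)
    classification <- sig |>
      dplyr::mutate(class = dplyr::case_when(
        !.data$alpha_significant ~ "linear",
        .data$direction == "superlinear" ~ "superlinear",
        .data$direction == "sublinear" ~ "sublinear",
        TRUE ~ "modulated"
      )) |>
      dplyr::select("neuron_id", "class", "alpha", "alpha_p",
                    "max_modcoef", "min_modcoef")
  }
  delta_grid <- NULL
  if (!is.null(fits$AM) && !is.null(fits$AM$global)) {
    delta_grid <- evaluate_delta_grid(fits$AM$global, grid)
  }
  report <- structure(
    list(fits = fits, deviance = devs, classification = classification,
         significance = sig, delta_grid = delta_grid, n_dropped = n_dropped,
         seed = seed, grid = grid),
    class = "msi_comparison"
  )
  if (!is.null(out_dir)) write_report(report, data_f, out_dir)
  report
}

#' Neurons with a significant late-window unimodal response
#'
#' @param data Response table with `b` column.
#' @param grid Stimulus design.
#' @param p_threshold Per-neuron significance level (default 0.001),
#'   Bonferroni-corrected over the unimodal patterns tested.
#' @param window_s Late-window length in seconds.
#' @return Character vector of responsive neuron ids.
#' @export
responsive_neurons <- function(data, grid, p_threshold = 0.001,
                               window_s = 0.08) {
  uni <- late_responses(data)
  uni <- dplyr::filter(uni, xor(!is.na(.data$phi_V) & .data$I_V > 0,
                                !is.na(.data$phi_A) & .data$I_A > 0))
  n_tests <- dplyr::n_distinct(uni$phi_V, uni$phi_A, uni$I_V, uni$I_A)
  ids <- unique(data$neuron_id)
  keep <- vapply(ids, function(id) {
    d <- uni[uni$neuron_id == id, ]
    j <- which.max(d$R_obs)
    theta <- max(dispersion(d$R_obs[j], d$sigma_obs[j]), 1)
    count <- round(d$R_obs[j] * window_s * d$n_trials[j])
    p <- responsiveness_test(count, d$n_trials[j], window_s, d$b[1],
                             theta)$p_value
    p * n_tests < p_threshold
  }, logical(1))
  ids[keep]
}

#' Evaluate the fitted modulation function on a display grid
#'
#' @param global An `msi_global`.
#' @param grid Stimulus design (sets the intensity levels).
#' @param offsets Azimuthal offsets (degrees) between the stimulus and
#'   the effective RF azimuth.
#' @return A tibble `offset_deg`, `intensity`, `delta`.
#' @export
evaluate_delta_grid <- function(global, grid = stimulus_grid(),
                                offsets = seq(-90, 90, by = 10)) {
  lv <- grid$auditory_intensities[grid$auditory_intensities > 0]
  tidyr::expand_grid(offset_deg = offsets, intensity = lv) |>
    dplyr::mutate(delta = modulation_delta(.data$offset_deg, .data$intensity,
                                           phi_eff = 0, global = global))
}

write_report <- function(report, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_responses(data, file.path(out_dir, "responses.csv"))
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    write_params(f$params, f$global, f$variant,
                 file.path(out_dir, paste0("params_", nm, ".json")))
  }
  readr::write_csv(report$deviance, file.path(out_dir, "deviance.csv"),
                   progress = FALSE)
  if (!is.null(report$significance)) {
    readr::write_csv(report$significance,
                     file.path(out_dir, "significance.csv"), progress = FALSE)
  }
  if (!is.null(report$delta_grid)) {
    readr::write_csv(report$delta_grid,
                     file.path(out_dir, "delta_grid.csv"), progress = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.msi_comparison <- function(x, ...) {
  cat("<msi_comparison>\n")
  print(as.data.frame(x$deviance), row.names = FALSE)
  if (!is.null(x$classification)) {
    cat("neuron classes:\n")
    print(table(x$classification$class))
  }
  invisible(x)
}
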