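#' Read and write response tables
#'
#' Response tables are comma-separated, UTF-8, '.'-decimal files with a
#' header and one row per (neuron, non-redundant stimulus pattern, response
#' window). Required columns: `neuron_id`, `window` (`"early"` or
#' `"late"`), `phi_V`, `phi_A` (degrees, empty when the modality is
#' absent), `I_V` (fractional contrast), `I_A` (dB SPL), `R_obs` (Hz),
#' `sigma_obs` (Hz), `n_trials`. Optional per-neuron columns (`b`,
#' `phi_eff_init`, ...) are preserved. Writing then reading a table
#' reproduces it exactly for decimal-representable values.
#'
#' @param path File path.
#' @return `read_responses()` returns a validated tibble;
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_responses(tb)
}

#' @rdname read_responses
#' @param data A response tibble.
#' @export
write_responses <- function(data, path) {
  validate_responses(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a response table
#'
#' Checks the schema described in [read_responses()]; errors name the
#' offending column or row.
#'
#' @param data A data frame.
#' @return The data as a tibble, invisibly validated.
#' @export
validate_responses <- function(data) {
  required <- c("neuron_id", "window", "phi_V", "phi_A", "I_V", "I_A",
                "R_obs", "sigma_obs", "n_trials")
  miss <- setdiff(required, names(data))
  if (length(miss) > 0) {
    abort(paste0("response table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "scmsi_schema_error")
  }
  bad_window <- which(!data$window %in% c("early", "late"))
  if (length(bad_window) > 0) {
    abort(paste0("unknown window label '", data$window[bad_window[1]],
                 "' in row ", bad_window[1], "."), class = "scmsi_schema_error")
  }
  bad_rate <- which(data$R_obs < 0 | data$sigma_obs < 0)
  if (length(bad_rate) > 0) {
    abort(paste0("negative rate or SEM in row ", bad_rate[1], "."),
          class = "scmsi_schema_error")
  }
  bad_trials <- which(data$n_trials < 2)
  if (length(bad_trials) > 0) {
    abort(paste0("fewer than 2 trials in row ", bad_trials[1], "."),
          class = "scmsi_schema_error")
  }
  key <- paste(data$neuron_id, data$window, data$phi_V, data$phi_A,
               data$I_V, data$I_A)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("duplicate (neuron, pattern, window) row at row ", dup[1],
                 " (neuron ", data$neuron_id[dup[1]], ")."),
          class = "scmsi_duplicate_row")
  }
  tibble::as_tibble(data)
}

params_to_list <- function(params, global = NULL, variant = "AM") {
  neurons <- purrr::pmap(params, function(neuron_id, F_V, F_A, I_V50, n_V,
                                          I_A50, n_A, alpha, phi_eff, b, ...) {
    list(id = neuron_id,
         F_V = as.list(F_V), F_A = as.list(F_A),
         I_V50 = I_V50, n_V = n_V, I_A50 = I_A50, n_A = n_A,
         alpha = alpha, phi_eff = phi_eff, b = b)
  })
  out <- list(neurons = neurons, variant = variant)
  if (!is.null(global)) {
    out$global <- list(exc = global$exc, inh = global$inh)
  }
  out
}

#' Read and write model parameters as JSON
#'
#' Serializes a per-neuron parameter table plus the shared modulation
#' function to the schema `{neurons: [{id, F_V: {azimuth: Hz}, F_A: {...},
#' I_V50, n_V, I_A50, n_A, alpha, phi_eff, b}], global: {exc: {A, sigma,
#' I50, n}, inh: {...}}, variant}`.
#'
#' @param params A tibble of [neuron_params()] rows.
#' @param global An [global_modulation()] object or `NULL`.
#' @param variant Model variant label stored with the file.
#' @param path File path.
#' @return `read_params()` returns a list with elements `params` (tibble),
#'   `global` (`msi_global` or `NULL`), and `variant`.
#' @export
write_params <- function(params, global = NULL, variant = "AM", path) {
  jsonlite::write_json(params_to_list(params, global, variant), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$neurons)) {
    abort("parameter file has no `neurons` entry.", class = "scmsi_schema_error")
  }
  params <- purrr::map_dfr(x$neurons, function(np) {
    neuron_params(
      neuron_id = np$id,
      F_V = unlist(np$F_V), F_A = unlist(np$F_A),
      I_V50 = np$I_V50, n_V = np$n_V, I_A50 = np$I_A50, n_A = np$n_A,
      alpha = np$alpha %||% 1, phi_eff = np$phi_eff %||% 0, b = np$b
    )
  })
  global <- if (!is.null(x$global)) {
    global_modulation(exc = unlist(x$global$exc), inh = unlist(x$global$inh))
  }
  list(params = params, global = global, variant = x$variant %||% "AM")
}

#' Read and write a stimulus design as JSON
#'
#' @param grid An [stimulus_grid()] object.
#' @param path File path.
#' @return `read_design()` returns an `msi_grid` rebuilt from the stored
#'   level vectors.
#' @export
write_design <- function(grid, path) {
  stopifnot(inherits(grid, "msi_grid"))
  jsonlite::write_json(
    grid[c("visual_intensities", "auditory_intensities",
           "visual_azimuths", "auditory_azimuths")],
    path, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_grid(x$visual_intensities, x$auditory_intensities,
                x$visual_azimuths, x$auditory_azimuths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
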