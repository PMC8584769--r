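#' Tidy a fitted multisensory model
#'
#' One row per free parameter: `neuron_id` (`NA` for the shared
#' modulation parameters), `term`, `estimate`, and, when
#' [estimate_errors()] has run, `std.error` and flags.
#'
#' @param x An `msi_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.msi_fit <- function(x, ...) {
  if (!is.null(x$param_errors)) return(x$param_errors)
  nt <- purrr::pmap_dfr(x$params, function(neuron_id, F_V, F_A, I_V50, n_V,
                                           I_A50, n_A, alpha, phi_eff, b, ...) {
    tibble::tibble(
      neuron_id = neuron_id,
      term = c(paste0("F_V_", names(F_V)), "I_V50", "n_V",
               paste0("F_A_", names(F_A)), "I_A50", "n_A",
               if (x$variant != "L") c("alpha", "phi_eff")),
      estimate = c(unname(F_V), I_V50, n_V, unname(F_A), I_A50, n_A,
                   if (x$variant != "L") c(alpha, phi_eff))
    )
  })
  if (is.null(x$global)) return(nt)
  g <- .g_to_vec(x$global)
  dplyr::bind_rows(nt, tibble::tibble(
    neuron_id = NA_character_,
    term = c("exc_A", "exc_sigma", "exc_I50", "exc_n",
             "inh_A", "inh_sigma", "inh_I50", "inh_n"),
    estimate = g
  ))
}

#' One-row fit summary
#'
#' @param x An `msi_fit`.
#' @param ... Unused.
#' @return A tibble with `variant`, `n_neurons`, `nll`, `deviance`, `df`,
#'   `d_per_df`, `outlier_deviance`, `gof_p`, `converged`, `n_restarts`.
#' @export
glance.msi_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, n_neurons = nrow(x$params), nll = x$nll,
    deviance = x$deviance$D, df = x$deviance$df,
    d_per_df = x$deviance$d_per_df,
    outlier_deviance = x$deviance$outlier_deviance,
    gof_p = x$deviance$gof_p, converged = x$converged,
    n_restarts = length(x$restart_nlls %||% 1)
  )
}

#' Tidy a deviance report
#'
#' @param x An `msi_deviance`.
#' @param ... Unused.
#' @return The per-neuron deviance tibble.
#' @export
tidy.msi_deviance <- function(x, ...) x$per_neuron

#' @export
glance.msi_deviance <- function(x, ...) {
  tibble::tibble(variant = x$variant, deviance = x$D, df = x$df,
                 d_per_df = x$d_per_df,
                 outlier_deviance = x$outlier_deviance, gof_p = x$gof_p)
}

#' Tidy a topographic-map fit
#'
#' @param x An `msi_topography`.
#' @param ... Unused.
#' @export
tidy.msi_topography <- function(x, ...) {
  tibble::tibble(term = c("slope", "offset"),
                 estimate = c(x$slope, x$offset),
                 std.error = c(x$slope_se, x$offset_se))
}

#' Plot the fitted modulation function
#'
#' Heat map of `delta(offset, intensity)`: positive regions (warm colors)
#' mark where multisensory enhancement is possible, negative regions
#' (cool) where suppression dominates.
#'
#' @param object An `msi_fit` with a fitted global modulation (or an
#'   `msi_global`).
#' @param grid Stimulus design for the intensity levels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msi_fit <- function(object, grid = stimulus_grid(), ...) {
  if (is.null(object$global)) {
    abort("the linear model has no modulation function to plot.")
  }
  plot_modulation(object$global, grid)
}

#' @rdname autoplot.msi_fit
#' @export
plot_modulation <- function(object, grid = stimulus_grid(), ...) {
  global <- if (inherits(object, "msi_fit")) object$global else object
  stopifnot(inherits(global, "msi_global"))
  dg <- evaluate_delta_grid(global, grid, offsets = seq(-90, 90, by = 5))
  ggplot2::ggplot(dg, ggplot2::aes(.data$offset_deg, factor(.data$intensity),
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "azimuthal offset from effective RF (deg)",
                  y = "auditory intensity (dB SPL)",
                  fill = expression(delta)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Deviance per degree of freedom of each fitted variant; the dashed line
#' at 1 marks a perfect fit under the quasi-Poisson likelihood.
#'
#' @param object An `msi_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msi_comparison <- function(object, ...) {
  ggplot2::ggplot(object$deviance,
                  ggplot2::aes(.data$variant, .data$d_per_df)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "model", y = "deviance / df") +
    ggplot2::theme_minimal()
}

#' Plot convergence traces
#'
#' @param fit An `msi_fit`.
#' @return A ggplot of NLL against alternation cycle, by phase.
#' @export
plot_trace <- function(fit) {
  stopifnot(inherits(fit, "msi_fit"))
  ggplot2::ggplot(fit$trace,
                  ggplot2::aes(.data$iteration, .data$nll,
                               colour = .data$phase)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "alternation cycle", y = "NLL (= D/2)") +
    ggplot2::theme_minimal()
}
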