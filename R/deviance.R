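#' Quasi-Poisson dispersion factor
#'
#' `theta = sigma_obs^2 / R_obs`, the per-pattern variance-to-mean scaling
#' of the trial firing rates, computed from the observed mean rate and its
#' standard error. When the observed rate or its SEM is zero the ratio is
#' undefined and is replaced by `floor` (Poisson dispersion by default).
#'
#' @param R_obs Observed mean firing rate (Hz); vectorized.
#' @param sigma_obs SEM of the firing rate (Hz); vectorized.
#' @param floor Value used where theta is undefined.
#' @return Numeric vector of dispersion factors.
#' @export
dispersion <- function(R_obs, sigma_obs, floor = 1) {
  stopifnot(all(R_obs >= 0), all(sigma_obs >= 0), floor > 0)
  theta <- ifelse(R_obs > 0 & sigma_obs > 0, sigma_obs^2 / R_obs, floor)
  theta
}

#' Per-pattern quasi-Poisson deviance term
#'
#' Twice the negative log-likelihood ratio against the saturated model for
#' one (neuron, pattern) cell:
#' `2 R_obs / theta * (R_model / R_obs - 1 - log(R_model / R_obs))`.
#' For `R_obs = 0` the continuous limit `2 R_model / theta` is used. The
#' term is non-negative and zero exactly when `R_model = R_obs`.
#'
#' @param R_obs Observed mean rate (Hz); vectorized.
#' @param R_model Model rate (Hz), positive; vectorized.
#' @param theta Dispersion factor, positive; vectorized.
#' @return Numeric vector of deviance contributions.
#' @export
deviance_term <- function(R_obs, R_model, theta) {
  if (any(R_model <= 0)) abort("`R_model` must be positive (apply the rate floor upstream).",
                               class = "scmsi_domain_error")
  if (any(theta <= 0)) abort("`theta` must be positive.", class = "scmsi_domain_error")
  n <- max(length(R_obs), length(R_model), length(theta))
  R_obs <- rep_len(R_obs, n); R_model <- rep_len(R_model, n)
  theta <- rep_len(theta, n)
  zero <- R_obs == 0
  out <- numeric(n)
  if (any(!zero)) {
    r <- R_model[!zero] / R_obs[!zero]
    out[!zero] <- 2 * R_obs[!zero] / theta[!zero] * (r - 1 - log(r))
  }
  out[zero] <- 2 * R_model[zero] / theta[zero]
  out
}

#' Model degrees of freedom
#'
#' With 168 non-redundant stimulus patterns per neuron, the modulated
#' models spend 12 individual parameters per neuron plus 8 global ones:
#' `df = 168 N - (12 N + 8) = 156 N - 8`. The linear model has no
#' modulation (10 individual parameters, no global): `df = 158 N`.
#'
#' @param n_neurons Number of modeled neurons (>= 1).
#' @param variant `"AM"`, `"VM"`, or `"L"`.
#' @param n_patterns Non-redundant patterns per neuron (168 for the
#'   default design).
#' @return Integer count.
#' @export
degrees_of_freedom <- function(n_neurons, variant = c("AM", "VM", "L"),
                               n_patterns = 168) {
  variant <- match.arg(variant)
  if (n_neurons < 1) abort("`n_neurons` must be at least 1.")
  if (variant == "L") n_neurons * (n_patterns - 10)
  else n_neurons * (n_patterns - 12) - 8
}

n_free_params <- function(n_neurons, variant) {
  if (variant == "L") 10L * n_neurons else 12L * n_neurons + 8L
}

#' Goodness-of-fit p-value from the deviance
#'
#' Uses the asymptotic chi-squared distribution of twice the negative
#' log-likelihood ratio (Wilks): upper-tail probability of
#' `chi^2(df)` at the observed deviance.
#'
#' @param D Total deviance (>= 0).
#' @param df Degrees of freedom (> 0).
#' @return Upper-tail probability.
#' @export
gof_pvalue <- function(D, df) {
  stopifnot(all(D >= 0), all(df > 0))
  pchisq(D, df, lower.tail = FALSE)
}

#' Total quasi-Poisson deviance of a dataset under the model
#'
#' Sums the per-pattern deviance over the non-redundant late-window
#' patterns of each neuron, then over neurons. Dispersion factors are
#' plug-in values from the observed table ([dispersion()]), never
#' re-estimated during fitting.
#'
#' @param data A response table (see [simulate_trials()] /
#'   [read_responses()]): one row per (neuron, pattern) with columns
#'   `neuron_id`, `phi_V`, `phi_A`, `I_V`, `I_A`, `R_obs`, `sigma_obs`,
#'   `b`; blank patterns and non-late windows are dropped.
#' @param params A tibble of [neuron_params()] rows (one per neuron).
#' @param global An [global_modulation()] object (ignored for `"L"`).
#' @param variant `"AM"`, `"VM"`, or `"L"`.
#' @param n_patterns Expected pattern count per neuron (checked; `NULL`
#'   skips the check).
#' @param floor Rate floor passed to [predict_rate()].
#' @return An object of class `msi_deviance`: list with `D`, `df`,
#'   `d_per_df`, `outlier_deviance` (`D/df - 1`), `gof_p`, and
#'   `per_neuron`, a tibble of per-neuron `D`, `df`, `d_per_df` (per-neuron
#'   df ignores the global parameters' fractional share: 168 - 12 for the
#'   modulated models, 168 - 10 for the linear model).
#' @export
total_deviance <- function(data, params, global = NULL,
                           variant = c("AM", "VM", "L"),
                           n_patterns = 168, floor = 1e-3) {
  variant <- match.arg(variant)
  data <- late_responses(data)
  ids <- unique(data$neuron_id)
  missing_p <- setdiff(ids, params$neuron_id)
  if (length(missing_p) > 0) {
    abort(paste0("no parameters for neuron(s): ",
                 paste(missing_p, collapse = ", ")))
  }
  if (!is.null(n_patterns)) {
    cnt <- dplyr::count(data, .data$neuron_id)
    bad <- dplyr::filter(cnt, .data$n != n_patterns)
    if (nrow(bad) > 0) {
      abort(paste0("neuron(s) without the full ", n_patterns,
                   " non-redundant late-window patterns: ",
                   paste(bad$neuron_id, "(", bad$n, ")", collapse = ", ")),
            class = "scmsi_missing_patterns")
    }
  }
  per <- purrr::map_dfr(ids, function(id) {
    d_n <- dplyr::filter(data, .data$neuron_id == id)
    np <- dplyr::filter(params, .data$neuron_id == id)
    pred <- predict_rate(d_n, np, global, variant, floor = floor)
    theta <- table_dispersion(d_n)
    D_i <- sum(deviance_term(d_n$R_obs, pred$R_model, theta))
    df_i <- nrow(d_n) - if (variant == "L") 10L else 12L
    tibble::tibble(neuron_id = id, D = D_i, df = df_i,
                   d_per_df = D_i / df_i)
  })
  D <- sum(per$D)
  df <- if (variant == "L") sum(per$df) else sum(per$df) - 8L
  structure(
    list(D = D, df = df, d_per_df = D / df, outlier_deviance = D / df - 1,
         gof_p = gof_pvalue(D, df), per_neuron = per, variant = variant),
    class = "msi_deviance"
  )
}

#' @export
print.msi_deviance <- function(x, ...) {
  cat(sprintf("<msi_deviance> %s model: D = %.4g on %d df (D/DF = %.4g, outlier deviance = %.4g)\n",
              x$variant, x$D, x$df, x$d_per_df, x$outlier_deviance))
  cat(sprintf("  goodness-of-fit p = %.3g over %d neurons\n",
              x$gof_p, nrow(x$per_neuron)))
  invisible(x)
}

# per-row dispersion: a known `theta` column (rate units) wins over the
# plug-in SEM ratio
table_dispersion <- function(data) {
  if ("theta" %in% names(data)) {
    stopifnot(all(data$theta > 0))
    data$theta
  } else {
    dispersion(data$R_obs, data$sigma_obs)
  }
}

# keep late-window, non-blank rows
late_responses <- function(data) {
  if ("window" %in% names(data)) {
    data <- dplyr::filter(data, .data$window == "late")
  }
  dplyr::filter(data, !(is.na(.data$phi_V) & is.na(.data$phi_A)) |
                  .data$I_V > 0 | .data$I_A > 0)
}
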