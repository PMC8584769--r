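#' Hill-type intensity sigmoid
#'
#' `S(I; I50, n) = I^n / (I50^n + I^n)`: fraction of the maximal evoked
#' rate at intensity `I`, with half-maximum at `I50` and slope exponent
#' `n`. `S(0) = 0` for `n > 0`; the function is monotone non-decreasing
#' in `I` and bounded in `[0, 1)`.
#'
#' @param I Intensity (same units as `I50`), non-negative; vectorized.
#' @param I50 Half-maximum intensity, positive.
#' @param n Hill exponent, non-negative.
#' @return Numeric vector of fractions.
#' @examples
#' sigmoid(40, I50 = 40, n = 4)  # 0.5
#' @export
sigmoid <- function(I, I50, n) {
  if (any(I < 0)) abort("intensity `I` must be non-negative.",
                        class = "scmsi_domain_error")
  if (I50 <= 0) abort("`I50` must be positive.", class = "scmsi_domain_error")
  if (n < 0) abort("Hill exponent `n` must be non-negative.",
                   class = "scmsi_domain_error")
  # work on the ratio to avoid overflow of I^n at large exponents
  r <- (I / I50)^n
  out <- r / (1 + r)
  out[is.infinite(r)] <- 1
  out
}

#' Unit-height Gaussian of azimuthal offset
#'
#' `G(x; sigma) = exp(-x^2 / (2 sigma^2))`: value 1 at zero offset,
#' `exp(-1/2)` at one width.
#'
#' @param x Offset in degrees; vectorized.
#' @param sigma Width in degrees, positive.
#' @return Numeric vector in `(0, 1]`.
#' @export
gaussian_unit <- function(x, sigma) {
  if (sigma <= 0) abort("`sigma` must be positive.",
                        class = "scmsi_domain_error")
  exp(-0.5 * (x / sigma)^2)
}

#' Construct one half (excitatory or inhibitory) of the modulation function
#'
#' @param A Relative amplitude (unitless, >= 0).
#' @param sigma Azimuthal width (degrees).
#' @param I50,n Intensity-sigmoid parameters of the half.
#' @return A named list.
#' @export
modulation_half <- function(A, sigma, I50, n) {
  stopifnot(A >= 0, sigma > 0, I50 > 0, n >= 0)
  list(A = A, sigma = sigma, I50 = I50, n = n)
}

#' Construct the dataset-global modulation function
#'
#' The modulation function is shared by every neuron in a dataset. Its value
#' `delta(phi, I) = A_Exc G(phi_eff - phi, sigma_Exc) S(I; I50_Exc, n_Exc) -
#' A_Inh G(phi_eff - phi, sigma_Inh) S(I; I50_Inh, n_Inh)` is the exponent
#' of the per-neuron modulation weight `alpha`; it carries 8 free
#' parameters (4 per half).
#'
#' @param exc,inh [modulation_half()] lists (or named vectors/lists with
#'   elements `A`, `sigma`, `I50`, `n`).
#' @return An object of class `msi_global`.
#' @export
global_modulation <- function(exc, inh) {
  as_half <- function(h) modulation_half(h[["A"]], h[["sigma"]], h[["I50"]], h[["n"]])
  structure(list(exc = as_half(exc), inh = as_half(inh)), class = "msi_global")
}

#' Default center-surround modulation function
#'
#' A narrow, low-threshold excitatory center (`A = 2`, `sigma = 25` deg,
#' `I50 = 25` dB, `n = 2`) and a broad, high-threshold inhibitory surround
#' (`A = 3`, `sigma = 60` deg, `I50 = 45` dB, `n = 4`). The resulting
#' `delta` is positive only near the effective receptive-field azimuth and
#' only at low sound levels (spatial matching), and turns negative
#' everywhere as the sound level grows (inverse effectiveness).
#'
#' @return An `msi_global` object.
#' @export
default_global <- function() {
  global_modulation(
    exc = modulation_half(A = 2, sigma = 25, I50 = 25, n = 2),
    inh = modulation_half(A = 3, sigma = 60, I50 = 45, n = 4)
  )
}

#' @export
print.msi_global <- function(x, ...) {
  cat("<msi_global> shared modulation function (8 parameters)\n")
  for (t in c("exc", "inh")) {
    h <- x[[t]]
    cat(sprintf("  %s: A = %.3g, sigma = %.3g deg, I50 = %.3g, n = %.3g\n",
                t, h$A, h$sigma, h$I50, h$n))
  }
  invisible(x)
}

#' Evaluate the modulation exponent delta
#'
#' Computes `delta = A_Exc * G(phi_eff - phi, sigma_Exc) * S(I; exc) -
#' A_Inh * G(phi_eff - phi, sigma_Inh) * S(I; inh)` for the modulating
#' stimulus at azimuth `phi` and intensity `I`. Under the
#' audition-modulated model the modulating stimulus is the auditory one;
#' under the vision-modulated model it is the visual one. When the
#' modulating stimulus is absent (`I == 0` or `phi` is `NA`) delta is 0.
#'
#' @param phi Stimulus azimuth (degrees); vectorized, `NA` = absent.
#' @param I Stimulus intensity; vectorized.
#' @param phi_eff Effective receptive-field azimuth of the neuron (degrees).
#' @param global An [global_modulation()] object.
#' @return Numeric vector of exponents (0 where the stimulus is absent).
#' @export
modulation_delta <- function(phi, I, phi_eff, global) {
  stopifnot(inherits(global, "msi_global"))
  n <- max(length(phi), length(I))
  phi <- rep_len(phi, n)
  I <- rep_len(I, n)
  absent <- is.na(phi) | is.na(I) | I == 0
  Iz <- ifelse(absent, 0, I)
  e <- global$exc
  i <- global$inh
  d <- e$A * gaussian_unit(phi_eff - ifelse(absent, phi_eff, phi), e$sigma) *
    sigmoid(Iz, e$I50, e$n) -
    i$A * gaussian_unit(phi_eff - ifelse(absent, phi_eff, phi), i$sigma) *
    sigmoid(Iz, i$I50, i$n)
  d[absent] <- 0
  d
}

#' Construct per-neuron model parameters
#'
#' A neuron carries 12 free parameters under the modulated models: three
#' maximal visually evoked rates `F_V` (one per visual stimulus location),
#' three maximal auditory evoked rates `F_A`, visual and auditory intensity
#' sigmoid pairs (`I_V50`, `n_V`, `I_A50`, `n_A`), the modulation weight
#' `alpha >= 1`, and the effective receptive-field azimuth `phi_eff`. The
#' baseline rate `b` is measured, not fitted. Under the linear model
#' `alpha` is pinned to 1 and `phi_eff` is irrelevant (10 free parameters).
#'
#' @param neuron_id Identifier.
#' @param F_V,F_A Named numeric vectors of maximal evoked rates (Hz); names
#'   are the stimulus azimuths in degrees.
#' @param I_V50,n_V,I_A50,n_A Sigmoid parameters per modality.
#' @param alpha Modulation weight (>= 1).
#' @param phi_eff Effective RF azimuth (degrees).
#' @param b Baseline firing rate (Hz), measured.
#' @return A one-row tibble with list-columns `F_V`, `F_A`.
#' @export
neuron_params <- function(neuron_id, F_V, F_A, I_V50, n_V, I_A50, n_A,
                          alpha = 1, phi_eff = 0, b = 0) {
  stopifnot(!is.null(names(F_V)), !is.null(names(F_A)),
            I_V50 > 0, I_A50 > 0, n_V >= 0, n_A >= 0, alpha > 0, b >= 0)
  tibble::tibble(
    neuron_id = as.character(neuron_id),
    F_V = list(F_V), F_A = list(F_A),
    I_V50 = I_V50, n_V = n_V, I_A50 = I_A50, n_A = n_A,
    alpha = alpha, phi_eff = phi_eff, b = b
  )
}

lookup_F <- function(Fmap, phi) {
  out <- rep(0, length(phi))
  present <- !is.na(phi)
  if (any(present)) {
    idx <- match(as.character(phi[present]), names(Fmap))
    if (anyNA(idx)) {
      abort(paste0("azimuth ", paste(unique(phi[present][is.na(idx)]), collapse = ", "),
                   " has no evoked-rate entry."), class = "scmsi_unknown_azimuth")
    }
    out[present] <- unname(Fmap[idx])
  }
  out
}

#' Predict late-window firing rates for stimulus patterns
#'
#' Implements the population model of visuoauditory responses:
#' `R = alpha^delta * (F_V(phi_V) S(I_V) + F_A(phi_A) S(I_A) + b)`.
#' An absent modality contributes nothing to the linear sum; under the
#' audition-modulated (`"AM"`) variant `delta` is evaluated at the auditory
#' stimulus, under the vision-modulated (`"VM"`) variant at the visual
#' stimulus, and under the linear (`"L"`) variant the modulation
#' coefficient is 1. Predicted rates are floored at a small positive
#' `floor` so the quasi-Poisson log-likelihood is defined even when
#' relaxed-phase bounds make the linear sum negative.
#'
#' @param pattern_data A data frame with columns `phi_V`, `phi_A`, `I_V`,
#'   `I_A` (e.g. [patterns()] of a grid).
#' @param neuron A one-row [neuron_params()] tibble (or equivalent list).
#' @param global An [global_modulation()] object (ignored for `"L"`).
#' @param variant `"AM"`, `"VM"`, or `"L"`.
#' @param floor Minimal predicted rate in Hz.
#' @return The input with columns `delta` and `R_model` appended.
#' @export
predict_rate <- function(pattern_data, neuron, global = NULL,
                         variant = c("AM", "VM", "L"), floor = 1e-3) {
  variant <- match.arg(variant)
  np <- as.list(neuron)
  if (is.data.frame(neuron)) {
    stopifnot(nrow(neuron) == 1)
    np <- purrr::map(np, ~ if (is.list(.x)) .x[[1]] else .x)
  }
  phi_V <- pattern_data$phi_V
  phi_A <- pattern_data$phi_A
  I_V <- pattern_data$I_V
  I_A <- pattern_data$I_A
  vis <- !is.na(I_V) & I_V > 0
  aud <- !is.na(I_A) & I_A > 0
  lin <- np$b +
    ifelse(vis, lookup_F(np$F_V, ifelse(vis, phi_V, NA)) *
             sigmoid(ifelse(vis, I_V, 0), np$I_V50, np$n_V), 0) +
    ifelse(aud, lookup_F(np$F_A, ifelse(aud, phi_A, NA)) *
             sigmoid(ifelse(aud, I_A, 0), np$I_A50, np$n_A), 0)
  delta <- rep(0, nrow(pattern_data))
  coef <- rep(1, nrow(pattern_data))
  if (variant != "L") {
    stopifnot(inherits(global, "msi_global"))
    delta <- switch(variant,
      AM = modulation_delta(phi_A, I_A, np$phi_eff, global),
      VM = modulation_delta(phi_V, I_V, np$phi_eff, global)
    )
    coef <- np$alpha^delta
  }
  dplyr::mutate(tibble::as_tibble(pattern_data),
                delta = delta,
                R_model = pmax(coef * lin, floor))
}
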