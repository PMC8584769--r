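#' Per-neuron modulation significance
#'
#' Classifies each neuron's nonlinearity from the fitted modulated model:
#' a one-sided Wald test of the modulation weight (`alpha > 1`), and
#' delta-method tests of the extreme modulation coefficients
#' `alpha^delta` over the bimodal stimulus grid. `max(alpha^delta)`
#' significantly above 1 marks superlinear addition, the extreme
#' coefficient significantly below 1 marks sublinear addition; a neuron
#' showing both (possible because `delta` changes sign over the grid) is
#' labeled by the larger absolute log-coefficient. All tests use the
#' Hessian-based parameter covariance ([estimate_errors()]).
#'
#' @param fit A fitted modulated `msi_fit` with `param_errors` attached.
#' @param grid The [stimulus_grid()] the data were collected on.
#' @param p_threshold Significance threshold (default 0.01).
#' @return A tibble with one row per neuron: `alpha`, `alpha_se`,
#'   `alpha_p`, `alpha_significant`, `max_modcoef`, `max_modcoef_p`,
#'   `min_modcoef`, `min_modcoef_p`, `modcoef_significant`, `direction`
#'   (`"superlinear"`, `"sublinear"`, or `"linear"`), and `skipped`
#'   (`TRUE` when errors were unavailable for the neuron).
#' @export
test_modulation_significance <- function(fit, grid, p_threshold = 0.01) {
  stopifnot(inherits(fit, "msi_fit"))
  if (fit$variant == "L") {
    abort("the linear model has no modulation to test; fit an AM or VM model.")
  }
  if (is.null(fit$param_errors)) {
    abort("parameter errors are required; run `estimate_errors()` first.")
  }
  bi <- dplyr::filter(patterns(grid), .data$type == "bimodal")
  phi_s <- if (fit$variant == "AM") bi$phi_A else bi$phi_V
  I_s <- if (fit$variant == "AM") bi$I_A else bi$I_V
  g <- .g_to_vec(fit$global)
  vc <- fit$vcov
  pe <- fit$param_errors

  purrr::map_dfr(fit$params$neuron_id, function(id) {
    np <- fit$params[fit$params$neuron_id == id, ]
    alpha <- np$alpha
    row_a <- paste(id, "alpha", sep = ":")
    at_bound_a <- pe$at_bound[match(row_a, paste(pe$neuron_id, pe$term, sep = ":"))]
    # Wald error of alpha conditional on the population-level modulation
    # function: the marginal error is infinite along the exact
    # amplitude/weight rescaling degeneracy, but whether THIS neuron is
    # nonlinear given the shared field is identified, so the test uses
    # the neuron-block Hessian
    se_a <- if (!is.null(fit$neuron_hessians)) {
      B <- fit$neuron_hessians[[id]]
      v <- tryCatch(solve(B)[11, 11], error = function(e) Inf)
      if (is.finite(v) && v > 0) sqrt(v) else Inf
    } else {
      pe$std.error[match(row_a, paste(pe$neuron_id, pe$term, sep = ":"))]
    }
    skipped <- !is.finite(se_a) && !isTRUE(at_bound_a)
    # one-sided Wald test of alpha > 1; a weight pinned at the lower bound
    # cannot be significant
    alpha_p <- if (alpha <= 1 + 1e-9 || !is.finite(se_a) || se_a == 0) 0.5
    else pnorm((alpha - 1) / se_a, lower.tail = FALSE)

    # modulation coefficient over the bimodal grid as a function of
    # (alpha, phi_eff, global): delta-method error of the extreme log values
    nms <- c(row_a, paste(id, "phi_eff", sep = ":"),
             paste(NA, c("exc_A", "exc_sigma", "exc_I50", "exc_n",
                         "inh_A", "inh_sigma", "inh_I50", "inh_n"), sep = ":"))
    x0 <- c(alpha, np$phi_eff, g)
    logm_fun <- function(x, k) {
      gl <- .vec_to_g(x[3:10])
      d <- modulation_delta(phi_s[k], I_s[k], x[2], gl)
      d * log(x[1])
    }
    d_all <- modulation_delta(phi_s, I_s, np$phi_eff, fit$global)
    logm_all <- d_all * log(alpha)
    k_max <- which.max(logm_all)
    k_min <- which.min(logm_all)
    sub_ok <- all(nms %in% rownames(vc))
    test_extreme <- function(k) {
      lm0 <- logm_all[k]
      if (!sub_ok || alpha <= 1 + 1e-9) {
        return(list(m = exp(lm0), p = if (alpha <= 1 + 1e-9) 1 else NA_real_))
      }
      gr <- vapply(seq_along(x0), function(j) {
        h <- 1e-5 * (1 + abs(x0[j]))
        xp <- x0; xp[j] <- x0[j] + h
        xm <- x0; xm[j] <- x0[j] - h
        (logm_fun(xp, k) - logm_fun(xm, k)) / (2 * h)
      }, numeric(1))
      vsub <- vc[nms, nms]
      v <- drop(t(gr) %*% vsub %*% gr)
      if (!is.finite(v) || v < 0) return(list(m = exp(lm0), p = NA_real_))
      z <- lm0 / sqrt(max(v, 1e-300))
      list(m = exp(lm0), p = 2 * pnorm(-abs(z)))
    }
    mx <- test_extreme(k_max)
    mn <- test_extreme(k_min)

    sup <- isTRUE(mx$p < p_threshold) && mx$m > 1
    sub <- isTRUE(mn$p < p_threshold) && mn$m < 1
    direction <- if (sup && sub) {
      if (abs(log(mx$m)) >= abs(log(mn$m))) "superlinear" else "sublinear"
    } else if (sup) "superlinear" else if (sub) "sublinear" else "linear"

    tibble::tibble(
      neuron_id = id, alpha = alpha, alpha_se = se_a, alpha_p = alpha_p,
      alpha_significant = alpha_p < p_threshold,
      max_modcoef = mx$m, max_modcoef_p = mx$p,
      min_modcoef = mn$m, min_modcoef_p = mn$p,
      modcoef_significant = sup || sub,
      direction = direction, skipped = skipped
    )
  })
}
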