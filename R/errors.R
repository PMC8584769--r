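#' Finite-difference Hessian
#'
#' Central-difference Hessian of a scalar function; used for curvature
#' based error estimates of the fitted negative log-likelihood.
#'
#' @param f Scalar function of a numeric vector.
#' @param x Point of evaluation.
#' @param h Step sizes (scalar or vector; default scales with `|x|`).
#' @return A symmetric numeric matrix.
#' @export
fd_hessian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- 1e-4 * (1 + abs(x))
  h <- rep_len(h, n)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (j in seq_len(n)) {
    ej <- numeric(n); ej[j] <- h[j]
    H[j, j] <- (f(x + ej) - 2 * f0 + f(x - ej)) / h[j]^2
    if (j < n) for (k in (j + 1):n) {
      ek <- numeric(n); ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) + f(x - ej - ek)) /
        (4 * h[j] * h[k])
    }
  }
  H
}

.free_term_names <- function(prep, variant) {
  nt <- c(paste0("F_V_", prep$vis_az), "I_V50", "n_V",
          paste0("F_A_", prep$aud_az), "I_A50", "n_A")
  if (variant != "L") nt <- c(nt, "alpha", "phi_eff")
  gt <- c("exc_A", "exc_sigma", "exc_I50", "exc_n",
          "inh_A", "inh_sigma", "inh_I50", "inh_n")
  list(neuron = nt, global = if (variant == "L") character(0) else gt)
}

#' Hessian-based parameter errors
#'
#' Estimates symmetric 1-sigma errors of every free parameter from the
#' finite-difference Hessian of the negative log-likelihood (`NLL = D/2`)
#' at the optimum. The Hessian is assembled blockwise: each neuron's
#' deviance yields its own 12x12 (10x10 for the linear model) block and
#' its cross-block with the 8 global parameters; the global block sums
#' over neurons. Errors are the square roots of the diagonal of the
#' (pseudo-)inverse. Directions with non-positive curvature are flagged
#' and their parameters get infinite errors; parameters sitting on an
#' active box bound are flagged `at_bound`.
#'
#' @param fit An `msi_fit`.
#' @param data The response table the fit was computed on.
#' @return The fit with `param_errors` (a tidy tibble: `neuron_id`,
#'   `term`, `estimate`, `std.error`, `at_bound`, `flagged`) and `vcov`
#'   attached.
#' @export
estimate_errors <- function(fit, data) {
  stopifnot(inherits(fit, "msi_fit"))
  prep <- prep_fit_data(data)
  variant <- fit$variant
  floor <- fit$config$floor
  plist <- .params_to_p(fit$params, prep)
  g <- if (variant == "L") rep(0, 8) else .g_to_vec(fit$global)
  n_neuron_par <- if (variant == "L") prep$n_vis + prep$n_aud + 4 else
    prep$n_vis + prep$n_aud + 6
  n_g <- if (variant == "L") 0L else 8L
  N <- length(prep$neurons)
  n_free <- N * n_neuron_par + n_g
  H <- matrix(0, n_free, n_free)
  blocks <- vector("list", N)
  g_idx <- if (n_g > 0) N * n_neuron_par + seq_len(n_g) else integer(0)

  for (i in seq_len(N)) {
    nd <- prep$neurons[[i]]
    p <- plist[[i]]
    idx_i <- (i - 1) * n_neuron_par + seq_len(n_neuron_par)
    if (variant == "L") {
      f <- function(x) {
        q <- p; q[seq_len(n_neuron_par)] <- x
        .neuron_dev(nd, q, g, variant, prep$n_vis, floor) / 2
      }
      blocks[[i]] <- fd_hessian(f, p[seq_len(n_neuron_par)])
      H[idx_i, idx_i] <- blocks[[i]]
    } else {
      # joint block over (neuron params, global params) from this neuron's
      # deviance; the global-global part accumulates across neurons
      f <- function(x) {
        q <- x[seq_len(n_neuron_par)]
        gg <- x[n_neuron_par + seq_len(8)]
        .neuron_dev(nd, q, gg, variant, prep$n_vis, floor) / 2
      }
      Hi <- fd_hessian(f, c(p, g))
      blocks[[i]] <- Hi[seq_len(n_neuron_par), seq_len(n_neuron_par)]
      H[idx_i, idx_i] <- Hi[seq_len(n_neuron_par), seq_len(n_neuron_par)]
      H[idx_i, g_idx] <- Hi[seq_len(n_neuron_par), n_neuron_par + seq_len(8)]
      H[g_idx, idx_i] <- t(H[idx_i, g_idx])
      H[g_idx, g_idx] <- H[g_idx, g_idx] +
        Hi[n_neuron_par + seq_len(8), n_neuron_par + seq_len(8)]
    }
  }

  ev <- eigen(H, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-9
  bad <- ev$values < tol  # singular or negative-curvature directions
  inv_vals <- ifelse(bad, 0, 1 / pmax(ev$values, tol))
  vc <- ev$vectors %*% (inv_vals * t(ev$vectors))
  se <- sqrt(pmax(diag(vc), 0))
  # variance along flat / non-positive-definite directions is unbounded:
  # any parameter with appreciable loading there is unidentified (the
  # modulation scale itself is an exact flat direction of this model, so
  # infinite alpha / amplitude errors are expected, not a defect)
  if (any(bad)) {
    load <- rowSums(ev$vectors[, bad, drop = FALSE]^2)
    se[load > 1e-6] <- Inf
  }
  flagged <- !is.finite(se)

  nm <- .free_term_names(prep, variant)
  ids <- names(prep$neurons)
  terms <- c(unlist(lapply(ids, function(id) nm$neuron)), nm$global)
  owner <- c(rep(ids, each = n_neuron_par), rep(NA_character_, n_g))
  est <- c(unlist(lapply(plist, function(p) p[seq_len(n_neuron_par)])),
           if (n_g > 0) g)
  phase2 <- phase_bounds(2, prep$n_vis, prep$n_aud)
  lower <- c(rep(phase2$neuron_lower[seq_len(n_neuron_par)], N),
             if (n_g > 0) phase2$global_lower)
  upper <- c(rep(phase2$neuron_upper[seq_len(n_neuron_par)], N),
             if (n_g > 0) phase2$global_upper)
  at_bound <- abs(est - lower) < 1e-6 * pmax(1, abs(lower)) |
    abs(est - upper) < 1e-6 * pmax(1, abs(upper))

  rownames(vc) <- colnames(vc) <- paste(owner, terms, sep = ":")
  fit$param_errors <- tibble::tibble(
    neuron_id = owner, term = terms, estimate = est, std.error = se,
    at_bound = at_bound, flagged = flagged | at_bound
  )
  fit$vcov <- vc
  names(blocks) <- ids
  fit$neuron_hessians <- blocks
  fit$hessian_npd <- any(ev$values < 0)
  fit
}
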