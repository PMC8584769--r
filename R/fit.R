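#' Fitting configuration
#'
#' @param n_restarts Number of random restarts of the whole two-phase
#'   procedure; the restart minimizing the negative log-likelihood wins
#'   (ties within `1e-6` go to the lowest restart index).
#' @param tol Convergence tolerance on the negative log-likelihood
#'   (`NLL = D/2`) per outer alternation cycle.
#' @param max_outer Maximum alternation cycles per phase.
#' @param inner_cap Alternation cycles between refinement passes.
#' @param maxit_block Iteration cap of the bounded quasi-Newton optimizer
#'   within one block.
#' @param floor Rate floor (Hz) applied to model predictions before the
#'   log-likelihood.
#' @param profile Run the profile-likelihood refinement pass (sweeps each
#'   global parameter over a +-2 sigma grid with the others re-optimized,
#'   restarting the alternation whenever a better optimum is found)?
#' @param init_A Stabilizing initial value of the modulation amplitudes.
#' @return A list of class `msi_config`.
#' @export
msi_config <- function(n_restarts = 30, tol = 0.1, max_outer = 200,
                       inner_cap = 10, maxit_block = 60, floor = 1e-3,
                       profile = TRUE, init_A = 0.1) {
  structure(list(n_restarts = n_restarts, tol = tol, max_outer = max_outer,
                 inner_cap = inner_cap, maxit_block = maxit_block,
                 floor = floor, profile = profile, init_A = init_A),
            class = "msi_config")
}

# initial per-neuron parameters from the unimodal patterns only
.init_unisensory <- function(nd, prep, bounds, floor, maxit = 200) {
  n_vis <- prep$n_vis; n_aud <- prep$n_aud
  fit_modality <- function(pres_mask, idx, I, n_F, I50_rng, b) {
    rows <- which(pres_mask)
    flagged <- FALSE
    if (length(rows) == 0 || all(nd$Robs[rows] == 0)) {
      return(list(F = rep(0, n_F), I50 = exp(mean(log(I50_rng))), n = 2,
                  flagged = TRUE))
    }
    sub <- list(Robs = nd$Robs[rows], w = nd$w[rows], wz = nd$wz[rows],
                zero = nd$zero[rows])
    ii <- I[rows]; loc <- idx[rows]
    F0 <- vapply(seq_len(n_F), function(k) {
      r <- sub$Robs[loc == k]
      if (length(r) == 0) 0 else max(0, max(r) - b)
    }, numeric(1))
    start <- c(pmin(F0, 100), exp(mean(log(I50_rng))), 2)
    lower <- c(rep(0, n_F), I50_rng[1], 0)
    upper <- c(rep(100, n_F), I50_rng[2], 5)
    fn <- function(p) {
      R <- pmax(b + p[loc] * .sig(ii, p[n_F + 1], p[n_F + 2]), floor)
      .dev_sum(sub, R)
    }
    res <- .opt_block(start, fn, lower, upper, maxit)
    list(F = res$par[seq_len(n_F)], I50 = res$par[n_F + 1],
         n = res$par[n_F + 2], flagged = flagged)
  }
  vis_only <- nd$vnum > 0 & nd$anum == 0
  aud_only <- nd$anum > 0 & nd$vnum == 0
  v <- fit_modality(vis_only, nd$vidx, nd$iv, n_vis,
                    c(bounds$neuron_lower[n_vis + 1], bounds$neuron_upper[n_vis + 1]),
                    nd$b)
  a <- fit_modality(aud_only, nd$aidx, nd$ia, n_aud,
                    c(bounds$neuron_lower[n_vis + n_aud + 3],
                      bounds$neuron_upper[n_vis + n_aud + 3]),
                    nd$b)
  p <- c(v$F, v$I50, v$n, a$F, a$I50, a$n, 1.01, nd$phi_eff_init)
  attr(p, "flagged") <- v$flagged || a$flagged
  p
}

#' Initial unisensory parameter estimates for each neuron
#'
#' Fits each modality's maximal evoked rates and intensity sigmoid by
#' minimizing the quasi-Poisson deviance restricted to that modality's
#' unimodal patterns (no modulation term). `alpha` starts at its narrow-
#' phase lower bound and `phi_eff` at the supplied location-derived value
#' (`phi_eff_init` column of the table; for neurons without one, the
#' auditory azimuth of the largest auditory-only response). Neurons with
#' no unimodal response at all get minimal-response defaults and are
#' flagged in the `init_flagged` column.
#'
#' @param data A late-window response table with `b` (and ideally
#'   `phi_eff_init`) columns.
#' @param floor Rate floor (Hz).
#' @return A tibble of [neuron_params()] rows plus `init_flagged`.
#' @export
init_unisensory <- function(data, floor = 1e-3) {
  prep <- prep_fit_data(data)
  bounds <- phase_bounds(1, prep$n_vis, prep$n_aud)
  purrr::map_dfr(prep$neurons, function(nd) {
    p <- .init_unisensory(nd, prep, bounds, floor)
    out <- .p_to_params(p, nd, prep)
    out$init_flagged <- attr(p, "flagged")
    out
  })
}

.p_to_params <- function(p, nd, prep) {
  n_vis <- prep$n_vis; n_aud <- prep$n_aud
  neuron_params(
    neuron_id = nd$neuron_id,
    F_V = setNames(p[seq_len(n_vis)], prep$vis_az),
    F_A = setNames(p[n_vis + 2 + seq_len(n_aud)], prep$aud_az),
    I_V50 = p[n_vis + 1], n_V = p[n_vis + 2],
    I_A50 = p[n_vis + n_aud + 3], n_A = p[n_vis + n_aud + 4],
    alpha = p[length(p) - 1], phi_eff = p[length(p)], b = nd$b
  )
}

.params_to_p <- function(params, prep) {
  lapply(names(prep$neurons), function(id) {
    np <- params[params$neuron_id == id, ]
    c(unname(np$F_V[[1]][as.character(prep$vis_az)]), np$I_V50, np$n_V,
      unname(np$F_A[[1]][as.character(prep$aud_az)]), np$I_A50, np$n_A,
      np$alpha, np$phi_eff)
  })
}

.g_to_vec <- function(global) {
  with(global, c(exc$A, exc$sigma, exc$I50, exc$n,
                 inh$A, inh$sigma, inh$I50, inh$n))
}

.vec_to_g <- function(g) {
  global_modulation(exc = c(A = g[1], sigma = g[2], I50 = g[3], n = g[4]),
                    inh = c(A = g[5], sigma = g[6], I50 = g[7], n = g[8]))
}

# one phase of the alternating block-coordinate fit
.run_phase <- function(prep, plist, g, variant, phase, config, trace,
                       phase_label) {
  bounds <- phase_bounds(phase, prep$n_vis, prep$n_aud)
  floor <- config$floor
  nll <- .total_dev(prep, plist, g, variant, floor) / 2
  trace <- rbind(trace, data.frame(phase = phase_label, iteration = 0L,
                                   nll = nll))
  converged <- FALSE
  iter <- 0L
  if (variant == "L") {
    # neuron blocks are independent: one pass per phase suffices
    for (i in seq_along(plist)) {
      res <- .fit_neuron(prep$neurons[[i]], plist[[i]], g, variant, phase,
                         bounds, prep$n_vis, floor, config$maxit_block)
      plist[[i]] <- res$p
    }
    nll <- .total_dev(prep, plist, g, variant, floor) / 2
    trace <- rbind(trace, data.frame(phase = phase_label, iteration = 1L,
                                     nll = nll))
    return(list(plist = plist, g = g, nll = nll, trace = trace,
                converged = TRUE))
  }
  repeat {
    # alternate neuron and global refits until the NLL change drops below
    # tol (or the per-round cap, after which the refinement step takes over)
    inner <- 0L
    alt_converged <- FALSE
    repeat {
      iter <- iter + 1L; inner <- inner + 1L
      for (i in seq_along(plist)) {
        res <- .fit_neuron(prep$neurons[[i]], plist[[i]], g, variant, phase,
                           bounds, prep$n_vis, floor, config$maxit_block)
        plist[[i]] <- res$p
      }
      gres <- .fit_global(prep, plist, g, variant, bounds, floor,
                          maxit = config$maxit_block)
      g <- gres$g
      jres <- .fit_mod_joint(prep, plist, g, variant, phase, bounds, floor,
                             maxit = config$maxit_block)
      plist <- jres$plist
      g <- jres$g
      new_nll <- .total_dev(prep, plist, g, variant, floor) / 2
      trace <- rbind(trace, data.frame(phase = phase_label, iteration = iter,
                                       nll = new_nll))
      gain <- nll - new_nll
      nll <- new_nll
      if (gain < config$tol) { alt_converged <- TRUE; break }
      if (inner >= config$inner_cap || iter >= config$max_outer) break
    }
    if (iter >= config$max_outer) break
    # refinement: joint polish over all free parameters, then a profile
    # sweep of the global parameters; alternation resumes on any gain
    ref_start <- nll
    jp <- .fit_all_joint(prep, plist, g, variant, phase, bounds, floor,
                         maxit = 2000)
    if (jp$dev / 2 < nll - 1e-9) {
      plist <- jp$plist; g <- jp$g; nll <- jp$dev / 2
      trace <- rbind(trace, data.frame(phase = phase_label, iteration = iter,
                                       nll = nll))
    }
    if (config$profile) {
      prof <- .profile_global(prep, plist, g, variant, bounds, floor)
      if (prof$dev / 2 < nll - 1e-9) {
        g <- prof$g
        nll <- prof$dev / 2
        trace <- rbind(trace, data.frame(phase = phase_label,
                                         iteration = iter, nll = nll))
      }
    }
    if (alt_converged && ref_start - nll < config$tol) {
      converged <- TRUE
      break
    }
  }
  list(plist = plist, g = g, nll = nll, trace = trace, converged = converged)
}

#' Two-phase alternating maximum-likelihood fit
#'
#' Fits the chosen model variant to a late-window response table by
#' block-coordinate descent on the quasi-Poisson deviance: each neuron's
#' individual parameters are refit with the shared modulation function
#' frozen, then the 8 modulation parameters are refit with every neuron
#' frozen, and the two refits alternate until the negative log-likelihood
#' changes by less than the tolerance, followed by a profile-likelihood
#' refinement of the modulation parameters. Phase 1 uses narrow parameter
#' boxes with `phi_eff` pinned to its location-derived value; Phase 2
#' relaxes the boxes and frees `phi_eff`. The linear variant has no shared
#' parameters, so its neurons are fit independently.
#'
#' @param data Response table with per-neuron `b` (and `phi_eff_init`)
#'   columns; only late-window, non-blank rows enter the likelihood.
#' @param variant `"AM"`, `"VM"`, or `"L"`.
#' @param config An [msi_config()].
#' @param seed Integer seed for the random modulation initialization.
#' @return An object of class `msi_fit`: parameter tibble, `msi_global`,
#'   [total_deviance()] report, convergence trace, and flags.
#' @export
alternating_fit <- function(data, variant = c("AM", "VM", "L"),
                            config = msi_config(), seed = 1) {
  variant <- match.arg(variant)
  prep <- prep_fit_data(data)
  bounds1 <- phase_bounds(1, prep$n_vis, prep$n_aud)
  set.seed(seed)
  # random modulation start in the narrow boxes; amplitudes kept small to
  # stabilize the first neuron refits
  g <- runif(8, bounds1$global_lower, bounds1$global_upper)
  g[c(1, 5)] <- config$init_A
  plist <- lapply(prep$neurons, function(nd)
    .init_unisensory(nd, prep, bounds1, config$floor, config$maxit_block))
  init_flags <- vapply(plist, function(p) isTRUE(attr(p, "flagged")), logical(1))
  plist <- lapply(plist, as.numeric)
  trace <- NULL
  ph1 <- .run_phase(prep, plist, g, variant, 1, config, trace, "phase1")
  ph2 <- .run_phase(prep, ph1$plist, ph1$g, variant, 2, config, ph1$trace,
                    "phase2")
  params <- purrr::map_dfr(seq_along(prep$neurons), function(i)
    .p_to_params(ph2$plist[[i]], prep$neurons[[i]], prep))
  if (variant == "L") params$alpha <- 1
  global <- if (variant == "L") NULL else .vec_to_g(ph2$g)
  dev <- total_deviance(data, params, global, variant,
                        n_patterns = NULL, floor = config$floor)
  dev$df <- degrees_of_freedom(nrow(params), variant,
                               n_patterns = length(prep$neurons[[1]]$Robs))
  dev$d_per_df <- dev$D / dev$df
  dev$outlier_deviance <- dev$d_per_df - 1
  dev$gof_p <- gof_pvalue(dev$D, dev$df)
  structure(
    list(params = params, global = global, variant = variant,
         deviance = dev, nll = ph2$nll,
         trace = tibble::as_tibble(ph2$trace),
         converged = ph1$converged && ph2$converged,
         init_flagged = init_flags,
         restart_seed = seed, config = config),
    class = "msi_fit"
  )
}

#' Multi-restart fit
#'
#' Repeats [alternating_fit()] with independently drawn random initial
#' modulation parameters and keeps the restart with the smallest negative
#' log-likelihood (ties within 1e-6 resolved to the lowest restart index).
#'
#' @inheritParams alternating_fit
#' @param n_restarts Number of restarts (default from `config`).
#' @param seed Master seed; per-restart seeds are drawn from it.
#' @return The best `msi_fit`, with `restart_nlls` recording every
#'   restart's final NLL.
#' @export
multi_restart <- function(data, variant = c("AM", "VM", "L"),
                          config = msi_config(), n_restarts = NULL, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(n_restarts)) n_restarts <- config$n_restarts
  stopifnot(n_restarts >= 1)
  if (variant == "L") n_restarts <- 1L  # no random initialization to vary
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_restarts)
  fits <- lapply(seeds, function(s)
    alternating_fit(data, variant, config, seed = s))
  nlls <- vapply(fits, `[[`, numeric(1), "nll")
  best <- which(nlls <= min(nlls) + 1e-6)[1]
  fit <- fits[[best]]
  fit$restart_nlls <- nlls
  fit$restart_index <- best
  fit
}

#' Fit a multisensory integration model
#'
#' High-level entry point: multi-restart two-phase alternating fit,
#' followed (for the modulated variants) by Hessian-based parameter
#' errors.
#'
#' @inheritParams multi_restart
#' @param errors Estimate 1-sigma parameter errors from the Hessian?
#' @return An `msi_fit` (see [alternating_fit()]), with `param_errors`
#'   when `errors = TRUE`.
#' @export
fit_msi <- function(data, variant = c("AM", "VM", "L"),
                    n_restarts = 1, seed = 1, config = msi_config(),
                    errors = TRUE) {
  variant <- match.arg(variant)
  fit <- multi_restart(data, variant, config, n_restarts, seed)
  if (errors) fit <- estimate_errors(fit, data)
  fit
}

#' @export
print.msi_fit <- function(x, ...) {
  cat(sprintf("<msi_fit> %s model, %d neurons\n", x$variant, nrow(x$params)))
  cat(sprintf("  NLL = %.4g; D/DF = %.4g (df = %d); converged: %s\n",
              x$nll, x$deviance$d_per_df, x$deviance$df, x$converged))
  if (!is.null(x$restart_nlls)) {
    cat(sprintf("  restarts: %d (best index %d)\n",
                length(x$restart_nlls), x$restart_index))
  }
  invisible(x)
}
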