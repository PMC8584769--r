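# Internal fitting machinery: fast per-neuron data structures, analytic
# gradients, and block-coordinate objectives. All rates in Hz, azimuths in
# degrees. Canonical free-parameter order per neuron:
#   F_V (one per visual location), I_V50, n_V,
#   F_A (one per auditory location), I_A50, n_A, alpha, phi_eff
# Global order: A_exc, sigma_exc, I50_exc, n_exc, A_inh, sigma_inh,
#   I50_inh, n_inh.

.sig <- function(I, I50, n) {
  r <- (I / I50)^n
  out <- r / (1 + r)
  out[is.infinite(r)] <- 1
  out
}

# dS/dI50 and dS/dn given S (zero where I == 0)
.sig_dI50 <- function(S, I50, n) -n / I50 * S * (1 - S)
.sig_dn <- function(S, I, I50) {
  out <- S * (1 - S) * log(I / I50)
  out[I == 0] <- 0
  out
}

.gau <- function(x, s) exp(-0.5 * (x / s)^2)

# box bounds from the two fitting phases
phase_bounds <- function(phase, n_vis = 3, n_aud = 3) {
  stopifnot(phase %in% c(1, 2))
  if (phase == 1) {
    list(
      neuron_lower = c(rep(0, n_vis), 0.01, 0, rep(0, n_aud), 0.1, 0, 1.01, -Inf),
      neuron_upper = c(rep(100, n_vis), 1, 5, rep(100, n_aud), 100, 5, 30, Inf),
      global_lower = c(0, 18, 0.1, 0.1, 0, 18, 0.1, 0.1),
      global_upper = c(10, 100, 100, 5, 10, 100, 100, 5)
    )
  } else {
    list(
      neuron_lower = c(rep(-100, n_vis), 0.01, 0, rep(-100, n_aud), 0.1, 0, 1, -100),
      neuron_upper = c(rep(200, n_vis), 3, 30, rep(200, n_aud), 300, 30, 50, 150),
      global_lower = c(0, 18, 0.1, 0.1, 0, 18, 0.1, 0.1),
      global_upper = c(20, 100, 200, 5, 20, 100, 200, 5)
    )
  }
}

free_idx <- function(variant, phase, n_par) {
  if (variant == "L") seq_len(n_par - 2)
  else if (phase == 1) seq_len(n_par - 1)
  else seq_len(n_par)
}

# per-neuron flat arrays for the late-window likelihood
prep_fit_data <- function(data) {
  data <- late_responses(data)
  if (!"b" %in% names(data)) {
    abort("fitting needs a per-neuron baseline column `b` in the response table.")
  }
  vis_az <- sort(unique(data$phi_V[!is.na(data$phi_V)]))
  aud_az <- sort(unique(data$phi_A[!is.na(data$phi_A)]))
  ids <- unique(data$neuron_id)
  neurons <- lapply(ids, function(id) {
    d <- data[data$neuron_id == id, ]
    vpres <- !is.na(d$phi_V) & d$I_V > 0
    apres <- !is.na(d$phi_A) & d$I_A > 0
    vidx <- match(d$phi_V, vis_az); vidx[!vpres] <- 1L
    aidx <- match(d$phi_A, aud_az); aidx[!apres] <- 1L
    theta <- table_dispersion(d)
    phi_eff_init <- if ("phi_eff_init" %in% names(d)) d$phi_eff_init[1] else {
      au <- apres & !vpres
      if (any(au)) d$phi_A[au][which.max(d$R_obs[au])] else mean(aud_az)
    }
    list(
      neuron_id = id, b = d$b[1], phi_eff_init = phi_eff_init,
      Robs = d$R_obs, theta = theta,
      w = 2 * d$R_obs / theta, wz = 2 / theta, zero = d$R_obs == 0,
      iv = ifelse(vpres, d$I_V, 0), ia = ifelse(apres, d$I_A, 0),
      phiV = ifelse(vpres, d$phi_V, 0), phiA = ifelse(apres, d$phi_A, 0),
      vnum = as.numeric(vpres), anum = as.numeric(apres),
      vidx = vidx, aidx = aidx, n_vis = length(vis_az),
      M = {
        ivm <- ifelse(vpres, d$I_V, 0); iam <- ifelse(apres, d$I_A, 0)
        pvm <- ifelse(vpres, d$phi_V, 0); pam <- ifelse(apres, d$phi_A, 0)
        uiv <- sort(unique(ivm)); uia <- sort(unique(iam))
        uphiV <- sort(unique(pvm)); uphiA <- sort(unique(pam))
        M <- cbind(d$R_obs, theta, 2 * d$R_obs / theta, 2 / theta,
                   as.numeric(d$R_obs == 0), ivm, iam, pvm, pam,
                   as.numeric(vpres), as.numeric(apres),
                   as.numeric(vidx), as.numeric(aidx),
                   as.numeric(match(ivm, uiv)), as.numeric(match(iam, uia)),
                   as.numeric(match(pvm, uphiV)),
                   as.numeric(match(pam, uphiA)))
        attr(M, "uiv") <- uiv; attr(M, "uia") <- uia
        attr(M, "uphiV") <- uphiV; attr(M, "uphiA") <- uphiA
        M
      }
    )
  })
  names(neurons) <- ids
  list(neurons = neurons, vis_az = vis_az, aud_az = aud_az,
       n_vis = length(vis_az), n_aud = length(aud_az),
       Ms = lapply(neurons, `[[`, "M"),
       bs = vapply(neurons, `[[`, numeric(1), "b"))
}

# deviance contributions for a vector of model rates
.dev_sum <- function(nd, R) {
  z <- nd$zero
  r <- R[!z] / nd$Robs[!z]
  sum(nd$w[!z] * (r - 1 - log(r))) + sum(nd$wz[z] * R[z])
}

# d(deviance)/dR; equals 2/theta at R_obs = 0
.dev_dR <- function(nd, R) (2 / nd$theta) * (1 - nd$Robs / R)

# forward pass for one neuron: rates plus the pieces gradients reuse
.neuron_forward <- function(nd, p, g, variant, n_vis, floor) {
  Fv <- p[seq_len(n_vis)]
  IV50 <- p[n_vis + 1]; nV <- p[n_vis + 2]
  off <- n_vis + 2
  n_aud <- length(p) - off - 4
  Fa <- p[off + seq_len(n_aud)]
  IA50 <- p[off + n_aud + 1]; nA <- p[off + n_aud + 2]
  alpha <- p[length(p) - 1]; phi_eff <- p[length(p)]
  Sv <- .sig(nd$iv, IV50, nV) * nd$vnum
  Sa <- .sig(nd$ia, IA50, nA) * nd$anum
  lin <- nd$b + Fv[nd$vidx] * Sv + Fa[nd$aidx] * Sa
  if (variant == "L") {
    delta <- 0; coef <- 1
    mnum <- 0; dphi <- 0; Ge <- Gi <- Se <- Si <- 0
  } else {
    if (variant == "AM") { mphi <- nd$phiA; mI <- nd$ia; mnum <- nd$anum }
    else { mphi <- nd$phiV; mI <- nd$iv; mnum <- nd$vnum }
    dphi <- phi_eff - mphi
    Ge <- .gau(dphi, g[2]); Se <- .sig(mI, g[3], g[4])
    Gi <- .gau(dphi, g[6]); Si <- .sig(mI, g[7], g[8])
    delta <- (g[1] * Ge * Se - g[5] * Gi * Si) * mnum
    coef <- exp(delta * log(alpha))
  }
  Rraw <- coef * lin
  list(R = pmax(Rraw, floor), active = as.numeric(Rraw > floor),
       Sv = Sv, Sa = Sa, lin = lin, delta = delta, coef = coef, Rraw = Rraw,
       Fv = Fv, IV50 = IV50, nV = nV, Fa = Fa, IA50 = IA50, nA = nA,
       alpha = alpha, phi_eff = phi_eff, n_aud = n_aud,
       mnum = mnum, dphi = dphi, Ge = Ge, Gi = Gi, Se = Se, Si = Si)
}

.variant_code <- function(variant) match(variant, c("L", "AM", "VM")) - 1L

.neuron_dev <- function(nd, p, g, variant, n_vis, floor) {
  cpp_neuron_dev(nd$M, nd$b, n_vis, p, g, .variant_code(variant), floor)
}

# analytic gradient of the per-neuron deviance w.r.t. the full parameter
# vector (alpha / phi_eff entries unused under L)
.neuron_grad <- function(nd, p, g, variant, n_vis, floor,
                         want_global = FALSE) {
  cpp_neuron_grad(nd$M, nd$b, n_vis, p, g, .variant_code(variant), floor,
                  want_global)
}

# joint quasi-Newton polish over every free parameter (all neurons plus
# the shared modulation function); used as part of the refinement step to
# escape the slow zigzag valleys of plain block alternation
.fit_all_joint <- function(prep, plist, g, variant, phase, bounds, floor,
                           maxit = 150) {
  N <- length(plist)
  npar <- length(plist[[1]])
  idx <- free_idx(variant, phase, npar)
  k <- length(idx)
  has_g <- variant != "L"
  x0 <- c(unlist(lapply(plist, `[`, idx)), if (has_g) g)
  lower <- c(rep(bounds$neuron_lower[idx], N), if (has_g) bounds$global_lower)
  upper <- c(rep(bounds$neuron_upper[idx], N), if (has_g) bounds$global_upper)
  unpack <- function(x) {
    pl <- plist
    for (i in seq_len(N)) pl[[i]][idx] <- x[(i - 1) * k + seq_len(k)]
    list(plist = pl, g = if (has_g) x[N * k + seq_len(8)] else g)
  }
  vcode <- .variant_code(variant)
  sel <- c(unlist(lapply(seq_len(N) - 1L, function(i) i * npar + idx)),
           if (has_g) N * npar + seq_len(8))
  fn <- function(x) {
    u <- unpack(x)
    cpp_total_dev(prep$Ms, prep$bs, prep$n_vis, u$plist, u$g, vcode, floor)
  }
  gr <- function(x) {
    u <- unpack(x)
    cpp_total_grad(prep$Ms, prep$bs, prep$n_vis, u$plist, u$g, vcode,
                   floor)[sel]
  }
  res <- .opt_block(x0, fn, lower, upper, maxit, gr = gr,
                    scale = .box_scale(lower, upper))
  u <- unpack(res$par)
  list(plist = u$plist, g = u$g, dev = res$value)
}

.total_dev <- function(prep, plist, g, variant, floor) {
  cpp_total_dev(prep$Ms, prep$bs, prep$n_vis, plist, g,
                .variant_code(variant), floor)
}

# characteristic parameter scales from the box widths (for optim parscale)
.box_scale <- function(lower, upper) {
  s <- upper - lower
  s[!is.finite(s)] <- 250
  pmax(s, 1e-2)
}

# bounded quasi-Newton minimization that never accepts a worse point
.opt_block <- function(par, fn, lower, upper, maxit = 200, gr = NULL,
                       scale = NULL) {
  par <- pmin(pmax(par, lower), upper)
  f0 <- fn(par)
  ctrl <- list(maxit = maxit)
  if (!is.null(scale)) ctrl$parscale <- scale
  res <- tryCatch(
    optim(par, fn, gr = gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = ctrl),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value) || res$value > f0) {
    list(par = par, value = f0, improved = FALSE, failed = is.null(res))
  } else {
    list(par = res$par, value = res$value, improved = res$value < f0,
         failed = FALSE)
  }
}

# fit one neuron's free parameters with the global function frozen
.fit_neuron <- function(nd, p, g, variant, phase, bounds, n_vis, floor,
                        maxit = 200) {
  idx <- free_idx(variant, phase, length(p))
  fn <- function(x) {
    q <- p; q[idx] <- x
    .neuron_dev(nd, q, g, variant, n_vis, floor)
  }
  gr <- function(x) {
    q <- p; q[idx] <- x
    .neuron_grad(nd, q, g, variant, n_vis, floor)[idx]
  }
  res <- .opt_block(p[idx], fn, bounds$neuron_lower[idx],
                    bounds$neuron_upper[idx], maxit, gr = gr,
                    scale = .box_scale(bounds$neuron_lower[idx],
                                       bounds$neuron_upper[idx]))
  if (res$failed) warn(paste0("neuron ", nd$neuron_id,
                              ": block optimizer failed; keeping previous parameters."))
  p[idx] <- res$par
  list(p = p, dev = res$value)
}

# precompute what the global block needs: with individual parameters fixed
# only the modulation coefficient changes, so cache the linear sums
.prep_global <- function(prep, plist, variant, floor) {
  mods <- vector("list", length(prep$neurons))
  const_dev <- 0
  for (i in seq_along(prep$neurons)) {
    nd <- prep$neurons[[i]]
    p <- plist[[i]]
    fw <- .neuron_forward(nd, p, g = rep(1, 8), variant = "L",
                          n_vis = prep$n_vis, floor = floor)
    mod <- if (variant == "AM") nd$anum > 0 else nd$vnum > 0
    fixedR <- pmax(fw$lin[!mod], floor)
    sub <- list(Robs = nd$Robs[!mod], w = nd$w[!mod], wz = nd$wz[!mod],
                zero = nd$zero[!mod])
    const_dev <- const_dev + .dev_sum(sub, fixedR)
    mods[[i]] <- list(
      lin = fw$lin[mod],
      phi = if (variant == "AM") nd$phiA[mod] else nd$phiV[mod],
      I = if (variant == "AM") nd$ia[mod] else nd$iv[mod],
      la = log(p[length(p) - 1]), phi_eff = p[length(p)],
      Robs = nd$Robs[mod], w = nd$w[mod], wz = nd$wz[mod],
      theta = nd$theta[mod], zero = nd$zero[mod]
    )
  }
  list(
    lin = unlist(lapply(mods, `[[`, "lin")),
    dphi = unlist(lapply(mods, function(m) m$phi_eff - m$phi)),
    I = unlist(lapply(mods, `[[`, "I")),
    la = unlist(lapply(mods, function(m) rep(m$la, length(m$lin)))),
    Robs = unlist(lapply(mods, `[[`, "Robs")),
    w = unlist(lapply(mods, `[[`, "w")),
    wz = unlist(lapply(mods, `[[`, "wz")),
    theta = unlist(lapply(mods, `[[`, "theta")),
    zero = unlist(lapply(mods, `[[`, "zero")),
    const_dev = const_dev
  )
}

.global_forward <- function(gp, g, floor) {
  Ge <- .gau(gp$dphi, g[2]); Se <- .sig(gp$I, g[3], g[4])
  Gi <- .gau(gp$dphi, g[6]); Si <- .sig(gp$I, g[7], g[8])
  delta <- g[1] * Ge * Se - g[5] * Gi * Si
  Rraw <- exp(delta * gp$la) * gp$lin
  list(R = pmax(Rraw, floor), active = as.numeric(Rraw > floor),
       Rraw = Rraw, Ge = Ge, Se = Se, Gi = Gi, Si = Si)
}

.global_dev <- function(gp, g, floor) {
  fw <- .global_forward(gp, g, floor)
  z <- gp$zero
  r <- fw$R[!z] / gp$Robs[!z]
  gp$const_dev + sum(gp$w[!z] * (r - 1 - log(r))) + sum(gp$wz[z] * fw$R[z])
}

.global_grad <- function(gp, g, floor) {
  fw <- .global_forward(gp, g, floor)
  gR <- (2 / gp$theta) * (1 - gp$Robs / fw$R) * fw$active
  t0 <- gR * fw$Rraw * gp$la
  c(sum(t0 * fw$Ge * fw$Se),
    sum(t0 * g[1] * fw$Se * fw$Ge * (gp$dphi^2 / g[2]^3)),
    sum(t0 * g[1] * fw$Ge * .sig_dI50(fw$Se, g[3], g[4])),
    sum(t0 * g[1] * fw$Ge * .sig_dn(fw$Se, gp$I, g[3])),
    -sum(t0 * fw$Gi * fw$Si),
    -sum(t0 * g[5] * fw$Si * fw$Gi * (gp$dphi^2 / g[6]^3)),
    -sum(t0 * g[5] * fw$Gi * .sig_dI50(fw$Si, g[7], g[8])),
    -sum(t0 * g[5] * fw$Gi * .sig_dn(fw$Si, gp$I, g[7])))
}

# fit the 8 shared modulation parameters with every neuron frozen
.fit_global <- function(prep, plist, g, variant, bounds, floor, maxit = 300,
                        fixed = integer(0), gp = NULL) {
  if (is.null(gp)) gp <- .prep_global(prep, plist, variant, floor)
  idx <- setdiff(seq_along(g), fixed)
  fn <- function(x) {
    gg <- g; gg[idx] <- x
    .global_dev(gp, gg, floor)
  }
  gr <- function(x) {
    gg <- g; gg[idx] <- x
    .global_grad(gp, gg, floor)[idx]
  }
  res <- .opt_block(g[idx], fn, bounds$global_lower[idx],
                    bounds$global_upper[idx], maxit, gr = gr,
                    scale = .box_scale(bounds$global_lower[idx],
                                       bounds$global_upper[idx]))
  if (res$failed) warn("global block optimizer failed; keeping previous parameters.")
  g[idx] <- res$par
  list(g = g, dev = res$value)
}

# joint refit of the modulation block: the 8 global parameters together
# with every neuron's alpha (and, in phase 2, phi_eff). With the tuning
# parameters frozen the linear sums are fixed, so this is a cheap joint
# descent along the alpha <-> amplitude valley that plain alternation
# zigzags through. NLL can only decrease (same accept-if-better contract).
.fit_mod_joint <- function(prep, plist, g, variant, phase, bounds, floor,
                           maxit = 200) {
  N <- length(plist)
  gp <- .prep_global(prep, plist, variant, floor)
  n_row <- vapply(seq_len(N), function(i) {
    nd <- prep$neurons[[i]]
    sum(if (variant == "AM") nd$anum > 0 else nd$vnum > 0)
  }, numeric(1))
  ridx <- rep(seq_len(N), n_row)
  phi_mod <- gp$dphi  # phi_eff_i - phi at current phi_eff
  phi_stim <- unlist(lapply(seq_len(N), function(i) {
    nd <- prep$neurons[[i]]
    m <- if (variant == "AM") nd$anum > 0 else nd$vnum > 0
    if (variant == "AM") nd$phiA[m] else nd$phiV[m]
  }))
  npar <- length(plist[[1]])
  alpha0 <- vapply(plist, function(p) p[npar - 1], numeric(1))
  phi0 <- vapply(plist, function(p) p[npar], numeric(1))
  free_phi <- phase == 2
  unpack <- function(x) {
    list(g = x[1:8], alpha = x[8 + seq_len(N)],
         phi = if (free_phi) x[8 + N + seq_len(N)] else phi0)
  }
  forward <- function(u) {
    dphi <- u$phi[ridx] - phi_stim
    Ge <- .gau(dphi, u$g[2]); Se <- .sig(gp$I, u$g[3], u$g[4])
    Gi <- .gau(dphi, u$g[6]); Si <- .sig(gp$I, u$g[7], u$g[8])
    delta <- u$g[1] * Ge * Se - u$g[5] * Gi * Si
    la <- log(u$alpha)[ridx]
    Rraw <- exp(delta * la) * gp$lin
    list(R = pmax(Rraw, floor), active = as.numeric(Rraw > floor),
         Rraw = Rraw, delta = delta, la = la, dphi = dphi,
         Ge = Ge, Se = Se, Gi = Gi, Si = Si)
  }
  fn <- function(x) {
    fw <- forward(unpack(x))
    z <- gp$zero
    r <- fw$R[!z] / gp$Robs[!z]
    gp$const_dev + sum(gp$w[!z] * (r - 1 - log(r))) + sum(gp$wz[z] * fw$R[z])
  }
  gr <- function(x) {
    u <- unpack(x)
    fw <- forward(u)
    gR <- (2 / gp$theta) * (1 - gp$Robs / fw$R) * fw$active
    t0 <- gR * fw$Rraw * fw$la
    gg <- c(sum(t0 * fw$Ge * fw$Se),
            sum(t0 * u$g[1] * fw$Se * fw$Ge * (fw$dphi^2 / u$g[2]^3)),
            sum(t0 * u$g[1] * fw$Ge * .sig_dI50(fw$Se, u$g[3], u$g[4])),
            sum(t0 * u$g[1] * fw$Ge * .sig_dn(fw$Se, gp$I, u$g[3])),
            -sum(t0 * fw$Gi * fw$Si),
            -sum(t0 * u$g[5] * fw$Si * fw$Gi * (fw$dphi^2 / u$g[6]^3)),
            -sum(t0 * u$g[5] * fw$Gi * .sig_dI50(fw$Si, u$g[7], u$g[8])),
            -sum(t0 * u$g[5] * fw$Gi * .sig_dn(fw$Si, gp$I, u$g[7])))
    ga <- as.numeric(rowsum(gR * fw$Rraw * fw$delta, ridx,
                            reorder = TRUE)) / u$alpha
    out <- c(gg, ga)
    if (free_phi) {
      ddphi <- u$g[1] * fw$Se * fw$Ge * (-fw$dphi / u$g[2]^2) -
        u$g[5] * fw$Si * fw$Gi * (-fw$dphi / u$g[6]^2)
      out <- c(out, as.numeric(rowsum(t0 * ddphi, ridx, reorder = TRUE)))
    }
    out
  }
  ai <- npar - 1; pi_ <- npar
  x0 <- c(g, alpha0, if (free_phi) phi0)
  lower <- c(bounds$global_lower, rep(bounds$neuron_lower[ai], N),
             if (free_phi) rep(bounds$neuron_lower[pi_], N))
  upper <- c(bounds$global_upper, rep(bounds$neuron_upper[ai], N),
             if (free_phi) rep(bounds$neuron_upper[pi_], N))
  res <- .opt_block(x0, fn, lower, upper, maxit, gr = gr,
                    scale = .box_scale(lower, upper))
  u <- unpack(res$par)
  for (i in seq_len(N)) {
    plist[[i]][ai] <- u$alpha[i]
    if (free_phi) plist[[i]][pi_] <- u$phi[i]
  }
  list(plist = plist, g = u$g, dev = res$value)
}

# profile-likelihood refinement of the global parameters: sweep each
# parameter over +-2 sigma (5 points, Hessian-diagonal sigma) with the
# remaining global parameters re-optimized; return any improvement found
.profile_global <- function(prep, plist, g, variant, bounds, floor) {
  gp <- .prep_global(prep, plist, variant, floor)
  dev0 <- .global_dev(gp, g, floor)
  best <- list(g = g, dev = dev0)
  for (j in seq_along(g)) {
    h <- max(1e-3, 1e-2 * abs(g[j]))
    gj <- function(x) { gg <- g; gg[j] <- x; .global_dev(gp, gg, floor) }
    curv <- (gj(g[j] + h) - 2 * dev0 + gj(g[j] - h)) / h^2 / 2  # of NLL = D/2
    sig <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else
      (bounds$global_upper[j] - bounds$global_lower[j]) / 8
    sig <- min(sig, (bounds$global_upper[j] - bounds$global_lower[j]) / 4)
    for (s in c(-2, -1, 1, 2)) {
      val <- min(max(g[j] + s * sig, bounds$global_lower[j]),
                 bounds$global_upper[j])
      gg <- best$g; gg[j] <- val
      sub <- .fit_global(prep, plist, gg, variant, bounds, floor,
                         maxit = 50, fixed = j, gp = gp)
      if (sub$dev < best$dev - 1e-9) best <- list(g = sub$g, dev = sub$dev)
    }
  }
  best
}
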