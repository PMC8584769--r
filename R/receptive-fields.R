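#' Fit a visual receptive field (2D Gaussian, Poisson likelihood)
#'
#' Maximum-likelihood fit of `rate = baseline + amplitude *
#' exp(-((az-cx)^2 + (el-cy)^2) / (2 sigma^2))` to spike counts on a
#' flashed-spot grid (the standard mapping design is 16 azimuths x 7
#' elevations at 10 degree spacing, 12 repeats). Counts at each location
#' are modeled as Poisson with mean `rate * exposure_s * repeats`; errors
#' come from the inverse Hessian of the negative log-likelihood.
#'
#' @param grid_counts Data frame with columns `azimuth`, `elevation`
#'   (degrees) and `count` (summed spikes over repeats).
#' @param repeats Stimulus repeats per location.
#' @param exposure_s Response-collection window per presentation (s).
#' @return An object of class `msi_rf`: list with `modality = "visual"`,
#'   `center` (azimuth, elevation), `width` (sigma, degrees),
#'   `amplitude`, `baseline` (Hz), `errors`, `reliable` flag.
#' @export
fit_visual_rf <- function(grid_counts, repeats = 12, exposure_s = 0.5) {
  stopifnot(all(c("azimuth", "elevation", "count") %in% names(grid_counts)))
  az <- grid_counts$azimuth; el <- grid_counts$elevation
  y <- grid_counts$count
  expo <- repeats * exposure_s
  nll <- function(p) {
    mu <- pmax((p[1] + p[2] * exp(-((az - p[3])^2 + (el - p[4])^2) /
                                    (2 * p[5]^2))) * expo, 1e-9)
    sum(mu - y * log(mu))
  }
  b0 <- max(min(y) / expo, 0.01)
  amp0 <- max(max(y) / expo - b0, 0.1)
  start <- c(b0, amp0, az[which.max(y)], el[which.max(y)], 15)
  lower <- c(0, 0, min(az) - 30, min(el) - 30, 2)
  upper <- c(Inf, Inf, max(az) + 30, max(el) + 30, 180)
  res <- optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
               hessian = TRUE, control = list(maxit = 500))
  se <- .se_from_hessian(res$hessian)
  reliable <- is.finite(se[2]) && res$par[2] > 2 * se[2]
  structure(
    list(modality = "visual",
         center = c(azimuth = res$par[3], elevation = res$par[4]),
         width = res$par[5], amplitude = res$par[2], baseline = res$par[1],
         errors = c(baseline = se[1], amplitude = se[2], azimuth = se[3],
                    elevation = se[4], width = se[5]),
         reliable = reliable, nll = res$value),
    class = "msi_rf"
  )
}

#' Fit an auditory receptive field (symmetric Kent distribution)
#'
#' Directional tuning on the sphere is modeled as `rate = baseline +
#' amplitude * exp(kappa * (cos(gamma) - 1))` where `gamma` is the angle
#' between the stimulus direction and the RF center — the symmetric
#' (ovalness-free) special case of the Kent distribution, normalized to
#' unit peak. Counts are Poisson over the virtual-speaker grid (standard
#' design: 5 elevations x 17 azimuths = 85 directions). The reported
#' width is the angular radius at which the density drops to
#' `exp(-1/2)` of the peak: `acos(1 - 1/(2 kappa))`; a concentration too
#' small for that radius to exist (near-isotropic response) flags the fit.
#'
#' @param grid_counts Data frame with columns `azimuth`, `elevation`
#'   (degrees) and `count`.
#' @param repeats Repeats per direction.
#' @param exposure_s Response window per presentation (s).
#' @return An `msi_rf` with `modality = "auditory"` and `width` the
#'   1-sigma-equivalent angular radius in degrees.
#' @export
fit_auditory_rf <- function(grid_counts, repeats = 30, exposure_s = 0.1) {
  stopifnot(all(c("azimuth", "elevation", "count") %in% names(grid_counts)))
  y <- grid_counts$count
  expo <- repeats * exposure_s
  dirs <- .sph_to_unit(grid_counts$azimuth, grid_counts$elevation)
  nll <- function(p) {
    c0 <- as.vector(.sph_to_unit(p[3], p[4]))
    cosg <- pmin(pmax(drop(dirs %*% c0), -1), 1)
    mu <- pmax((p[1] + p[2] * exp(p[5] * (cosg - 1))) * expo, 1e-9)
    sum(mu - y * log(mu))
  }
  b0 <- max(min(y) / expo, 0.01)
  amp0 <- max(max(y) / expo - b0, 0.1)
  start <- c(b0, amp0, grid_counts$azimuth[which.max(y)],
             grid_counts$elevation[which.max(y)], 4)
  lower <- c(0, 0, -180, -10, 1e-3)
  upper <- c(Inf, Inf, 180, 90, 200)
  res <- optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
               hessian = TRUE, control = list(maxit = 500))
  kappa <- res$par[5]
  isotropic <- kappa <= 0.25  # e^{-1/2} radius undefined beyond 180 deg
  width <- if (isotropic) 180 else acos(1 - 1 / (2 * kappa)) * 180 / pi
  se <- .se_from_hessian(res$hessian)
  reliable <- !isotropic && is.finite(se[2]) && res$par[2] > 2 * se[2]
  structure(
    list(modality = "auditory",
         center = c(azimuth = res$par[3], elevation = res$par[4]),
         width = width, kappa = kappa, amplitude = res$par[2],
         baseline = res$par[1],
         errors = c(baseline = se[1], amplitude = se[2], azimuth = se[3],
                    elevation = se[4], kappa = se[5]),
         reliable = reliable, isotropic = isotropic, nll = res$value),
    class = "msi_rf"
  )
}

.sph_to_unit <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180; el <- el_deg * pi / 180
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

.se_from_hessian <- function(H) {
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc)) return(rep(Inf, nrow(H)))
  d <- diag(vc)
  ifelse(d > 0, sqrt(d), Inf)
}

#' @export
print.msi_rf <- function(x, ...) {
  cat(sprintf("<msi_rf> %s RF: center (%.1f, %.1f) deg, width %.1f deg%s\n",
              x$modality, x$center[1], x$center[2], x$width,
              if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Fit the topographic map of receptive-field azimuth
#'
#' Error-weighted linear regression of RF azimuth on anteroposterior
#' position in the superior colliculus: `azimuth = slope * AP + offset`.
#' The weights are the inverse variances of the per-neuron azimuth
#' estimates; slope and offset standard errors come from the weighted
#' normal equations (known measurement errors, no residual rescaling).
#'
#' @param data Data frame with columns `ap_mm` (anteroposterior position,
#'   mm), `azimuth` (degrees), `azimuth_se` (1-sigma error, degrees).
#' @return An object of class `msi_topography`: `slope` (deg/mm),
#'   `offset` (deg), `slope_se`, `offset_se`, `exact` flag (2-point
#'   interpolation), and the per-neuron table.
#' @export
fit_topography <- function(data) {
  stopifnot(all(c("ap_mm", "azimuth", "azimuth_se") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$azimuth_se))
  n <- nrow(data)
  if (n < 2) abort("need at least 2 neurons with finite azimuth errors.")
  if (length(unique(data$ap_mm)) < 2) {
    abort("degenerate anteroposterior spread: all positions identical.")
  }
  se <- data$azimuth_se
  se[se == 0] <- 1e-6  # exact inputs: numerically tiny errors
  w <- 1 / se^2
  X <- cbind(offset = 1, slope = data$ap_mm)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * data$azimuth))
  vc <- solve(XtWX)
  structure(
    list(slope = unname(beta["slope", 1]), offset = unname(beta["offset", 1]),
         slope_se = sqrt(vc["slope", "slope"]),
         offset_se = sqrt(vc["offset", "offset"]),
         exact = n == 2, n = n, data = tibble::as_tibble(data)),
    class = "msi_topography"
  )
}

#' @export
print.msi_topography <- function(x, ...) {
  cat(sprintf("<msi_topography> azimuth = (%.1f +- %.1f) deg/mm x AP + (%.1f +- %.1f) deg (n = %d)\n",
              x$slope, x$slope_se, x$offset, x$offset_se, x$n))
  invisible(x)
}

#' Azimuthal overlap of visual and auditory receptive fields
#'
#' Two RFs overlap when their 1-sigma azimuthal intervals
#' (`center +- width`) intersect.
#'
#' @param visual,auditory `msi_rf` objects.
#' @return A one-row tibble: `overlaps`, `larger_auditory`.
#' @export
rf_overlap <- function(visual, auditory) {
  stopifnot(inherits(visual, "msi_rf"), inherits(auditory, "msi_rf"))
  iv <- visual$center[["azimuth"]] + c(-1, 1) * visual$width
  ia <- auditory$center[["azimuth"]] + c(-1, 1) * auditory$width
  tibble::tibble(
    overlaps = iv[1] <= ia[2] && ia[1] <= iv[2],
    larger_auditory = auditory$width > visual$width
  )
}
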