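vis_grid <- tidyr::expand_grid(azimuth = seq(-75, 75, by = 10),
                               elevation = seq(-30, 30, by = 10))
aud_grid <- tidyr::expand_grid(azimuth = seq(-144, 144, by = 18),
                               elevation = seq(0, 80, by = 20))

test_that("the visual RF fit recovers a noiseless Gaussian bump", {
  rate <- 2 + 25 * exp(-((vis_grid$azimuth - 20)^2 +
                           (vis_grid$elevation - 10)^2) / (2 * 15^2))
  d <- data.frame(vis_grid, count = round(rate * 6))
  rf <- fit_visual_rf(d, repeats = 12, exposure_s = 0.5)
  expect_equal(nrow(d), 112)
  expect_equal(unname(rf$center["azimuth"]), 20, tolerance = 0.5)
  expect_equal(unname(rf$center["elevation"]), 10, tolerance = 0.5)
  expect_equal(rf$width, 15, tolerance = 0.5)
  expect_true(rf$reliable)
})

test_that("a flat visual response is flagged unreliable", {
  d <- data.frame(vis_grid, count = 12)
  rf <- fit_visual_rf(d)
  expect_false(rf$reliable)
  expect_lt(rf$amplitude, 1)
})

test_that("visual RF centers are recovered within 5 degrees RMSE under Poisson noise", {
  set.seed(91)
  errs <- replicate(40, {
    cx <- runif(1, -40, 40)
    rate <- 3 + 20 * exp(-((vis_grid$azimuth - cx)^2 +
                             vis_grid$elevation^2) / (2 * 15^2))
    d <- data.frame(vis_grid, count = rpois(nrow(vis_grid), rate * 6))
    fit_visual_rf(d)$center[["azimuth"]] - cx
  })
  expect_lt(sqrt(mean(errs^2)), 5)
})

test_that("the auditory Kent fit recovers center and radius", {
  kappa <- 4
  dirs <- scmsi:::.sph_to_unit(aud_grid$azimuth, aud_grid$elevation)
  c0 <- as.vector(scmsi:::.sph_to_unit(30, 20))
  rate <- 2 + 30 * exp(kappa * (drop(dirs %*% c0) - 1))
  d <- data.frame(aud_grid, count = round(rate * 3))
  expect_equal(nrow(d), 85)
  rf <- fit_auditory_rf(d, repeats = 30, exposure_s = 0.1)
  expect_equal(unname(rf$center["azimuth"]), 30, tolerance = 2)
  expect_equal(rf$kappa, kappa, tolerance = 0.2)
  expect_equal(rf$width, acos(1 - 1 / (2 * kappa)) * 180 / pi,
               tolerance = 2)
  expect_true(rf$reliable)
})

test_that("an isotropic auditory response collapses the concentration", {
  d <- data.frame(aud_grid, count = 30)
  rf <- fit_auditory_rf(d)
  expect_lt(rf$amplitude, 1)
  expect_false(rf$reliable)
})

test_that("topography fits are exact on noise-free collinear input", {
  ap <- seq(0.1, 1.5, length.out = 12)
  d <- data.frame(ap_mm = ap, azimuth = 77 * ap - 1.6, azimuth_se = 0)
  fit <- fit_topography(d)
  expect_equal(fit$slope, 77, tolerance = 1e-6)
  expect_equal(fit$offset, -1.6, tolerance = 1e-6)
  t2 <- fit_topography(d[1:2, ])
  expect_true(t2$exact)
  expect_error(fit_topography(data.frame(ap_mm = 1, azimuth = 1,
                                         azimuth_se = 1)), "2 neurons")
  expect_error(fit_topography(data.frame(ap_mm = c(1, 1), azimuth = 1:2,
                                         azimuth_se = c(1, 1))), "degenerate")
  expect_equal(tidy(fit)$estimate, c(77, -1.6), tolerance = 1e-6)
})

test_that("RF overlap follows one-sigma interval intersection", {
  mk <- function(center, width, modality = "visual") {
    structure(list(modality = modality,
                   center = c(azimuth = center, elevation = 0),
                   width = width, reliable = TRUE), class = "msi_rf")
  }
  expect_true(rf_overlap(mk(10, 15), mk(10, 15))$overlaps)
  expect_false(rf_overlap(mk(-50, 10), mk(50, 10))$overlaps)
  # centers 20 apart, widths 15 and 10: [5,35] meets [30,50]
  r <- rf_overlap(mk(20, 15), mk(40, 10))
  expect_true(r$overlaps)
  expect_false(r$larger_auditory)
})
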