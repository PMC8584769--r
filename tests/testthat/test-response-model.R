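test_that("the intensity sigmoid has its defining properties", {
  expect_equal(sigmoid(40, 40, 4), 0.5)
  expect_equal(sigmoid(40, 40, 0.3), 0.5)
  expect_equal(sigmoid(2 * 30, 30, 1), 2 / 3)
  # direct arithmetic oracle
  expect_equal(sigmoid(30, 40, 4), 30^4 / (40^4 + 30^4))
  expect_equal(sigmoid(0, 10, 2), 0)
  I <- seq(0, 100, by = 5)
  expect_true(all(diff(sigmoid(I, 35, 2.5)) >= 0))
  expect_true(all(sigmoid(I, 35, 2.5) >= 0 & sigmoid(I, 35, 2.5) < 1))
  expect_error(sigmoid(-1, 10, 2), class = "scmsi_domain_error")
  expect_error(sigmoid(1, -1, 2), class = "scmsi_domain_error")
})

test_that("the unit Gaussian is centered, symmetric and scaled by sigma", {
  expect_equal(gaussian_unit(0, 30), 1)
  expect_equal(gaussian_unit(30, 30), exp(-0.5))
  x <- runif(20, -90, 90)
  expect_equal(gaussian_unit(-x, 42), gaussian_unit(x, 42))
  expect_error(gaussian_unit(1, 0), class = "scmsi_domain_error")
})

test_that("the modulation exponent matches direct arithmetic", {
  gm <- global_modulation(
    exc = modulation_half(A = 2, sigma = 25, I50 = 25, n = 2),
    inh = modulation_half(A = 3, sigma = 60, I50 = 45, n = 4)
  )
  # neuron at phi_eff = 10 deg, auditory stimulus at 0 deg, 30 dB
  got <- modulation_delta(phi = 0, I = 30, phi_eff = 10, global = gm)
  want <- 2 * exp(-0.5 * (10 / 25)^2) * (30^2 / (25^2 + 30^2)) -
    3 * exp(-0.5 * (10 / 60)^2) * (30^4 / (45^4 + 30^4))
  expect_equal(got, want)
  # both amplitudes zero: no modulation anywhere
  gm0 <- global_modulation(exc = c(A = 0, sigma = 25, I50 = 25, n = 2),
                           inh = c(A = 0, sigma = 60, I50 = 45, n = 4))
  expect_equal(modulation_delta(runif(10, -60, 60), runif(10, 10, 60),
                                5, gm0), rep(0, 10))
  # absent stimulus: delta is 0 regardless of azimuth entries
  expect_equal(modulation_delta(c(NA, 20), c(30, 0), 0, gm), c(0, 0))
  # aligned, saturating intensity: delta approaches A_exc - A_inh
  expect_equal(modulation_delta(10, 1e9, 10, gm), 2 - 3, tolerance = 1e-6)
})

test_that("the default modulation is center-surround with inverse effectiveness", {
  gm <- default_global()
  offs <- seq(-80, 80, by = 20)
  low <- modulation_delta(offs, 20, 0, gm)
  high <- modulation_delta(offs, 50, 0, gm)
  expect_gt(low[offs == 0], 0)          # enhancement at the aligned center
  expect_lt(min(low), 0)                # suppressive surround
  expect_true(all(high < 0))            # strong sound: suppression everywhere
})

test_that("predict_rate equals an independently coded response equation", {
  set.seed(77)
  g <- stimulus_grid()
  pats <- patterns(g)
  gm <- default_global()
  for (variant in c("AM", "VM", "L")) {
    np <- neuron_params("x", F_V = setNames(runif(3, 5, 40), g$visual_azimuths),
                        F_A = setNames(runif(3, 5, 40), g$auditory_azimuths),
                        I_V50 = 0.4, n_V = 2, I_A50 = 35, n_A = 3,
                        alpha = 3, phi_eff = 25, b = 4)
    got <- predict_rate(pats, np, gm, variant)
    # plain-loop oracle
    want <- vapply(seq_len(nrow(pats)), function(j) {
      FV <- np$F_V[[1]]; FA <- np$F_A[[1]]
      sv <- if (!is.na(pats$phi_V[j]) && pats$I_V[j] > 0) {
        FV[[as.character(pats$phi_V[j])]] *
          pats$I_V[j]^2 / (0.4^2 + pats$I_V[j]^2)
      } else 0
      sa <- if (!is.na(pats$phi_A[j]) && pats$I_A[j] > 0) {
        FA[[as.character(pats$phi_A[j])]] *
          pats$I_A[j]^3 / (35^3 + pats$I_A[j]^3)
      } else 0
      lin <- sv + sa + 4
      if (variant == "L") return(max(lin, 1e-3))
      phi <- if (variant == "AM") pats$phi_A[j] else pats$phi_V[j]
      I <- if (variant == "AM") pats$I_A[j] else pats$I_V[j]
      del <- if (is.na(phi) || I == 0) 0 else {
        2 * exp(-0.5 * ((25 - phi) / 25)^2) * I^2 / (25^2 + I^2) -
          3 * exp(-0.5 * ((25 - phi) / 60)^2) * I^4 / (45^4 + I^4)
      }
      max(3^del * lin, 1e-3)
    }, numeric(1))
    expect_equal(got$R_model, want, tolerance = 1e-12)
  }
})

test_that("a blank pattern returns the baseline and alpha = 1 collapses variants", {
  g <- stimulus_grid()
  blank <- patterns(g, blank = TRUE)[patterns(g, blank = TRUE)$type == "blank", ]
  np <- neuron_params("x", F_V = setNames(c(10, 20, 30), g$visual_azimuths),
                      F_A = setNames(c(10, 20, 30), g$auditory_azimuths),
                      I_V50 = 0.4, n_V = 2, I_A50 = 35, n_A = 3,
                      alpha = 5, phi_eff = 30, b = 3.5)
  expect_equal(predict_rate(blank, np, default_global(), "AM")$R_model, 3.5)
  np1 <- np; np1$alpha <- 1
  pats <- patterns(g)
  r_am <- predict_rate(pats, np1, default_global(), "AM")$R_model
  r_vm <- predict_rate(pats, np1, default_global(), "VM")$R_model
  r_l <- predict_rate(pats, np1, NULL, "L")$R_model
  expect_equal(r_am, r_l)
  expect_equal(r_vm, r_l)
  # under AM, visual-only patterns carry no modulation
  vis_only <- pats$type == "visual"
  r_am5 <- predict_rate(pats, np, default_global(), "AM")$R_model
  expect_equal(r_am5[vis_only], r_l[vis_only])
  expect_error(predict_rate(data.frame(phi_V = 45, phi_A = NA, I_V = 0.5,
                                       I_A = 0), np, NULL, "L"),
               class = "scmsi_unknown_azimuth")
})
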