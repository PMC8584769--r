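# builds a minimal fitted object around chosen parameters so the Wald
# machinery can be exercised against hand-computed values
mock_fit <- function(alpha, se_alpha, phi_eff = 30, grid = stimulus_grid(),
                     global = default_global()) {
  params <- neuron_params("m1",
    F_V = setNames(c(10, 10, 10), grid$visual_azimuths),
    F_A = setNames(c(10, 10, 10), grid$auditory_azimuths),
    I_V50 = 0.4, n_V = 2, I_A50 = 30, n_A = 2,
    alpha = alpha, phi_eff = phi_eff, b = 2)
  terms <- c(paste0("F_V_", grid$visual_azimuths), "I_V50", "n_V",
             paste0("F_A_", grid$auditory_azimuths), "I_A50", "n_A",
             "alpha", "phi_eff")
  gterms <- c("exc_A", "exc_sigma", "exc_I50", "exc_n",
              "inh_A", "inh_sigma", "inh_I50", "inh_n")
  owner <- c(rep("m1", 12), rep(NA_character_, 8))
  all_terms <- c(terms, gterms)
  se <- c(rep(0.5, 10), se_alpha, 2, rep(1e-4, 8))
  vc <- diag(se^2)
  rownames(vc) <- colnames(vc) <- paste(owner, all_terms, sep = ":")
  structure(list(
    params = params, global = global, variant = "AM",
    param_errors = tibble::tibble(neuron_id = owner, term = all_terms,
                                  estimate = 0, std.error = se,
                                  at_bound = FALSE, flagged = FALSE),
    vcov = vc, config = msi_config()
  ), class = "msi_fit")
}

test_that("alpha at 1 yields unit modulation coefficients and no calls", {
  fit <- mock_fit(alpha = 1, se_alpha = 0.2)
  res <- test_modulation_significance(fit, stimulus_grid())
  expect_false(res$alpha_significant)
  expect_equal(res$max_modcoef, 1)
  expect_equal(res$min_modcoef, 1)
  expect_false(res$modcoef_significant)
  expect_equal(res$direction, "linear")
})

test_that("the Wald test on alpha matches the closed-form one-sided p", {
  fit <- mock_fit(alpha = 2.5, se_alpha = 0.4)
  res <- test_modulation_significance(fit, stimulus_grid())
  expect_equal(res$alpha_p, pnorm((2.5 - 1) / 0.4, lower.tail = FALSE))
  expect_true(res$alpha_significant)
})

test_that("the extreme modulation coefficients equal alpha to the extreme delta", {
  gm <- default_global()
  fit <- mock_fit(alpha = 4, se_alpha = 0.1, phi_eff = 30, global = gm)
  g <- stimulus_grid()
  res <- test_modulation_significance(fit, g)
  bi <- patterns(g)[patterns(g)$type == "bimodal", ]
  deltas <- modulation_delta(bi$phi_A, bi$I_A, 30, gm)
  expect_equal(res$max_modcoef, 4^max(deltas))
  expect_equal(res$min_modcoef, 4^min(deltas))
  # with tight errors both directions are significant; the label follows
  # the larger absolute log coefficient
  expect_true(res$modcoef_significant)
  expect_equal(res$direction,
               if (abs(log(res$max_modcoef)) >= abs(log(res$min_modcoef)))
                 "superlinear" else "sublinear")
})

test_that("the linear variant refuses the significance machinery", {
  fx <- fx_am5()
  fl <- alternating_fit(fx$data, "L", msi_config(), seed = 1)
  expect_error(test_modulation_significance(fl, stimulus_grid()), "linear")
  f_no_err <- fx$fit
  f_no_err$param_errors <- NULL
  expect_error(test_modulation_significance(f_no_err, stimulus_grid()),
               "estimate_errors")
})
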