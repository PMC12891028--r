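test_that("reconstructed targets encode the published operating points", {
  tg <- build_fit_targets()
  expect_equal(nrow(tg), 4 * 9)
  half <- tg |>
    dplyr::group_by(.data$sl_um, .data$phos) |>
    dplyr::summarise(
      pCa50 = approx(force_norm, pCa, xout = 0.5)$y, .groups = "drop")
  expect_equal(half$pCa50[half$sl_um == 1.9 & !half$phos], 5.56,
               tolerance = 0.01)
  expect_equal(half$pCa50[half$sl_um == 2.3 & half$phos], 5.76,
               tolerance = 0.01)
})

test_that("log-likelihood is zero at a perfect fit and rises with sigma", {
  geom <- default_geom
  pars <- calibrated_params()
  va <- model_variant("A")
  tg <- build_fit_targets()
  # make the data equal to the model's own predictions -> log-lik 0
  pred <- sarcphos:::predict_targets(geom, pars, va, tg)
  tg_self <- dplyr::mutate(tg, force_norm = pred$model)
  th <- c(phi_P = log10(pars$phi_P), k_force = log10(pars$k_force))
  expect_equal(log_likelihood(th, geom, pars, va, tg_self), 0,
               tolerance = 1e-9)

  # doubling sigma raises the log-likelihood of any misfit
  ll1 <- log_likelihood(th, geom, pars, va, tg)
  ll2 <- log_likelihood(th, geom, pars, va,
                        dplyr::mutate(tg, sigma = 2 * sigma))
  expect_gt(ll2, ll1)

  # out-of-bounds parameters are rejected
  expect_identical(log_likelihood(c(phi_P = log10(100), k_force = -2.3),
                                  geom, pars, va, tg), -Inf)
})

test_that("likelihood peaks at the generating parameters (grid-scan oracle)", {
  geom <- default_geom
  pars <- calibrated_params()
  pars$phi_P <- 5
  va <- model_variant("A")
  tg <- build_fit_targets(pCa_grid = seq(6.4, 4.9, by = -0.3))
  truth <- sarcphos:::predict_targets(geom, pars, va, tg)
  tg_true <- dplyr::mutate(tg, force_norm = truth$model)
  lls <- vapply(c(2, 3.5, 5, 7, 10), function(phi) {
    log_likelihood(c(phi_P = log10(phi), k_force = log10(pars$k_force)),
                   geom, pars, va, tg_true)
  }, numeric(1))
  expect_equal(which.max(lls), 3)
})

test_that("the ensemble sampler recovers an analytic Gaussian posterior", {
  mu <- 0.5; s <- 0.1
  lp <- function(th) -0.5 * ((th[["x"]] - mu) / s)^2
  fit <- run_ensemble_mcmc(lp, c(x = 0.3), n_walkers = 10, n_steps = 400,
                           seed = 3, burn_in = 100)
  draws <- log10(tidy(fit)$value)
  se <- sd(draws) / sqrt(50)  # generous: heavy chain autocorrelation
  expect_lt(abs(mean(draws) - mu), 3 * se + 0.02)
  expect_equal(sd(draws), s, tolerance = 0.25)

  # determinism: same seed, identical chains
  fit2 <- run_ensemble_mcmc(lp, c(x = 0.3), n_walkers = 10, n_steps = 400,
                            seed = 3, burn_in = 100)
  expect_identical(fit$chain, fit2$chain)

  # posterior width shrinks with smaller observation noise
  lp_tight <- function(th) -0.5 * ((th[["x"]] - mu) / (s / 4))^2
  fit3 <- run_ensemble_mcmc(lp_tight, c(x = 0.3), n_walkers = 10,
                            n_steps = 400, seed = 3, burn_in = 100)
  expect_lt(sd(log10(tidy(fit3)$value)), sd(draws))

  expect_error(run_ensemble_mcmc(lp, c(x = 0.3), n_walkers = 1), "walkers")
})

test_that("baseline calibration hits the requested operating points", {
  pars <- calibrated_params()
  fp19 <- force_pca_curve(default_geom, pars, model_variant("none"), "none",
                          1.9)
  fp23 <- force_pca_curve(default_geom, pars, model_variant("none"), "none",
                          2.3)
  expect_equal(fp19$fit$pCa50, 5.56, tolerance = 0.001)
  expect_equal(fp23$fit$pCa50, 5.64, tolerance = 0.001)

  # idempotence: recalibrating calibrated parameters is a no-op
  pars2 <- calibrate_baseline(default_geom, pars)
  expect_equal(pars2$a_kon, pars$a_kon, tolerance = 0.02)
  expect_equal(pars2$passive_gain, pars$passive_gain, tolerance = 0.05)

  # unreachable operating point: bracketing error
  expect_error(calibrate_baseline(default_geom, pCa50_short = 9),
               "unreachable|bracket")
})

test_that("a free phosphorylation factor is recovered from synthetic targets", {
  geom <- default_geom
  pars <- calibrated_params()
  gen <- pars; gen$phi_P <- 3
  va <- model_variant("A")
  tg <- build_fit_targets(pCa_grid = seq(6.4, 4.9, by = -0.3))
  truth <- sarcphos:::predict_targets(geom, gen, va, tg)
  tg_true <- dplyr::mutate(tg, force_norm = truth$model)
  lp <- function(theta) log_likelihood(theta, geom, pars, va, tg_true,
                                       bounds = list(phi_P = c(1, 40)))
  fit <- run_ensemble_mcmc(lp, c(phi_P = log10(4)), n_walkers = 8,
                           n_steps = 40, seed = 7, burn_in = 15)
  expect_equal(unname(fit$map[["phi_P"]]), 3, tolerance = 0.25)
})
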