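test_that("time course follows the closed-form two-population relaxation", {
  # kinase absent: nothing gets phosphorylated
  ps0 <- population_set(
    tibble::tibble(fraction = 1, k_P = 1, k_D = 0.1, p0 = 0),
    kinase_conc = 0, phosphatase_conc = 0.5
  )
  tc0 <- simulate_time_course(ps0, c(0, 5, 50))
  expect_equal(tc0$p_total, c(0, 0, 0))

  # single population, k_P[K] = 0.1 min^-1, no phosphatase: 1 - e^-1 at 10 min
  ps1 <- population_set(
    tibble::tibble(fraction = 1, k_P = 0.5, k_D = 0, p0 = 0),
    kinase_conc = 0.2, phosphatase_conc = 0, p_max = 1
  )
  tc1 <- simulate_time_course(ps1, c(0, 10))
  expect_equal(tc1$p_total[2], 1 - exp(-1), tolerance = 1e-12)

  # zero-rate population is flagged and held at p0
  ps_dead <- population_set(
    tibble::tibble(fraction = 1, k_P = 0, k_D = 0, p0 = 0.3),
    kinase_conc = 0, phosphatase_conc = 0, p_max = 1
  )
  tc_dead <- simulate_time_course(ps_dead, c(0, 100))
  expect_true(attr(tc_dead, "degenerate"))
  expect_equal(tc_dead$p_total, c(0.3, 0.3))
})

test_that("time course plateau matches the steady-state dose-response", {
  ps <- default_population_set(kinase_conc = 0.05, phosphatase_conc = 0.1)
  tc <- simulate_time_course(ps, c(0, 1e6))
  dr <- steady_state_dose_response(ps, c(0.01, 0.05, 1))
  expect_equal(tc$p_total[2], dr$p_total[2], tolerance = 1e-8)
})

test_that("dose-response has hyperbolic population components", {
  ps <- default_population_set(phosphatase_conc = 0.1)
  dr <- steady_state_dose_response(ps, c(1e-4, 0.01, 0.1, 1e3))
  # population at its EC50 sits at one half
  expect_equal(dr$p_fast[dr$K_uM == 0.01], 0.5, tolerance = 1e-12)
  expect_equal(dr$p_slow[dr$K_uM == 0.1], 0.5, tolerance = 1e-12)
  # K -> 0 vanishes, K -> infinity approaches p_max
  expect_lt(dr$p_total[1], 0.01)
  expect_equal(dr$p_total[4] / ps$p_max, 1, tolerance = 1e-3)
  expect_true(all(diff(dr$p_total) > 0))
  dr_hi <- steady_state_dose_response(ps, 0.1 * 1e4)
  expect_equal(dr_hi$p_total,
               ps$p_max * (1e3 / (1e3 + 0.01) * 31 / 49 +
                             1e3 / (1e3 + 0.1) * 18 / 49),
               tolerance = 1e-9)
})

test_that("biosensor readout is linear in phosphate transferred", {
  ps <- default_population_set()
  tc <- simulate_time_course(ps, seq(0, 60, by = 5))
  f1 <- biosensor_signal(tc, rlc_conc = 25, gain = 2)
  f2 <- biosensor_signal(tc, rlc_conc = 50, gain = 2)
  expect_equal(f2$fluorescence, 2 * f1$fluorescence)

  flat <- biosensor_signal(tibble::tibble(t_min = 0:10, p_total = 0),
                           background_rate = 0)
  expect_equal(flat$fluorescence, rep(0, 11))
})

test_that("biexponential fit recovers noiseless parameters exactly", {
  t <- seq(0, 200, by = 2)
  y <- 0.5 * (1 - exp(-0.2 * t)) + 0.5 * (1 - exp(-0.02 * t))
  fit <- fit_biexponential(t, y)
  expect_equal(fit$k1, 0.2, tolerance = 1e-6)
  expect_equal(fit$k2, 0.02, tolerance = 1e-6)
  expect_equal(fit$A1, 0.5, tolerance = 1e-6)
  expect_equal(fit$A2, 0.5, tolerance = 1e-6)
  expect_true(fit$prefers_biexp)

  # single-exponential input: second phase unsupported by the F-test
  y1 <- 0.8 * (1 - exp(-0.1 * t)) + rnorm(length(t), 0, 1e-4)
  fit1 <- suppressWarnings(fit_biexponential(t, y1))
  expect_true(min(fit1$A1, fit1$A2) < 0.05 || !fit1$prefers_biexp)
})

test_that("default fixture time course shows order-of-magnitude rate split", {
  ps <- default_population_set()
  tc <- simulate_time_course(ps, seq(0, 180, by = 2))
  fit <- fit_biexponential(tc$t_min, tc$p_total)
  expect_equal(fit$k1 / fit$k2, 10, tolerance = 1e-4)
})

test_that("isolated-RLC control is monophasic", {
  d <- generate_dataset("isolated_rlc", seed = 3)
  fit <- suppressWarnings(fit_biexponential(d$data$t_min, d$data$p_total))
  expect_false(fit$prefers_biexp && min(fit$A1, fit$A2) > 0.05)
  expect_equal(fit$k_app, 0.3 * 0.2, tolerance = 0.05)
})

test_that("biphasic fit recovers the default EC50 pair", {
  ps <- default_population_set(phosphatase_conc = 0.1)
  dr <- steady_state_dose_response(ps, 10^seq(-3, 1, length.out = 12))
  fit <- fit_biphasic(dr$K_uM, dr$p_total)
  expect_equal(fit$EC50_1, 0.01, tolerance = 1e-4)
  expect_equal(fit$EC50_2, 0.1, tolerance = 1e-4)

  # single population: second amplitude collapses
  ps1 <- population_set(
    tibble::tibble(fraction = 1, k_P = 1, k_D = 0.1, p0 = 0),
    phosphatase_conc = 0.1, p_max = 1
  )
  dr1 <- steady_state_dose_response(ps1, 10^seq(-3, 1, length.out = 12))
  fit1 <- suppressWarnings(fit_biphasic(dr1$K_uM, dr1$p_total))
  expect_lt(min(fit1$A1, fit1$A2), 0.05)
})

test_that("biphasic EC50s are recovered within 20% under 5% noise", {
  ps <- default_population_set(phosphatase_conc = 0.1)
  K <- 10^seq(-3, 1, length.out = 12)
  clean <- steady_state_dose_response(ps, K)$p_total
  set.seed(11)
  rec <- t(replicate(50, {
    y <- clean * (1 + rnorm(length(K), 0, 0.05))
    f <- tryCatch(suppressWarnings(fit_biphasic(K, y)),
                  error = function(e) NULL)
    if (is.null(f)) c(NA, NA) else c(f$EC50_1, f$EC50_2)
  }))
  med <- apply(rec, 2, median, na.rm = TRUE)
  expect_equal(med[1], 0.01, tolerance = 0.2)
  expect_equal(med[2], 0.1, tolerance = 0.2)
})

test_that("input validation catches malformed kinetics inputs", {
  expect_error(population_set(
    tibble::tibble(fraction = c(0.6, 0.6), k_P = 1, k_D = 1, p0 = 0)),
    "sum to 1")
  expect_error(fit_biexponential(1:4, 1:4), "6 points")
  expect_error(fit_biphasic(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1, 8)), "decades")
})
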