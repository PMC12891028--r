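test_that("head rates implement the mechanosensing and placement rules", {
  p <- sarcomere_params(phi_P = 3)

  # no filament load: phosphorylation has no effect on OFF->ON
  r0 <- head_rates("C", "blocked", F_sense = 0, thin_on = 1, params = p,
                   variant = model_variant("A"), phosphorylated = TRUE)
  expect_equal(r0$off_on, p$k1_0)

  f <- 100
  rA_b <- head_rates("C", "blocked", f, 1, params = p,
                     variant = model_variant("A"), phosphorylated = TRUE)
  rA_f <- head_rates("C", "free", f, 1, params = p,
                     variant = model_variant("A"), phosphorylated = TRUE)
  rA_d <- head_rates("D", "blocked", f, 1, params = p,
                     variant = model_variant("A"), phosphorylated = TRUE)
  rC_f <- head_rates("C", "free", f, 1, params = p,
                     variant = model_variant("C"), phosphorylated = TRUE)
  rB_d <- head_rates("D", "blocked", f, 1, params = p,
                     variant = model_variant("B"), phosphorylated = TRUE)
  base <- p$k1_0 * (1 + p$k_force * f)
  boost <- p$k1_0 * (1 + p$phi_P * p$k_force * f)
  expect_equal(rA_b$off_on, boost)   # Model A boosts C-zone blocked heads
  expect_equal(rA_f$off_on, base)    # ... but not free heads
  expect_equal(rA_d$off_on, base)    # ... and not D-zone heads
  expect_equal(rC_f$off_on, boost)   # Model C boosts both C-zone heads
  expect_equal(rB_d$off_on, boost)   # Model B boosts blocked heads everywhere

  # unphosphorylated or variant "none" reduces exactly to baseline
  r_un <- head_rates("C", "blocked", f, 1, params = p,
                     variant = model_variant("A"), phosphorylated = FALSE)
  r_no <- head_rates("C", "blocked", f, 1, params = p,
                     variant = model_variant("none"), phosphorylated = TRUE)
  expect_equal(r_un$off_on, base)
  expect_equal(r_no$off_on, base)
})

test_that("relaxing conditions produce no force and no attached heads", {
  prot <- sim_protocol(pCa = 9, duration = 1)
  sim <- mean_field_simulate(default_geom, sarcomere_params(),
                             model_variant("A"), "none", prot)
  last <- sim$trace[nrow(sim$trace), ]
  expect_lt(last$force_pN, 1)
  expect_lt(last$fg, 0.01)
})

test_that("with k_force = 0 the steady state matches the linear closed form", {
  # independent oracle: with constant k1 the 3-state chain and the
  # activation quadratic decouple from force
  p <- sarcomere_params(k_force = 0, a_hold = 0, passive_gain = 0)
  geom <- default_geom
  pCa <- 4.0
  Ca <- 10^(-pCa) * 1e6
  kap <- p$a_kon * Ca
  cc <- 2 * p$a_coop
  a <- max(Re(polyroot(c(kap, cc * kap - kap - p$a_koff, -cc * kap))))
  ra <- p$k3 * a / p$k4
  fg <- ra / (1 + p$k2 / p$k1_0 + ra)
  f_analytic <- p$f_head * total_heads(geom) * fg

  fp <- force_pca_curve(geom, p, model_variant("none"), "none", 1.9,
                        pCa_grid = c(6.5, 6.2, 6.0, 5.8, 5.6, pCa))  # last point = oracle pCa
  expect_equal(fp$points$force_pN[6], f_analytic, tolerance = 1e-6)

  # Monte-Carlo mean within 3 standard errors of the closed form
  fmc <- vapply(1:6, function(s) {
    prot <- sim_protocol(sarcomere_length = 1.9, pCa = pCa, duration = 2,
                         seed = s)
    tr <- run_simulation(geom, p, model_variant("none"), "none", prot)$trace
    mean(tr$force_pN[tr$t_s >= 1.5])
  }, numeric(1))
  se <- sd(fmc) / sqrt(length(fmc))
  expect_lt(abs(mean(fmc) - f_analytic), 3 * se + 1e-9)
})

test_that("occupancies are conserved at every step in both engines", {
  prot <- sim_protocol(pCa = 5.5, duration = 0.5, seed = 2)
  for (sim in list(
    mean_field_simulate(default_geom, sarcomere_params(), model_variant("A"),
                        "all", prot),
    run_simulation(default_geom, sarcomere_params(), model_variant("A"),
                   "all", prot)
  )) {
    sums <- apply(sim$class_occ, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(sim$class_occ >= -1e-12))
  }
})

test_that("phi_P = 1 collapses all variants onto the baseline", {
  p <- sarcomere_params(phi_P = 1)
  prot <- sim_protocol(pCa = 5.5, duration = 0.5, seed = 5)
  traces <- lapply(c("A", "B", "C", "none"), function(v) {
    mean_field_simulate(default_geom, p, model_variant(v), "all", prot)$trace
  })
  for (i in 2:4) expect_equal(traces[[i]], traces[[1]], tolerance = 1e-12)

  mc <- lapply(c("A", "C", "none"), function(v) {
    run_simulation(default_geom, p, model_variant(v), "all", prot)$trace
  })
  expect_identical(mc[[1]], mc[[2]])
  expect_identical(mc[[1]], mc[[3]])
})

test_that("steady force is monotone in calcium and pCa50 in phi_P", {
  pars <- calibrated_params()
  fp <- force_pca_curve(default_geom, pars, model_variant("none"), "none",
                        1.9, seq(6.8, 4.6, by = -0.2))
  expect_true(all(diff(fp$points$force_pN) > -1e-9))

  shifts <- vapply(c(1, 3, 6, 12), function(phi) {
    p <- pars; p$phi_P <- phi
    suppressWarnings(force_pca_curve(default_geom, p, model_variant("A"),
                                     "all", 1.9)$fit$pCa50)
  }, numeric(1))
  expect_true(all(diff(shifts) > -1e-6))
})

test_that("mean-field ODE, algebraic steady state and Monte Carlo agree", {
  pars <- calibrated_params()
  grid6 <- c(6.4, 6.0, 5.8, 5.6, 5.2, 4.6)
  ss <- force_pca_curve(default_geom, pars, model_variant("A"), "none", 1.9,
                        grid6, engine = "mean_field_ss")
  ode <- force_pca_curve(default_geom, pars, model_variant("A"), "none", 1.9,
                         grid6, engine = "mean_field", duration = 6)
  expect_equal(ode$points$force_pN, ss$points$force_pN, tolerance = 0.02)

  # MC vs mean field at saturating calcium, averaged over seeds
  fmc <- vapply(1:6, function(s) {
    prot <- sim_protocol(sarcomere_length = 1.9, pCa = 4.0, duration = 2,
                         seed = s)
    tr <- run_simulation(default_geom, pars, model_variant("A"), "none",
                         prot)$trace
    mean(tr$force_pN[tr$t_s >= 1.5])
  }, numeric(1))
  prot <- sim_protocol(sarcomere_length = 1.9, pCa = 4.0, duration = 2)
  mf <- mean_field_simulate(default_geom, pars, model_variant("A"), "none",
                            prot)$trace
  fmf <- mean(mf$force_pN[mf$t_s >= 1.5])
  expect_lt(abs(mean(fmc) - fmf) / fmf, 0.05)
})

test_that("steady state is independent of the initial ON/FG split", {
  pars <- calibrated_params()
  prot <- sim_protocol(pCa = 5.4, duration = 6)
  s1 <- mean_field_simulate(default_geom, pars, model_variant("A"), "none",
                            prot)
  s2 <- mean_field_simulate(default_geom, pars, model_variant("A"), "none",
                            prot, init_occ = c(on = 0.7, fg = 0.2))
  expect_equal(s1$trace$force_pN[nrow(s1$trace)],
               s2$trace$force_pN[nrow(s2$trace)], tolerance = 1e-6)
})

test_that("ktr matches the two-state closed form and requires a restretch", {
  # ON <-> FG only: huge k1, k2 = 0, thin filament always on
  p <- sarcomere_params(k1_0 = 500, k_force = 0, k2 = 0, k3 = 30, k4 = 10,
                        a_kon = 1000, a_koff = 0, a_coop = 0, a_hold = 0,
                        passive_gain = 0)
  prot <- sim_protocol(sarcomere_length = 1.9, pCa = 4.0, duration = 2.5,
                       mode = "ktr_slack_restretch", t_slack = 1.5)
  fit <- ktr_protocol(default_geom, p, model_variant("none"), "none", prot)
  expect_equal(fit$k_tr, 30 + 10, tolerance = 0.02)

  expect_error(
    ktr_protocol(default_geom, p, model_variant("none"), "none",
                 sim_protocol(mode = "slack_only")),
    "restretch"
  )
})

test_that("phosphorylation raises force and ktr under Model A", {
  pars <- calibrated_params()
  fine <- c(6.2, 6.0, 5.9, 5.8, 5.7, 5.6, 5.4, 5.0)
  u <- force_pca_curve(default_geom, pars, model_variant("A"), "none", 2.3,
                       fine)
  ph <- force_pca_curve(default_geom, pars, model_variant("A"), "all", 2.3,
                        fine)
  # higher force throughout the physiological activation range (pCa ~5.8)
  expect_gt(ph$points$force_pN[fine == 5.8], u$points$force_pN[fine == 5.8])

  prot <- sim_protocol(sarcomere_length = 1.9, pCa = 4.8, duration = 3,
                       mode = "ktr_slack_restretch", t_slack = 1.8)
  ku <- ktr_protocol(default_geom, pars, model_variant("A"), "none", prot)
  kp <- ktr_protocol(default_geom, pars, model_variant("A"), "all", prot)
  expect_gt(kp$k_tr, ku$k_tr)
})

test_that("too-large time steps are rejected in the Monte-Carlo engine", {
  prot <- sim_protocol(pCa = 5.5, duration = 0.1, dt = 0.01)
  expect_error(
    run_simulation(default_geom, sarcomere_params(), model_variant("A"),
                   "none", prot),
    "dt"
  )
})
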