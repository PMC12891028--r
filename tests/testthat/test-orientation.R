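test_that("order parameters hit their landmark angles", {
  expect_equal(p2_of_angle(0), 1)
  expect_equal(p2_of_angle(90), -0.5)
  expect_equal(p2_of_angle(54.7356103), 0, tolerance = 1e-7)
  expect_equal(p4_of_angle(0), 1)

  # uniform distribution on the sphere averages to zero
  m <- max_entropy_map(tibble::tibble(vx = 0, vy = 0, vz = 1, p2 = 0.4)[0, ],
                       resolution = 2)
  expect_equal(p2_of_distribution(m), 0, tolerance = 1e-6)
})

test_that("degenerate pairs mirror and involute", {
  expect_equal(degenerate_pair(60, 30), c(beta = 120, gamma = 210))
  expect_equal(degenerate_pair(90, 0), c(beta = 90, gamma = 180))
  p <- degenerate_pair(37.2, 311.5)
  expect_equal(degenerate_pair(p["beta"], p["gamma"]),
               c(beta = 37.2, gamma = 311.5), ignore_attr = TRUE)
})

test_that("maximum-entropy maps reproduce their constraints and symmetry", {
  cons <- tibble::tibble(
    vx = c(0, 0.6), vy = c(0, 0.2), vz = c(1, 0.9),
    p2 = c(0.3, 0.1), p4 = c(0.1, NA)
  )
  m <- max_entropy_map(cons, resolution = 3)
  # round trip: achieved moments equal the inputs
  expect_lt(max(abs(m$achieved - m$targets)), 1e-4)
  # normalization with the sin(beta) measure
  expect_equal(sum(m$grid$density * m$grid$weight), 1, tolerance = 1e-9)
  expect_true(all(m$grid$density >= 0))

  # degeneracy symmetry: density(beta, gamma) == density(180-beta, gamma+180)
  g <- m$grid
  key <- paste(round(g$beta, 6), round(g$gamma, 6))
  partner <- paste(round(180 - g$beta, 6), round((g$gamma + 180) %% 360, 6))
  expect_equal(g$density[match(partner, key)], g$density, tolerance = 1e-9)

  # infeasible constraints are rejected
  expect_error(max_entropy_map(tibble::tibble(vx = 0, vy = 0, vz = 1,
                                              p2 = 1.2)), "-0.5, 1")
})

test_that("a probe along the molecular axis with high <P2> concentrates at the pole", {
  m <- max_entropy_map(tibble::tibble(vx = 0, vy = 0, vz = 1, p2 = 0.95),
                       resolution = 2)
  g <- m$grid
  mass_polar <- sum(g$density[g$beta < 20 | g$beta > 160] *
                      g$weight[g$beta < 20 | g$beta > 160])
  expect_gt(mass_polar, 0.8)
})

test_that("peak finding resolves populations and degeneracy partners", {
  # flat map: no peaks
  flat <- max_entropy_map(
    tibble::tibble(vx = 0, vy = 0, vz = 1, p2 = 0.4)[0, ], resolution = 4)
  expect_equal(nrow(find_peaks(flat)), 0)

  # synthetic two-population map built from two von-Mises-like bumps plus
  # their degeneracy partners
  grid <- flat$grid
  bump <- function(b0, g0, kappa = 40) {
    cd <- cos(grid$beta * pi / 180) * cos(b0 * pi / 180) +
      sin(grid$beta * pi / 180) * sin(b0 * pi / 180) *
        cos((grid$gamma - g0) * pi / 180)
    exp(kappa * (cd - 1))
  }
  dens <- bump(60, 40) + bump(120, 220) + bump(95, 150) + bump(85, 330)
  grid$density <- dens / sum(dens * grid$weight)
  synth <- flat
  synth$grid <- grid
  pk <- find_peaks(synth, min_separation = 20)
  expect_equal(nrow(pk), 4)
  expect_equal(length(unique(pk$group)), 2)
})

test_that("Euler angles recover synthetic helix orientations", {
  # helix along the filament axis: beta = 0
  ca_par <- ideal_helix_ca(36, axis = c(0, 0, 1))
  ref <- ideal_helix_ca(8, axis = c(1, 0, 0), origin = c(15, 0, 5))
  e_par <- euler_from_structure(rbind(ca_par, ref), 1:36, 37:44)
  expect_lt(e_par["beta"], 2)

  # helix perpendicular: beta = 90
  ca_perp <- ideal_helix_ca(36, axis = c(1, 0, 0))
  ref2 <- ideal_helix_ca(8, axis = c(0, 1, 0), origin = c(5, 15, 0))
  e_perp <- euler_from_structure(rbind(ca_perp, ref2), 1:36, 37:44)
  expect_equal(unname(e_perp["beta"]), 90, tolerance = 2)

  expect_error(euler_from_structure(ca_par[1:3, , drop = FALSE], 1:3, 1:3),
               ">= 4")
})

test_that("Euler angles are invariant under rigid rotation of model and axis", {
  ca <- ideal_helix_ca(18, axis = c(1, 1, 2))
  ref <- ideal_helix_ca(8, axis = c(0, 1, 0), origin = c(12, -4, 8))
  coords <- rbind(ca, ref)
  e0 <- euler_from_structure(coords, 1:18, 19:26, axis = c(0, 0, 1))

  th <- 0.7; ph <- 1.9
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  R <- Rz %*% Rx
  e1 <- euler_from_structure(coords %*% t(R), 1:18, 19:26,
                             axis = as.numeric(R %*% c(0, 0, 1)))
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("two-phase transient fits recover generating rates", {
  d <- generate_dataset("slack_restretch_pre", seed = 4)
  fit <- fit_p2_transient(d$data, d$truth$events)
  ph <- fit$phases
  expect_equal(ph$rate_s[ph$phase == "Ph1"], 60, tolerance = 0.05)
  expect_equal(ph$rate_s[ph$phase == "Ph2"], 13, tolerance = 0.05)
  expect_true(all(ph$present))

  # slack-only trace: Ph2 absent
  spec <- fixture_spec("slack_restretch_pre")
  spec$params$restretch <- FALSE
  d2 <- generate_dataset(spec, seed = 4)
  fit2 <- fit_p2_transient(d2$data, d2$truth$events)
  expect_false(fit2$phases$present[fit2$phases$phase == "Ph2"])
})

test_that("predicted <P2> mixes state occupancies within basis bounds", {
  prot <- sim_protocol(pCa = 9, duration = 0.3)
  sim <- mean_field_simulate(default_geom, sarcomere_params(),
                             model_variant("none"), "none", prot)
  p2 <- predicted_p2(sim, basis = c(OFF = 0.2, ON = 0.2, FG = 0.2))
  expect_equal(p2$p2, rep(0.2, nrow(p2)), tolerance = 1e-9)

  basis <- c(OFF = 0.15, ON = -0.05, FG = -0.15)
  prot2 <- sim_protocol(pCa = 4.8, duration = 1.5)
  sim2 <- mean_field_simulate(default_geom, sarcomere_params(),
                              model_variant("none"), "none", prot2)
  p2b <- predicted_p2(sim2, basis)
  expect_true(all(p2b$p2 <= max(basis) + 1e-12 &
                    p2b$p2 >= min(basis) - 1e-12))
  # activation moves heads out of OFF: <P2> decreases from its relaxed value
  expect_lt(p2b$p2[nrow(p2b)], p2b$p2[1])

  expect_error(predicted_p2(sim2, basis = c(OFF = 2, ON = 0, FG = 0)),
               "-0.5, 1")
})
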