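#' Second-rank order parameter of an angle
#'
#' `P2(theta) = (3 cos^2 theta - 1) / 2`, ranging from -0.5 (probe
#' perpendicular to the filament axis) to 1 (parallel).
#'
#' @param theta_deg angle(s) in degrees.
#' @return Numeric vector.
#' @export
p2_of_angle <- function(theta_deg) {
  c2 <- cos(theta_deg * pi / 180)^2
  (3 * c2 - 1) / 2
}

#' Fourth-rank order parameter of an angle
#' @param theta_deg angle(s) in degrees.
#' @return `P4(cos theta) = (35 c^4 - 30 c^2 + 3)/8`.
#' @export
p4_of_angle <- function(theta_deg) {
  c2 <- cos(theta_deg * pi / 180)^2
  (35 * c2^2 - 30 * c2 + 3) / 8
}

#' Order parameter of an orientation distribution
#'
#' Integrates `P2(beta)` over a maximum-entropy map (with the `sin beta`
#' measure already folded into the map weights) or averages it over a sample
#' of angles.
#'
#' @param x an `me_map` from [max_entropy_map()], or a numeric vector of beta
#'   angles (degrees) to average over.
#' @return Scalar `<P2>`.
#' @export
p2_of_distribution <- function(x) {
  if (inherits(x, "me_map")) {
    g <- x$grid
    sum(g$density * g$weight * p2_of_angle(g$beta)) /
      sum(g$density * g$weight)
  } else {
    mean(p2_of_angle(as.numeric(x)))
  }
}

#' Degeneracy partner of an orientation
#'
#' Polarized fluorescence cannot distinguish `(beta, gamma)` from
#' `(180 - beta, gamma + 180)`; this returns the partner orientation.
#' Applying it twice is the identity.
#'
#' @param beta,gamma Euler angles in degrees (`beta` in `[0, 180]`,
#'   `gamma` in `[0, 360)`).
#' @return Named numeric vector `c(beta, gamma)`.
#' @export
degenerate_pair <- function(beta, gamma) {
  c(beta = 180 - beta, gamma = (gamma + 180) %% 360)
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

# direction cosine of probe axis v (unit, molecular frame) with the lab z
# (filament) axis after orienting the molecule by (beta, gamma):
# R = Ry(beta) %*% Rz(gamma)
probe_cos_theta <- function(beta_deg, gamma_deg, v) {
  b <- beta_deg * pi / 180
  g <- gamma_deg * pi / 180
  -sin(b) * (v[1] * cos(g) - v[2] * sin(g)) + cos(b) * v[3]
}

#' Maximum-entropy orientation distribution over (beta, gamma)
#'
#' Finds the smoothest (maximum-entropy) distribution on the Euler-angle grid
#' consistent with measured second- and fourth-rank order parameters from one
#' or more probes: `f(beta, gamma) propto exp(sum_j lambda_j2 P2(cos theta_j)
#' + lambda_j4 P4(cos theta_j))`, where `theta_j` is the angle between probe
#' j's axis and the filament axis. The Lagrange multipliers are solved by
#' minimizing the convex dual (log partition function minus the measured
#' moments) with BFGS; achieved order parameters match the measurements to
#' 1e-4. Because P2 and P4 are even in `cos theta`, every solved map is
#' automatically symmetric under the `(beta, gamma) -> (180 - beta, gamma +
#' 180)` degeneracy.
#'
#' @param constraints tibble/data.frame with one row per probe: columns
#'   `vx`, `vy`, `vz` (probe axis in the molecular frame; normalized
#'   internally), `p2`, and optionally `p4` (`NA` to constrain `P2` only).
#' @param resolution nominal grid spacing in degrees: gamma is uniform at
#'   this spacing, and beta uses `180/resolution` Gauss-Legendre nodes in
#'   `cos(beta)`, so the grid weights integrate the Legendre features to
#'   machine precision.
#' @param tol moment-matching tolerance.
#' @return An `me_map`: `grid` tibble (`beta`, `gamma`, `weight` = quadrature
#'   measure, `density` normalized so `sum(density * weight) = 1`),
#'   `lambda`, `achieved` versus requested moments.
#' @export
max_entropy_map <- function(constraints, resolution = 2, tol = 1e-4) {
  constraints <- tibble::as_tibble(constraints)
  if (!all(c("vx", "vy", "vz", "p2") %in% names(constraints))) {
    stop("`constraints` needs columns vx, vy, vz, p2 (and optionally p4).",
         call. = FALSE)
  }
  if (!("p4" %in% names(constraints))) constraints$p4 <- NA_real_
  if (any(constraints$p2 < -0.5 | constraints$p2 > 1)) {
    stop("<P2> must lie in [-0.5, 1].", call. = FALSE)
  }
  # Legendre feasibility: P4 has sharp bounds given P2; use the loose ones
  if (any(!is.na(constraints$p4) &
          (constraints$p4 < -3 / 7 | constraints$p4 > 1))) {
    stop("<P4> outside its Legendre bounds.", call. = FALSE)
  }

  gl <- gauss_legendre(max(4L, round(180 / resolution)))
  beta <- acos(rev(gl$nodes)) * 180 / pi           # ascending in beta
  w_beta <- rev(gl$weights) / 2                    # sums to 1
  gamma <- seq(resolution / 2, 360 - resolution / 2, by = resolution)
  grid <- tidyr::expand_grid(beta = beta, gamma = gamma)
  weight <- rep(w_beta, each = length(gamma)) / length(gamma)

  # feature matrix: one column per active constraint
  feats <- list()
  targets <- c()
  for (j in seq_len(nrow(constraints))) {
    v <- c(constraints$vx[j], constraints$vy[j], constraints$vz[j])
    v <- v / sqrt(sum(v^2))
    ct <- probe_cos_theta(grid$beta, grid$gamma, v)
    c2 <- ct^2
    feats[[length(feats) + 1]] <- (3 * c2 - 1) / 2
    targets <- c(targets, constraints$p2[j])
    if (!is.na(constraints$p4[j])) {
      feats[[length(feats) + 1]] <- (35 * c2^2 - 30 * c2 + 3) / 8
      targets <- c(targets, constraints$p4[j])
    }
  }
  X <- if (length(feats)) do.call(cbind, feats)
  else matrix(0, nrow(grid), 0)

  if (ncol(X) == 0) {
    dens <- rep(1, nrow(grid))
  } else {
    dual <- function(lam) {
      e <- as.numeric(X %*% lam)
      m <- max(e)
      log(sum(weight * exp(e - m))) + m - sum(lam * targets)
    }
    dual_grad <- function(lam) {
      e <- as.numeric(X %*% lam)
      w <- weight * exp(e - max(e))
      w <- w / sum(w)
      as.numeric(crossprod(X, w)) - targets
    }
    opt <- optim(rep(0, ncol(X)), dual, dual_grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    lam <- opt$par
    e <- as.numeric(X %*% lam)
    dens <- exp(e - max(e))
  }
  dens <- dens / sum(dens * weight)
  achieved <- if (ncol(X)) as.numeric(crossprod(X, dens * weight)) else numeric(0)
  if (length(targets) && max(abs(achieved - targets)) > tol) {
    stop("Maximum-entropy solver did not reach the measured moments ",
         "(max residual ", signif(max(abs(achieved - targets)), 3),
         "); constraints may be near-infeasible.", call. = FALSE)
  }

  out_grid <- dplyr::mutate(grid, weight = weight, density = dens)
  structure(
    list(grid = out_grid, resolution = resolution,
         lambda = if (ncol(X)) lam else numeric(0),
         achieved = achieved, targets = targets, constraints = constraints),
    class = "me_map"
  )
}

#' @export
print.me_map <- function(x, ...) {
  cat("<me_map> ", x$resolution, "deg grid, ", nrow(x$constraints),
      " probe(s), ", length(x$targets), " moment constraint(s)\n", sep = "")
  if (length(x$targets)) {
    cat("  achieved moments: ",
        paste(sprintf("%.4f", x$achieved), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.me_map <- function(x, ...) x$grid

#' Peaks of a maximum-entropy map
#'
#' Local maxima of the density (8-neighbourhood on the grid, with gamma
#' wrap-around) above `min_height` times the global maximum, merged when
#' closer than `min_separation` (great-circle distance treating (beta, gamma)
#' as spherical coordinates). Peaks are grouped with their degeneracy
#' partners.
#'
#' @param map an `me_map`.
#' @param min_separation merge radius in degrees.
#' @param min_height height threshold as a fraction of the maximum density.
#' @return Tibble `beta`, `gamma`, `height`, `group` (degeneracy-partner
#'   group id); empty for a flat map.
#' @export
find_peaks <- function(map, min_separation = 20, min_height = 0.2) {
  stopifnot(inherits(map, "me_map"))
  g <- map$grid
  nb <- length(unique(g$beta))
  ng <- length(unique(g$gamma))
  dens <- matrix(g$density, nrow = nb, ncol = ng, byrow = TRUE)
  if (diff(range(dens)) < 1e-10 * max(dens)) {
    return(tibble::tibble(beta = numeric(0), gamma = numeric(0),
                          height = numeric(0), group = integer(0)))
  }
  shift_g <- function(m, k) m[, ((seq_len(ng) - 1 + k) %% ng) + 1, drop = FALSE]
  pad <- function(m, k) { # shift along beta with -Inf padding
    if (k == 1) rbind(m[-1, , drop = FALSE], -Inf)
    else if (k == -1) rbind(-Inf, m[-nb, , drop = FALSE])
    else m
  }
  is_max <- dens >= 0
  for (db in -1:1) for (dg in -1:1) {
    if (db == 0 && dg == 0) next
    is_max <- is_max & (dens >= pad(shift_g(dens, dg), db))
  }
  is_max <- is_max & dens >= min_height * max(dens)
  idx <- which(is_max, arr.ind = TRUE)
  betas <- sort(unique(g$beta))
  gammas <- sort(unique(g$gamma))
  peaks <- tibble::tibble(beta = betas[idx[, 1]], gamma = gammas[idx[, 2]],
                          height = dens[idx])
  peaks <- dplyr::arrange(peaks, dplyr::desc(.data$height))

  ang_dist <- function(b1, g1, b2, g2) {
    cd <- cos(b1 * pi / 180) * cos(b2 * pi / 180) +
      sin(b1 * pi / 180) * sin(b2 * pi / 180) * cos((g1 - g2) * pi / 180)
    acos(pmin(1, pmax(-1, cd))) * 180 / pi
  }
  # merge near-duplicates (keep the highest)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- seq.int(i + 1, nrow(peaks))
      d <- ang_dist(peaks$beta[i], peaks$gamma[i],
                    peaks$beta[later], peaks$gamma[later])
      keep[later[d < min_separation]] <- FALSE
    }
  }
  peaks <- peaks[keep, ]
  # group degeneracy partners
  group <- rep(NA_integer_, nrow(peaks))
  gid <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (!is.na(group[i])) next
    gid <- gid + 1L
    group[i] <- gid
    partner <- degenerate_pair(peaks$beta[i], peaks$gamma[i])
    if (i < nrow(peaks)) {
      rest <- seq.int(i + 1, nrow(peaks))
      d <- ang_dist(partner["beta"], partner["gamma"],
                    peaks$beta[rest], peaks$gamma[rest])
      hit <- rest[is.na(group[rest]) & d < min_separation]
      if (length(hit)) group[hit[1]] <- gid
    }
  }
  dplyr::mutate(peaks, group = group)
}

# ---- Euler angles from atomic structures ---------------------------------

# least-squares axis through a set of points (first principal axis),
# oriented from the first to the last point
ls_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  ax <- sv$v[, 1]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Euler angles of the RLC E-helix from an atomic model
#'
#' Computes `beta`, the angle between the least-squares axis through the
#' E-helix C-alpha positions and the filament axis, and `gamma`, the azimuth
#' of the reference (E-to-G inter-helix) vector about the E-helix axis.
#' The gamma zero convention: `gamma = 0` when the reference vector lies in
#' the plane spanned by the E-helix axis and the filament axis (on the
#' filament-axis side), increasing right-handedly about the E-helix axis.
#'
#' @param model a `bio3d` `pdb` object (see [bio3d::read.pdb()]), a path to a
#'   PDB/mmCIF file, or a numeric matrix of C-alpha coordinates (one row per
#'   residue, columns x, y, z) in which case `e_helix`/`reference` index rows.
#' @param e_helix residue numbers (or row indices) of the E-helix span
#'   (>= 4 C-alpha positions).
#' @param reference residue numbers (or row indices) of the reference-frame
#'   span (e.g. the G-helix) whose centroid defines the azimuth vector.
#' @param axis filament axis vector (length-3, nonzero) in the model frame.
#' @param chain chain identifier when `model` is a pdb object/file.
#' @return Named vector `c(beta, gamma)` in degrees.
#' @export
euler_from_structure <- function(model, e_helix, reference,
                                 axis = c(0, 0, 1), chain = NULL) {
  if (sqrt(sum(axis^2)) == 0) stop("`axis` must be nonzero.", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))

  get_ca <- function(resno) {
    if (is.matrix(model)) {
      if (any(resno < 1 | resno > nrow(model))) {
        stop("Row indices out of range: ",
             paste(resno[resno < 1 | resno > nrow(model)], collapse = ", "),
             call. = FALSE)
      }
      return(model[resno, , drop = FALSE])
    }
    pdb <- if (is.character(model)) bio3d::read.pdb(model) else model
    sel <- pdb$atom$elety == "CA" & pdb$atom$resno %in% resno
    if (!is.null(chain)) sel <- sel & pdb$atom$chain == chain
    found <- pdb$atom$resno[sel]
    missing <- setdiff(resno, found)
    if (length(missing)) {
      stop("Missing C-alpha atoms for residues: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    as.matrix(pdb$atom[sel, c("x", "y", "z")])
  }

  ca_e <- get_ca(e_helix)
  ca_r <- get_ca(reference)
  if (nrow(ca_e) < 4) stop("E-helix span must cover >= 4 residues.", call. = FALSE)

  e_ax <- ls_axis(ca_e)
  beta <- acos(pmin(1, pmax(-1, sum(e_ax * axis)))) * 180 / pi

  # reference vector: E-helix centroid -> reference centroid, projected
  # perpendicular to the E-helix axis
  ref <- colMeans(ca_r) - colMeans(ca_e)
  ref_perp <- ref - sum(ref * e_ax) * e_ax
  # gamma = 0 direction: filament axis projected perpendicular to e_ax
  zero <- axis - sum(axis * e_ax) * e_ax
  if (sqrt(sum(zero^2)) < 1e-9) {
    # E-helix parallel to the filament axis: gamma undefined, return 0
    return(c(beta = beta, gamma = 0))
  }
  zero <- zero / sqrt(sum(zero^2))
  if (sqrt(sum(ref_perp^2)) < 1e-9) {
    stop("Reference vector is parallel to the E-helix axis; ",
         "gamma is undefined.", call. = FALSE)
  }
  ref_perp <- ref_perp / sqrt(sum(ref_perp^2))
  y_dir <- c(e_ax[2] * zero[3] - e_ax[3] * zero[2],
             e_ax[3] * zero[1] - e_ax[1] * zero[3],
             e_ax[1] * zero[2] - e_ax[2] * zero[1])
  gamma <- atan2(sum(ref_perp * y_dir), sum(ref_perp * zero)) * 180 / pi
  c(beta = beta, gamma = gamma %% 360)
}

#' Build an ideal alpha-helix C-alpha trace
#'
#' Synthetic helix generator used for orientation tests and examples: 1.5 A
#' rise and 100 degrees rotation per residue on a 2.3 A radius, along an
#' arbitrary axis.
#'
#' @param n_res number of residues.
#' @param axis helix axis direction.
#' @param origin translation applied to all coordinates.
#' @param phase initial phase angle (degrees).
#' @return Matrix `n_res` x 3 of coordinates (Angstrom).
#' @export
ideal_helix_ca <- function(n_res = 12, axis = c(0, 0, 1), origin = c(0, 0, 0),
                           phase = 0) {
  axis <- axis / sqrt(sum(axis^2))
  t_ang <- (phase + 100 * (seq_len(n_res) - 1)) * pi / 180
  local <- cbind(2.3 * cos(t_ang), 2.3 * sin(t_ang), 1.5 * (seq_len(n_res) - 1))
  # rotate z onto the requested axis
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * axis)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  sweep(local %*% t(R), 2, origin, "+")
}

# ---- <P2> transients ------------------------------------------------------

#' Two-phase analysis of a slack-restretch order-parameter transient
#'
#' Fits single exponentials to the two phases of the `<P2>` transient:
#' Phase 1 (Ph1), the partial recovery toward the relaxed value between the
#' step release and the restretch (myosin heads detaching and partially
#' re-forming the OFF state), and Phase 2 (Ph2), the decline after the
#' restretch as motors leave the folded OFF state and re-attach. With no
#' restretch event (slack-only protocol) Ph2 is reported absent.
#'
#' @param trace tibble with columns `t_s` and `p2`.
#' @param events named numeric vector with `release` and optionally
#'   `restretch` times (s).
#' @param noise_floor minimum phase amplitude; below it the phase is flagged
#'   absent rather than fitted.
#' @return A `p2_transient_fit`: tibble row per phase (`phase`, `rate_s`,
#'   `amplitude`, `value_start`, `value_end`, `present`), plus steady levels.
#' @export
fit_p2_transient <- function(trace, events, noise_floor = 0.005) {
  stopifnot(all(c("t_s", "p2") %in% names(trace)))
  if (!("release" %in% names(events))) {
    stop("`events` must contain a release time.", call. = FALSE)
  }
  t_rel <- events[["release"]]
  t_re <- if ("restretch" %in% names(events)) events[["restretch"]] else NA
  if (t_rel < min(trace$t_s) || t_rel > max(trace$t_s)) {
    stop("Release event outside the trace.", call. = FALSE)
  }

  fit_phase <- function(sub, label) {
    if (nrow(sub) < 10L) {
      stop("Phase ", label, " window has fewer than 10 points.", call. = FALSE)
    }
    amp0 <- sub$p2[nrow(sub)] - sub$p2[1]
    if (abs(amp0) < noise_floor) {
      return(tibble::tibble(phase = label, rate_s = NA_real_, amplitude = 0,
                            value_start = sub$p2[1],
                            value_end = sub$p2[nrow(sub)], present = FALSE))
    }
    dat <- data.frame(ts = sub$t_s - sub$t_s[1], y = sub$p2)
    fit <- minpack.lm::nlsLM(
      y ~ yinf + (y0 - yinf) * exp(-k * ts), data = dat,
      start = list(yinf = sub$p2[nrow(sub)], y0 = sub$p2[1], k = 20),
      lower = c(-0.5, -0.5, 1e-3), upper = c(1, 1, 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- coef(fit)
    tibble::tibble(phase = label, rate_s = unname(cf["k"]),
                   amplitude = unname(cf["yinf"] - cf["y0"]),
                   value_start = unname(cf["y0"]),
                   value_end = unname(cf["yinf"]), present = TRUE)
  }

  ph1_end <- if (is.na(t_re)) max(trace$t_s) else t_re
  ph1 <- fit_phase(trace[trace$t_s >= t_rel & trace$t_s < ph1_end, ], "Ph1")
  ph2 <- if (is.na(t_re)) {
    tibble::tibble(phase = "Ph2", rate_s = NA_real_, amplitude = NA_real_,
                   value_start = NA_real_, value_end = NA_real_,
                   present = FALSE)
  } else {
    fit_phase(trace[trace$t_s >= t_re, ], "Ph2")
  }

  pre <- trace$p2[trace$t_s < t_rel]
  structure(
    list(phases = dplyr::bind_rows(ph1, ph2),
         p2_act = mean(pre[seq.int(max(1, length(pre) - 20), length(pre))]),
         events = events),
    class = "p2_transient_fit"
  )
}

#' @export
print.p2_transient_fit <- function(x, ...) {
  cat("<p2_transient_fit> <P2>_ACT =", sprintf("%.3f", x$p2_act), "\n")
  print(x$phases)
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.p2_transient_fit <- function(x, ...) x$phases

#' Predicted order-parameter transient from simulator occupancies
#'
#' Maps the head-weighted state occupancies of a [mean_field_simulate()] /
#' [run_simulation()] result onto `<P2>(t) = sum_state occupancy(t) *
#' basis[state]`, mixing only the probe-exchanged heads (all heads share the
#' same per-state basis values, so the exchanged fraction cancels).
#'
#' @param sim a `sim_result`.
#' @param basis named numeric: `<P2>` of the OFF, ON and FG states, each in
#'   `[-0.5, 1]`.
#' @return Tibble `t_s`, `p2` plus the simulation's events as an attribute.
#' @export
predicted_p2 <- function(sim, basis = c(OFF = 0.15, ON = -0.05, FG = -0.15)) {
  stopifnot(inherits(sim, "sim_result"),
            all(c("OFF", "ON", "FG") %in% names(basis)))
  if (any(basis < -0.5 | basis > 1)) {
    stop("Basis <P2> values must lie in [-0.5, 1].", call. = FALSE)
  }
  tr <- sim$trace
  out <- tibble::tibble(
    t_s = tr$t_s,
    p2 = basis[["OFF"]] * tr$off + basis[["ON"]] * tr$on +
      basis[["FG"]] * tr$fg
  )
  attr(out, "events") <- sim$events
  out
}
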