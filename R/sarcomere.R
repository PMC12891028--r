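#' Kinetic parameters of the mechanosensing half-sarcomere model
#'
#' Myosin heads cycle independently between an OFF (folded, unavailable), an
#' ON (disordered, available) and a force-generating (FG, actin-attached)
#' state. Thick-filament mechanosensing enters through the OFF-to-ON rate,
#' `k1 = k1_0 * (1 + g * k_force * F_sense)`, where `F_sense` is the total
#' half-filament force (active plus titin-like passive) and `g` is the
#' phosphorylation multiplier `phi_P` for heads targeted by the active model
#' variant (1 otherwise). Phosphorylation therefore has no effect at zero
#' filament load, consistent with the small effect of RLC phosphorylation on
#' relaxed heads.
#'
#' @param k1_0 base OFF->ON rate (s^-1).
#' @param k_force mechanosensing gain (pN^-1).
#' @param k2 ON->OFF rate (s^-1).
#' @param k3 attachment rate (s^-1), scaled by thin-filament activation and
#'   overlap.
#' @param k4 detachment rate (s^-1).
#' @param f_head force per attached head (pN).
#' @param a_kon thin-filament unit activation rate (uM^-1 s^-1).
#' @param a_koff thin-filament unit deactivation rate (s^-1).
#' @param a_coop nearest-neighbour cooperativity factor: an inactive unit
#'   activates at `a_kon [Ca] (1 + a_coop n_active_neighbours)`.
#' @param a_hold attached-crossbridge hold on thin-filament deactivation:
#'   a unit's deactivation rate is scaled by `(1 - f_attached)^a_hold`,
#'   where `f_attached` is the attached fraction of the heads the unit
#'   regulates. Force-generating heads thereby keep their regulatory unit
#'   active, the second classical source of force-pCa cooperativity next to
#'   neighbour coupling.
#' @param phi_P phosphorylation multiplier on `k_force` (>= 1).
#' @param passive_gain titin-like passive force per um of sarcomere length
#'   above slack (pN um^-1).
#' @param sl_slack slack sarcomere length (um) above which passive force
#'   develops.
#' @return A `sarcomere_params` list.
#' @export
sarcomere_params <- function(k1_0 = 5, k_force = 0.0045, k2 = 80, k3 = 80,
                             k4 = 12, f_head = 2, a_kon = 7, a_koff = 100,
                             a_coop = 4, a_hold = 1.5, phi_P = 6,
                             passive_gain = 320, sl_slack = 1.9) {
  p <- list(k1_0 = k1_0, k_force = k_force, k2 = k2, k3 = k3, k4 = k4,
            f_head = f_head, a_kon = a_kon, a_koff = a_koff, a_coop = a_coop,
            a_hold = a_hold, phi_P = phi_P, passive_gain = passive_gain,
            sl_slack = sl_slack)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                         logical(1))]
  bad <- setdiff(bad, "sl_slack")
  if (length(bad)) stop("Nonnegative scalar required for: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (phi_P < 1) stop("`phi_P` must be >= 1.", call. = FALSE)
  structure(p, class = "sarcomere_params")
}

#' Phosphorylation-placement model variants
#'
#' Which (zone, head-role) combinations respond to RLC phosphorylation:
#' * `"A"` — blocked heads in the C-zone only,
#' * `"B"` — blocked heads over the whole thick filament (P, C and D zones),
#' * `"C"` — both blocked and free heads in the C-zone,
#' * `"none"` — no heads respond.
#'
#' @param name `"A"`, `"B"`, `"C"` or `"none"`.
#' @return A `model_variant` with `name`, `target_zones`, `target_roles`.
#' @export
model_variant <- function(name = c("A", "B", "C", "none")) {
  name <- match.arg(name)
  spec <- switch(name,
    A = list(zones = "C", roles = "blocked"),
    B = list(zones = c("P", "C", "D"), roles = "blocked"),
    C = list(zones = "C", roles = c("blocked", "free")),
    none = list(zones = character(0), roles = character(0))
  )
  structure(list(name = name, target_zones = spec$zones,
                 target_roles = spec$roles),
            class = "model_variant")
}

#' Per-head transition rates of the kinetic scheme
#'
#' @param zone,role head address (`"P"/"C"/"D"`, `"blocked"/"free"`).
#' @param F_sense sensed filament force (pN, >= 0).
#' @param thin_on local thin-filament activation (fraction 0-1).
#' @param overlap thick/thin overlap at the head's crown (0-1).
#' @param params [sarcomere_params()].
#' @param variant [model_variant()].
#' @param phosphorylated logical, is this head's RLC phosphorylated.
#' @return Named list of rates `off_on`, `on_off`, `on_fg`, `fg_on` (s^-1).
#' @export
head_rates <- function(zone, role, F_sense, thin_on, overlap = 1,
                       params = sarcomere_params(),
                       variant = model_variant("A"),
                       phosphorylated = FALSE) {
  stopifnot(F_sense >= 0)
  g <- if (phosphorylated && zone %in% variant$target_zones &&
           role %in% variant$target_roles) params$phi_P else 1
  list(
    off_on = params$k1_0 * (1 + g * params$k_force * max(0, F_sense)),
    on_off = params$k2,
    on_fg = params$k3 * thin_on * overlap,
    fg_on = params$k4
  )
}

#' Simulation protocol
#'
#' @param sarcomere_length um.
#' @param pCa -log10 of the calcium concentration (molar).
#' @param duration total simulated time (s).
#' @param dt time step (s).
#' @param mode `"isometric"`, `"ktr_slack_restretch"` or `"slack_only"`.
#' @param t_slack time of the step release (s).
#' @param slack_duration unloaded interval before restretch (s).
#' @param slack_fraction fractional length release, in (0, 0.5].
#' @param seed RNG seed for the Monte-Carlo engine.
#' @return A `sim_protocol` list.
#' @export
sim_protocol <- function(sarcomere_length = 1.9, pCa = 4.8, duration = 4,
                         dt = 5e-4,
                         mode = c("isometric", "ktr_slack_restretch",
                                  "slack_only"),
                         t_slack = 0.6 * duration, slack_duration = 0.02,
                         slack_fraction = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  if (slack_fraction <= 0 || slack_fraction > 0.5) {
    stop("`slack_fraction` must lie in (0, 0.5].", call. = FALSE)
  }
  structure(list(sarcomere_length = sarcomere_length, pCa = pCa,
                 duration = duration, dt = dt, mode = mode,
                 t_slack = t_slack, slack_duration = slack_duration,
                 slack_fraction = slack_fraction, seed = seed),
            class = "sim_protocol")
}

# ---- internal: class decomposition --------------------------------------

# Aggregate the half filament into (zone, role, phospho) head classes.
# phospho_map: "all", "none", or an occupancy map (per-crown phosphorylated
# fraction); per zone the head-weighted mean occupancy q splits the class
# into phosphorylated (weight q) and unphosphorylated (1 - q) subclasses.
build_classes <- function(geom, params, variant, phospho_map, sl_um) {
  crowns <- geometry_table(geom)
  occ <- if (identical(phospho_map, "all")) rep(1, nrow(crowns))
  else if (identical(phospho_map, "none")) rep(0, nrow(crowns))
  else if (is.data.frame(phospho_map) && "occupancy" %in% names(phospho_map)) {
    stopifnot(nrow(phospho_map) == nrow(crowns))
    phospho_map$occupancy
  } else stop("`phospho_map` must be \"all\", \"none\" or an occupancy map.",
              call. = FALSE)

  ov <- crown_overlap(crowns$position_nm, geom$thin_filament_length, sl_um)
  zinfo <- tibble::tibble(zone = crowns$zone, occ = occ, ov = ov,
                          heads = crowns$heads) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      q = if (sum(.data$heads) > 0) sum(.data$occ * .data$heads) / sum(.data$heads) else 0,
      overlap = if (sum(.data$heads) > 0) sum(.data$ov * .data$heads) / sum(.data$heads) else 0,
      heads = sum(.data$heads),
      .groups = "drop"
    )

  cls <- tidyr::expand_grid(
    zone = factor(c("P", "C", "D"), levels = c("P", "C", "D")),
    role = c("blocked", "free"),
    phospho = c(TRUE, FALSE)
  ) |>
    dplyr::left_join(zinfo, by = "zone") |>
    dplyr::mutate(
      heads = .data$heads / 2 * ifelse(.data$phospho, .data$q, 1 - .data$q),
      g = ifelse(.data$phospho &
                   as.character(.data$zone) %in% variant$target_zones &
                   .data$role %in% variant$target_roles,
                 params$phi_P, 1)
    ) |>
    dplyr::filter(.data$heads > 0)
  cls
}

# fraction of each crown overlapped by the (inextensible) thin filament
crown_overlap <- function(position_nm, thin_len_um, sl_um) {
  z_tip <- sl_um * 1000 / 2 - thin_len_um * 1000  # thin filament tip, nm from M-line
  as.numeric(position_nm >= z_tip)
}

# steady-state thin-filament activation (mean field): solves
# a_kon*Ca*(1 + 2*a_coop*a)*(1 - a) = koff_eff*a for a in [0, 1],
# with koff_eff = a_koff*(1 - fg_attached)^a_hold supplied by the caller
thin_activation_ss <- function(Ca_uM, params, koff_eff = params$a_koff) {
  kap <- params$a_kon * Ca_uM
  cc <- 2 * params$a_coop
  # -cc*kap*a^2 + (cc*kap - kap - a_koff)*a + kap = 0
  A <- -cc * kap
  B <- cc * kap - kap - koff_eff
  C <- kap
  disc <- sqrt(pmax(0, B^2 - 4 * A * C))
  a <- ifelse(abs(A) < 1e-14,
              ifelse(abs(B) < 1e-14, 0, -C / B),
              (-B - disc) / (2 * A))
  pmin(1, pmax(0, a))
}

# vectorized steady-state force over a pCa grid by monotone fixed-point
# iteration of the coupled (activation, force) system from the relaxed state
# upward (the lowest stable fixed point, the one the relaxed-start ODE
# reaches)
steady_force <- function(pCa, sl_um, cls, params) {
  Ca <- 10^(-pCa) * 1e6
  passive <- params$passive_gain * max(0, sl_um - params$sl_slack)
  r_attach <- params$k3 * cls$overlap / params$k4   # per class, times a
  w_ov <- cls$heads * cls$overlap
  w_ov <- if (sum(w_ov) > 0) w_ov / sum(w_ov) else cls$heads / sum(cls$heads)
  Fv <- rep(passive, length(pCa))
  a <- rep(0, length(pCa))
  fg <- matrix(0, nrow(cls), length(pCa))
  for (it in seq_len(20000)) {
    k1 <- params$k1_0 * (1 + outer(cls$g, pmax(0, Fv)) * params$k_force)
    ra <- outer(r_attach, a)                         # class x pCa
    fg <- ra / (1 + params$k2 / k1 + ra)
    fg_w <- as.numeric(w_ov %*% fg)                  # attached fraction felt by units
    koff_eff <- params$a_koff * (1 - pmin(1, fg_w))^params$a_hold
    a_new <- thin_activation_ss(Ca, params, koff_eff)
    Fa <- params$f_head * colSums(cls$heads * fg)
    Fn <- passive + Fa
    if (max(abs(Fn - Fv)) < 1e-9 && max(abs(a_new - a)) < 1e-11) {
      Fv <- Fn; a <- a_new; break
    }
    Fv <- Fn; a <- a_new
  }
  list(force_active = Fv - passive, force_sense = Fv, a = a,
       fg = fg, passive = passive)
}

overlap_weights <- function(cls) {
  w <- cls$heads * cls$overlap
  if (sum(w) > 0) w / sum(w) else cls$heads / sum(cls$heads)
}

# ---- mean-field ODE engine ----------------------------------------------

mean_field_derivs <- function(t, y, ctx) {
  p <- ctx$params
  nc <- nrow(ctx$cls)
  a <- y[1]
  on <- y[2:(nc + 1)]
  fg <- y[(nc + 2):(2 * nc + 1)]
  off <- 1 - on - fg
  Fa <- p$f_head * sum(ctx$cls$heads * fg)
  F_sense <- if (ctx$unloaded) 0 else Fa + ctx$passive
  k1 <- p$k1_0 * (1 + ctx$cls$g * p$k_force * max(0, F_sense))
  att <- p$k3 * ctx$a_gate * ctx$cls$overlap * a
  d_on <- k1 * off - p$k2 * on - att * on + p$k4 * fg
  d_fg <- att * on - p$k4 * fg
  fg_w <- sum(ctx$w_ov * fg)
  koff_eff <- p$a_koff * (1 - min(1, fg_w))^p$a_hold
  d_a <- p$a_kon * ctx$Ca * (1 + 2 * p$a_coop * a) * (1 - a) - koff_eff * a
  list(c(d_a, d_on, d_fg))
}

integrate_phase <- function(y0, times, ctx) {
  out <- deSolve::ode(y = y0, times = times, func = mean_field_derivs,
                      parms = ctx, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (anyNA(out)) stop("Mean-field integration failed (NaN state).", call. = FALSE)
  out
}

#' Deterministic mean-field half-sarcomere simulation
#'
#' Integrates the zone/role-aggregated ODEs of the kinetic scheme with a
#' self-consistent force term. Deterministic counterpart of
#' [run_simulation()]; same rate laws, same protocols.
#'
#' @param geom a [build_half_filament()] geometry.
#' @param params [sarcomere_params()].
#' @param variant [model_variant()].
#' @param phospho_map `"all"`, `"none"`, or an occupancy map from
#'   [occupancy_from_level()].
#' @param protocol [sim_protocol()].
#' @param init_occ optional named vector `c(on = , fg = )`: initial ON and FG
#'   occupancy applied to every head class (default all heads OFF). The
#'   steady state is independent of this split.
#' @return A `sim_result`: `trace` tibble (`t_s`, `force_pN`, `a_thin`,
#'   `off`, `on`, `fg` head-weighted fractions), per-class occupancy array
#'   `class_occ`, the class table, and protocol `events`.
#' @export
mean_field_simulate <- function(geom, params = sarcomere_params(),
                                variant = model_variant("A"),
                                phospho_map = "none",
                                protocol = sim_protocol(),
                                init_occ = c(on = 0, fg = 0)) {
  stopifnot(inherits(protocol, "sim_protocol"))
  cls <- build_classes(geom, params, variant, phospho_map,
                       protocol$sarcomere_length)
  sl <- protocol$sarcomere_length
  passive <- params$passive_gain * max(0, sl - params$sl_slack)
  ctx <- list(params = params, cls = cls, Ca = 10^(-protocol$pCa) * 1e6,
              passive = passive, unloaded = FALSE, a_gate = 1,
              w_ov = overlap_weights(cls))
  nc <- nrow(cls)
  if (init_occ[["on"]] + init_occ[["fg"]] > 1) {
    stop("Initial ON + FG occupancy cannot exceed 1.", call. = FALSE)
  }
  y0 <- c(0, rep(init_occ[["on"]], nc), rep(init_occ[["fg"]], nc))

  grid <- function(t0, t1) {
    ts <- seq(t0, t1, by = protocol$dt)
    if (ts[length(ts)] < t1 - 1e-12) ts <- c(ts, t1)
    ts
  }

  events <- c()
  if (protocol$mode == "isometric") {
    out <- integrate_phase(y0, grid(0, protocol$duration), ctx)
  } else {
    t_sl <- protocol$t_slack
    if (t_sl <= 0 || t_sl >= protocol$duration) {
      stop("`t_slack` must fall inside the protocol duration.", call. = FALSE)
    }
    ph1 <- integrate_phase(y0, grid(0, t_sl), ctx)
    y1 <- ph1[nrow(ph1), -1]
    ctx2 <- ctx
    ctx2$unloaded <- TRUE
    sl_short <- sl * (1 - protocol$slack_fraction)
    ctx2$cls <- build_classes(geom, params, variant, phospho_map, sl_short)
    ctx2$w_ov <- overlap_weights(ctx2$cls)
    if (protocol$mode == "slack_only") {
      ph2 <- integrate_phase(y1, grid(t_sl, protocol$duration), ctx2)
      out <- rbind(ph1, ph2[-1, ])
      events <- c(release = t_sl)
      attr(out, "unloaded_from") <- t_sl
    } else {
      t_re <- t_sl + protocol$slack_duration
      if (t_re >= protocol$duration) {
        stop("Restretch falls outside the protocol duration.", call. = FALSE)
      }
      ph2 <- integrate_phase(y1, grid(t_sl, t_re), ctx2)
      y2 <- ph2[nrow(ph2), -1]
      # restretch forcibly detaches attached heads: FG -> ON
      on2 <- y2[2:(nc + 1)] + y2[(nc + 2):(2 * nc + 1)]
      y3 <- c(y2[1], on2, rep(0, nc))
      ph3 <- integrate_phase(y3, grid(t_re, protocol$duration), ctx)
      # keep ph3's first row so the restretch instant reflects the
      # post-detachment state
      out <- rbind(ph1, ph2[-c(1, nrow(ph2)), ], ph3)
      events <- c(release = t_sl, restretch = t_re)
      attr(out, "unloaded_from") <- t_sl
      attr(out, "unloaded_to") <- t_re
    }
  }

  finalize_sim(out, cls, params, protocol, events, engine = "mean_field")
}

finalize_sim <- function(out, cls, params, protocol, events, engine) {
  nc <- nrow(cls)
  t_s <- out[, 1]
  a <- out[, 2]
  on <- out[, 3:(nc + 2), drop = FALSE]
  fg <- out[, (nc + 3):(2 * nc + 2), drop = FALSE]
  off <- 1 - on - fg
  wt <- cls$heads / sum(cls$heads)
  Fa <- params$f_head * as.numeric(fg %*% cls$heads)
  # recorded force is zero while the preparation is unloaded
  loaded <- rep(TRUE, length(t_s))
  u0 <- attr(out, "unloaded_from")
  u1 <- attr(out, "unloaded_to")
  if (!is.null(u0)) {
    loaded <- t_s < u0 | (if (!is.null(u1)) t_s >= u1 else FALSE)
  }
  force <- ifelse(loaded, Fa, 0)

  trace <- tibble::tibble(
    t_s = t_s, force_pN = force, a_thin = a,
    off = as.numeric(off %*% wt),
    on = as.numeric(on %*% wt),
    fg = as.numeric(fg %*% wt)
  )
  class_occ <- array(c(off, on, fg),
                     dim = c(length(t_s), nc, 3),
                     dimnames = list(NULL, NULL, c("OFF", "ON", "FG")))
  structure(list(trace = trace, class_occ = class_occ, classes = cls,
                 events = events, params = params, protocol = protocol,
                 engine = engine),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trace
  cat("<sim_result> ", x$engine, " engine, mode ", x$protocol$mode,
      ", pCa ", x$protocol$pCa, ", SL ", x$protocol$sarcomere_length, " um\n",
      sep = "")
  cat(sprintf("  final force %.1f pN; final occupancies OFF %.3f ON %.3f FG %.3f\n",
              tr$force_pN[nrow(tr)], tr$off[nrow(tr)], tr$on[nrow(tr)],
              tr$fg[nrow(tr)]))
  invisible(x)
}

#' Stochastic per-head half-sarcomere simulation
#'
#' Advances every myosin head (1 thick filament: crowns x dimers x 2 heads)
#' and every thin-filament regulatory unit (2 thin filaments x 26 units of 7
#' actins) by fixed-step tau-leaping. Head transition probabilities are
#' `rate * dt` (the step errors out if any head rate times `dt` exceeds 0.1);
#' regulatory-unit switching uses the exact exponential probability
#' `1 - exp(-rate dt)` because calcium binding can be much faster than the
#' head cycle. Nearest-neighbour cooperativity scales a unit's activation
#' rate by `1 + a_coop * n_active_neighbours`.
#'
#' @inheritParams mean_field_simulate
#' @return A `sim_result` (same shape as [mean_field_simulate()]).
#' @export
run_simulation <- function(geom, params = sarcomere_params(),
                           variant = model_variant("A"),
                           phospho_map = "none",
                           protocol = sim_protocol()) {
  stopifnot(inherits(protocol, "sim_protocol"))
  set.seed(protocol$seed)
  dt <- protocol$dt
  p <- params
  heads <- head_addresses(geom)
  n_heads <- nrow(heads)

  # phosphorylation flags per head
  occ <- if (identical(phospho_map, "all")) rep(1, geom$n_crowns_half)
  else if (identical(phospho_map, "none")) rep(0, geom$n_crowns_half)
  else phospho_map$occupancy
  phos <- runif(n_heads) < occ[heads$crown]
  g <- ifelse(phos & as.character(heads$zone) %in% variant$target_zones &
                as.character(heads$role) %in% variant$target_roles,
              p$phi_P, 1)

  sl <- protocol$sarcomere_length
  ov <- crown_overlap(heads$position_nm, geom$thin_filament_length, sl)
  passive <- p$passive_gain * max(0, sl - p$sl_slack)
  Ca <- 10^(-protocol$pCa) * 1e6

  # thin-filament units: 2 filaments x 26 units; head -> unit by axial position
  n_units <- 26L
  u_len <- geom$thin_filament_length * 1000 / n_units
  unit_of <- function(pos_nm, sl_um) {
    z <- sl_um * 1000 / 2 - pos_nm        # distance from the Z-line
    u <- ceiling(z / u_len)
    u[u < 1L | u > n_units] <- NA_integer_
    u
  }
  tf <- rep_len(c(1L, 2L), n_heads)       # alternate dimers between filaments
  head_unit <- unit_of(heads$position_nm, sl)
  unit_active <- matrix(FALSE, nrow = 2, ncol = n_units)

  # per-head max rate check (tau-leap validity)
  max_k1 <- p$k1_0 * (1 + max(g) * p$k_force *
                        (passive + p$f_head * n_heads))
  if (max(p$k2, p$k3, p$k4, max_k1) * dt > 0.1) {
    stop("`dt` too large: a head transition rate times dt exceeds 0.1.",
         call. = FALSE)
  }

  n_steps <- ceiling(protocol$duration / dt)
  t_s <- (0:n_steps) * dt
  state <- rep(0L, n_heads)   # 0 OFF, 1 ON, 2 FG
  t_sl <- protocol$t_slack
  t_re <- t_sl + protocol$slack_duration
  has_slack <- protocol$mode != "isometric"
  has_restretch <- protocol$mode == "ktr_slack_restretch"
  if (has_slack && (t_sl <= 0 || t_sl >= protocol$duration)) {
    stop("`t_slack` must fall inside the protocol duration.", call. = FALSE)
  }
  sl_short <- sl * (1 - protocol$slack_fraction)
  ov_short <- crown_overlap(heads$position_nm, geom$thin_filament_length, sl_short)
  unit_short <- unit_of(heads$position_nm, sl_short)

  # class bookkeeping for occupancy traces
  cls_id <- interaction(heads$zone, heads$role, phos, drop = TRUE)
  nc <- nlevels(cls_id)
  cls_idx <- as.integer(cls_id)
  cls_n <- tabulate(cls_idx, nc)

  force_tr <- numeric(n_steps + 1)
  a_tr <- numeric(n_steps + 1)
  occ_tr <- array(0, dim = c(n_steps + 1, nc, 3),
                  dimnames = list(NULL, levels(cls_id), c("OFF", "ON", "FG")))
  record <- function(i, state, loaded) {
    Fa <- p$f_head * sum(state == 2L)
    force_tr[i] <<- if (loaded) Fa else 0
    a_tr[i] <<- mean(unit_active)
    for (s in 0:2) {
      occ_tr[i, , s + 1] <<- tabulate(cls_idx[state == s], nc) / cls_n
    }
  }
  record(1, state, TRUE)

  events <- c()
  if (has_slack) events <- c(release = t_sl)
  if (has_restretch) events <- c(events, restretch = t_re)

  for (i in seq_len(n_steps)) {
    t_now <- t_s[i]
    unloaded <- has_slack && t_now >= t_sl &&
      (!has_restretch || t_now < t_re)
    ov_i <- if (unloaded) ov_short else ov
    unit_i <- if (unloaded) unit_short else head_unit

    # restretch: forcibly detach all attached heads
    if (has_restretch && t_s[i] < t_re && t_s[i + 1] >= t_re) {
      state[state == 2L] <- 1L
    }

    Fa <- p$f_head * sum(state == 2L)
    F_sense <- if (unloaded) 0 else Fa + passive

    # thin-filament units (exact exponential switch probabilities);
    # attached heads hold their regulatory unit active
    uidx <- (unit_i - 1L) * 2L + tf
    att <- tabulate(uidx[state == 2L & !is.na(uidx)], 2L * n_units)
    tot <- tabulate(uidx[!is.na(uidx)], 2L * n_units)
    f_att <- ifelse(tot > 0, att / tot, 0)
    hold <- matrix((1 - f_att)^p$a_hold, nrow = 2)
    left <- cbind(FALSE, unit_active[, -n_units, drop = FALSE])
    right <- cbind(unit_active[, -1, drop = FALSE], FALSE)
    n_nb <- left + right
    r_on <- p$a_kon * Ca * (1 + p$a_coop * n_nb)
    p_on <- 1 - exp(-r_on * dt)
    p_off <- 1 - exp(-p$a_koff * hold * dt)
    u <- matrix(runif(2 * n_units), nrow = 2)
    newly_on <- !unit_active & u < p_on
    newly_off <- unit_active & u < p_off
    unit_active <- (unit_active | newly_on) & !newly_off

    # heads
    k1 <- p$k1_0 * (1 + g * p$k_force * max(0, F_sense))
    r <- runif(n_heads)
    off_i <- state == 0L
    state[off_i & r < k1 * dt] <- 1L
    on_i <- state == 1L & !off_i
    thin_on <- !is.na(unit_i) &
      unit_active[cbind(tf, ifelse(is.na(unit_i), 1L, unit_i))]
    p_attach <- p$k3 * ov_i * as.numeric(thin_on) * dt
    p_detach_on <- p$k2 * dt
    # competing exits from ON: partition one uniform draw
    go_off <- on_i & r < p_detach_on
    go_fg <- on_i & !go_off & r < p_detach_on + p_attach
    state[go_off] <- 0L
    state[go_fg] <- 2L
    fg_i <- state == 2L & !go_fg
    state[fg_i & r < p$k4 * dt] <- 1L

    loaded <- !(has_slack && t_s[i + 1] >= t_sl &&
                  (!has_restretch || t_s[i + 1] < t_re))
    record(i + 1, state, loaded)
  }

  wt <- cls_n / sum(cls_n)
  trace <- tibble::tibble(
    t_s = t_s, force_pN = force_tr, a_thin = a_tr,
    off = as.numeric(occ_tr[, , "OFF"] %*% wt),
    on = as.numeric(occ_tr[, , "ON"] %*% wt),
    fg = as.numeric(occ_tr[, , "FG"] %*% wt)
  )
  cls_tab <- tibble::tibble(class = levels(cls_id), heads = cls_n)
  structure(list(trace = trace, class_occ = occ_tr, classes = cls_tab,
                 events = events, params = params, protocol = protocol,
                 engine = "monte_carlo"),
            class = "sim_result")
}
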