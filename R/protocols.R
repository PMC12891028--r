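#' Fit the Hill equation to force-pCa points
#'
#' `F(pCa) = F_max / (1 + 10^(n_H (pCa - pCa50)))`: `pCa50` is the calcium
#' sensitivity (-log10 Ca for half-maximal force) and `n_H` the
#' steepness/cooperativity.
#'
#' @param pCa pCa values (>= 6 points spanning the transition).
#' @param force forces (any scale; `F_max` is fitted).
#' @return A `hill_fit` with `F_max`, `pCa50`, `n_H`, `rss`.
#' @export
fit_hill <- function(pCa, force) {
  if (length(pCa) < 6L) stop("Need at least 6 pCa points.", call. = FALSE)
  dat <- data.frame(pCa = pCa, y = force)
  mid <- pCa[which.min(abs(force - max(force) / 2))]
  starts <- list(
    list(Fmax = max(force), pCa50 = mid, nH = 4),
    list(Fmax = max(force), pCa50 = mid, nH = 2),
    list(Fmax = max(force), pCa50 = mean(range(pCa)), nH = 8)
  )
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Fmax / (1 + 10^(nH * (pCa - pCa50))),
                        data = dat, start = s,
                        lower = c(0, min(pCa) - 2, 0.1),
                        upper = c(Inf, max(pCa) + 2, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Hill fit failed to converge.", call. = FALSE)
  cf <- coef(fit)
  if (cf["pCa50"] <= min(pCa) || cf["pCa50"] >= max(pCa)) {
    warning("Fitted pCa50 lies at the edge of the pCa range: ",
            "data may not be sigmoidal.", call. = FALSE)
  }
  structure(list(F_max = unname(cf["Fmax"]), pCa50 = unname(cf["pCa50"]),
                 n_H = unname(cf["nH"]), rss = sum(residuals(fit)^2),
                 fit = fit),
            class = "hill_fit")
}

#' Hill-equation forces at given pCa
#' @param pCa pCa values.
#' @param pCa50,n_H,F_max Hill parameters.
#' @return Numeric force vector.
#' @export
hill_force <- function(pCa, pCa50, n_H, F_max = 1) {
  F_max / (1 + 10^(n_H * (pCa - pCa50)))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> pCa50 = %.3f, n_H = %.2f, F_max = %.4g\n",
              x$pCa50, x$n_H, x$F_max))
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("F_max", "pCa50", "n_H"),
                 estimate = c(x$F_max, x$pCa50, x$n_H))
}

#' @rdname tidy-sarcphos
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(pCa50 = x$pCa50, n_H = x$n_H, F_max = x$F_max, rss = x$rss)
}

#' Steady-state force-pCa relation of the half-sarcomere model
#'
#' Computes the steady active force at each pCa and fits the Hill equation.
#' Three engines share the same rate laws: `"mean_field_ss"` solves the
#' self-consistent steady state algebraically (fast, used inside fitting),
#' `"mean_field"` integrates the ODEs and averages the last 20% of the trace,
#' `"monte_carlo"` does the same on the stochastic per-head engine.
#'
#' @inheritParams mean_field_simulate
#' @param sl_um sarcomere length (um).
#' @param pCa_grid pCa values spanning the transition (>= 6 points).
#' @param engine `"mean_field_ss"`, `"mean_field"` or `"monte_carlo"`.
#' @param duration,dt,seed passed to the trace engines.
#' @return A `force_pca` object: `points` tibble (`pCa`, `force_pN`,
#'   `force_norm`) and the `hill_fit`.
#' @export
force_pca_curve <- function(geom, params = sarcomere_params(),
                            variant = model_variant("A"),
                            phospho_map = "none", sl_um = 1.9,
                            pCa_grid = seq(6.4, 4.8, by = -0.2),
                            engine = c("mean_field_ss", "mean_field",
                                       "monte_carlo"),
                            duration = 4, dt = 5e-4, seed = 1L) {
  engine <- match.arg(engine)
  if (length(pCa_grid) < 6L) stop("`pCa_grid` needs >= 6 points.", call. = FALSE)
  if (engine == "mean_field_ss") {
    cls <- build_classes(geom, params, variant, phospho_map, sl_um)
    force <- steady_force(pCa_grid, sl_um, cls, params)$force_active
  } else {
    runner <- if (engine == "mean_field") mean_field_simulate else run_simulation
    force <- vapply(pCa_grid, function(pca) {
      prot <- sim_protocol(sarcomere_length = sl_um, pCa = pca,
                           duration = duration, dt = dt, mode = "isometric",
                           seed = seed)
      tr <- runner(geom, params, variant, phospho_map, prot)$trace
      tail_i <- tr$t_s >= 0.8 * duration
      mean(tr$force_pN[tail_i])
    }, numeric(1))
  }
  fit <- fit_hill(pCa_grid, force)
  points <- tibble::tibble(pCa = pCa_grid, force_pN = force,
                           force_norm = force / fit$F_max)
  structure(list(points = points, fit = fit, sl_um = sl_um, engine = engine),
            class = "force_pca")
}

#' @export
print.force_pca <- function(x, ...) {
  cat(sprintf("<force_pca> SL %.2f um, %s engine: pCa50 = %.3f, n_H = %.2f\n",
              x$sl_um, x$engine, x$fit$pCa50, x$fit$n_H))
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.force_pca <- function(x, ...) x$points

#' @rdname tidy-sarcphos
#' @export
glance.force_pca <- function(x, ...) {
  tibble::tibble(sl_um = x$sl_um, engine = x$engine,
                 pCa50 = x$fit$pCa50, n_H = x$fit$n_H, F_max = x$fit$F_max)
}

#' Rate of force redevelopment after a slack-restretch maneuver
#'
#' Runs a `ktr_slack_restretch` protocol and fits a single exponential
#' `F(t) = F_plateau - (F_plateau - F0) exp(-k_tr (t - t_restretch))` to the
#' force redevelopment after the restretch.
#'
#' @inheritParams mean_field_simulate
#' @param engine `"mean_field"` or `"monte_carlo"`.
#' @return A `ktr_fit` with `k_tr` (s^-1), `F_plateau` (pN), plus the
#'   underlying `sim_result`.
#' @export
ktr_protocol <- function(geom, params = sarcomere_params(),
                         variant = model_variant("A"),
                         phospho_map = "none",
                         protocol = sim_protocol(mode = "ktr_slack_restretch"),
                         engine = c("mean_field", "monte_carlo")) {
  engine <- match.arg(engine)
  if (protocol$mode != "ktr_slack_restretch") {
    stop("ktr requires `mode = \"ktr_slack_restretch\"` ",
         "(a slack-only release has no restretch, so k_tr is undefined).",
         call. = FALSE)
  }
  runner <- if (engine == "mean_field") mean_field_simulate else run_simulation
  sim <- runner(geom, params, variant, phospho_map, protocol)
  fit <- fit_force_redevelopment(sim)
  structure(c(fit, list(sim = sim)), class = "ktr_fit")
}

fit_force_redevelopment <- function(sim) {
  tr <- sim$trace
  t_re <- sim$events[["restretch"]]
  t_sl <- sim$events[["release"]]
  pre <- tr$force_pN[tr$t_s < t_sl]
  plateau_pre <- mean(pre[seq.int(max(1, length(pre) - 20), length(pre))])
  post <- tr[tr$t_s >= t_re, ]
  amp <- max(post$force_pN) - post$force_pN[1]
  if (amp < 0.05 * plateau_pre) {
    stop("No force redevelopment (amplitude < 5% of the prior plateau).",
         call. = FALSE)
  }
  dat <- data.frame(ts = post$t_s - t_re, y = post$force_pN)
  s <- list(Fp = max(post$force_pN), F0 = post$force_pN[1], k = 10)
  fit <- minpack.lm::nlsLM(y ~ Fp - (Fp - F0) * exp(-k * ts), data = dat,
                           start = s, lower = c(0, 0, 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(k_tr = unname(cf["k"]), F_plateau = unname(cf["Fp"]),
       F_pre = plateau_pre, rss = sum(residuals(fit)^2))
}

#' @export
print.ktr_fit <- function(x, ...) {
  cat(sprintf("<ktr_fit> k_tr = %.2f s^-1, plateau %.1f pN (pre-release %.1f pN)\n",
              x$k_tr, x$F_plateau, x$F_pre))
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
glance.ktr_fit <- function(x, ...) {
  tibble::tibble(k_tr = x$k_tr, F_plateau = x$F_plateau, F_pre = x$F_pre)
}
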