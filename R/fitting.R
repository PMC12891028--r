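#' Reconstruct experimental force-pCa targets as Hill curves
#'
#' The four experimental conditions (short/long sarcomere length, before/after
#' RLC phosphorylation) are represented as Hill curves through the published
#' calcium sensitivities: pCa50 5.56 and 5.64 at SL 1.9 um (shift +0.08) and
#' 5.64 and 5.76 at SL 2.3 um (shift +0.12). Steepness values are fixtures:
#' n_H = 4 everywhere except the phosphorylated long-SL condition (n_H = 2.8),
#' whose cooperativity is reduced after phosphorylation.
#'
#' @param pCa_grid pCa values for every condition.
#' @param sigma observation noise (normalized force units).
#' @return Tibble with `sl_um`, `phos` (logical), `pCa`, `force_norm`,
#'   `sigma` — the fitting target format.
#' @export
build_fit_targets <- function(pCa_grid = seq(6.4, 4.8, by = -0.2),
                              sigma = 0.03) {
  conds <- tibble::tibble(
    sl_um = c(1.9, 1.9, 2.3, 2.3),
    phos = c(FALSE, TRUE, FALSE, TRUE),
    pCa50 = c(5.56, 5.64, 5.64, 5.76),
    n_H = c(4, 4, 4, 2.8)
  )
  conds |>
    tidyr::expand_grid(pCa = pCa_grid) |>
    dplyr::mutate(force_norm = hill_force(.data$pCa, .data$pCa50, .data$n_H),
                  sigma = sigma) |>
    dplyr::select("sl_um", "phos", "pCa", "force_norm", "sigma")
}

#' Calibrate the unphosphorylated operating point
#'
#' Root-finds `a_kon` so the unphosphorylated model's pCa50 at SL 1.9 um
#' matches `pCa50_short`, then `passive_gain` so the pCa50 at SL 2.3 um
#' matches `pCa50_long`. Because passive force only develops above the slack
#' length (1.9 um by default), the two 1D root-finds are nested, not coupled.
#' Tolerance 0.005 pCa units; idempotent on already-calibrated parameters.
#'
#' @param geom a [build_half_filament()] geometry.
#' @param params starting [sarcomere_params()].
#' @param pCa50_short,pCa50_long target calcium sensitivities.
#' @param pCa_grid grid used to measure pCa50.
#' @param a_kon_range,passive_range bracketing intervals.
#' @return Calibrated `sarcomere_params`.
#' @export
calibrate_baseline <- function(geom, params = sarcomere_params(),
                               pCa50_short = 5.56, pCa50_long = 5.64,
                               pCa_grid = seq(6.4, 4.8, by = -0.2),
                               a_kon_range = c(0.05, 100),
                               passive_range = c(0, 6000)) {
  none <- model_variant("none")
  pca50_at <- function(pars, sl) {
    suppressWarnings(
      force_pca_curve(geom, pars, none, "none", sl, pCa_grid)$fit$pCa50
    )
  }
  f1 <- function(log_akon) {
    pars <- params; pars$a_kon <- 10^log_akon
    pca50_at(pars, 1.9) - pCa50_short
  }
  r1 <- tryCatch(
    uniroot(f1, log10(a_kon_range), tol = 1e-4),
    error = function(e) stop("`a_kon` root not bracketed in [",
                             a_kon_range[1], ", ", a_kon_range[2],
                             "]: requested pCa50 unreachable.", call. = FALSE)
  )
  params$a_kon <- 10^r1$root

  f2 <- function(pg) {
    pars <- params; pars$passive_gain <- pg
    pca50_at(pars, 2.3) - pCa50_long
  }
  r2 <- tryCatch(
    uniroot(f2, passive_range, tol = 1e-2),
    error = function(e) stop("`passive_gain` root not bracketed: requested ",
                             "long-SL pCa50 unreachable.", call. = FALSE)
  )
  params$passive_gain <- r2$root

  achieved_s <- pca50_at(params, 1.9)
  achieved_l <- pca50_at(params, 2.3)
  if (abs(achieved_s - pCa50_short) > 0.005 ||
      abs(achieved_l - pCa50_long) > 0.005) {
    stop("Calibration did not converge to within 0.005 pCa.", call. = FALSE)
  }
  params
}

#' Model normalized force-pCa predictions for a set of target conditions
#'
#' @keywords internal
predict_targets <- function(geom, params, variant, targets) {
  conds <- dplyr::distinct(targets, .data$sl_um, .data$phos)
  purrr::pmap_dfr(conds, function(sl_um, phos) {
    rows <- targets[targets$sl_um == sl_um & targets$phos == phos, ]
    fp <- suppressWarnings(force_pca_curve(
      geom, params, variant, if (phos) "all" else "none",
      sl_um, rows$pCa, engine = "mean_field_ss"
    ))
    dplyr::mutate(rows, model = fp$points$force_norm)
  })
}

#' Log-likelihood of simulator parameters against force-pCa targets
#'
#' Gaussian likelihood `-1/2 sum(((model - data) / sigma)^2)` over all curve
#' points, using the deterministic mean-field steady-state engine, plus
#' log-uniform priors on the free parameters within their bounds.
#'
#' @param theta named vector of free parameters on log10 scale (names among
#'   those of [sarcomere_params()]; the headline fit frees `phi_P` and
#'   `k_force`).
#' @param geom,params,variant model context; `params` supplies the fixed
#'   values.
#' @param targets tibble from [build_fit_targets()].
#' @param bounds named list of `c(lower, upper)` (natural scale) per free
#'   parameter.
#' @return Scalar log-posterior (`-Inf` outside bounds or on simulation
#'   failure).
#' @export
log_likelihood <- function(theta, geom, params, variant, targets,
                           bounds = default_fit_bounds()) {
  for (nm in names(theta)) {
    v <- 10^theta[[nm]]
    b <- bounds[[nm]]
    if (is.null(b)) stop("No bounds for parameter ", nm, call. = FALSE)
    if (v < b[1] || v > b[2]) return(-Inf)
    params[[nm]] <- v
  }
  pred <- tryCatch(predict_targets(geom, params, variant, targets),
                   error = function(e) NULL)
  if (is.null(pred)) {
    warning("Simulation failed during likelihood evaluation.", call. = FALSE)
    return(-Inf)
  }
  # log-uniform prior in the bounds is flat on the log10 scale
  -0.5 * sum(((pred$model - pred$force_norm) / pred$sigma)^2)
}

#' @rdname log_likelihood
#' @export
default_fit_bounds <- function() {
  list(phi_P = c(1, 40), k_force = c(1e-4, 0.2))
}

#' Affine-invariant ensemble MCMC (stretch move)
#'
#' The Goodman-Weare ensemble sampler: each walker is updated by stretching
#' past a randomly chosen companion walker with scale `z ~ g(z) propto
#' 1/sqrt(z)` on `[1/a, a]`, accepted with probability
#' `z^(d-1) exp(lp_new - lp_old)`. Chains are exactly reproducible given
#' `seed`, `n_walkers` and `n_steps`.
#'
#' @param log_post function taking a named log10-scale parameter vector and
#'   returning the log-posterior.
#' @param init named vector, log10-scale center of the initial walker cloud.
#' @param n_walkers number of walkers (>= 2 x number of parameters).
#' @param n_steps number of ensemble steps.
#' @param seed RNG seed.
#' @param a stretch scale (default 2).
#' @param init_spread s.d. of the initial cloud (log10 units).
#' @param burn_in steps discarded by [tidy.ensemble_mcmc()] and the MAP
#'   summary (the raw chain is kept).
#' @return An `ensemble_mcmc` object: `chain` array (step x walker x param),
#'   `log_post` matrix, `acceptance` fraction, `map` (named vector, natural
#'   scale), `burn_in`.
#' @export
run_ensemble_mcmc <- function(log_post, init, n_walkers = 16, n_steps = 150,
                              seed = 1L, a = 2, init_spread = 0.05,
                              burn_in = ceiling(n_steps / 3)) {
  d <- length(init)
  if (n_walkers < 2 * d) stop("Need at least 2 walkers per parameter.",
                              call. = FALSE)
  set.seed(seed)
  nm <- names(init)
  pos <- matrix(rnorm(n_walkers * d, mean = rep(init, each = n_walkers),
                      sd = init_spread),
                nrow = n_walkers, dimnames = list(NULL, nm))
  lp <- apply(pos, 1, function(th) log_post(setNames(th, nm)))
  tries <- 0
  while (any(!is.finite(lp)) && tries < 50) {
    bad <- !is.finite(lp)
    pos[bad, ] <- matrix(rnorm(sum(bad) * d, mean = rep(init, each = sum(bad)),
                               sd = init_spread), ncol = d)
    lp[bad] <- apply(pos[bad, , drop = FALSE], 1,
                     function(th) log_post(setNames(th, nm)))
    tries <- tries + 1
  }
  if (any(!is.finite(lp))) {
    stop("Could not initialize all walkers at finite log-posterior.",
         call. = FALSE)
  }

  chain <- array(NA_real_, dim = c(n_steps, n_walkers, d),
                 dimnames = list(NULL, NULL, nm))
  lp_tr <- matrix(NA_real_, n_steps, n_walkers)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (k in seq_len(n_walkers)) {
      j <- sample(seq_len(n_walkers)[-k], 1L)
      z <- (1 + (a - 1) * runif(1))^2 / a
      prop <- pos[j, ] + z * (pos[k, ] - pos[j, ])
      lp_new <- log_post(setNames(prop, nm))
      log_acc <- (d - 1) * log(z) + lp_new - lp[k]
      if (is.finite(lp_new) && log(runif(1)) < log_acc) {
        pos[k, ] <- prop
        lp[k] <- lp_new
        n_acc <- n_acc + 1L
      }
    }
    chain[s, , ] <- pos
    lp_tr[s, ] <- lp
  }
  acceptance <- n_acc / (n_steps * n_walkers)
  if (acceptance < 0.05) {
    warning("Ensemble acceptance fraction below 0.05; ",
            "consider narrower bounds or a smaller stretch scale.",
            call. = FALSE)
  }
  best <- which(lp_tr == max(lp_tr), arr.ind = TRUE)[1, ]
  map_log <- chain[best[1], best[2], ]
  structure(
    list(chain = chain, log_post = lp_tr, acceptance = acceptance,
         map = setNames(10^map_log, nm), map_log10 = setNames(map_log, nm),
         burn_in = burn_in, n_walkers = n_walkers, n_steps = n_steps,
         seed = seed),
    class = "ensemble_mcmc"
  )
}

#' @export
print.ensemble_mcmc <- function(x, ...) {
  cat("<ensemble_mcmc> ", x$n_walkers, " walkers x ", x$n_steps,
      " steps (burn-in ", x$burn_in, "), acceptance ",
      sprintf("%.2f", x$acceptance), "\n", sep = "")
  cat("  MAP: ", paste(sprintf("%s = %.4g", names(x$map), x$map),
                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.ensemble_mcmc <- function(x, ...) {
  keep <- seq.int(x$burn_in + 1L, dim(x$chain)[1])
  purrr::map_dfr(dimnames(x$chain)[[3]], function(nm) {
    v <- x$chain[keep, , nm]
    tibble::tibble(
      step = rep(keep, times = ncol(v)),
      walker = rep(seq_len(ncol(v)), each = length(keep)),
      parameter = nm,
      value = 10^as.numeric(v)
    )
  })
}

#' @rdname tidy-sarcphos
#' @export
glance.ensemble_mcmc <- function(x, ...) {
  draws <- tidy(x)
  draws |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value),
                     median = median(.data$value),
                     sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(map = unname(x$map[.data$parameter]),
                  acceptance = x$acceptance)
}

#' Joint MCMC fit of the phosphorylation mechanosensing parameters
#'
#' Fits the free parameters (by default `phi_P` and `k_force`) of a
#' phosphorylation-placement variant jointly to the four reconstructed
#' force-pCa conditions, starting from a baseline-calibrated parameter set.
#'
#' @param geom geometry.
#' @param params calibrated [sarcomere_params()] (see [calibrate_baseline()]).
#' @param variant [model_variant()] to fit.
#' @param targets tibble from [build_fit_targets()].
#' @param free names of free parameters.
#' @param n_walkers,n_steps,seed,burn_in MCMC settings.
#' @return An `ensemble_mcmc`; `$map_params` holds the full `sarcomere_params`
#'   at the MAP.
#' @export
fit_phospho_model <- function(geom, params, variant = model_variant("A"),
                              targets = build_fit_targets(),
                              free = c("phi_P", "k_force"),
                              n_walkers = 16, n_steps = 150, seed = 1L,
                              burn_in = ceiling(n_steps / 3)) {
  lp <- function(theta) log_likelihood(theta, geom, params, variant, targets)
  init <- setNames(log10(unlist(params[free])), free)
  fit <- run_ensemble_mcmc(lp, init, n_walkers = n_walkers, n_steps = n_steps,
                           seed = seed, burn_in = burn_in)
  map_params <- params
  for (nm in free) map_params[[nm]] <- unname(fit$map[nm])
  fit$map_params <- map_params
  fit$variant <- variant$name
  fit
}

#' Summed squared residual of a variant against the targets
#'
#' Used for model discrimination: evaluating Models B and C at Model A's
#' best-fit parameters quantifies how badly uniform-filament or both-head
#' phosphorylation placement overshoots the experimental curves.
#'
#' @inheritParams fit_phospho_model
#' @return Scalar sum of squared (model - data) residuals over all points.
#' @export
model_ssr <- function(geom, params, variant, targets = build_fit_targets()) {
  pred <- predict_targets(geom, params, variant, targets)
  sum((pred$model - pred$force_norm)^2)
}

#' Phosphorylation-induced pCa50 shift of a fitted model
#'
#' @inheritParams fit_phospho_model
#' @param sl_um sarcomere length.
#' @param pCa_grid grid for the Hill fits.
#' @return One-row tibble: `sl_um`, `pCa50_unphos`, `pCa50_phos`, `shift`.
#' @export
pca50_shift <- function(geom, params, variant = model_variant("A"),
                        sl_um = 1.9, pCa_grid = seq(6.4, 4.8, by = -0.2)) {
  u <- suppressWarnings(force_pca_curve(geom, params, variant, "none",
                                        sl_um, pCa_grid))
  p <- suppressWarnings(force_pca_curve(geom, params, variant, "all",
                                        sl_um, pCa_grid))
  tibble::tibble(sl_um = sl_um, pCa50_unphos = u$fit$pCa50,
                 pCa50_phos = p$fit$pCa50,
                 shift = p$fit$pCa50 - u$fit$pCa50)
}
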