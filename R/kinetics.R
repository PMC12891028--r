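#' Two-population kinase/phosphatase system for RLC phosphorylation
#'
#' RLC phosphorylation in intact myofilaments is modelled as two (or more)
#' kinetically distinct myosin-head populations, each phosphorylated by the
#' kinase (second-order rate `k_P`, units uM^-1 min^-1) and dephosphorylated
#' by the phosphatase (`k_D`, uM^-1 min^-1) under mass action. The
#' phosphorylated fraction of population i relaxes mono-exponentially towards
#' `p_ss,i = k_P[K] / (k_P[K] + k_D[P])` with observed rate
#' `k_P[K] + k_D[P]`, so the head-weighted total is biexponential in time and
#' biphasic in steady-state kinase dose.
#'
#' @param populations tibble/data.frame with one row per population and
#'   columns `fraction` (summing to 1), `k_P`, `k_D` (uM^-1 min^-1) and
#'   `p0` (initial phosphorylated fraction). A `name` column is optional.
#' @param kinase_conc active kinase concentration (uM).
#' @param phosphatase_conc phosphatase concentration (uM).
#' @param p_max cap on the attainable phosphorylation level (mol Pi per mol
#'   RLC); e.g. about 0.65 with BDM versus 0.95 with blebbistatin as the
#'   myosin inhibitor.
#' @return A `population_set` object.
#' @examples
#' ps <- default_population_set()
#' simulate_time_course(ps, t_grid = seq(0, 120, by = 1))
#' @export
population_set <- function(populations,
                           kinase_conc = 0.2,
                           phosphatase_conc = 0,
                           p_max = 0.95) {
  populations <- tibble::as_tibble(populations)
  req <- c("fraction", "k_P", "k_D", "p0")
  if (!all(req %in% names(populations))) {
    stop("`populations` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!("name" %in% names(populations))) {
    populations$name <- paste0("pop", seq_len(nrow(populations)))
  }
  if (abs(sum(populations$fraction) - 1) > 1e-9) {
    stop("Population fractions must sum to 1.", call. = FALSE)
  }
  if (any(populations$fraction < 0) || any(populations$k_P < 0) ||
      any(populations$k_D < 0)) {
    stop("Fractions and rate constants must be nonnegative.", call. = FALSE)
  }
  if (any(populations$p0 < 0 | populations$p0 > 1)) {
    stop("`p0` must lie in [0, 1].", call. = FALSE)
  }
  if (kinase_conc < 0 || phosphatase_conc < 0) {
    stop("Concentrations must be nonnegative.", call. = FALSE)
  }
  if (p_max <= 0 || p_max > 1) stop("`p_max` must lie in (0, 1].", call. = FALSE)
  structure(
    list(populations = populations, kinase_conc = kinase_conc,
         phosphatase_conc = phosphatase_conc, p_max = p_max),
    class = "population_set"
  )
}

#' Default two-population fixtures
#'
#' The default fixture has a fast population (the heads in the P- and C-zones
#' of the default geometry, fraction 0.633) with `k_P` ten times that of the
#' slow (D-zone) population, and `k_D` such that at 0.1 uM phosphatase the
#' steady-state half-max kinase concentrations are 0.01 uM (fast) and 0.1 uM
#' (slow). `fast = "C"` gives the alternate fixture where only C-zone heads
#' (fraction 0.551) are fast.
#'
#' @param fast which zones form the fast population: `"PC"` (default) or `"C"`.
#' @param kinase_conc,phosphatase_conc,p_max passed to [population_set()].
#' @return A `population_set`.
#' @export
default_population_set <- function(fast = c("PC", "C"),
                                   kinase_conc = 0.2,
                                   phosphatase_conc = 0,
                                   p_max = 0.95) {
  fast <- match.arg(fast)
  f_fast <- if (fast == "PC") 31 / 49 else 27 / 49
  pops <- tibble::tibble(
    name = c("fast", "slow"),
    fraction = c(f_fast, 1 - f_fast),
    k_P = c(1.0, 0.1),
    k_D = c(0.1, 0.1),
    p0 = 0
  )
  population_set(pops, kinase_conc = kinase_conc,
                 phosphatase_conc = phosphatase_conc, p_max = p_max)
}

pop_rates <- function(popset) {
  p <- popset$populations
  rate <- p$k_P * popset$kinase_conc + p$k_D * popset$phosphatase_conc
  p_ss <- ifelse(rate > 0, p$k_P * popset$kinase_conc / rate, NA_real_)
  list(rate = rate, p_ss = p_ss)
}

#' Simulate a phosphorylation time course
#'
#' Closed-form per-population relaxation
#' `p_i(t) = p_ss,i + (p0_i - p_ss,i) exp(-(k_P,i[K] + k_D,i[P]) t)` with
#' `p_ss,i = k_P,i[K] / (k_P,i[K] + k_D,i[P])`; the total is the
#' fraction-weighted sum scaled by `p_max`. No integrator is involved.
#' If a population has zero total rate its steady state is undefined; it is
#' held at `p0` and flagged in the `degenerate` attribute.
#'
#' @param popset a [population_set()].
#' @param t_grid sorted, nonnegative times (min).
#' @return Tibble with `t_min`, one `p_<name>` column per population, and
#'   `p_total` (mol Pi per mol RLC).
#' @export
simulate_time_course <- function(popset, t_grid) {
  stopifnot(inherits(popset, "population_set"))
  if (is.unsorted(t_grid) || any(t_grid < 0)) {
    stop("`t_grid` must be sorted and nonnegative.", call. = FALSE)
  }
  p <- popset$populations
  r <- pop_rates(popset)
  cols <- purrr::pmap(
    list(p$p0, r$rate, r$p_ss),
    function(p0, rate, p_ss) {
      if (rate <= 0) rep(p0, length(t_grid))
      else p_ss + (p0 - p_ss) * exp(-rate * t_grid)
    }
  )
  names(cols) <- paste0("p_", p$name)
  out <- tibble::as_tibble(cols)
  out$p_total <- popset$p_max *
    as.numeric(as.matrix(out) %*% p$fraction)
  out <- dplyr::bind_cols(tibble::tibble(t_min = t_grid), out)
  degenerate <- r$rate <= 0 & abs(p$p0 - ifelse(is.na(r$p_ss), p$p0, r$p_ss)) > 0
  attr(out, "degenerate") <- any(r$rate <= 0)
  out
}

#' Steady-state dose-response of phosphorylation versus kinase concentration
#'
#' Each population follows a hyperbola `p_ss,i(K) = K / (K + EC50_i)` with
#' `EC50_i = (k_D,i / k_P,i) [P]`; the total is the fraction-weighted sum
#' scaled by `p_max`, hence biphasic when the populations' EC50s differ.
#' With `[P] = 0` every EC50 collapses to zero (a step); the result carries a
#' `degenerate` attribute in that case.
#'
#' @param popset a [population_set()]; its `kinase_conc` is ignored, the grid
#'   is used instead.
#' @param K_grid sorted positive kinase concentrations (uM).
#' @return Tibble with `K_uM`, per-population `p_<name>`, and `p_total`.
#' @export
steady_state_dose_response <- function(popset, K_grid) {
  stopifnot(inherits(popset, "population_set"))
  if (is.unsorted(K_grid) || any(K_grid <= 0)) {
    stop("`K_grid` must be sorted and positive.", call. = FALSE)
  }
  p <- popset$populations
  if (any(p$k_P <= 0)) {
    stop("All populations need `k_P` > 0 for a dose-response.", call. = FALSE)
  }
  ec50 <- p$k_D / p$k_P * popset$phosphatase_conc
  cols <- purrr::map(ec50, function(e) K_grid / (K_grid + e))
  names(cols) <- paste0("p_", p$name)
  out <- tibble::as_tibble(cols)
  out$p_total <- popset$p_max * as.numeric(as.matrix(out) %*% p$fraction)
  out <- dplyr::bind_cols(tibble::tibble(K_uM = K_grid), out)
  attr(out, "ec50") <- setNames(ec50, p$name)
  attr(out, "degenerate") <- popset$phosphatase_conc == 0
  out
}

#' ADP-biosensor fluorescence readout
#'
#' The biosensor reports ADP, the byproduct of phosphate transfer, so its
#' fluorescence is strictly linear in the phosphate transferred:
#' `F(t) = gain * (rlc_conc * p_total(t) + background_rate * t)`.
#'
#' @param timecourse tibble from [simulate_time_course()] (columns `t_min`,
#'   `p_total`).
#' @param rlc_conc RLC concentration (uM).
#' @param gain fluorescence units per uM ADP ( > 0 ).
#' @param background_rate background ATPase rate (uM min^-1).
#' @return Tibble with `t_min` and `fluorescence`.
#' @export
biosensor_signal <- function(timecourse, rlc_conc = 25, gain = 1,
                             background_rate = 0) {
  stopifnot(all(c("t_min", "p_total") %in% names(timecourse)))
  if (gain <= 0) stop("`gain` must be > 0.", call. = FALSE)
  tibble::tibble(
    t_min = timecourse$t_min,
    fluorescence = gain * (rlc_conc * timecourse$p_total +
                             background_rate * timecourse$t_min)
  )
}

exp_rise_formula <- function(n) {
  if (n == 1L) y ~ offset + A1 * (1 - exp(-k1 * t))
  else y ~ offset + A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t))
}

#' Fit a rising single- or biexponential model
#'
#' Least-squares fit of `y = offset + sum_j A_j (1 - exp(-k_j t))` with one or
#' two phases; rates are reported sorted descending (`k1 >= k2`). A residual
#' F-test against the nested single-exponential fit indicates whether the
#' second phase is supported.
#'
#' @param t times (min), at least 6 points.
#' @param y phosphorylation signal (mol Pi per mol RLC), finite.
#' @param n_phases 2 (default) or 1 for the single-exponential variant, whose
#'   single rate is the apparent rate `k_app`.
#' @return A `biexp_fit` object; see [tidy.biexp_fit()]. Fields: `A1`, `A2`,
#'   `k1`, `k2` (min^-1), `offset`, `rss`, `f_test` (p-value of the 2- vs
#'   1-phase comparison, `NA` when `n_phases = 1`), `prefers_biexp`.
#' @export
fit_biexponential <- function(t, y, n_phases = 2L) {
  if (length(t) < 6L) stop("Need at least 6 points.", call. = FALSE)
  if (!all(is.finite(y))) stop("`y` must be finite.", call. = FALSE)
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases %in% c(1L, 2L))

  fit1 <- fit_exp_rise(t, y, 1L)
  fit <- if (n_phases == 2L) fit_exp_rise(t, y, 2L) else fit1

  rss1 <- sum(residuals(fit1)^2)
  rss2 <- sum(residuals(fit)^2)
  f_test <- NA_real_
  prefers_biexp <- FALSE
  if (n_phases == 2L) {
    df2 <- length(t) - 5L
    fstat <- max(0, (rss1 - rss2) / 2) / max(rss2 / df2, .Machine$double.eps)
    f_test <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
    prefers_biexp <- is.finite(f_test) && f_test < 0.05
  }

  cf <- coef(fit)
  if (n_phases == 1L) {
    out <- list(A1 = unname(cf["A1"]), A2 = 0, k1 = unname(cf["k1"]), k2 = NA_real_,
                offset = unname(cf["offset"]), n_phases = 1L)
  } else {
    ord <- order(c(cf["k1"], cf["k2"]), decreasing = TRUE)
    A <- c(cf["A1"], cf["A2"])[ord]
    k <- c(cf["k1"], cf["k2"])[ord]
    if (all(k > 0) && abs(k[1] - k[2]) / k[1] < 0.05) {
      warning("Fitted rates within 5%: phases are indistinguishable.",
              call. = FALSE)
    }
    out <- list(A1 = unname(A[1]), A2 = unname(A[2]),
                k1 = unname(k[1]), k2 = unname(k[2]),
                offset = unname(cf["offset"]), n_phases = 2L)
  }
  out$rss <- rss2
  out$rss_monophasic <- rss1
  out$f_test <- f_test
  out$prefers_biexp <- prefers_biexp
  out$k_app <- unname(coef(fit1)["k1"])
  out$fit <- fit
  structure(out, class = "biexp_fit")
}

fit_exp_rise <- function(t, y, n) {
  span <- max(t[t > 0], na.rm = TRUE)
  amp <- max(y) - min(y)
  k0 <- 2 / span
  starts <- if (n == 1L) {
    list(list(offset = min(y), A1 = amp, k1 = k0),
         list(offset = min(y), A1 = amp, k1 = 10 * k0),
         list(offset = min(y), A1 = amp, k1 = k0 / 10))
  } else {
    list(list(offset = min(y), A1 = amp / 2, A2 = amp / 2, k1 = 5 * k0, k2 = k0 / 2),
         list(offset = min(y), A1 = amp / 2, A2 = amp / 2, k1 = 20 * k0, k2 = k0),
         list(offset = min(y), A1 = amp * 0.7, A2 = amp * 0.3, k1 = k0, k2 = k0 / 10))
  }
  dat <- data.frame(t = t, y = y)
  lower <- rep(0, 2 * n + 1)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(exp_rise_formula(n), data = dat, start = s,
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit)) return(fit)
  }
  stop("Exponential fit failed to converge (", n, " phase(s)); ",
       "check data range and signal-to-noise.", call. = FALSE)
}

#' Fit a two-site biphasic dose-response
#'
#' Least-squares fit of `p(K) = baseline + A1 K/(K + EC50_1) + A2 K/(K + EC50_2)`
#' with `EC50_1 < EC50_2` on return. Warns when the two EC50s are within 10%
#' of each other (effectively monophasic).
#'
#' @param K kinase concentrations (uM), at least 8 points spanning >= 3 decades.
#' @param p phosphorylation levels.
#' @return A `biphasic_fit` object with `A1`, `A2`, `EC50_1`, `EC50_2` (uM),
#'   `baseline`, `rss`.
#' @export
fit_biphasic <- function(K, p) {
  if (length(K) < 8L) stop("Need at least 8 dose points.", call. = FALSE)
  if (log10(max(K) / min(K)) < 3) {
    stop("Dose points must span at least 3 decades.", call. = FALSE)
  }
  dat <- data.frame(K = K, y = p)
  gm <- exp(mean(log(K)))
  amp <- max(p) - min(p)
  starts <- list(
    list(baseline = min(p), A1 = amp / 2, A2 = amp / 2, E1 = gm / 10, E2 = gm * 10),
    list(baseline = min(p), A1 = amp / 2, A2 = amp / 2, E1 = gm / 30, E2 = gm * 3),
    list(baseline = min(p), A1 = amp * 0.6, A2 = amp * 0.4, E1 = gm, E2 = gm * 30)
  )
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + A1 * K / (K + E1) + A2 * K / (K + E2),
        data = dat, start = s, lower = rep(0, 5),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Biphasic fit failed to converge.", call. = FALSE)
  }
  cf <- coef(fit)
  ord <- order(c(cf["E1"], cf["E2"]))
  A <- c(cf["A1"], cf["A2"])[ord]
  E <- c(cf["E1"], cf["E2"])[ord]
  if (E[2] > 0 && (E[2] - E[1]) / E[2] < 0.1) {
    warning("EC50s within 10%: dose-response is effectively monophasic.",
            call. = FALSE)
  }
  structure(
    list(A1 = unname(A[1]), A2 = unname(A[2]),
         EC50_1 = unname(E[1]), EC50_2 = unname(E[2]),
         baseline = unname(cf["baseline"]),
         rss = sum(residuals(fit)^2), fit = fit),
    class = "biphasic_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (x$n_phases == 1L) {
    cat(sprintf("<biexp_fit> monophasic: k_app = %.4g min^-1, A = %.4g\n",
                x$k1, x$A1))
  } else {
    cat(sprintf(
      "<biexp_fit> k1 = %.4g, k2 = %.4g min^-1 (ratio %.3g); A1 = %.3g, A2 = %.3g\n",
      x$k1, x$k2, x$k1 / x$k2, x$A1, x$A2))
    cat(sprintf("  F-test vs monophasic: p = %.3g (%s)\n", x$f_test,
                if (x$prefers_biexp) "biexponential preferred" else "monophasic adequate"))
  }
  invisible(x)
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf(
    "<biphasic_fit> EC50 = %.4g and %.4g uM; A1 = %.3g, A2 = %.3g, baseline = %.3g\n",
    x$EC50_1, x$EC50_2, x$A1, x$A2, x$baseline))
  invisible(x)
}

#' @rdname tidy-sarcphos
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "A2", "k1", "k2", "offset"),
    estimate = c(x$A1, x$A2, x$k1, x$k2, x$offset)
  )
}

#' @rdname tidy-sarcphos
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(n_phases = x$n_phases, rss = x$rss,
                 rss_monophasic = x$rss_monophasic,
                 f_test = x$f_test, prefers_biexp = x$prefers_biexp,
                 k_app = x$k_app)
}

#' @rdname tidy-sarcphos
#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A1", "A2", "EC50_1", "EC50_2", "baseline"),
    estimate = c(x$A1, x$A2, x$EC50_1, x$EC50_2, x$baseline)
  )
}

#' @rdname tidy-sarcphos
#' @export
glance.biphasic_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss)
}
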