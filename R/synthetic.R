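#' Named fixture specifications
#'
#' Generator specifications mirroring the study conditions each pipeline
#' stage expects:
#' \describe{
#'   \item{`rat_myofibril_default`}{two-population phosphorylation time
#'     course, kinase only (rates 0.2 and 0.02 min^-1, 10:1).}
#'   \item{`rat_dose_response`}{steady-state dose-response at 0.1 uM
#'     phosphatase (EC50s 0.01 and 0.1 uM).}
#'   \item{`isolated_rlc`}{single-population (monophasic) time course, the
#'     isolated-RLC control.}
#'   \item{`trabecula_shortSL` / `trabecula_longSL`}{unphosphorylated
#'     force-pCa Hill data at SL 1.9 um (pCa50 5.56, n_H 4) and 2.3 um
#'     (pCa50 5.64, n_H 4).}
#'   \item{`czone_5min`}{fluorescence profile with C+P-zone-only occupancy
#'     (early-timepoint pattern, global level ~0.2).}
#'   \item{`spillover_60pct`}{sequential C-then-D occupancy at global level
#'     0.6.}
#'   \item{`slack_restretch_pre` / `slack_restretch_post`}{`<P2>` transients
#'     with Ph1/Ph2 phases; pre-phosphorylation Ph2 rate 13 s^-1 (= ktr),
#'     post-phosphorylation Ph2 rate 24 s^-1 (faster than ktr 16 s^-1).}
#' }
#'
#' @param name fixture name.
#' @return A `generator_spec` list understood by [generate_dataset()].
#' @export
fixture_spec <- function(name = c("rat_myofibril_default", "rat_dose_response",
                                  "isolated_rlc",
                                  "trabecula_shortSL", "trabecula_longSL",
                                  "czone_5min", "spillover_60pct",
                                  "slack_restretch_pre",
                                  "slack_restretch_post")) {
  name <- match.arg(name)
  spec <- switch(name,
    rat_myofibril_default = list(
      kind = "phospho_timecourse",
      params = list(popset = default_population_set(),
                    t_grid = seq(0, 180, by = 2)),
      noise = list(model = "gaussian", sigma = 0.01)
    ),
    rat_dose_response = list(
      kind = "dose_response",
      params = list(popset = default_population_set(phosphatase_conc = 0.1),
                    K_grid = 10^seq(-3, 1, length.out = 12)),
      noise = list(model = "gaussian", sigma = 0.01)
    ),
    isolated_rlc = list(
      kind = "phospho_timecourse",
      params = list(popset = population_set(
        tibble::tibble(name = "rlc", fraction = 1, k_P = 0.3, k_D = 0, p0 = 0),
        kinase_conc = 0.2, p_max = 1),
        t_grid = seq(0, 120, by = 2)),
      noise = list(model = "gaussian", sigma = 0.01)
    ),
    trabecula_shortSL = list(
      kind = "force_pca",
      params = list(pCa50 = 5.56, n_H = 4, F_max = 1,
                    pCa_grid = seq(6.4, 4.8, by = -0.2)),
      noise = list(model = "gaussian", sigma = 0.03)
    ),
    trabecula_longSL = list(
      kind = "force_pca",
      params = list(pCa50 = 5.64, n_H = 4, F_max = 1,
                    pCa_grid = seq(6.4, 4.8, by = -0.2)),
      noise = list(model = "gaussian", sigma = 0.03)
    ),
    czone_5min = list(
      kind = "profile",
      params = list(level = 0.2, mode = "sequential",
                    fill_order = "PC_then_D"),
      noise = list(model = "poisson", scale = 2000)
    ),
    spillover_60pct = list(
      kind = "profile",
      params = list(level = 0.6, mode = "sequential",
                    fill_order = "C_then_D"),
      noise = list(model = "poisson", scale = 2000)
    ),
    slack_restretch_pre = list(
      kind = "p2_transient",
      params = list(p2_relaxed = 0.15, p2_act = -0.05, dp2_ph1 = 0.08,
                    rate_ph1 = 60, rate_ph2 = 13,
                    t_release = 0.5, t_restretch = 0.55, t_end = 1.5,
                    dt = 2e-4, restretch = TRUE),
      noise = list(model = "gaussian", sigma = 0.004)
    ),
    slack_restretch_post = list(
      kind = "p2_transient",
      params = list(p2_relaxed = 0.15, p2_act = -0.09, dp2_ph1 = 0.08,
                    rate_ph1 = 60, rate_ph2 = 24,
                    t_release = 0.5, t_restretch = 0.55, t_end = 1.5,
                    dt = 2e-4, restretch = TRUE),
      noise = list(model = "gaussian", sigma = 0.004)
    )
  )
  spec$name <- name
  structure(spec, class = "generator_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Seeded generators producing data with the statistical structure each
#' analysis stage assumes, together with the generating parameters, so that
#' every fit operation can be validated by parameter recovery without any
#' external data.
#'
#' @param spec a `generator_spec` from [fixture_spec()], or a list with
#'   fields `kind`, `params`, `noise` (`list(model = "none"|"gaussian"|
#'   "poisson", sigma=/scale=)`).
#' @param seed RNG seed (mandatory; identical seeds give identical data).
#' @param n_replicates number of replicate noise realizations.
#' @param geom geometry used by profile generators.
#' @return List with `data` (tibble, stage CSV schema, with a `replicate`
#'   column when `n_replicates > 1`) and `truth` (generating parameters).
#' @export
generate_dataset <- function(spec, seed = 1L, n_replicates = 1L,
                             geom = build_half_filament()) {
  if (is.character(spec)) spec <- fixture_spec(spec)
  stopifnot(!is.null(spec$kind), !is.null(spec$noise))
  set.seed(seed)
  kinds <- c("force_pca", "phospho_timecourse", "dose_response", "profile",
             "p2_transient")
  if (!(spec$kind %in% kinds)) {
    stop("Unknown generator kind '", spec$kind, "'.", call. = FALSE)
  }
  p <- spec$params

  clean <- switch(spec$kind,
    force_pca = tibble::tibble(
      pCa = p$pCa_grid,
      force_norm = hill_force(p$pCa_grid, p$pCa50, p$n_H, p$F_max)
    ),
    phospho_timecourse = {
      tc <- simulate_time_course(p$popset, p$t_grid)
      tibble::tibble(t_min = tc$t_min, p_total = tc$p_total)
    },
    dose_response = {
      dr <- steady_state_dose_response(p$popset, p$K_grid)
      tibble::tibble(K_uM = dr$K_uM, p_total = dr$p_total)
    },
    profile = {
      occ <- occupancy_from_level(geom, p$level, mode = p$mode,
                                  fill_order = p$fill_order)
      prof <- render_profile(geom, occ)
      tibble::tibble(position_um = prof$position_um,
                     intensity = prof$intensity)
    },
    p2_transient = {
      t_s <- seq(0, p$t_end, by = p$dt)
      p2 <- rep(p$p2_act, length(t_s))
      ph1 <- t_s >= p$t_release &
        (if (p$restretch) t_s < p$t_restretch else TRUE)
      p2[ph1] <- p$p2_act + p$dp2_ph1 *
        (1 - exp(-p$rate_ph1 * (t_s[ph1] - p$t_release)))
      if (p$restretch) {
        top <- p$p2_act + p$dp2_ph1 *
          (1 - exp(-p$rate_ph1 * (p$t_restretch - p$t_release)))
        ph2 <- t_s >= p$t_restretch
        p2[ph2] <- p$p2_act + (top - p$p2_act) *
          exp(-p$rate_ph2 * (t_s[ph2] - p$t_restretch))
      }
      tibble::tibble(t_s = t_s, p2 = p2)
    }
  )

  ycol <- setdiff(names(clean), c("pCa", "t_min", "K_uM", "position_um", "t_s"))
  noisy <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    out <- clean
    y <- out[[ycol]]
    out[[ycol]] <- switch(spec$noise$model,
      none = y,
      gaussian = y + rnorm(length(y), 0, spec$noise$sigma),
      poisson = rpois(length(y), pmax(0, y) * spec$noise$scale) /
        spec$noise$scale,
      stop("Unknown noise model '", spec$noise$model, "'.", call. = FALSE)
    )
    dplyr::mutate(out, replicate = r)
  })
  if (n_replicates == 1L) noisy$replicate <- NULL

  truth <- p
  truth$popset <- NULL
  if (!is.null(p$popset)) {
    truth$populations <- p$popset$populations
    truth$kinase_conc <- p$popset$kinase_conc
    truth$phosphatase_conc <- p$popset$phosphatase_conc
    truth$p_max <- p$popset$p_max
  }
  if (spec$kind == "p2_transient") {
    truth$events <- c(release = p$t_release,
                      if (p$restretch) c(restretch = p$t_restretch))
  }
  list(data = noisy, truth = truth,
       spec = list(kind = spec$kind, name = spec$name, seed = seed,
                   noise = spec$noise))
}
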