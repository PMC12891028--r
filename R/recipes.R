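#' End-to-end analysis recipes
#'
#' Each recipe chains the package stages on synthetic fixtures and returns a
#' report of the quantities it computed. All recipes are hermetic (inputs are
#' generated in-process) and deterministic given `seed`.
#'
#' \describe{
#'   \item{`fig1_kinetics`}{generates the two-population time course and the
#'     steady-state dose-response, fits the biexponential and biphasic
#'     models, reports rates, the rate ratio and both EC50s.}
#'   \item{`fig2_profiles`}{renders the MHC and phospho-RLC profiles
#'     (C+P-zone occupancy and sequential spillover at level 0.6) and
#'     reports their FWHM.}
#'   \item{`fig5_models`}{calibrates the baseline, MCMC-fits Model A to the
#'     reconstructed force-pCa targets and reports the fitted
#'     phosphorylation-induced pCa50 shifts and the variant SSR comparison.}
#'   \item{`fig6_transients`}{simulates slack-restretch protocols with and
#'     without phosphorylation, derives `<P2>` transients and ktr, and fits
#'     the two phases.}
#' }
#'
#' @param name recipe name.
#' @param seed global seed.
#' @param geom filament geometry.
#' @param fast logical; use reduced MCMC settings (recipe `fig5_models`).
#' @param dry_run validate the configuration and return the planned steps
#'   without computing.
#' @return A list with `report` (tibble of `quantity`, `value`) and
#'   stage-specific objects; for `dry_run = TRUE`, the step list only.
#' @export
run_recipe <- function(name = c("fig1_kinetics", "fig2_profiles",
                                "fig5_models", "fig6_transients"),
                       seed = 1L, geom = build_half_filament(),
                       fast = TRUE, dry_run = FALSE) {
  name <- match.arg(name)
  steps <- switch(name,
    fig1_kinetics = c("generate rat_myofibril_default + rat_dose_response",
                      "fit_biexponential", "fit_biphasic"),
    fig2_profiles = c("render MHC/czone_5min/spillover_60pct profiles",
                      "profile_fwhm"),
    fig5_models = c("calibrate_baseline", "build_fit_targets",
                    "fit_phospho_model(A)", "pca50_shift x2", "model_ssr x3"),
    fig6_transients = c("ktr_protocol pre/post", "predicted_p2",
                        "fit_p2_transient pre/post")
  )
  if (dry_run) return(list(recipe = name, steps = steps))

  if (name == "fig1_kinetics") {
    tc <- generate_dataset("rat_myofibril_default", seed = seed)
    bx <- fit_biexponential(tc$data$t_min, tc$data$p_total)
    dr <- generate_dataset("rat_dose_response", seed = seed)
    bp <- fit_biphasic(dr$data$K_uM, dr$data$p_total)
    report <- tibble::tibble(
      quantity = c("k1_min", "k2_min", "rate_ratio", "EC50_1_uM", "EC50_2_uM"),
      value = c(bx$k1, bx$k2, bx$k1 / bx$k2, bp$EC50_1, bp$EC50_2)
    )
    return(list(report = report, biexp = bx, biphasic = bp))
  }

  if (name == "fig2_profiles") {
    mhc <- render_profile(geom)
    czone <- render_profile(geom, occupancy_from_level(
      geom, 31 / 49, mode = "sequential", fill_order = "PC_then_D"))
    spill <- render_profile(geom, occupancy_from_level(
      geom, 0.6, mode = "sequential", fill_order = "C_then_D"))
    report <- tibble::tibble(
      quantity = c("fwhm_mhc_um", "fwhm_czone_um", "fwhm_spillover60_um"),
      value = c(profile_fwhm(mhc)$fwhm_um, profile_fwhm(czone)$fwhm_um,
                profile_fwhm(spill)$fwhm_um)
    )
    return(list(report = report,
                profiles = list(mhc = mhc, czone = czone, spillover = spill)))
  }

  if (name == "fig5_models") {
    params <- calibrate_baseline(geom)
    targets <- build_fit_targets()
    nw <- if (fast) 12 else 16
    ns <- if (fast) 60 else 150
    fit <- fit_phospho_model(geom, params, model_variant("A"), targets,
                             n_walkers = nw, n_steps = ns, seed = seed)
    mp <- fit$map_params
    fine <- seq(6.6, 4.8, by = -0.1)
    s19 <- pca50_shift(geom, mp, model_variant("A"), 1.9, fine)
    s23 <- pca50_shift(geom, mp, model_variant("A"), 2.3, fine)
    ssr <- vapply(c("A", "B", "C"), function(v)
      model_ssr(geom, mp, model_variant(v), targets), numeric(1))
    report <- tibble::tibble(
      quantity = c("pCa50_shift_SL1.9", "pCa50_shift_SL2.3",
                   "ssr_A", "ssr_B", "ssr_C", "phi_P_map", "k_force_map"),
      value = c(s19$shift, s23$shift, ssr, fit$map[["phi_P"]],
                fit$map[["k_force"]])
    )
    return(list(report = report, fit = fit, params = params,
                shifts = dplyr::bind_rows(s19, s23)))
  }

  # fig6_transients
  params <- sarcomere_params()
  prot <- sim_protocol(sarcomere_length = 1.9, pCa = 4.8, duration = 3,
                       mode = "ktr_slack_restretch", t_slack = 1.8,
                       seed = seed)
  pre <- ktr_protocol(geom, params, model_variant("A"), "none", prot)
  post <- ktr_protocol(geom, params, model_variant("A"), "all", prot)
  p2_pre <- predicted_p2(pre$sim)
  p2_post <- predicted_p2(post$sim)
  f_pre <- fit_p2_transient(p2_pre, pre$sim$events)
  f_post <- fit_p2_transient(p2_post, post$sim$events)
  ph2 <- function(f) f$phases$rate_s[f$phases$phase == "Ph2"]
  report <- tibble::tibble(
    quantity = c("ktr_pre_s", "ktr_post_s", "ph2_pre_s", "ph2_post_s",
                 "p2_act_pre", "p2_act_post"),
    value = c(pre$k_tr, post$k_tr, ph2(f_pre), ph2(f_post),
              f_pre$p2_act, f_post$p2_act)
  )
  list(report = report, ktr = list(pre = pre, post = post),
       p2 = list(pre = f_pre, post = f_post))
}
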