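#' Plot methods
#'
#' `autoplot()` methods (and `plot_*()` wrappers) for the package's result
#' types, all returning ggplot objects.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name plots-sarcphos
NULL

#' @rdname plots-sarcphos
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position_um, y = .data$intensity)) +
    geom_line(color = "darkgreen") +
    labs(x = "Axial position (µm from M-line)",
         y = "Normalized intensity") +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @export
autoplot.force_pca <- function(object, ...) {
  fit <- object$fit
  curve <- tibble::tibble(
    pCa = seq(max(object$points$pCa), min(object$points$pCa),
              length.out = 200)
  )
  curve$force_norm <- hill_force(curve$pCa, fit$pCa50, fit$n_H)
  ggplot(object$points, aes(x = .data$pCa, y = .data$force_norm)) +
    geom_point() +
    geom_line(data = curve, color = "firebrick") +
    scale_x_reverse() +
    labs(x = "pCa", y = "Normalized force",
         subtitle = sprintf("pCa50 = %.2f, n_H = %.2f", fit$pCa50, fit$n_H)) +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @export
autoplot.sim_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("force_pN", "off", "on", "fg"),
                            names_to = "signal")
  p <- ggplot(tr, aes(x = .data$t_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~signal, scales = "free_y", ncol = 1) +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
  if (length(object$events)) {
    p <- p + geom_vline(xintercept = unname(object$events),
                        linetype = "dashed", color = "grey50")
  }
  p
}

#' @rdname plots-sarcphos
#' @export
autoplot.me_map <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$gamma, y = .data$beta,
                          fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    scale_y_reverse() +
    labs(x = expression(gamma ~ "(deg)"), y = expression(beta ~ "(deg)"),
         fill = "Density") +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @export
autoplot.ensemble_mcmc <- function(object, ...) {
  draws <- tidy(object)
  ggplot(draws, aes(x = .data$value)) +
    geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    facet_wrap(~parameter, scales = "free") +
    scale_x_log10() +
    labs(x = "Parameter value (post burn-in draws)", y = "Count") +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @param timecourse tibble from [simulate_time_course()].
#' @export
plot_time_course <- function(timecourse, ...) {
  long <- tidyr::pivot_longer(timecourse, dplyr::starts_with("p_"),
                              names_to = "population", names_prefix = "p_")
  ggplot(long, aes(x = .data$t_min, y = .data$value,
                   color = .data$population)) +
    geom_line() +
    labs(x = "Time (min)", y = "Phosphorylation (mol Pi / mol RLC)") +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @param dose_response tibble from [steady_state_dose_response()].
#' @export
plot_dose_response <- function(dose_response, ...) {
  ggplot(dose_response, aes(x = .data$K_uM, y = .data$p_total)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    scale_x_log10() +
    labs(x = "Kinase concentration (µM)",
         y = "Steady-state phosphorylation (mol Pi / mol RLC)") +
    theme_minimal()
}

#' @rdname plots-sarcphos
#' @param p2_trace tibble with `t_s`, `p2` (see [predicted_p2()]).
#' @export
plot_p2_transient <- function(p2_trace, ...) {
  p <- ggplot(p2_trace, aes(x = .data$t_s, y = .data$p2)) +
    geom_line(color = "purple4") +
    labs(x = "Time (s)", y = expression("<" * P[2] * ">")) +
    theme_minimal()
  ev <- attr(p2_trace, "events")
  if (!is.null(ev) && length(ev)) {
    p <- p + geom_vline(xintercept = unname(ev), linetype = "dashed",
                        color = "grey50")
  }
  p
}
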