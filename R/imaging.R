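#' Per-crown phosphorylation occupancy at a given global level
#'
#' Distributes a global phosphorylation level (mol Pi per mol RLC,
#' head-weighted mean occupancy) over the crowns of a half filament.
#'
#' Two modes are available:
#' \describe{
#'   \item{`sequential`}{The fast-filling group of crowns is occupied
#'     uniformly until saturated, after which D-zone crowns fill one by one
#'     outward from the C/D boundary (full crowns, then one partial crown),
#'     and finally any remaining group. `fill_order = "C_then_D"` (default)
#'     saturates the C-zone first, then spills into the D-zone, then the
#'     P-zone — the pattern in which all C-zone motors are phosphorylated
#'     before D-zone motors. `fill_order = "PC_then_D"` groups P with C.}
#'   \item{`kinetic`}{Occupancies follow the two-population time course of
#'     `popset` at the time where the total reaches `level`: fast-population
#'     zones share one occupancy, the remaining (D-zone) crowns another.}
#' }
#'
#' @param geom a [build_half_filament()] geometry.
#' @param level global phosphorylation level in `[0, 1]`.
#' @param mode `"sequential"` or `"kinetic"`.
#' @param fill_order `"C_then_D"` or `"PC_then_D"` (sequential mode).
#' @param popset a [population_set()] for kinetic mode; its fast population is
#'   mapped onto `fast_zones`.
#' @param fast_zones zones carrying the fast population in kinetic mode.
#' @return An occupancy map: the geometry table plus an `occupancy` column,
#'   with attribute `global_level`. Head-weighted mean occupancy equals
#'   `level` exactly.
#' @export
occupancy_from_level <- function(geom, level,
                                 mode = c("sequential", "kinetic"),
                                 fill_order = c("C_then_D", "PC_then_D"),
                                 popset = default_population_set(),
                                 fast_zones = c("P", "C")) {
  stopifnot(inherits(geom, "filament_geometry"))
  mode <- match.arg(mode)
  fill_order <- match.arg(fill_order)
  if (level < 0 || level > 1) stop("`level` must lie in [0, 1].", call. = FALSE)

  crowns <- geometry_table(geom)
  n <- nrow(crowns)
  occ <- numeric(n)
  # every crown carries the same head count, so crown mass = 1/n of the level
  if (mode == "sequential") {
    groups <- if (fill_order == "C_then_D") {
      list(first = which(crowns$zone == "C"),
           spill = which(crowns$zone == "D"),
           last = which(crowns$zone == "P"))
    } else {
      list(first = which(crowns$zone %in% c("P", "C")),
           spill = which(crowns$zone == "D"),
           last = integer(0))
    }
    remaining <- level * n   # crown-equivalents to distribute
    n1 <- length(groups$first)
    fill1 <- min(1, remaining / n1)
    occ[groups$first] <- fill1
    remaining <- remaining - fill1 * n1
    if (remaining > 1e-12) {
      # D crowns outward from the C/D boundary: ordered by position
      spill <- groups$spill[order(crowns$position_nm[groups$spill])]
      for (i in spill) {
        take <- min(1, remaining)
        occ[i] <- take
        remaining <- remaining - take
        if (remaining <= 1e-12) break
      }
    }
    if (remaining > 1e-12 && length(groups$last) > 0) {
      occ[groups$last] <- occ[groups$last] + remaining / length(groups$last)
    }
  } else {
    stopifnot(inherits(popset, "population_set"))
    fast_idx <- crowns$zone %in% fast_zones
    p <- popset$populations
    if (nrow(p) != 2L) stop("Kinetic mode expects a two-population set.", call. = FALSE)
    f_fast <- mean(fast_idx)
    if (abs(f_fast - p$fraction[1]) > 1e-6) {
      stop("Fast-population fraction (", signif(p$fraction[1], 3),
           ") does not match the head fraction of `fast_zones` (",
           signif(f_fast, 3), ").", call. = FALSE)
    }
    total_at <- function(t) {
      tc <- simulate_time_course(popset, t)
      tc$p_total[1]
    }
    p_inf <- total_at(1e7)
    if (level > p_inf + 1e-9) {
      stop("Requested level ", level, " exceeds the kinetic plateau ",
           signif(p_inf, 4), ".", call. = FALSE)
    }
    t_star <- if (level <= 0) 0 else
      uniroot(function(t) total_at(t) - level, c(0, 1e7), tol = 1e-10)$root
    tc <- simulate_time_course(popset, t_star)
    occ[fast_idx] <- popset$p_max * tc[[paste0("p_", p$name[1])]][1]
    occ[!fast_idx] <- popset$p_max * tc[[paste0("p_", p$name[2])]][1]
    # remove residual root-finding error so the mean is exact
    if (level > 0 && sum(occ) > 0) occ <- occ * level * n / sum(occ)
  }

  out <- dplyr::mutate(crowns, occupancy = occ)
  attr(out, "global_level") <- level
  out
}

#' Render a 1D A-band fluorescence intensity profile
#'
#' Places a Gaussian point-spread function at every crown of both mirrored
#' half filaments of one sarcomere's A-band doublet, weighted by heads per
#' crown times occupancy (or times 1 for a uniform myosin heavy chain stain),
#' and samples the sum on a regular pixel grid centered on the M-line.
#' Noise-free profiles are normalized to a maximum of 1.
#'
#' @param geom a [build_half_filament()] geometry.
#' @param occupancy an occupancy map from [occupancy_from_level()], a numeric
#'   vector of per-crown occupancies, or `NULL` for a uniform (MHC-like)
#'   stain.
#' @param psf_sigma Gaussian PSF sigma (um); default 0.060 um (FWHM ~140 nm).
#' @param pixel_size pixel size (um); default 0.0325 um.
#' @param noise `"none"` or `"poisson"`.
#' @param noise_scale expected photon count at unit intensity for Poisson
#'   noise.
#' @param seed RNG seed used when `noise = "poisson"`.
#' @return An `intensity_profile`: tibble with `position_um`, `intensity`, and
#'   attributes `psf_sigma`, `pixel_size`.
#' @export
render_profile <- function(geom, occupancy = NULL,
                           psf_sigma = 0.060, pixel_size = 0.0325,
                           noise = c("none", "poisson"),
                           noise_scale = 1000, seed = NULL) {
  stopifnot(inherits(geom, "filament_geometry"))
  noise <- match.arg(noise)
  if (psf_sigma <= 0 || pixel_size <= 0) {
    stop("`psf_sigma` and `pixel_size` must be > 0.", call. = FALSE)
  }
  if (pixel_size > psf_sigma) {
    warning("`pixel_size` exceeds `psf_sigma`: profile is undersampled.",
            call. = FALSE)
  }
  crowns <- geometry_table(geom)
  occ <- if (is.null(occupancy)) {
    rep(1, nrow(crowns))
  } else if (is.data.frame(occupancy)) {
    stopifnot("occupancy" %in% names(occupancy),
              nrow(occupancy) == nrow(crowns))
    occupancy$occupancy
  } else {
    stopifnot(length(occupancy) == nrow(crowns))
    as.numeric(occupancy)
  }
  if (any(occ < 0 | occ > 1)) stop("Occupancies must lie in [0, 1].", call. = FALSE)

  w <- crowns$heads * occ
  pos_um <- crowns$position_nm / 1000
  centers <- c(-rev(pos_um), pos_um)
  weights <- c(rev(w), w)

  half_span <- max(pos_um) + 5 * psf_sigma
  n_half <- ceiling(half_span / pixel_size)
  x <- seq(-n_half, n_half) * pixel_size

  intensity <- colSums(weights * exp(-0.5 * outer(centers, x, "-")^2 / psf_sigma^2))
  if (max(intensity) > 0) intensity <- intensity / max(intensity)

  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    intensity <- rpois(length(intensity), noise_scale * intensity) / noise_scale
  }

  out <- tibble::tibble(position_um = x, intensity = intensity)
  attr(out, "psf_sigma") <- psf_sigma
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Full width at half maximum of an intensity profile
#'
#' Background is estimated as the mean of the outer 10% of pixels (5% at each
#' end). The FWHM is the distance between the outermost linear-interpolated
#' crossings of `background + (peak - background) / 2`, which for an A-band
#' doublet with a central dip measures the outer envelope width.
#'
#' @param profile an `intensity_profile` or any data frame with columns
#'   `position_um` and `intensity` (>= 5 points, equally spaced).
#' @return One-row tibble: `fwhm_um`, `peak_position_um`, `peak_value`,
#'   `background`.
#' @export
profile_fwhm <- function(profile) {
  stopifnot(all(c("position_um", "intensity") %in% names(profile)))
  x <- profile$position_um
  y <- profile$intensity
  if (length(x) < 5L) stop("Profile needs at least 5 points.", call. = FALSE)
  n_bg <- max(1L, floor(0.05 * length(x)))
  bg <- mean(c(y[seq_len(n_bg)], y[seq.int(length(y) - n_bg + 1L, length(y))]))
  peak <- max(y)
  if (peak <= bg) stop("Profile has no peak above background.", call. = FALSE)
  half <- bg + (peak - bg) / 2
  above <- y >= half
  if (above[1] || above[length(above)]) {
    stop("Profile truncated: half-max level not reached at the edges.",
         call. = FALSE)
  }
  idx <- which(above)
  i1 <- idx[1]               # first point at/above half
  i2 <- idx[length(idx)]     # last point at/above half
  x_left <- x[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (x[i1] - x[i1 - 1])
  x_right <- x[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * (x[i2 + 1] - x[i2])
  tibble::tibble(
    fwhm_um = x_right - x_left,
    peak_position_um = x[which.max(y)],
    peak_value = peak,
    background = bg
  )
}
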