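#' Build a crown-resolved half thick filament
#'
#' Constructs the myosin thick-filament geometry used throughout the package:
#' a half filament of `n_crowns_half` crowns of myosin head dimers, indexed
#' 1-based from the M-line side, each crown assigned to one of the three
#' canonical zones (P nearest the M-line, then the cMyBP-C-containing C-zone,
#' then the D-zone at the filament tip).
#'
#' Axial positions are measured in nm from the M-line center, with
#' `position(k) = bare_zone_half_width + k * crown_spacing`, so the default
#' rodent configuration (49 crowns: 4 P, 27 C, 18 D; 14.33 nm spacing; 80 nm
#' bare-zone half width) spans about 782 nm per half filament, i.e. an A-band
#' doublet of about 1.56 um, and places 27/49 = 55.1% of the heads in the
#' C-zone.
#'
#' @param n_crowns_half integer, crowns per half filament.
#' @param zone_counts named integer vector `c(P = , C = , D = )` giving the
#'   number of crowns per zone, in M-line-to-tip order. Must sum to
#'   `n_crowns_half`; zones with zero crowns are allowed.
#' @param crown_spacing axial crown repeat (nm).
#' @param bare_zone_half_width half width of the myosin-free bare zone (nm).
#' @param dimers_per_crown myosin molecules (head pairs) per crown.
#' @param thin_filament_length thin-filament length (um), used by the
#'   sarcomere simulator for overlap and thin-filament unit placement.
#'
#' @return An object of class `filament_geometry`: a list with the scalar
#'   configuration fields plus `crowns`, a tibble with one row per crown
#'   (`crown`, `zone`, `position_nm`, `heads`).
#' @examples
#' geom <- build_half_filament()
#' zone_fractions(geom)
#' @export
build_half_filament <- function(n_crowns_half = 49L,
                                zone_counts = c(P = 4L, C = 27L, D = 18L),
                                crown_spacing = 14.33,
                                bare_zone_half_width = 80,
                                dimers_per_crown = 3L,
                                thin_filament_length = 1.12) {
  n_crowns_half <- as.integer(n_crowns_half)
  if (is.na(n_crowns_half) || n_crowns_half < 1L) {
    stop("`n_crowns_half` must be a positive integer.", call. = FALSE)
  }
  if (crown_spacing <= 0) stop("`crown_spacing` must be > 0.", call. = FALSE)
  if (bare_zone_half_width < 0) {
    stop("`bare_zone_half_width` must be >= 0.", call. = FALSE)
  }
  if (dimers_per_crown < 1L) stop("`dimers_per_crown` must be >= 1.", call. = FALSE)
  if (!all(c("P", "C", "D") %in% names(zone_counts))) {
    stop("`zone_counts` must be named with P, C and D (use 0 for empty zones).",
         call. = FALSE)
  }
  zone_counts <- as.integer(zone_counts[c("P", "C", "D")])
  if (anyNA(zone_counts) || any(zone_counts < 0L)) {
    stop("Zone crown counts must be nonnegative integers.", call. = FALSE)
  }
  if (sum(zone_counts) != n_crowns_half) {
    stop("Zone crown counts must sum to `n_crowns_half` ",
         "(zones are contiguous P, then C, then D).", call. = FALSE)
  }

  zone <- rep(c("P", "C", "D"), times = zone_counts)
  crowns <- tibble::tibble(
    crown = seq_len(n_crowns_half),
    zone = factor(zone, levels = c("P", "C", "D")),
    position_nm = bare_zone_half_width + seq_len(n_crowns_half) * crown_spacing,
    heads = 2L * as.integer(dimers_per_crown)
  )

  structure(
    list(
      n_crowns_half = n_crowns_half,
      crown_spacing = crown_spacing,
      bare_zone_half_width = bare_zone_half_width,
      dimers_per_crown = as.integer(dimers_per_crown),
      thin_filament_length = thin_filament_length,
      crowns = crowns
    ),
    class = "filament_geometry"
  )
}

#' @export
print.filament_geometry <- function(x, ...) {
  fr <- zone_fractions(x)
  cat("<filament_geometry> ", x$n_crowns_half, " crowns x ",
      x$dimers_per_crown, " dimers (", total_heads(x), " heads/half filament)\n",
      sep = "")
  cat("  crown spacing ", x$crown_spacing, " nm, bare-zone half width ",
      x$bare_zone_half_width, " nm\n", sep = "")
  cat("  zone head fractions: ",
      paste(sprintf("%s %.3f", fr$zone, fr$fraction), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Per-crown geometry table
#'
#' @param geom a `filament_geometry`.
#' @return Tibble with columns `crown`, `zone`, `position_nm`, `heads`.
#' @export
geometry_table <- function(geom) {
  stopifnot(inherits(geom, "filament_geometry"))
  geom$crowns
}

#' Total heads per half filament
#' @param geom a `filament_geometry`.
#' @return Integer head count (crowns x dimers x 2).
#' @export
total_heads <- function(geom) {
  stopifnot(inherits(geom, "filament_geometry"))
  geom$n_crowns_half * geom$dimers_per_crown * 2L
}

#' Fraction of myosin heads in each zone
#'
#' Because every crown carries the same number of heads, zone head fractions
#' equal zone crown fractions; with the default rodent geometry the C-zone
#' holds 27/49 = 0.551 of the heads.
#'
#' @param geom a `filament_geometry`.
#' @return Tibble with columns `zone`, `crowns`, `heads`, `fraction`.
#' @export
zone_fractions <- function(geom) {
  stopifnot(inherits(geom, "filament_geometry"))
  geom$crowns |>
    dplyr::count(.data$zone, name = "crowns", .drop = FALSE) |>
    dplyr::mutate(
      heads = .data$crowns * geom$dimers_per_crown * 2L,
      fraction = .data$heads / sum(.data$heads)
    )
}

#' Axial extent of a zone
#'
#' @param geom a `filament_geometry`.
#' @param zone one of `"P"`, `"C"`, `"D"`.
#' @return Numeric length-2 vector, min and max crown positions (nm from the
#'   M-line center) of the crowns in that zone.
#' @export
zone_extent <- function(geom, zone) {
  stopifnot(inherits(geom, "filament_geometry"))
  zone <- match.arg(zone, c("P", "C", "D"))
  pos <- geom$crowns$position_nm[geom$crowns$zone == zone]
  if (length(pos) == 0L) {
    stop("Zone '", zone, "' contains no crowns in this geometry.", call. = FALSE)
  }
  c(min(pos), max(pos))
}

#' Mirrored full-filament axial span
#'
#' @param geom a `filament_geometry`.
#' @return Full bipolar filament span in nm:
#'   `2 * (bare_zone_half_width + n_crowns_half * crown_spacing)`.
#' @export
filament_span <- function(geom) {
  stopifnot(inherits(geom, "filament_geometry"))
  2 * (geom$bare_zone_half_width + geom$n_crowns_half * geom$crown_spacing)
}

#' Head addresses of a half filament
#'
#' Enumerates every myosin head as (crown, dimer, role); each dimer carries
#' exactly one blocked and one free head, reflecting the asymmetric
#' interacting-heads motif.
#'
#' @param geom a `filament_geometry`.
#' @return Tibble with columns `crown`, `zone`, `position_nm`, `dimer`,
#'   `role` (`"blocked"`/`"free"`).
#' @export
head_addresses <- function(geom) {
  stopifnot(inherits(geom, "filament_geometry"))
  geom$crowns |>
    dplyr::select("crown", "zone", "position_nm") |>
    tidyr::expand_grid(
      dimer = seq_len(geom$dimers_per_crown),
      role = factor(c("blocked", "free"), levels = c("blocked", "free"))
    )
}
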