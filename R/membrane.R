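#' Implicit membrane geometry
#'
#' Describes the implicit bilayer the protein is oriented in: a hydrophobic
#' core of half-width `core_half_width`, flanked by head-group zones of width
#' `head_width`, embedded in solvent. Zone transitions are smoothed with a
#' sigmoid of width `smoothing_width` so the potential is differentiable
#' everywhere. Optionally the model holds two parallel membranes at
#' center-to-center spacing `spacing_D` (midplanes at z = -D/2 and +D/2), or a
#' single membrane with constant global curvature `curvature_c` (realized as
#' a sphere of radius 1/|c| tangent to the planar midplane; the sign of `c`
#' selects the bowl direction, and the formulation is continuous as c -> 0).
#'
#' Electrostatics approximate each leaflet's head-group plane as a uniformly
#' charged sheet. The default sheet charge is zero; the positive-inside rule
#' is probed by assigning a slight negative density to the inner (lower)
#' leaflet during ranking.
#'
#' @param core_half_width half-width of the hydrophobic core, nm.
#' @param head_width width of each head-group zone, nm.
#' @param tail_type,head_type bead types representing core and head zones.
#' @param smoothing_width sigmoid smoothing width, nm.
#' @param leaflet_charge_density length-2 numeric, e/nm^2, c(inner, outer).
#' @param n_membranes 1 or 2.
#' @param spacing_D center-to-center membrane spacing, nm (n_membranes = 2).
#' @param curvature_c signed global curvature, 1/nm (0 = planar).
#' @param coulomb_cutoff charged-sheet integration disc radius, nm.
#' @param dielectric_scale relative-dielectric divisor for the Coulomb
#'   prefactor (default 15).
#' @return a `membrane_model` list.
#' @export
membrane_model <- function(core_half_width = 1.4, head_width = 0.6,
                           tail_type = "C1", head_type = "Na",
                           smoothing_width = 0.25,
                           leaflet_charge_density = c(0, 0),
                           n_membranes = 1, spacing_D = NULL,
                           curvature_c = 0, coulomb_cutoff = 3,
                           dielectric_scale = 15) {
  stopifnot_scalar(core_half_width, "core_half_width", positive = TRUE)
  stopifnot_scalar(smoothing_width, "smoothing_width", positive = TRUE)
  if (head_width < 0) abort("`head_width` must be >= 0")
  if (!n_membranes %in% c(1, 2)) abort("`n_membranes` must be 1 or 2")
  if (length(leaflet_charge_density) == 1L)
    leaflet_charge_density <- rep(leaflet_charge_density, 2)
  w <- core_half_width + head_width
  if (n_membranes == 2) {
    if (is.null(spacing_D)) abort("two membranes need `spacing_D`")
    if (spacing_D <= 2 * w)
      abort("`spacing_D` must exceed 2*(core_half_width + head_width)")
    if (curvature_c != 0)
      abort("global curvature is supported for single membranes only")
  }
  if (abs(curvature_c) * w >= 1)
    abort("|curvature_c| * (core_half_width + head_width) must be < 1")
  structure(
    list(core_half_width = core_half_width, head_width = head_width,
         tail_type = tail_type, head_type = head_type,
         smoothing_width = smoothing_width,
         leaflet_charge_density = leaflet_charge_density,
         n_membranes = n_membranes, spacing_D = spacing_D,
         curvature_c = curvature_c, coulomb_cutoff = coulomb_cutoff,
         dielectric_scale = dielectric_scale),
    class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model: %d membrane(s), core %.2f nm, head %.2f nm%s%s>\n",
              x$n_membranes, x$core_half_width, x$head_width,
              if (x$n_membranes == 2) sprintf(", D = %.2f nm", x$spacing_D) else "",
              if (x$curvature_c != 0) sprintf(", c = %.3f /nm", x$curvature_c) else ""))
  invisible(x)
}

membrane_midplanes <- function(membrane, D = NULL) {
  if (membrane$n_membranes == 2) {
    D <- D %||% membrane$spacing_D
    c(-D / 2, D / 2)
  } else 0
}

# z positions of the charged head-group sheets (and structure-marker planes)
membrane_plane_zs <- function(membrane, D = NULL) {
  off <- membrane$core_half_width + membrane$head_width / 2
  mids <- membrane_midplanes(membrane, D)
  as.numeric(vapply(mids, function(m) c(m - off, m + off), numeric(2)))
}

# sheet table: z position + signed surface charge density (inner leaflet =
# lower sheet of each membrane)
membrane_sheets <- function(membrane, D = NULL) {
  off <- membrane$core_half_width + membrane$head_width / 2
  mids <- membrane_midplanes(membrane, D)
  dens <- membrane$leaflet_charge_density
  do.call(rbind, lapply(mids, function(m)
    data.frame(z = c(m - off, m + off), density = c(dens[1], dens[2]))))
}

# signed distance of points from a membrane midplane surface; positive above.
# For curvature c != 0 the midplane is a sphere of radius 1/|c| tangent to
# z = mid at the axis: d = sign(c) * (1/|c| - |X - (0, 0, mid + 1/c)|),
# which tends to z - mid as c -> 0.
midplane_signed_distance <- function(xyz, mid = 0, c = 0) {
  if (abs(c) < 1e-9) return(xyz[, 3] - mid)
  z0 <- mid + 1 / c
  d <- sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - z0)^2)
  sign(c) * (1 / abs(c) - d)
}

#' Signed distances to the membrane zone boundaries
#'
#' For each point, returns the signed distance to the midplane of each
#' membrane plus the distances to the core and head-zone boundaries
#' (negative inside). Used by the mean field; exposed for inspection.
#'
#' @param xyz n-by-3 matrix or data frame of positions (nm).
#' @param membrane a [membrane_model()].
#' @param D override spacing for double membranes.
#' @param c override curvature.
#' @return tibble with columns `membrane`, `d_mid` (signed, positive above),
#'   `d_core` (|d_mid| - core_half_width) and `d_head`
#'   (|d_mid| - core_half_width - head_width).
#' @export
zone_signed_distances <- function(xyz, membrane, D = NULL, c = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) abort("`xyz` must have 3 columns")
  c <- c %||% membrane$curvature_c
  mids <- membrane_midplanes(membrane, D)
  core <- membrane$core_half_width
  head_w <- membrane$head_width
  single <- membrane$n_membranes == 1
  purrr::map_dfr(seq_along(mids), function(i) {
    d <- midplane_signed_distance(xyz, mids[i], if (single) c else 0)
    tibble(membrane = i, d_mid = d, d_core = abs(d) - core,
           d_head = abs(d) - core - head_w)
  })
}
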