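#' Rigid-body placements
#'
#' A placement is the minimization state of the rigid body: the insertion
#' depth `z` (nm), a direction 3-vector `v` (the image of the protein's local
#' z axis; need not be normalized) and a spin 2-vector `w` describing the
#' rotation about `v`. For double membranes the spacing `D` is part of the
#' state, and for curved membranes the curvature `c`. The (v, w) pair avoids
#' the artificial minimization barriers of (theta, phi) angles.
#'
#' The rotation is `R = R_spin(v_hat, atan2(w2, w1)) %*% R_align(z -> v_hat)`;
#' `w = c(1, 0)` is zero spin.
#'
#' @param z insertion depth, nm.
#' @param v direction 3-vector.
#' @param w spin 2-vector.
#' @param D optional membrane spacing, nm.
#' @param c optional curvature, 1/nm.
#' @return a `placement` list.
#' @export
placement <- function(z = 0, v = c(0, 0, 1), w = c(1, 0), D = NULL, c = NULL) {
  if (length(v) != 3 || vnorm(v) <= 0) abort("`v` must be a nonzero 3-vector")
  if (length(w) != 2) abort("`w` must be a 2-vector")
  if (vnorm(w) <= 0) w <- c(1, 0)
  structure(list(z = z, v = as.numeric(v), w = as.numeric(w), D = D, c = c),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  ang <- placement_angles(x)
  cat(sprintf("<placement: z = %.3f nm, tilt = %.1f deg, phi = %.1f deg%s%s>\n",
              x$z, ang[["theta"]] * 180 / pi, ang[["phi"]] * 180 / pi,
              if (!is.null(x$D)) sprintf(", D = %.2f nm", x$D) else "",
              if (!is.null(x$c)) sprintf(", c = %.3f /nm", x$c) else ""))
  invisible(x)
}

# rotation taking the unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cc <- sum(a * b)
  if (cc < -1 + 1e-12) {  # antipodal: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(ax - sum(ax * a) * a)
    return(axis_angle_matrix(ax, pi))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cc)
}

axis_angle_matrix <- function(axis, angle) {
  axis <- unit(axis)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation matrix of a placement
#' @param p a [placement()].
#' @return 3x3 proper rotation matrix.
#' @export
placement_rotation <- function(p) {
  vhat <- unit(p$v)
  Ra <- rotation_between(c(0, 0, 1), vhat)
  Rs <- axis_angle_matrix(vhat, atan2(p$w[2], p$w[1]))
  Rs %*% Ra
}

# recover a placement (v, w) from a rotation matrix (z passed through)
placement_from_matrix <- function(R, z, D = NULL, c = NULL) {
  v <- R %*% c(0, 0, 1)
  Ra <- rotation_between(c(0, 0, 1), as.numeric(v))
  p0 <- Ra %*% c(1, 0, 0)                 # reference transverse vector
  q <- R %*% c(1, 0, 0)                   # image of local x
  ca <- sum(p0 * q)
  cr <- c(p0[2] * q[3] - p0[3] * q[2], p0[3] * q[1] - p0[1] * q[3],
          p0[1] * q[2] - p0[2] * q[1])
  sa <- sum(unit(as.numeric(v)) * cr)
  placement(z = z, v = as.numeric(v), w = c(ca, sa), D = D, c = c)
}

# tilt theta (angle of v to membrane normal) and azimuth phi
placement_angles <- function(p) {
  vhat <- unit(p$v)
  c(theta = acos(max(-1, min(1, vhat[3]))), phi = atan2(vhat[2], vhat[1]) %% (2 * pi))
}

#' Tilt angle of a placement in degrees
#' @param p a [placement()].
#' @export
tilt_angle <- function(p) placement_angles(p)[["theta"]] * 180 / pi

#' Reflect a placement through the membrane midplane
#'
#' Mirrors the rigid body through z = 0. Because the potential depends only
#' on bead z coordinates (and laterally-invariant terms), the mirrored body
#' is realized by the proper rotation `diag(1, -1, -1) %*% R` together with
#' `z -> -z`; with neutral charged sheets the reflected configuration has the
#' identical potential, and with a slightly negatively charged inner leaflet
#' the side obeying the positive-inside rule scores lower.
#'
#' @param p a single-membrane [placement()].
#' @return the reflected placement; an involution.
#' @export
reflect_config <- function(p) {
  R <- placement_rotation(p)
  Rr <- diag(c(1, -1, -1)) %*% R
  placement_from_matrix(Rr, z = -p$z, D = p$D, c = p$c)
}

# free coordinates <-> parameter vector for the minimizer
placement_to_par <- function(p, use_D = FALSE, use_c = FALSE) {
  par <- c(p$z, p$v, p$w)
  if (use_D) par <- c(par, p$D)
  if (use_c) par <- c(par, p$c %||% 0)
  par
}

par_to_placement <- function(par, use_D = FALSE, use_c = FALSE) {
  D <- NULL; cc <- NULL
  k <- 6
  if (use_D) { k <- k + 1; D <- par[k] }
  if (use_c) { k <- k + 1; cc <- par[k] }
  placement(z = par[1], v = par[2:4], w = par[5:6], D = D, c = cc)
}

# direction (theta, phi) -> placement pieces
direction_to_v <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
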