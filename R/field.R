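#' Quasi-uniform probe shell on a sphere
#'
#' Places `n` probe positions on a sphere of radius `radius_d` around a
#' center using the Fibonacci-sphere construction. The probe shell models
#' the time-averaged first solvation/lipid shell of a CG bead: the
#' environmental bead density peaks at the Lennard-Jones minimum distance d.
#'
#' @param center 3-vector, nm.
#' @param radius_d shell radius, nm (typically \eqn{2^{1/6}\bar\sigma}).
#' @param n number of probes (>= 4).
#' @return n-by-3 matrix of positions; deterministic.
#' @export
probe_shell <- function(center = c(0, 0, 0), radius_d = 0.528, n = 32) {
  if (n < 4) abort("`n` must be >= 4 probe positions")
  stopifnot_scalar(radius_d, "radius_d", positive = TRUE)
  d <- fibonacci_sphere(n)
  sweep(radius_d * d, 2, center, `+`)
}

# unit vectors, quasi-uniform on the full sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  zc <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - zc^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), zc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# zone mixing profile (shared closed form with the C++ kernel)
field_profile_r <- function(d, eps_w, eps_h, eps_t, a, b, sw) {
  g1 <- sigmoid((d - a) / sw) + sigmoid((-d - a) / sw)
  g2 <- sigmoid((d - b) / sw) + sigmoid((-d - b) / sw)
  -eps_t + (eps_t - eps_h) * g1 + (eps_h - eps_w) * g2
}

#' Smoothed mean-field membrane energy of a bead type
#'
#' The mean field assigns to a probe of type `T_A` at position X the
#' Lennard-Jones minimum \eqn{-\epsilon(T_A, T_{zone})} of the zone the
#' position falls in (solvent, head or tail), with zone transitions smoothed
#' by a sigmoid of the signed boundary distance scaled by the smoothing
#' width, so the result is continuous and differentiable everywhere and
#' reaches the zone plateaus away from the boundaries.
#'
#' @param type bead type name.
#' @param xyz n-by-3 positions, nm.
#' @param membrane a [membrane_model()].
#' @param table an [build_interaction_table()].
#' @param smoothing_width override the membrane's smoothing width, nm.
#' @param D,c optional spacing / curvature overrides.
#' @return numeric vector of energies, kJ/mol.
#' @export
mean_field_energy <- function(type, xyz, membrane, table,
                              smoothing_width = NULL, D = NULL, c = NULL) {
  xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  sw <- smoothing_width %||% membrane$smoothing_width
  cc <- c %||% membrane$curvature_c
  eps_w <- table_lookup(table, type, table$water_type)
  eps_h <- table_lookup(table, type, membrane$head_type)
  eps_t <- table_lookup(table, type, membrane$tail_type)
  a <- membrane$core_half_width
  b <- a + membrane$head_width
  mids <- membrane_midplanes(membrane, D)
  vals <- lapply(mids, function(m) {
    d <- midplane_signed_distance(xyz, m, if (membrane$n_membranes == 1) cc else 0)
    field_profile_r(d, eps_w, eps_h, eps_t, a, b, sw)
  })
  if (length(vals) == 2) vals[[1]] + vals[[2]] + eps_w else vals[[1]]
}

#' Charged-sheet Coulomb energy by disc quadrature
#'
#' Energy of a point charge at axial distance `axial_offset` above an
#' infinite charged sheet, integrated numerically over the disc of radius
#' `cutoff_R` directly below the charge (midpoint rule in the radial
#' coordinate). Converges to the closed form
#' \eqn{2\pi k \sigma q (\sqrt{R^2+z^2} - |z|) / \epsilon_r}.
#'
#' @param charge elementary charges (vectorized).
#' @param axial_offset distance from the sheet plane, nm (vectorized).
#' @param sheet_charge_density e/nm^2.
#' @param cutoff_R disc radius, nm.
#' @param n_quadrature number of radial rings (>= 8).
#' @param dielectric_scale relative-dielectric divisor.
#' @return energies, kJ/mol.
#' @export
sheet_coulomb <- function(charge, axial_offset, sheet_charge_density,
                          cutoff_R = 3, n_quadrature = 128,
                          dielectric_scale = 15) {
  if (n_quadrature < 8) abort("`n_quadrature` must be >= 8")
  stopifnot_scalar(cutoff_R, "cutoff_R", positive = TRUE)
  r <- (seq_len(n_quadrature) - 0.5) * cutoff_R / n_quadrature
  dr <- cutoff_R / n_quadrature
  pref <- COULOMB_KE / dielectric_scale * sheet_charge_density * 2 * pi
  z <- abs(axial_offset)
  # integral over rings: sum 2 pi r dr / sqrt(r^2 + z^2)
  s <- vapply(z, function(zz) sum(r * dr / sqrt(r^2 + zz^2)), numeric(1))
  pref * charge * s
}

# d(sheet_coulomb)/d(axial_offset), signed in the offset
sheet_coulomb_dz <- function(charge, axial_offset, sheet_charge_density,
                             cutoff_R = 3, n_quadrature = 128,
                             dielectric_scale = 15) {
  r <- (seq_len(n_quadrature) - 0.5) * cutoff_R / n_quadrature
  dr <- cutoff_R / n_quadrature
  pref <- COULOMB_KE / dielectric_scale * sheet_charge_density * 2 * pi
  vapply(seq_along(axial_offset), function(i) {
    zz <- axial_offset[i]
    -pref * charge[i] * zz * sum(r * dr / (r^2 + zz^2)^1.5)
  }, numeric(1))
}

#' Precompute the potential context of a protein
#'
#' Builds everything that does not change across placements: probe shells
#' (attached in the protein frame so the interior-occupancy test is
#' rotation-invariant), the interior mask, zone plateau depths per probe,
#' and the charged surface beads. The orientation pipeline builds this once
#' and evaluates many placements against it.
#'
#' @param protein a [cg_protein()] with the surface mask computed.
#' @param membrane a [membrane_model()].
#' @param table an [build_interaction_table()].
#' @param n_probes probes per bead (default 32).
#' @return a `potential_context` list.
#' @export
prepare_potential <- function(protein, membrane, table, n_probes = 32) {
  surf <- which(protein$surface)
  if (!length(surf)) abort("no surface beads: run find_surface_beads() first")
  types <- protein$type[surf]
  xyz <- coords(protein)
  shell <- fibonacci_sphere(n_probes)
  # per-bead shell radius: LJ-minimum distance of the bead's mean sigma
  sig_bar <- vapply(types, function(t) mean(table$sigma[t, ], na.rm = TRUE), numeric(1))
  d_b <- 2^(1 / 6) * sig_bar
  nb <- length(surf)
  U <- matrix(0, nb * n_probes, 3)
  for (i in seq_len(nb)) {
    rows <- ((i - 1) * n_probes + 1):(i * n_probes)
    U[rows, ] <- sweep(d_b[i] * shell, 2, xyz[surf[i], ], `+`)
  }
  occ <- cpp_min_dist(U, xyz) < attr(protein, "occupancy_radius")
  probe_bead <- rep(seq_len(nb), each = n_probes)
  keep <- !occ
  eps_w <- table_lookup(table, types, table$water_type)
  eps_h <- table_lookup(table, types, membrane$head_type)
  eps_t <- table_lookup(table, types, membrane$tail_type)
  ch_idx <- surf[protein$charge[surf] != 0]
  structure(list(
    U = U[keep, , drop = FALSE],
    probe_bead = probe_bead[keep],
    n_kept = tabulate(probe_bead[keep], nbins = nb),
    eps_w = eps_w[probe_bead[keep]],
    eps_h = eps_h[probe_bead[keep]],
    eps_t = eps_t[probe_bead[keep]],
    surface_idx = surf, n_probes = n_probes,
    charged_xyz = xyz[ch_idx, , drop = FALSE],
    charges = protein$charge[ch_idx],
    membrane = membrane, table = table
  ), class = "potential_context")
}

# Coulomb term between the protein's charged beads (world frame) and the
# leaflet sheets; returns value and optionally d/dz, d/dD and the A-matrix
# contribution for the rotation gradient
coulomb_term <- function(ctx, world_xyz, local_xyz, D, want_grad = FALSE) {
  mem <- ctx$membrane
  if (!length(ctx$charges) || all(mem$leaflet_charge_density == 0)) {
    return(list(value = 0, dz = 0, dD = 0, A = matrix(0, 3, 3)))
  }
  sheets <- membrane_sheets(mem, D)
  val <- 0; dz <- 0; dD <- 0; A <- matrix(0, 3, 3)
  for (s in seq_len(nrow(sheets))) {
    if (sheets$density[s] == 0) next
    h <- world_xyz[, 3] - sheets$z[s]
    val <- val + sum(sheet_coulomb(ctx$charges, h, sheets$density[s],
                                   mem$coulomb_cutoff, 128, mem$dielectric_scale))
    if (want_grad) {
      g <- sheet_coulomb_dz(ctx$charges, h, sheets$density[s],
                            mem$coulomb_cutoff, 128, mem$dielectric_scale)
      dz <- dz + sum(g)
      if (mem$n_membranes == 2) {
        # sheet z moves with its membrane midplane: dz_s/dD = -1/2 (inner), +1/2 (outer)
        dzs <- if (sheets$z[s] < 0) -0.5 else 0.5
        dD <- dD - dzs * sum(g)
      }
      A <- A + rbind(0, 0, colSums(g * local_xyz))
    }
  }
  list(value = val, dz = dz, dD = dD, A = A)
}

# evaluate the total potential (and gradient) of a prepared context at a
# placement; the parameter order is (z, v1:3, w1:2[, D][, c])
eval_potential <- function(ctx, p, want_grad = FALSE) {
  mem <- ctx$membrane
  R <- placement_rotation(p)
  D <- if (mem$n_membranes == 2) (p$D %||% mem$spacing_D) else 0
  cc <- p$c %||% mem$curvature_c
  lj <- cpp_total_field(ctx$U, ctx$eps_w, ctx$eps_h, ctx$eps_t, R, p$z,
                        mem$core_half_width, mem$head_width,
                        mem$smoothing_width, mem$n_membranes, D, cc, want_grad)
  world_ch <- if (length(ctx$charges))
    ctx$charged_xyz %*% t(R) + matrix(c(0, 0, p$z), length(ctx$charges), 3, byrow = TRUE)
  else matrix(0, 0, 3)
  cl <- coulomb_term(ctx, world_ch, ctx$charged_xyz, D, want_grad)
  value <- lj$value + cl$value
  if (!want_grad) return(list(value = value))
  A <- lj$A + cl$A
  JR <- rotation_jacobian(p)
  gv <- vapply(1:5, function(j) sum(JR[, , j] * A), numeric(1))
  grad <- c(lj$dz + cl$dz, gv)
  list(value = value, grad = grad,
       dD = lj$dD + cl$dD, dc = lj$dc)
}

# central-difference Jacobian of the 3x3 rotation map in (v, w); the field
# part of the gradient is analytic, this 3x3 map is cheap to difference
rotation_jacobian <- function(p, h = 1e-6) {
  J <- array(0, c(3, 3, 5))
  par <- c(p$v, p$w)
  rot <- function(q) {
    vhat <- q[1:3] / vnorm(q[1:3])
    axis_angle_matrix(vhat, atan2(q[5], q[4])) %*%
      rotation_between(c(0, 0, 1), vhat)
  }
  for (j in 1:5) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    J[, , j] <- (rot(pp) - rot(pm)) / (2 * h)
  }
  J
}

#' Mean-field score of a single bead
#'
#' Sums the smoothed mean field over the bead's probe shell, skipping probes
#' inside the protein, and adds the bead's charged-sheet Coulomb term when
#' the bead is charged.
#'
#' @param bead one-row slice of a [cg_protein()] (local frame).
#' @param world_position 3-vector, nm: the bead's placed position.
#' @param membrane a [membrane_model()].
#' @param table an [build_interaction_table()].
#' @param n_probes probes on the shell.
#' @param occupied interior test: function taking an n-by-3 matrix of probe
#'   positions (same frame as `world_position`) returning a logical vector.
#' @return energy, kJ/mol.
#' @export
bead_score <- function(bead, world_position, membrane, table, n_probes = 32,
                       occupied = NULL) {
  sig_bar <- mean(table$sigma[bead$type, ], na.rm = TRUE)
  probes <- probe_shell(world_position, 2^(1 / 6) * sig_bar, n_probes)
  if (!is.null(occupied)) probes <- probes[!occupied(probes), , drop = FALSE]
  e <- if (nrow(probes)) sum(mean_field_energy(bead$type, probes, membrane, table)) else 0
  if (bead$charge != 0 && any(membrane$leaflet_charge_density != 0)) {
    sheets <- membrane_sheets(membrane)
    for (s in seq_len(nrow(sheets)))
      if (sheets$density[s] != 0)
        e <- e + sheet_coulomb(bead$charge, world_position[3] - sheets$z[s],
                               sheets$density[s], membrane$coulomb_cutoff,
                               128, membrane$dielectric_scale)
  }
  e
}

#' Total rigid-body potential of a placed protein
#'
#' Transforms the surface beads by the placement and sums their mean-field
#' scores plus charged-sheet Coulomb terms. Invariant under lateral
#' translation and rotation about the membrane normal.
#'
#' @param protein a [cg_protein()] with surface mask computed.
#' @param placement a [placement()].
#' @param membrane a [membrane_model()].
#' @param table an [build_interaction_table()].
#' @param n_probes probes per bead.
#' @param context optionally a precomputed [prepare_potential()] context.
#' @return energy, kJ/mol.
#' @export
total_potential <- function(protein, placement, membrane, table,
                            n_probes = 32, context = NULL) {
  if (vnorm(placement$v) <= 0) abort("placement direction `v` must be nonzero")
  ctx <- context %||% prepare_potential(protein, membrane, table, n_probes)
  eval_potential(ctx, placement)$value
}

#' Gradient of the total potential
#'
#' Analytic gradient in (z, v, w); derivatives in D and c analytic through
#' the field. Matches central finite differences of [total_potential()].
#'
#' @inheritParams total_potential
#' @return named list: `value`, `grad` (length 6: z, v1:3, w1:2), `dD`, `dc`.
#' @export
potential_gradient <- function(protein, placement, membrane, table,
                               n_probes = 32, context = NULL) {
  ctx <- context %||% prepare_potential(protein, membrane, table, n_probes)
  eval_potential(ctx, placement, want_grad = TRUE)
}
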