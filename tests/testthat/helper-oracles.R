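# Independent brute-force oracles, written directly from the model
# definitions with plain loops; deliberately share no code with the package
# internals they check.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# smoothed three-zone field of one membrane at signed midplane distance d
oracle_profile <- function(d, ew, eh, et, core, head, sw) {
  g1 <- oracle_sigmoid((d - core) / sw) + oracle_sigmoid((-d - core) / sw)
  g2 <- oracle_sigmoid((d - core - head) / sw) +
    oracle_sigmoid((-d - core - head) / sw)
  -et + (et - eh) * g1 + (eh - ew) * g2
}

oracle_field <- function(type, X, membrane, table, D = NULL, curv = NULL) {
  ew <- table$eps[type, table$water_type]
  eh <- table$eps[type, membrane$head_type]
  et <- table$eps[type, membrane$tail_type]
  sw <- membrane$smoothing_width
  curv <- if (is.null(curv)) membrane$curvature_c else curv
  if (membrane$n_membranes == 2) {
    D <- if (is.null(D)) membrane$spacing_D else D
    oracle_profile(X[3] + D / 2, ew, eh, et, membrane$core_half_width,
                   membrane$head_width, sw) +
      oracle_profile(X[3] - D / 2, ew, eh, et, membrane$core_half_width,
                     membrane$head_width, sw) + ew
  } else {
    d <- if (abs(curv) < 1e-9) X[3] else {
      z0 <- 1 / curv
      sign(curv) * (1 / abs(curv) -
                      sqrt(X[1]^2 + X[2]^2 + (X[3] - z0)^2))
    }
    oracle_profile(d, ew, eh, et, membrane$core_half_width,
                   membrane$head_width, sw)
  }
}

# own Fibonacci shell (same published construction, written independently)
oracle_shell <- function(n) {
  ga <- pi * (3 - sqrt(5))
  t(sapply(seq_len(n), function(i) {
    z <- 1 - 2 * (i - 0.5) / n
    r <- sqrt(1 - z^2)
    c(r * cos(ga * (i - 1)), r * sin(ga * (i - 1)), z)
  }))
}

# closed-form potential of a uniformly charged disc on its axis
oracle_disc_coulomb <- function(q, z, density, R, dielectric_scale) {
  138.935458 / dielectric_scale * 2 * pi * density * q *
    (sqrt(R^2 + z^2) - abs(z))
}

# brute-force total potential: explicit loops over surface beads and probes
oracle_total_potential <- function(protein, placement, membrane, table,
                                   n_probes = 32) {
  R <- placement_rotation(placement)
  xyz <- as.matrix(protein[, c("x", "y", "z")])
  occ_r <- attr(protein, "occupancy_radius")
  shell <- oracle_shell(n_probes)
  total <- 0
  for (b in which(protein$surface)) {
    ty <- protein$type[b]
    sig_bar <- mean(table$sigma[ty, ], na.rm = TRUE)
    d_b <- 2^(1 / 6) * sig_bar
    for (k in seq_len(n_probes)) {
      u <- xyz[b, ] + d_b * shell[k, ]
      dmin <- min(sqrt(rowSums(sweep(xyz, 2, u)^2)))
      if (dmin < occ_r) next
      Xw <- as.numeric(R %*% u) + c(0, 0, placement$z)
      total <- total + oracle_field(ty, Xw, membrane, table,
                                    D = placement$D, curv = placement$c)
    }
    if (protein$charge[b] != 0 && any(membrane$leaflet_charge_density != 0)) {
      Xb <- as.numeric(R %*% xyz[b, ]) + c(0, 0, placement$z)
      off <- membrane$core_half_width + membrane$head_width / 2
      mids <- if (membrane$n_membranes == 2) {
        D <- if (is.null(placement$D)) membrane$spacing_D else placement$D
        c(-D / 2, D / 2)
      } else 0
      for (m in mids) for (lf in c(-1, 1)) {
        dens <- if (lf < 0) membrane$leaflet_charge_density[1] else
          membrane$leaflet_charge_density[2]
        if (dens == 0) next
        # quadrature matching the stated disc rule
        nq <- 128
        r <- (seq_len(nq) - 0.5) * membrane$coulomb_cutoff / nq
        dr <- membrane$coulomb_cutoff / nq
        h <- abs(Xb[3] - (m + lf * off))
        total <- total + 138.935458 / membrane$dielectric_scale * dens *
          protein$charge[b] * 2 * pi * sum(r * dr / sqrt(r^2 + h^2))
      }
    }
  }
  total
}

# brute-force PG score curve: double loop over beads x grid points
oracle_pg_curve <- function(protein, membranes, zs, pg_table, pg_type = "Nda",
                            half = 1.0, sw = 0.1, pg_density = -0.3) {
  xyz <- as.matrix(protein[, c("x", "y", "z")])
  out <- numeric(length(zs))
  for (i in seq_along(zs)) {
    L <- 0
    for (b in seq_len(nrow(protein))) {
      ew <- pg_table$eps[protein$type[b], pg_table$water_type]
      ep <- pg_table$eps[protein$type[b], pg_type]
      d <- xyz[b, 3] - zs[i]
      g <- oracle_sigmoid((d - half) / sw) + oracle_sigmoid((-d - half) / sw)
      L <- L + (-ep * (1 - g) - ew * g)
    }
    C <- 0
    if (pg_density != 0) {
      Rcut <- membranes$coulomb_cutoff
      nq <- 128
      r <- (seq_len(nq) - 0.5) * Rcut / nq
      dr <- Rcut / nq
      for (b in which(protein$charge != 0)) {
        h <- abs(xyz[b, 3] - zs[i])
        C <- C + 138.935458 / membranes$dielectric_scale * pg_density *
          protein$charge[b] * 2 * pi * sum(r * dr / sqrt(r^2 + h^2))
      }
      off <- membranes$core_half_width + membranes$head_width / 2
      pg_q <- pg_density * pi * Rcut^2
      for (m in c(-membranes$spacing_D / 2, membranes$spacing_D / 2))
        for (lf in c(-1, 1)) {
          dens <- if (lf < 0) membranes$leaflet_charge_density[1] else
            membranes$leaflet_charge_density[2]
          if (dens == 0) next
          h <- abs(zs[i] - (m + lf * off))
          C <- C + 138.935458 / membranes$dielectric_scale * dens * pg_q *
            2 * pi * sum(r * dr / sqrt(r^2 + h^2))
        }
    }
    out[i] <- L + C
  }
  out
}

# exhaustive first-hit ray casting over a dense direction set: a bead is
# surface if some ray from far outside hits it first
oracle_surface_set <- function(xyz, occ_r, n_dirs = 400) {
  dirs <- oracle_shell(n_dirs)
  marked <- logical(nrow(xyz))
  ctr <- colMeans(xyz)
  rad <- max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) + 2
  for (b in seq_len(nrow(xyz))) for (k in seq_len(n_dirs)) {
    dir <- dirs[k, ]
    origin <- xyz[b, ] - 2 * rad * dir
    best_t <- Inf; best_j <- 0
    for (j in seq_len(nrow(xyz))) {
      pv <- xyz[j, ] - origin
      t <- sum(pv * dir)
      if (t <= 0 || t >= best_t) next
      perp <- pv - t * dir
      if (sum(perp^2) <= occ_r^2) { best_t <- t; best_j <- j }
    }
    if (best_j == b) { marked[b] <- TRUE; break }
  }
  marked
}

# angle of the rank-1 axis relative to the ground-truth axis after a known
# pre-rotation (membrane symmetric: either sign accepted)
tilt_error <- function(report, pre_rotation) {
  p1 <- report$placements[[1]]
  aw <- placement_rotation(p1) %*% pre_rotation %*% c(0, 0, 1)
  acos(min(1, abs(aw[3]))) * 180 / pi
}

# convex hull vertices in 3D via many supporting directions (test-side only)
geometry_hull_vertices <- function(xyz) {
  dirs <- oracle_shell(200)
  unique(apply(dirs %*% t(xyz), 1, which.max))
}
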