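#' Fibonacci-lattice directions on the upper hemisphere
#'
#' Quasi-uniform starting directions for the orientation grid, built from
#' the golden-angle spiral with theta restricted to `[0, pi/2]`.
#'
#' @param n number of directions (>= 1).
#' @return tibble with columns `theta`, `phi` (radians).
#' @export
fibonacci_directions <- function(n) {
  if (n < 1) abort("`n` must be >= 1")
  if (n == 1) return(tibble(theta = 0, phi = 0))
  i <- seq_len(n) - 0.5
  ct <- 1 - i / n            # cos(theta) in (0, 1): upper hemisphere
  ga <- pi * (3 - sqrt(5))
  tibble(theta = acos(ct), phi = (ga * (seq_len(n) - 1)) %% (2 * pi))
}

#' Initial insertion depth for a grid direction
#'
#' `band` mode places the center of the hydrophobic band (in the rotated
#' frame) at the membrane center -- the depth heuristic Z(theta, phi).
#' `scan` mode is the fallback Z'(theta, phi): the argmin of the potential
#' over a uniform z grid at fixed direction, used when no band exists (e.g.
#' peripheral membrane proteins).
#'
#' @param protein a [cg_protein()]; `band` mode requires the
#'   [hydrophobicity_profile()] columns.
#' @param direction c(theta, phi) in radians.
#' @param mode `"band"` or `"scan"`.
#' @param potential_fn for scan mode: function(z) -> potential at fixed
#'   direction.
#' @param z_range,z_steps scan grid.
#' @return z, nm.
#' @export
initial_depth <- function(protein, direction, mode = c("band", "scan"),
                          potential_fn = NULL, z_range = c(-6, 6),
                          z_steps = 61) {
  mode <- match.arg(mode)
  if (mode == "band") {
    if (!"band_member" %in% names(protein))
      abort("band mode needs hydrophobicity_profile() columns")
    band <- protein$band_member & protein$surface
    if (!any(band)) {
      if (is.null(potential_fn))
        abort("no hydrophobic band beads and no potential_fn for scan fallback")
      warn("no hydrophobic band beads; falling back to z grid scan")
      return(initial_depth(protein, direction, "scan", potential_fn,
                           z_range, z_steps))
    }
    R <- placement_rotation(placement(v = direction_to_v(direction[1], direction[2])))
    zrot <- coords(protein)[band, , drop = FALSE] %*% R[3, ]
    return(-mean(zrot))
  }
  if (is.null(potential_fn)) abort("scan mode needs `potential_fn`")
  zs <- seq(z_range[1], z_range[2], length.out = z_steps)
  zs[which.min(vapply(zs, potential_fn, numeric(1)))]
}

#' Initial membrane spacing for a double-membrane grid entry
#'
#' Coarse grid search over admissible spacings D minimizing the potential at
#' fixed direction and depth. Admissible spacings exceed twice the full
#' membrane width.
#'
#' @param protein a [cg_protein()].
#' @param direction c(theta, phi).
#' @param membrane a two-membrane [membrane_model()].
#' @param potential_fn function(D) -> potential.
#' @param D_max largest spacing tried; default from the protein extent.
#' @param steps grid resolution.
#' @return D, nm.
#' @export
initial_double_spacing <- function(protein, direction, membrane, potential_fn,
                                   D_max = NULL, steps = 41) {
  w <- membrane$core_half_width + membrane$head_width
  R <- placement_rotation(placement(v = direction_to_v(direction[1], direction[2])))
  span <- diff(range(coords(protein) %*% R[3, ]))
  D_min <- 2 * w + 0.2
  D_max <- D_max %||% max(D_min + 1, span + 2 * w)
  if (D_max <= D_min)
    abort("no admissible membrane spacing; protein too short for double-membrane mode")
  Ds <- seq(D_min, D_max, length.out = steps)
  Ds[which.min(vapply(Ds, potential_fn, numeric(1)))]
}

#' AdaDelta rigid-body minimization
#'
#' Minimizes a differentiable potential over the free placement coordinates
#' with the AdaDelta update rule (decay `rho`, regularizer `eps`); no global
#' learning rate is needed. Coordinates are scaled so depth (nm) and the
#' rotation 5-vector take comparable steps. The direction `v` and spin `w`
#' are renormalized each iteration (the potential only depends on their
#' directions). The best placement seen is returned, so the final potential
#' never exceeds the starting one.
#'
#' @param start a [placement()].
#' @param potential_fn function(par, want_grad) returning
#'   `list(value, grad)`; `par` is `c(z, v, w[, D][, c])`.
#' @param n_iters iterations (default 150).
#' @param rho,eps AdaDelta hyperparameters.
#' @param coord_scale per-coordinate step scaling.
#' @param use_D,use_c whether D / c are free coordinates.
#' @return list of class `minimization_result`: `start`, `final`,
#'   `final_potential`, `iterations_run`, `converged`.
#' @export
minimize_config <- function(start, potential_fn, n_iters = 150, rho = 0.95,
                            eps = 1e-4, coord_scale = NULL,
                            use_D = FALSE, use_c = FALSE) {
  if (n_iters < 1) abort("`n_iters` must be >= 1")
  par <- placement_to_par(start, use_D, use_c)
  np <- length(par)
  coord_scale <- coord_scale %||% c(2, rep(1, 5),
                                    if (use_D) 2, if (use_c) 0.05)
  Eg2 <- numeric(np); Ed2 <- numeric(np)
  f0 <- potential_fn(par, TRUE)
  if (!is.finite(f0$value) || any(!is.finite(f0$grad)))
    abort(sprintf("non-finite potential or gradient at start (z = %.3f)", par[1]))
  best_val <- f0$value; best_par <- par
  val <- f0$value; grad <- f0$grad
  for (it in seq_len(n_iters)) {
    Eg2 <- rho * Eg2 + (1 - rho) * grad^2
    step <- -sqrt(Ed2 + eps) / sqrt(Eg2 + eps) * grad * coord_scale
    Ed2 <- rho * Ed2 + (1 - rho) * (step / coord_scale)^2
    par <- par + step
    # keep the rotation parametrization well-conditioned
    nv <- vnorm(par[2:4]); if (nv > 0) par[2:4] <- par[2:4] / nv
    nw <- vnorm(par[5:6]); if (nw > 0) par[5:6] <- par[5:6] / nw
    f <- potential_fn(par, TRUE)
    if (!is.finite(f$value) || any(!is.finite(f$grad)))
      abort(sprintf("non-finite potential or gradient at iteration %d (z = %.3f)", it, par[1]))
    val <- f$value; grad <- f$grad
    if (val < best_val) { best_val <- val; best_par <- par }
  }
  structure(list(start = start,
                 final = par_to_placement(best_par, use_D, use_c),
                 final_potential = best_val, iterations_run = n_iters,
                 converged = vnorm(grad * coord_scale) < 1e-2),
            class = "minimization_result")
}

# mixed clustering metric: max of depth and orientation-angle components.
# The potential is invariant under world rotation about the membrane normal,
# so two placements describe the same orientation iff their protein-frame
# membrane normals (R^T z_hat) coincide; the angle between those normals is
# the rotational component of the metric.
config_distance <- function(a, b, t_z, t_ang) {
  na <- t(placement_rotation(a)) %*% c(0, 0, 1)
  nb <- t(placement_rotation(b)) %*% c(0, 0, 1)
  ang <- acos(max(-1, min(1, sum(na * nb)))) * 180 / pi
  d <- max(abs(a$z - b$z) / t_z, ang / t_ang)
  if (!is.null(a$D) && !is.null(b$D)) d <- max(d, abs(a$D - b$D) / t_z)
  d
}

#' Cluster minimization results
#'
#' Iterative single-linkage assignment: each result joins the first existing
#' cluster containing a member within tolerance, else founds a new cluster.
#' The tolerance is a mixed metric: a pair is within tolerance when
#' `max(|dz|/t_z, angle/t_ang) <= 1`.
#'
#' @param results list of [minimize_config()] results.
#' @param t_z depth tolerance, nm.
#' @param t_ang rotation-angle tolerance, degrees.
#' @return integer vector of cluster ids (1-based, in founding order).
#' @export
cluster_configs <- function(results, t_z = 0.3, t_ang = 8) {
  if (t_z <= 0 || t_ang <= 0) abort("cluster tolerances must be > 0")
  n <- length(results)
  id <- integer(n)
  members <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (j in seq_along(members)) {
      for (k in members[[j]]) {
        if (config_distance(results[[i]]$final, results[[k]]$final,
                            t_z, t_ang) <= 1) {
          id[i] <- j; members[[j]] <- c(members[[j]], i); placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      members[[length(members) + 1L]] <- i
      id[i] <- length(members)
    }
  }
  id
}

# average a cluster: mean z (and D, c), mean protein-frame membrane normal.
# The representative rotation is the lowest-potential member's rotation
# nudged so its protein-frame normal matches the cluster mean normal.
average_placements <- function(placements, potentials = NULL) {
  zs <- vapply(placements, function(p) p$z, numeric(1))
  Ds <- vapply(placements, function(p) p$D %||% NA_real_, numeric(1))
  cs <- vapply(placements, function(p) p$c %||% NA_real_, numeric(1))
  ns <- vapply(placements, function(p)
    as.numeric(t(placement_rotation(p)) %*% c(0, 0, 1)), numeric(3))
  nbar <- unit(rowMeans(matrix(ns, nrow = 3)))
  m <- if (is.null(potentials)) 1L else which.min(potentials)
  Rm <- placement_rotation(placements[[m]])
  nm <- as.numeric(t(Rm) %*% c(0, 0, 1))
  Rrep <- Rm %*% t(rotation_between(nm, nbar))
  placement_from_matrix(Rrep, z = mean(zs),
                        D = if (all(is.na(Ds))) NULL else mean(Ds, na.rm = TRUE),
                        c = if (all(is.na(cs))) NULL else mean(cs, na.rm = TRUE))
}

#' Rank clustered minima
#'
#' Ranks cluster representatives by
#' `R_i = P(L_i) + lambda * (-log(|C_i| / |G|))`: the potential at the
#' representative penalized for small basin occupancy (the fraction of grid
#' starts that converged into the cluster, a proxy for basin depth).
#'
#' @param reps list of representative placements.
#' @param potentials potential at each representative, kJ/mol.
#' @param sizes cluster occupancies |C_i|.
#' @param n_grid total grid size |G|.
#' @param lambda occupancy penalty scale, kJ/mol (default 2).
#' @return tibble sorted ascending by `rank_score_R` with a `rank` column.
#' @export
rank_minima <- function(reps, potentials, sizes, n_grid, lambda = 2) {
  if (!length(reps)) abort("need at least one cluster")
  R <- potentials + lambda * (-log(sizes / n_grid))
  out <- tibble(cluster = seq_along(reps), potential = potentials,
                cluster_size = sizes, rank_score_R = R,
                representative = reps)
  out <- out[order(out$rank_score_R), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "cluster", "potential", "cluster_size", "rank_score_R",
          "representative")]
}
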