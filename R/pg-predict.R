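#' Peptidoglycan-layer slab field
#'
#' The PG layer is modeled as a sigmoid-smoothed slab of half-thickness
#' `pg_half_width` centered at `z_pg`, built exactly like the membrane mean
#' field but with a single representative PG bead type and the
#' Martini-2-style PG interaction table.
#'
#' @param type bead type of the probe bead.
#' @param xyz n-by-3 positions, nm.
#' @param z_pg slab center, nm.
#' @param pg_table PG interaction table (default bundled Martini-2-style).
#' @param pg_type representative PG bead type.
#' @param pg_half_width slab half-thickness, nm (default 1.0, i.e. a 2 nm
#'   slab).
#' @param smoothing_width sigmoid width, nm.
#' @return energies, kJ/mol.
#' @export
pg_field_energy <- function(type, xyz, z_pg,
                            pg_table = build_interaction_table("bundled_m2"),
                            pg_type = "Nda", pg_half_width = 1.0,
                            smoothing_width = 0.1) {
  xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  eps_w <- table_lookup(pg_table, type, pg_table$water_type)
  eps_p <- table_lookup(pg_table, type, pg_type)
  d <- xyz[, 3] - z_pg
  g <- sigmoid((d - pg_half_width) / smoothing_width) +
       sigmoid((-d - pg_half_width) / smoothing_width)
  -eps_p * (1 - g) - eps_w * g
}

#' Score curve for the peptidoglycan layer position
#'
#' For an oriented periplasm-spanning protein (double-membrane frame,
#' membranes at -D/2 and +D/2), samples the PG placement score
#' `P_PG(z) = C(z) + L(z)` on a z grid across the inter-membrane gap:
#' `L(z)` sums the slab mean field over all beads, and `C(z)` collects the
#' charged-sheet Coulomb terms between the (negatively charged) PG sheet,
#' the protein charges, and the membrane leaflet sheets.
#'
#' @param protein an oriented [cg_protein()] in the double-membrane frame.
#' @param membranes a 2-membrane [membrane_model()].
#' @param z_range `c(low, high)` inside the gap; default the gap minus one
#'   head width on each side.
#' @param steps grid size (default 0.1 nm resolution).
#' @param pg_table PG interaction table.
#' @param pg_type,pg_half_width,smoothing_width slab field parameters.
#' @param pg_sheet_density PG sheet charge density, e/nm^2 (default -0.3;
#'   PG charges are immobile, so electrostatics matter here).
#' @return tibble: `z`, `L`, `C`, `P` (= C + L).
#' @export
pg_score_curve <- function(protein, membranes, z_range = NULL, steps = NULL,
                           pg_table = build_interaction_table("bundled_m2"),
                           pg_type = "Nda", pg_half_width = 1.0,
                           smoothing_width = 0.1, pg_sheet_density = -0.3) {
  if (membranes$n_membranes != 2)
    abort("pg_score_curve needs a two-membrane model (the periplasmic gap)")
  D <- membranes$spacing_D
  w <- membranes$core_half_width + membranes$head_width
  gap <- c(-D / 2 + w, D / 2 - w)
  z_range <- z_range %||% (gap + c(1, -1) * membranes$head_width)
  if (z_range[1] < gap[1] - 1e-9 || z_range[2] > gap[2] + 1e-9)
    abort("`z_range` must lie inside the inter-membrane gap")
  steps <- steps %||% max(2L, ceiling(diff(z_range) / 0.1) + 1L)
  zs <- seq(z_range[1], z_range[2], length.out = steps)
  xyz <- coords(protein)

  L <- vapply(zs, function(z)
    sum(vapply(unique(protein$type), function(tt)
      sum(pg_field_energy(tt, xyz[protein$type == tt, , drop = FALSE], z,
                          pg_table, pg_type, pg_half_width, smoothing_width)),
      numeric(1))), numeric(1))

  C <- numeric(length(zs))
  if (pg_sheet_density != 0) {
    ch <- protein$charge != 0
    sheets <- membrane_sheets(membranes)
    R <- membranes$coulomb_cutoff
    pg_equiv_q <- pg_sheet_density * pi * R^2
    for (i in seq_along(zs)) {
      v <- 0
      if (any(ch))
        v <- v + sum(sheet_coulomb(protein$charge[ch], xyz[ch, 3] - zs[i],
                                   pg_sheet_density, R, 128,
                                   membranes$dielectric_scale))
      for (s in seq_len(nrow(sheets)))
        if (sheets$density[s] != 0)
          v <- v + sheet_coulomb(pg_equiv_q, zs[i] - sheets$z[s],
                                 sheets$density[s], R, 128,
                                 membranes$dielectric_scale)
      C[i] <- v
    }
  }
  tibble(z = zs, L = L, C = C, P = L + C)
}

#' Predict the peptidoglycan layer position from a score curve
#'
#' Without a bias the prediction is the global minimum of the curve. Because
#' external factors (e.g. Braun's lipoprotein) can fix the true position at
#' another local minimum, all local minima are reported; when a position
#' guess is supplied, a strong quadratic bias
#' `bias_strength * (z - guess)^2` is added before taking the argmin.
#'
#' @param curve tibble from [pg_score_curve()] (columns `z`, `P`).
#' @param bias_guess optional guessed position, nm.
#' @param bias_strength kJ/mol/nm^2 (default 50).
#' @return a `pg_prediction`: `z_pg`, `local_minima` tibble, the `curve`,
#'   and the bias settings.
#' @export
predict_pg_position <- function(curve, bias_guess = NULL, bias_strength = 50) {
  if (!nrow(curve)) abort("empty score curve")
  P <- curve$P
  score <- if (!is.null(bias_guess)) P + bias_strength * (curve$z - bias_guess)^2 else P
  n <- length(P)
  is_min <- vapply(seq_len(n), function(i)
    i > 1 && i < n && P[i] <= P[i - 1] && P[i] <= P[i + 1], logical(1))
  structure(list(
    z_pg = curve$z[which.min(score)],
    local_minima = tibble(z = curve$z[is_min], score = P[is_min]),
    curve = curve, bias_guess = bias_guess,
    bias_strength = if (!is.null(bias_guess)) bias_strength else NA_real_
  ), class = "pg_prediction")
}

#' @export
print.pg_prediction <- function(x, ...) {
  cat(sprintf("<pg_prediction: z_pg = %.2f nm, %d local minima%s>\n",
              x$z_pg, nrow(x$local_minima),
              if (!is.null(x$bias_guess))
                sprintf(", biased toward %.2f nm", x$bias_guess) else ""))
  invisible(x)
}

#' Cross-sectional area profile through a protein
#'
#' For each z, the area of the 2-D convex hull of the (x, y) coordinates of
#' beads within a slab of the given thickness. The hull approximates the
#' area the protein occludes in the PG mesh, which cannot fill concavities.
#'
#' @param protein a [cg_protein()].
#' @param z_range `c(low, high)`; default the protein extent.
#' @param steps number of slab centers.
#' @param slab_thickness nm (default 2, the PG layer thickness).
#' @return tibble: `z`, `n_beads`, `area` (nm^2; 0 when fewer than 3 beads).
#' @export
cross_section_profile <- function(protein, z_range = NULL, steps = NULL,
                                  slab_thickness = 2) {
  stopifnot_scalar(slab_thickness, "slab_thickness", positive = TRUE)
  xyz <- coords(protein)
  z_range <- z_range %||% range(xyz[, 3])
  steps <- steps %||% max(2L, ceiling(diff(z_range) / 0.1) + 1L)
  zs <- seq(z_range[1], z_range[2], length.out = steps)
  purrr::map_dfr(zs, function(z) {
    sel <- abs(xyz[, 3] - z) <= slab_thickness / 2
    tibble(z = z, n_beads = sum(sel), area = hull_area(xyz[sel, 1], xyz[sel, 2]))
  })
}

hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}
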