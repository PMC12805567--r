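#' Orient a CG protein in an implicit membrane
#'
#' The full orientation pipeline: surface finding, hydrophobicity profiling,
#' a Fibonacci grid of starting configurations with band-derived insertion
#' depths (and spacings for double membranes), AdaDelta minimization from
#' every start, a positive-inside reflection test, clustering of the minima,
#' ranking by potential and basin occupancy, and a curvature scan of the
#' leading orientations.
#'
#' @param protein a [cg_protein()].
#' @param table an [build_interaction_table()]; default the bundled
#'   Martini-3-style table.
#' @param membrane a [membrane_model()].
#' @param n_grid number of starting configurations (`-ng`; default 36,
#'   peripheral preset 72).
#' @param n_iters minimization iterations (`-ni`; default 150, peripheral
#'   preset 300).
#' @param depth_mode `"band"` (hydrophobic-band heuristic) or `"scan"`
#'   (z grid search; use for peripheral proteins).
#' @param double orient across two membranes (requires a 2-membrane model or
#'   sets one up with `spacing_D` guessed per start).
#' @param curvature minimize global curvature c alongside the placement.
#' @param positive_inside_density inner-leaflet charge density (e/nm^2) used
#'   only for the reflection ranking test; 0 disables the test.
#' @param n_probes probes per bead.
#' @param t_z,t_ang clustering tolerances (nm, degrees).
#' @param lambda rank occupancy penalty, kJ/mol.
#' @param curvature_scan_range,curvature_scan_steps P(c) scan over the
#'   leading orientations.
#' @param seed seed for the surface finder.
#' @param out_dir if given, ranked oriented structures are written there in
#'   the input format.
#' @return an `orientation_report`: ranked orientations (tibble via
#'   [generics::tidy()]), curvature scans, settings and the profiled protein.
#' @export
orient <- function(protein, table = build_interaction_table("bundled_m3"),
                   membrane = membrane_model(), n_grid = 36, n_iters = 150,
                   depth_mode = c("band", "scan"), double = FALSE,
                   curvature = FALSE, positive_inside_density = -0.02,
                   n_probes = 32, t_z = 0.3, t_ang = 8, lambda = 2,
                   curvature_scan_range = c(-0.1, 0.1),
                   curvature_scan_steps = 21, seed = 1, out_dir = NULL) {
  depth_mode <- match.arg(depth_mode)
  if (double && curvature) abort("double-membrane and curvature modes are mutually exclusive")
  if (double && membrane$n_membranes != 2)
    abort("double = TRUE needs a membrane_model(n_membranes = 2, spacing_D = ...)")
  if (all(protein$surface)) protein <- find_surface_beads(protein, seed = seed)
  if (!any(protein$surface)) abort("surface finding marked zero beads")
  protein <- hydrophobicity_profile(protein, table)

  ctx <- prepare_potential(protein, membrane, table, n_probes)
  use_D <- double; use_c <- curvature
  pot_fn <- function(par, want_grad = FALSE) {
    p <- par_to_placement(par, use_D, use_c)
    r <- eval_potential(ctx, p, want_grad)
    if (!want_grad) return(r)
    g <- r$grad
    if (use_D) g <- c(g, r$dD)
    if (use_c) g <- c(g, r$dc)
    list(value = r$value, grad = g)
  }

  dirs <- fibonacci_directions(n_grid)
  starts <- purrr::map(seq_len(n_grid), function(i) {
    th <- dirs$theta[i]; ph <- dirs$phi[i]
    v <- direction_to_v(th, ph)
    zfn <- function(z) eval_potential(ctx, placement(z = z, v = v))$value
    z0 <- initial_depth(protein, c(th, ph), depth_mode, potential_fn = zfn)
    D0 <- NULL
    if (double) {
      Dfn <- function(D) eval_potential(ctx, placement(z = z0, v = v, D = D))$value
      D0 <- initial_double_spacing(protein, c(th, ph), membrane, Dfn)
    }
    placement(z = z0, v = v, D = D0, c = if (curvature) 0 else NULL)
  })

  results <- purrr::map(starts, function(s)
    minimize_config(s, pot_fn, n_iters = n_iters, use_D = use_D, use_c = use_c))

  # positive-inside reflection test (single symmetric membranes only)
  if (!double && !curvature && positive_inside_density != 0 &&
      length(ctx$charges) > 0) {
    mem_pi <- membrane
    mem_pi$leaflet_charge_density <- c(positive_inside_density, 0)
    ctx_pi <- ctx; ctx_pi$membrane <- mem_pi
    results <- purrr::map(results, function(r) {
      refl <- reflect_config(r$final)
      p_here <- eval_potential(ctx_pi, r$final)$value
      p_refl <- eval_potential(ctx_pi, refl)$value
      if (p_refl < p_here) {
        r$final <- refl
        r$final_potential <- eval_potential(ctx, refl)$value
      }
      r
    })
  }

  ids <- cluster_configs(results, t_z = t_z, t_ang = t_ang)
  reps <- purrr::map(sort(unique(ids)), function(j)
    average_placements(purrr::map(results[ids == j], "final"),
                       purrr::map_dbl(results[ids == j], "final_potential")))
  pots <- vapply(reps, function(p) eval_potential(ctx, p)$value, numeric(1))
  sizes <- as.integer(table(ids))
  ranked <- rank_minima(reps, pots, sizes, n_grid, lambda = lambda)

  scans <- NULL
  if (!double) {
    cs <- seq(curvature_scan_range[1], curvature_scan_range[2],
              length.out = curvature_scan_steps)
    top <- head(ranked$rank, 3)
    scans <- purrr::map_dfr(top, function(rk) {
      p <- ranked$representative[[which(ranked$rank == rk)]]
      tibble(rank = rk, c = cs,
             potential = vapply(cs, function(ci) {
               pc <- p; pc$c <- ci
               eval_potential(ctx, pc)$value
             }, numeric(1)))
    })
  }

  rep_tbl <- purrr::map_dfr(seq_len(nrow(ranked)), function(i) {
    p <- ranked$representative[[i]]
    tibble(rank = ranked$rank[i], potential = ranked$potential[i],
           z = p$z, tilt = tilt_angle(p),
           phi = placement_angles(p)[["phi"]] * 180 / pi,
           D = p$D %||% NA_real_, c = p$c %||% NA_real_,
           cluster_size = ranked$cluster_size[i],
           rank_score_R = ranked$rank_score_R[i])
  })

  report <- structure(list(
    orientations = rep_tbl, placements = ranked$representative,
    curvature_scan = scans, results = results, cluster_id = ids,
    protein = protein,
    settings = list(n_grid = n_grid, n_iters = n_iters,
                    depth_mode = depth_mode, double = double,
                    curvature = curvature, n_probes = n_probes,
                    t_z = t_z, t_ang = t_ang, lambda = lambda, seed = seed,
                    membrane = membrane, table = table$source_label,
                    notes = paste("rank score R = P + lambda*(-log(size/n_grid));",
                                  "double-membrane D seeded by coarse grid search"))
  ), class = "orientation_report")

  if (!is.null(out_dir)) write_orientation_outputs(report, out_dir)
  report
}

#' @export
print.orientation_report <- function(x, ...) {
  cat(sprintf("<orientation_report: %d ranked orientation(s) from %d starts>\n",
              nrow(x$orientations), x$settings$n_grid))
  print(x$orientations)
  invisible(x)
}

#' Write ranked structures and the JSON report of an orientation run
#'
#' @param report an [orient()] result.
#' @param out_dir output directory (created if absent).
#' @param max_rank how many ranked structures to write.
#' @return paths written, invisibly.
#' @export
write_orientation_outputs <- function(report, out_dir, max_rank = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- attr(report$protein, "format") %||% "gro"
  mem <- report$settings$membrane
  paths <- character()
  for (i in seq_len(min(max_rank, nrow(report$orientations)))) {
    p <- report$placements[[i]]
    memi <- mem
    if (!is.null(p$D)) memi$spacing_D <- p$D
    f <- file.path(out_dir, sprintf("oriented_rank%d.%s", i, fmt))
    write_oriented_structure(report$protein, p, f, membrane = memi)
    paths <- c(paths, f)
  }
  jf <- file.path(out_dir, "orientation_report.json")
  jsonlite::write_json(list(
    orientations = report$orientations,
    settings = report$settings[c("n_grid", "n_iters", "depth_mode", "double",
                                 "curvature", "t_z", "t_ang", "lambda", "seed",
                                 "table", "notes")],
    files = basename(paths)
  ), jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$curvature_scan)) {
    tf <- file.path(out_dir, "curvature_scan.tsv")
    utils::write.table(report$curvature_scan, tf, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, tf)
  }
  invisible(c(paths, jf))
}
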