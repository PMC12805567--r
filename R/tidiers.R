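#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an orientation report
#'
#' @param x an [orient()] result.
#' @param ... unused.
#' @return tibble of ranked orientations: rank, potential (kJ/mol), z (nm),
#'   tilt and phi (degrees), D, c, cluster_size, rank_score_R.
#' @method tidy orientation_report
#' @export
tidy.orientation_report <- function(x, ...) x$orientations

#' @rdname tidy.orientation_report
#' @method glance orientation_report
#' @export
glance.orientation_report <- function(x, ...) {
  tibble(n_starts = x$settings$n_grid, n_iters = x$settings$n_iters,
         n_clusters = nrow(x$orientations),
         best_potential = min(x$orientations$potential),
         rank1_z = x$orientations$z[x$orientations$rank == 1],
         rank1_tilt = x$orientations$tilt[x$orientations$rank == 1])
}

#' Tidy a peptidoglycan position prediction
#'
#' @param x a [predict_pg_position()] result.
#' @param ... unused.
#' @return the sampled score curve as a tibble (z, L, C, P).
#' @method tidy pg_prediction
#' @export
tidy.pg_prediction <- function(x, ...) x$curve

#' @rdname tidy.pg_prediction
#' @method glance pg_prediction
#' @export
glance.pg_prediction <- function(x, ...) {
  tibble(z_pg = x$z_pg, n_local_minima = nrow(x$local_minima),
         biased = !is.null(x$bias_guess),
         score_min = min(x$curve$P), score_max = max(x$curve$P))
}

#' Tidy a peptidoglycan mesh
#'
#' @param x a `pg_mesh`.
#' @param ... unused.
#' @return the unit tibble.
#' @method tidy pg_mesh
#' @export
tidy.pg_mesh <- function(x, ...) x$units

#' @rdname tidy.pg_mesh
#' @method glance pg_mesh
#' @export
glance.pg_mesh <- function(x, ...) {
  sl <- strand_lengths(x)
  tibble(n_units = nrow(x$units), n_strands = nrow(sl),
         mean_strand_length = mean(sl$length),
         n_crosslinks = nrow(x$crosslinks),
         cell_x = x$cell[1], cell_y = x$cell[2], cell_z = x$cell[3],
         kl_final = attr(x, "kl_final") %||% NA_real_,
         mean_strain = attr(x, "mean_strain") %||% NA_real_)
}
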