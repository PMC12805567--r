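#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot the ranked orientations and their curvature scans
#'
#' Ranked potentials as points plus, when available, the potential-versus-
#' curvature scan of the leading orientations.
#'
#' @param object an [orient()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot orientation_report
#' @export
autoplot.orientation_report <- function(object, ...) {
  if (!is.null(object$curvature_scan)) {
    ggplot(object$curvature_scan,
           aes(x = .data$c, y = .data$potential,
               colour = factor(.data$rank))) +
      geom_line() +
      labs(x = "global curvature c (1/nm)", y = "potential (kJ/mol)",
           colour = "rank",
           title = "Potential vs membrane curvature for leading orientations") +
      theme_minimal()
  } else {
    ggplot(object$orientations, aes(x = .data$rank, y = .data$potential)) +
      geom_point(aes(size = .data$cluster_size)) +
      labs(x = "rank", y = "potential (kJ/mol)", size = "basin size",
           title = "Ranked orientation minima") +
      theme_minimal()
  }
}

#' Plot a peptidoglycan placement score curve
#'
#' The pseudo-potential P_PG(z) with local minima marked and the predicted
#' placement as a vertical line.
#'
#' @param object a [predict_pg_position()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pg_prediction
#' @export
autoplot.pg_prediction <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$z, y = .data$P)) +
    geom_line() +
    geom_point(data = object$local_minima,
               aes(x = .data$z, y = .data$score), colour = "red") +
    geom_vline(xintercept = object$z_pg, linetype = "dashed") +
    labs(x = "PG layer position z (nm)", y = expression(P[PG] * " (kJ/mol)"),
         title = "Peptidoglycan layer placement score") +
    theme_minimal()
}

#' Plot the strand length distribution of a mesh against a target
#'
#' @param object a `pg_mesh`.
#' @param target optional [length_target()] overlaid as a line.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pg_mesh
#' @export
autoplot.pg_mesh <- function(object, target = NULL, ...) {
  sl <- dplyr::count(strand_lengths(object), .data$length, name = "n")
  sl$fraction <- sl$n / sum(sl$n)
  p <- ggplot(sl, aes(x = .data$length, y = .data$fraction)) +
    geom_col() +
    labs(x = "strand length (units)", y = "fraction",
         title = "Glycan strand length distribution") +
    theme_minimal()
  if (!is.null(target)) {
    xs <- seq_len(object$n_units_per_line)
    dens <- target_density(target, xs)
    p <- p + geom_line(data = tibble(length = xs, d = dens / sum(dens)),
                       aes(x = .data$length, y = .data$d), colour = "blue")
  }
  p
}

#' Plot a cross-sectional area profile
#'
#' @param profile tibble from [cross_section_profile()].
#' @return a ggplot.
#' @export
plot_cross_section <- function(profile) {
  ggplot(profile, aes(x = .data$z, y = .data$area)) +
    geom_line() +
    labs(x = "z (nm)", y = expression("convex hull area (nm"^2 * ")"),
         title = "Protein cross-sectional area profile") +
    theme_minimal()
}
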