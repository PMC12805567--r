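#' Find environment-facing surface beads by ray casting
#'
#' Core beads never touch the environment, so they are removed before the
#' potential is evaluated. The finder shoots batches of rays from outside
#' the protein's bounding sphere toward randomly chosen target beads; the
#' first bead whose center lies within the occupancy radius of a ray is
#' marked as surface. Batches repeat until a batch marks fewer than
#' `stop_fraction * batch_size` new beads. The result is deterministic for a
#' fixed seed, and the marked set is monotone non-decreasing in the number
#' of batches.
#'
#' @param protein a [cg_protein()].
#' @param seed RNG seed for ray sampling.
#' @param batch_size rays per batch (default 512).
#' @param stop_fraction stop when new-hit fraction falls below this
#'   (default 0.01).
#' @param max_batches safety cap.
#' @return the protein with `surface` updated.
#' @export
find_surface_beads <- function(protein, seed = 1, batch_size = 512,
                               stop_fraction = 0.01, max_batches = 200) {
  if (batch_size < 1) abort("`batch_size` must be >= 1")
  if (stop_fraction <= 0 || stop_fraction >= 1) abort("`stop_fraction` must be in (0, 1)")
  xyz <- coords(protein)
  n <- nrow(xyz)
  if (n == 1L) {
    protein$surface <- TRUE
    return(protein)
  }
  ctr <- colMeans(xyz)
  rad <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2))) + 2
  occ <- attr(protein, "occupancy_radius")
  marked <- logical(n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (b in seq_len(max_batches)) {
    target <- sample.int(n, batch_size, replace = TRUE)
    # random ray directions; origin pulled back outside the bounding sphere
    dirs <- matrix(rnorm(batch_size * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    origins <- xyz[target, , drop = FALSE] - 2 * rad * dirs
    hits <- cpp_ray_first_hit(origins, dirs, xyz, occ)
    hits <- hits[hits > 0]
    new_hits <- sum(!marked[hits])
    marked[hits] <- TRUE
    if (new_hits < stop_fraction * batch_size) break
  }
  protein$surface <- marked
  protein
}

#' Hydrophobicity profile of a CG protein
#'
#' Assigns every bead a hydrophobicity score
#' `h = eps_max_water - eps(type, water)` (so beads interacting weakly with
#' water score high), smooths it over the neighborhood within `radius`
#' (default 2 nm), and flags the hydrophobic band as beads whose smoothed
#' score exceeds the cutoff. The band locates the membrane-facing belt and
#' seeds the initial insertion depth.
#'
#' @param protein a [cg_protein()].
#' @param table an [build_interaction_table()].
#' @param radius neighborhood radius, nm.
#' @param cutoff `"auto"` (mean + 0.5 sd of the smoothed score over surface
#'   beads) or a numeric cutoff C.
#' @return the protein tibble with columns `h`, `h_bar` and `band_member`
#'   added.
#' @export
hydrophobicity_profile <- function(protein, table, radius = 2.0,
                                   cutoff = "auto") {
  stopifnot_scalar(radius, "radius", positive = TRUE)
  eps_w <- table_lookup(table, protein$type, table$water_type)
  h <- max(table$eps[table$water_type, ], na.rm = TRUE) - eps_w
  xyz <- coords(protein)
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  within <- d2 <= radius^2
  h_bar <- as.numeric((within %*% h) / rowSums(within))
  if (identical(cutoff, "auto")) {
    hs <- h_bar[protein$surface]
    cutoff <- mean(hs) + 0.5 * sd(hs)
    if (!is.finite(cutoff)) cutoff <- mean(hs)
  }
  protein$h <- h
  protein$h_bar <- h_bar
  protein$band_member <- h_bar > cutoff
  attr(protein, "band_cutoff") <- cutoff
  protein
}
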