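#' Synthetic CG protein fixtures with known ground truth
#'
#' Generates idealized coarse-grained proteins whose optimal membrane
#' placement is known by construction: helical bundles and barrels carrying
#' a hydrophobic bead belt at a known depth, double-belt rods for
#' double-membrane tests, a bundle with a charged ring for the
#' positive-inside rule, and a dense cylinder for cell-wall carving tests.
#' Hydrophobic belt beads are LEU side-chain beads (type C1), the polar
#' remainder SER backbone beads (type P5), charged ring beads LYS SC2
#' (type Qd, +1 e).
#'
#' @param kind one of `"helical_bundle"`, `"barrel"`, `"double_belt"`,
#'   `"charged_ring_peripheral"`, `"toy_wall"`.
#' @param seed seed for the small coordinate jitter.
#' @param length total length along the axis, nm.
#' @param belt_half_width hydrophobic belt half-width, nm.
#' @param belt_separation center-to-center separation of the two belts
#'   (double_belt), nm.
#' @param n_helices helix count (bundle kinds).
#' @param barrel_radius barrel cylinder radius, nm.
#' @param ring_charge_n number of +1 ring beads (charged ring kind).
#' @param jitter coordinate jitter sd, nm.
#' @return list with `protein` (a [cg_protein()]), `ground_truth` (a
#'   [placement()]; for double_belt it carries the constructed spacing `D`)
#'   and the fixture `spec`.
#' @export
make_fixture <- function(kind = c("helical_bundle", "barrel", "double_belt",
                                  "charged_ring_peripheral", "toy_wall"),
                         seed = 1, length = NULL, belt_half_width = 1.5,
                         belt_separation = 10, n_helices = 4,
                         barrel_radius = 1.2, ring_charge_n = 8,
                         jitter = 0.015) {
  kind <- match.arg(kind)
  if (belt_half_width <= 0) abort("`belt_half_width` must be > 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  length <- length %||% switch(kind,
    helical_bundle = 9.8, barrel = 8, double_belt = belt_separation + 6,
    charged_ring_peripheral = 9.8, toy_wall = 6)
  zs <- seq(-length / 2, length / 2, by = 0.35)

  hydrophobic <- function(z) switch(kind,
    double_belt = (abs(z - belt_separation / 2) < belt_half_width) |
                  (abs(z + belt_separation / 2) < belt_half_width),
    toy_wall = rep(FALSE, base::length(z)),
    abs(z) < belt_half_width)

  place_column <- function(cx, cy, phase = 0, twist_r = 0.25) {
    tw <- phase + seq_along(zs) * 2 * pi / 10
    tibble(x = cx + twist_r * cos(tw), y = cy + twist_r * sin(tw), z = zs)
  }

  beads <- switch(kind,
    toy_wall = {
      g <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                       r = c(0.6, 1.2), z = zs)
      tibble(x = g$r * cos(g$a), y = g$r * sin(g$a), z = g$z)
    },
    barrel = {
      g <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13], z = zs)
      tibble(x = barrel_radius * cos(g$a), y = barrel_radius * sin(g$a), z = g$z)
    },
    {
      ang <- seq(0, 2 * pi, length.out = n_helices + 1)[-(n_helices + 1)]
      purrr::map_dfr(seq_len(n_helices), function(i)
        place_column(0.8 * cos(ang[i]), 0.8 * sin(ang[i]), phase = ang[i]))
    })

  beads$x <- beads$x + rnorm(nrow(beads), 0, jitter)
  beads$y <- beads$y + rnorm(nrow(beads), 0, jitter)
  beads$z <- beads$z + rnorm(nrow(beads), 0, jitter)

  hyd <- hydrophobic(beads$z)
  beads$resname <- ifelse(hyd, "LEU", "SER")
  beads$atom <- ifelse(hyd, "SC1", "BB")

  if (kind == "charged_ring_peripheral") {
    a <- seq(0, 2 * pi, length.out = ring_charge_n + 1)[-(ring_charge_n + 1)]
    ring <- tibble(x = 1.1 * cos(a), y = 1.1 * sin(a),
                   z = -length / 2 + 0.6 + rnorm(ring_charge_n, 0, jitter),
                   resname = "LYS", atom = "SC2")
    beads <- dplyr::bind_rows(beads, ring)
  }

  beads$resid <- seq_len(nrow(beads))
  protein <- cg_protein(beads)
  gt <- placement(z = 0, v = c(0, 0, 1),
                  D = if (kind == "double_belt") belt_separation else NULL)
  list(protein = protein, ground_truth = gt,
       spec = list(kind = kind, seed = seed, length = length,
                   belt_half_width = belt_half_width,
                   belt_separation = if (kind == "double_belt") belt_separation,
                   ring_charge_n = if (kind == "charged_ring_peripheral") ring_charge_n))
}

#' Apply a random rigid rotation to a protein
#'
#' Used by the randomized-input test protocol: a seeded uniform random
#' rotation (QR of a Gaussian matrix, determinant fixed to +1) applied to
#' the coordinates.
#'
#' @param protein a [cg_protein()].
#' @param seed RNG seed.
#' @return list: `protein` (rotated) and `rotation` (the 3x3 matrix used).
#' @export
random_rotation <- function(protein, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  list(protein = set_coords(protein, coords(protein) %*% t(Q)), rotation = Q)
}
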