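# Small structures and tables built in code for the tests.

toy_table <- function() build_interaction_table("toy")
m3_table <- function() build_interaction_table("bundled_m3")
m2_table <- function() build_interaction_table("bundled_m2")

# protein from raw coordinates; types via resname/atom pairs in the mapping
manual_protein <- function(xyz, resname = "LEU", atom = "SC1",
                           occupancy_radius = 0.264) {
  xyz <- matrix(xyz, ncol = 3)
  cg_protein(tibble::tibble(resid = seq_len(nrow(xyz)),
                            resname = rep_len(resname, nrow(xyz)),
                            atom = rep_len(atom, nrow(xyz)),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
             occupancy_radius = occupancy_radius)
}

cubic_lattice_protein <- function(spacing = 0.35, occ = 0.25) {
  g <- expand.grid(x = (-1:1) * spacing, y = (-1:1) * spacing,
                   z = (-1:1) * spacing)
  manual_protein(as.matrix(g), occupancy_radius = occ)
}

shell_protein <- function(n = 100, radius = 1.5) {
  manual_protein(radius * oracle_shell(n))
}

# minimal two-strand mesh with exactly one peptide cross-link: saturate with
# P_cl = 1, then keep the first link only
dimer_mesh <- function() {
  mesh <- generate_pg_mesh(cell = c(4, 4), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  mesh <- crosslink_mesh(mesh, crosslink_params(P_cl = 1, P_l = 0, P_o = 0),
                         seed = 1)
  mesh$crosslinks <- mesh$crosslinks[1, , drop = FALSE]
  mesh
}

expect_placement_equal <- function(a, b, tol = 1e-9) {
  expect_equal(placement_rotation(a), placement_rotation(b), tolerance = tol)
  expect_equal(a$z, b$z, tolerance = tol)
}
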