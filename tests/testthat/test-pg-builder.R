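test_that("mesh generation produces the expected lattice", {
  mesh <- generate_pg_mesh(cell = c(20, 20), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  sl <- strand_lengths(mesh)
  expect_equal(nrow(sl), 10)
  expect_true(all(sl$length == 20))
  expect_equal(nrow(mesh$units), 200)
  m2 <- generate_pg_mesh(cell = c(10, 10), layers = 2, seed = 1)
  expect_setequal(unique(m2$units$layer), c(0, 1))
  expect_equal(sum(m2$units$layer == 0), sum(m2$units$layer == 1))
  expect_error(generate_pg_mesh(cell = c(1, 1)), "too small")
})

test_that("strands wrap periodically: adjacency includes the seam bond", {
  mesh <- generate_pg_mesh(cell = c(6, 4), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  nb <- memorient:::strand_neighbors(mesh)
  # a cyclic 6-unit strand has 6 bonds including idx 5 -> idx 0
  line0 <- mesh$units[mesh$units$line == 0, ]
  ids <- line0$unit_id
  n_bonds_line0 <- sum(nb$unit1 %in% ids & nb$unit2 %in% ids)
  expect_equal(n_bonds_line0, 6)
  seam <- any((nb$unit1 %in% ids[line0$idx == 5] &
               nb$unit2 %in% ids[line0$idx == 0]) |
              (nb$unit2 %in% ids[line0$idx == 5] &
               nb$unit1 %in% ids[line0$idx == 0]))
  expect_true(seam)
})

test_that("carving removes exactly the units near a cylindrical protein", {
  mesh <- generate_pg_mesh(cell = c(20, 20), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  # center the mesh around the cylinder axis at (10, 10)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  cyl <- manual_protein(cbind(10 + 2 * cos(th), 10 + 2 * sin(th), 0))
  carved <- carve_protein(mesh, cyl, clearance = 0.5)
  sites <- memorient:::unit_bead_sites(mesh)
  d <- memorient:::cpp_min_dist(as.matrix(sites[, c("x", "y", "z")]),
                                memorient:::coords(cyl))
  should_go <- unique(sites$unit_id[d < 0.5])
  expect_setequal(setdiff(mesh$units$unit_id, carved$units$unit_id), should_go)
  # far protein: unchanged
  far <- manual_protein(c(100, 100, 100))
  expect_equal(carve_protein(mesh, far)$units, mesh$units)
  # full coverage empties the mesh with a warning
  blanket <- manual_protein(as.matrix(expand.grid(x = seq(0, 20, 0.5),
                                                  y = seq(0, 20, 0.5),
                                                  z = c(-0.3, 0))))
  expect_warning(empty <- carve_protein(mesh, blanket, clearance = 1),
                 "empty")
  expect_equal(nrow(empty$units), 0)
})

test_that("MCMC: step 0 only applies the final break pass; matched target freezes", {
  mesh <- generate_pg_mesh(cell = c(20, 12), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  tgt <- length_target(1, 8, 2)
  m0 <- match_length_distribution(mesh, tgt, steps = 0, seed = 1)
  expect_true(all(strand_lengths(m0)$length < 20))
  expect_equal(sum(strand_lengths(m0)$length), nrow(mesh$units))
  # acceptance at K == K_p is zero: with the target equal to the current
  # distribution, no move is ever accepted
  L <- mesh$n_units_per_line
  tgt_cur <- length_target(1, L, 1e-3)   # current state: all strands length L
  m1 <- match_length_distribution(mesh, tgt_cur, steps = 500, seed = 3)
  expect_equal(length(attr(m1, "kl_trace")), 1)
})

test_that("MCMC matches a unimodal target and conserves units", {
  mesh <- generate_pg_mesh(cell = c(40, 80), strand_spacing = 2,
                           unit_length = 1, seed = 1)   # 40 strands of 40
  tgt <- length_target(1, 8, 2)
  out <- match_length_distribution(mesh, tgt, steps = 20000, seed = 1)
  expect_equal(sum(strand_lengths(out)$length), nrow(mesh$units))
  expect_lte(attr(out, "kl_final"), 0.1)
  expect_lte(attr(out, "kl_final"), attr(out, "kl_initial"))
  expect_true(all(diff(attr(out, "kl_trace")) <= 1e-12))
  # reproducible per seed
  out2 <- match_length_distribution(mesh, tgt, steps = 2000, seed = 5)
  out3 <- match_length_distribution(mesh, tgt, steps = 2000, seed = 5)
  expect_identical(out2$units$strand_id, out3$units$strand_id)
  expect_error(match_length_distribution(mesh, length_target(1, 500, 0.01)),
               "zero probability")
})

test_that("cross-linking saturates at P_cl = 1, is empty at 0, binomial in between", {
  mesh <- generate_pg_mesh(cell = c(20, 20), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  none <- crosslink_mesh(mesh, crosslink_params(P_cl = 0), seed = 1)
  expect_equal(nrow(none$crosslinks), 0)
  expect_gt(length(none$flagged), 0)
  full <- crosslink_mesh(mesh, crosslink_params(P_cl = 1), seed = 1)
  expect_gt(nrow(full$crosslinks), 0)
  expect_false(any(duplicated(
    paste(pmin(full$crosslinks$unit1, full$crosslinks$unit2),
          pmax(full$crosslinks$unit1, full$crosslinks$unit2)))))
  # every link joins lattice-adjacent lines (including the PBC wrap)
  u <- full$units
  l1 <- u$line[match(full$crosslinks$unit1, u$unit_id)]
  l2 <- u$line[match(full$crosslinks$unit2, u$unit_id)]
  expect_true(all(abs(l1 - l2) %in% c(1, full$n_lines - 1)))
  # binomial statistics across seeds at P_cl = 0.5: linked count over the
  # eligible (both-free, in-reach) attempts
  got <- vapply(1:10, function(s) {
    m <- crosslink_mesh(mesh, crosslink_params(P_cl = 0.5), seed = s)
    c(nrow(m$crosslinks), attr(m, "n_eligible"))
  }, numeric(2))
  n_el <- sum(got[2, ])
  sd_bin <- sqrt(0.5 * 0.5 / n_el)
  expect_lt(abs(sum(got[1, ]) / n_el - 0.5), 3 * sd_bin)
})

test_that("interlayer links appear when P_l > 0 on a two-layer mesh", {
  mesh <- generate_pg_mesh(cell = c(10, 10), layers = 2, seed = 2)
  m <- crosslink_mesh(mesh, crosslink_params(P_cl = 1, P_l = 0.5), seed = 4)
  expect_true("interlayer" %in% m$crosslinks$kind)
  u <- m$units
  il <- m$crosslinks[m$crosslinks$kind == "interlayer", ]
  expect_true(all(u$layer[match(il$unit1, u$unit_id)] !=
                  u$layer[match(il$unit2, u$unit_id)]))
})

test_that("relaxation: rest-length mesh is a fixed point", {
  mesh <- generate_pg_mesh(cell = c(12, 12), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  mesh <- crosslink_mesh(mesh, crosslink_params(P_cl = 0.3), seed = 1)
  r <- relax_mesh(mesh, max_steps = 400)
  expect_lt(max(abs(r$cell / mesh$cell - 1)[1:2]), 0.005)
  expect_lt(attr(r, "mean_strain"), 1e-3)
})

test_that("a uniformly pre-stretched mesh relaxes to the oracle cell", {
  mesh <- generate_pg_mesh(cell = c(12, 12), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  # stretch: geometry 10% larger than rest lengths in x and y
  mesh$units$x <- mesh$units$x * 1.1
  mesh$units$y <- mesh$units$y * 1.1
  mesh$cell[1:2] <- mesh$cell[1:2] * 1.1
  # saturated cross-linking so the spring network spans both axes and the
  # oracle equilibrium (every bond at rest length) pins the cell uniquely
  mesh <- crosslink_mesh(mesh, crosslink_params(P_cl = 1), seed = 2)
  stretched_cell <- mesh$cell
  r <- relax_mesh(mesh, max_steps = 4000)
  oracle_cell <- stretched_cell[1] / 1.1   # all rest lengths met
  expect_lt(abs(r$cell[1] - oracle_cell) / oracle_cell, 0.02)
  expect_lt(abs(r$cell[2] - stretched_cell[2] / 1.1) /
            (stretched_cell[2] / 1.1), 0.02)
  expect_lte(attr(r, "mean_strain"), 0.02)
})

test_that("relaxation keeps carved units clear of the protein", {
  mesh <- generate_pg_mesh(cell = c(16, 16), strand_spacing = 2,
                           unit_length = 1, seed = 1)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  cyl <- manual_protein(cbind(8 + 2 * cos(th), 8 + 2 * sin(th), 0))
  carved <- carve_protein(mesh, cyl, clearance = 0.6)
  carved <- crosslink_mesh(carved, crosslink_params(P_cl = 0.5), seed = 1)
  r <- relax_mesh(carved, max_steps = 500, protein = cyl, clearance = 0.6)
  d <- memorient:::cpp_min_dist(as.matrix(r$units[, c("x", "y", "z")]),
                                memorient:::coords(cyl))
  expect_gt(min(d), 0.6 * 0.9)
})

test_that("topology export: interpeptide angle constants, empty case, round trip", {
  mesh <- dimer_mesh()
  expect_equal(nrow(mesh$crosslinks), 1)
  pre <- withr::local_tempfile()
  write_pg_topology(mesh, pre)
  ang <- read_pg_topology_angles(paste0(pre, ".itp"))
  ip <- ang[ang$comment == "interpeptide link", ]
  expect_equal(nrow(ip), 2)
  expect_equal(ip$theta0, c(114, 95))
  expect_equal(ip$fc, c(75, 75))
  # no cross-links -> no interpeptide entries
  m0 <- generate_pg_mesh(cell = c(4, 4), seed = 1)
  pre0 <- withr::local_tempfile()
  write_pg_topology(m0, pre0)
  ang0 <- read_pg_topology_angles(paste0(pre0, ".itp"))
  expect_false(any(ang0$comment == "interpeptide link"))
  # coordinates round trip through the GRO reader
  gro <- paste0(pre, ".gro")
  back <- read_cg_structure(gro)
  sites <- memorient:::unit_bead_sites(mesh)
  expect_equal(nrow(back), nrow(sites))
  expect_equal(back$x, sites$x, tolerance = 1e-3)
})
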