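test_that("LJ minimum matches a brute-force 1-D scan of the pair potential", {
  tab <- toy_table()
  res <- lj_min_energy("P", "W", tab)
  expect_equal(res$energy, -5)
  expect_equal(res$r_min, 2^(1 / 6) * 0.47)
  U <- function(r, e = 5, s = 0.47) 4 * e * ((s / r)^12 - (s / r)^6)
  sc <- optimize(U, c(0.3, 2), tol = 1e-12)
  expect_equal(sc$objective, res$energy, tolerance = 1e-9)
  expect_equal(sc$minimum, res$r_min, tolerance = 1e-6)
  expect_error(lj_min_energy("P", "NOPE", tab), "NOPE")
})

test_that("zone signed distances: planar closed form, curvature limit, double symmetry", {
  mem <- membrane_model(core_half_width = 1.4, head_width = 0.6)
  d <- zone_signed_distances(cbind(0, 0, 0), mem)
  expect_equal(d$d_core, -1.4)
  expect_equal(d$d_mid, 0)
  # continuity of the curved formulation at c -> 0
  d1 <- zone_signed_distances(cbind(3, 0, 1), mem, c = 1e-6)
  d0 <- zone_signed_distances(cbind(3, 0, 1), mem, c = 0)
  expect_equal(d1$d_mid, d0$d_mid, tolerance = 1e-4)
  # double membrane: midpoint equidistant from both midplanes
  mem2 <- membrane_model(n_membranes = 2, spacing_D = 10)
  d2 <- zone_signed_distances(cbind(0, 0, 0), mem2)
  expect_equal(abs(d2$d_mid), c(5, 5))
})

test_that("mean field reaches zone plateaus and the sigmoid midpoint", {
  tab <- m3_table()
  mem <- membrane_model()
  # deep solvent
  expect_equal(mean_field_energy("P5", cbind(0, 0, 30), mem, tab),
               -tab$eps["P5", "W"], tolerance = 1e-6, ignore_attr = TRUE)
  # core center
  expect_equal(mean_field_energy("C1", cbind(0, 0, 0), mem, tab),
               -tab$eps["C1", "C1"], tolerance = 1e-2, ignore_attr = TRUE)
  # exact core boundary with no head zone: midpoint of water and tail minima
  mem0 <- membrane_model(head_width = 0)
  expect_equal(mean_field_energy("C1", cbind(0, 0, 1.4), mem0, tab),
               (-tab$eps["C1", "W"] - tab$eps["C1", "C1"]) / 2,
               tolerance = 1e-3, ignore_attr = TRUE)
  # plateau attained beyond 6 smoothing widths
  z_out <- 1.4 + 0.6 + 6 * mem$smoothing_width
  expect_equal(mean_field_energy("C1", cbind(0, 0, z_out + 0.5), mem, tab),
               -tab$eps["C1", "W"],
               tolerance = 1e-3 * tab$eps["C1", "W"], ignore_attr = TRUE)
})

test_that("mean field z-gradient matches central finite differences", {
  tab <- m3_table()
  mem <- membrane_model()
  h <- 1e-5
  for (z in c(-2.2, -1.4, -0.7, 0.9, 1.7, 2.4)) {
    num <- (mean_field_energy("P5", cbind(0.3, 0.1, z + h), mem, tab) -
            mean_field_energy("P5", cbind(0.3, 0.1, z - h), mem, tab)) / (2 * h)
    hh <- 1e-3
    num2 <- (mean_field_energy("P5", cbind(0.3, 0.1, z + hh), mem, tab) -
             mean_field_energy("P5", cbind(0.3, 0.1, z - hh), mem, tab)) / (2 * hh)
    expect_equal(num2, num, tolerance = 1e-4 * max(1, abs(num)))
  }
})

test_that("probe shell is on-sphere, centered, and deterministic", {
  s <- probe_shell(c(1, 2, 3), radius_d = 0.528, n = 32)
  expect_equal(sqrt(rowSums(sweep(s, 2, c(1, 2, 3))^2)), rep(0.528, 32),
               tolerance = 1e-9)
  expect_lt(sqrt(sum((colMeans(s) - c(1, 2, 3))^2)), 0.02 * 0.528)
  expect_identical(s, probe_shell(c(1, 2, 3), 0.528, 32))
  expect_error(probe_shell(n = 3), ">= 4")
})

test_that("bead score: solvent plateau, full occupancy, boundary vs loop oracle", {
  tab <- m3_table()
  mem <- membrane_model()
  bead <- manual_protein(c(0, 0, 0), resname = "SER", atom = "BB")[1, ]
  far <- c(0, 0, 40)
  expect_equal(bead_score(bead, far, mem, tab, n_probes = 32),
               32 * -tab$eps["P5", "W"], tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(bead_score(bead, far, mem, tab, n_probes = 32,
                          occupied = function(x) rep(TRUE, nrow(x))), 0)
  # at the membrane boundary: equals explicit probe enumeration
  at_boundary <- c(0.2, -0.1, 1.4)
  d_b <- 2^(1 / 6) * mean(tab$sigma["P5", ], na.rm = TRUE)
  sh <- oracle_shell(32) * d_b
  direct <- sum(sapply(seq_len(32), function(k)
    oracle_field("P5", at_boundary + sh[k, ], mem, tab)))
  expect_equal(bead_score(bead, at_boundary, mem, tab, n_probes = 32), direct,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sheet Coulomb quadrature matches the closed disc potential", {
  for (case in list(c(1, 1, 3), c(-0.5, 0.4, 3), c(2, 2.5, 5))) {
    q <- case[1]; z <- case[2]; R <- case[3]
    got <- sheet_coulomb(q, z, 0.1, R, n_quadrature = 512)
    want <- oracle_disc_coulomb(q, z, 0.1, R, 15)
    expect_equal(got, want, tolerance = 1e-3 * abs(want))
  }
  expect_equal(sheet_coulomb(0, 1, 0.1, 3), 0)
  # |energy| decreases with distance from the sheet
  e <- abs(sheet_coulomb(rep(1, 5), c(0.5, 1, 2, 3, 4), 0.1, 3))
  expect_true(all(diff(e) < 0))
})

test_that("total potential equals the brute-force loop oracle", {
  tab <- m3_table()
  fx <- make_fixture("charged_ring_peripheral", seed = 2)
  p <- find_surface_beads(fx$protein, seed = 1)
  for (mem in list(membrane_model(),
                   membrane_model(leaflet_charge_density = c(-0.02, 0)),
                   membrane_model(curvature_c = 0.05))) {
    pl <- placement(z = 0.4, v = c(0.3, -0.2, 0.93), w = c(0.8, 0.6),
                    c = mem$curvature_c)
    got <- total_potential(p, pl, mem, tab)
    want <- oracle_total_potential(p, pl, mem, tab)
    expect_equal(got, want, tolerance = 1e-9 * abs(want))
  }
  # double membrane
  fx2 <- make_fixture("double_belt", seed = 2)
  p2 <- find_surface_beads(fx2$protein, seed = 1)
  mem2 <- membrane_model(n_membranes = 2, spacing_D = 10)
  pl2 <- placement(z = 0.1, v = c(0.05, 0, 1), D = 10.4)
  expect_equal(total_potential(p2, pl2, mem2, tab),
               oracle_total_potential(p2, pl2, mem2, tab),
               tolerance = 1e-9)
})

test_that("potential is invariant under lateral shifts of the protein", {
  tab <- m3_table()
  mem <- membrane_model()
  fx <- make_fixture("helical_bundle", seed = 1)
  p <- find_surface_beads(fx$protein, seed = 1)
  pl <- placement(z = 0.2, v = c(0.2, 0.3, 0.9))
  v0 <- total_potential(p, pl, mem, tab)
  shifted <- p
  shifted$x <- shifted$x + 5
  shifted$y <- shifted$y - 3
  # lateral shift in the placed frame: same bead z-coordinates after
  # placement with compensated rotation is nontrivial; shift in world x, y
  # via a laterally translated copy oriented identically
  ctx <- prepare_potential(p, mem, tab)
  R <- placement_rotation(pl)
  U2 <- ctx$U %*% t(R)
  U2[, 1] <- U2[, 1] + 5
  U2[, 2] <- U2[, 2] - 3
  ctx2 <- ctx
  ctx2$U <- U2
  v1 <- memorient:::eval_potential(ctx2, placement(z = pl$z))$value
  expect_equal(v1, v0, tolerance = 1e-9 * abs(v0))
})

test_that("reflection symmetry holds with neutral sheets (and is an involution)", {
  tab <- m3_table()
  mem <- membrane_model()
  fx <- make_fixture("helical_bundle", seed = 4)
  p <- find_surface_beads(fx$protein, seed = 1)
  ctx <- prepare_potential(p, mem, tab)
  set.seed(42)
  for (i in 1:10) {
    pl <- placement(z = runif(1, -1, 1), v = rnorm(3), w = rnorm(2))
    pr <- reflect_config(pl)
    a <- memorient:::eval_potential(ctx, pl)$value
    b <- memorient:::eval_potential(ctx, pr)$value
    expect_equal(b, a, tolerance = 1e-6 * abs(a))
    expect_placement_equal(reflect_config(pr), pl, tol = 1e-9)
  }
})

test_that("positive-inside rule: ring-inside configuration scores strictly lower", {
  tab <- m3_table()
  mem <- membrane_model(leaflet_charge_density = c(-0.02, 0))
  fx <- make_fixture("charged_ring_peripheral", seed = 3)
  p <- find_surface_beads(fx$protein, seed = 1)
  ctx <- prepare_potential(p, mem, tab)
  # ring sits at the bottom of the fixture; aligned placement puts it inside
  pl_in <- placement(z = 0, v = c(0, 0, 1))
  pl_out <- reflect_config(pl_in)
  expect_lt(memorient:::eval_potential(ctx, pl_in)$value,
            memorient:::eval_potential(ctx, pl_out)$value)
})

test_that("analytic gradients match central finite differences everywhere", {
  tab <- m3_table()
  fx <- make_fixture("double_belt", seed = 1)
  p <- find_surface_beads(fx$protein, seed = 1)
  cases <- list(
    list(mem = membrane_model(), use_D = FALSE, use_c = FALSE),
    list(mem = membrane_model(leaflet_charge_density = c(-0.05, 0.02)),
         use_D = FALSE, use_c = FALSE),
    list(mem = membrane_model(n_membranes = 2, spacing_D = 10), use_D = TRUE,
         use_c = FALSE),
    list(mem = membrane_model(), use_D = FALSE, use_c = TRUE)
  )
  set.seed(7)
  for (cs in cases) {
    ctx <- prepare_potential(p, cs$mem, tab)
    for (i in 1:5) {
      pl <- placement(z = runif(1, -1, 1), v = rnorm(3), w = rnorm(2),
                      D = if (cs$use_D) runif(1, 9, 11),
                      c = if (cs$use_c) runif(1, -0.06, 0.06))
      g <- memorient:::eval_potential(ctx, pl, want_grad = TRUE)
      grad <- c(g$grad, if (cs$use_D) g$dD, if (cs$use_c) g$dc)
      par <- memorient:::placement_to_par(pl, cs$use_D, cs$use_c)
      h <- 1e-4
      for (j in seq_along(par)) {
        pp <- par; pm <- par
        pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
        num <- (memorient:::eval_potential(
                  ctx, memorient:::par_to_placement(pp, cs$use_D, cs$use_c))$value -
                memorient:::eval_potential(
                  ctx, memorient:::par_to_placement(pm, cs$use_D, cs$use_c))$value) /
          (2 * h)
        scale <- max(abs(num), abs(grad[j]), 1e-3)
        expect_equal(grad[j], num, tolerance = 1e-3 * scale)
      }
    }
  }
})

test_that("mean field is continuous in curvature and spacing", {
  tab <- m3_table()
  mem <- membrane_model()
  X <- cbind(1.2, -0.4, 1.1)
  expect_equal(mean_field_energy("C1", X, mem, tab, c = 1e-7),
               mean_field_energy("C1", X, mem, tab, c = 0), tolerance = 1e-5)
  mem2 <- membrane_model(n_membranes = 2, spacing_D = 10)
  expect_equal(mean_field_energy("C1", X, mem2, tab, D = 10 + 1e-7),
               mean_field_energy("C1", X, mem2, tab, D = 10), tolerance = 1e-6)
})
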