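test_that("Fibonacci directions cover the hemisphere quasi-uniformly", {
  d <- fibonacci_directions(36)
  expect_equal(nrow(d), 36)
  expect_true(all(d$theta >= 0 & d$theta <= pi / 2))
  expect_true(all(d$phi >= 0 & d$phi < 2 * pi))
  # brute-force pairwise separation against the ideal hemisphere packing
  vecs <- cbind(sin(d$theta) * cos(d$phi), sin(d$theta) * sin(d$phi),
                cos(d$theta))
  min_sep <- Inf
  for (i in 1:35) for (j in (i + 1):36)
    min_sep <- min(min_sep, acos(min(1, sum(vecs[i, ] * vecs[j, ]))))
  ideal <- sqrt(2 * pi / 36)   # cap-packing estimate for 36 caps on 2*pi sr
  expect_gte(min_sep, 0.6 * ideal)
  expect_equal(fibonacci_directions(1)$theta, 0)
  expect_error(fibonacci_directions(0), ">= 1")
})

test_that("band-mode initial depth centers the hydrophobic belt", {
  tab <- m3_table()
  fx <- make_fixture("helical_bundle", seed = 1)
  p <- hydrophobicity_profile(find_surface_beads(fx$protein, seed = 1), tab)
  # shift the belt to local z0 = 1: depth should become about -1
  p_shift <- p
  p_shift$z <- p_shift$z + 1
  z <- initial_depth(p_shift, c(0, 0), mode = "band")
  expect_equal(z, -1, tolerance = 0.1)
  # all-band protein: centroid goes to the membrane center
  p_all <- p
  p_all$band_member <- TRUE
  expect_equal(initial_depth(p_all, c(0, 0), "band"),
               -mean(p_all$z), tolerance = 1e-9)
})

test_that("scan-mode initial depth finds a quadratic minimum on the grid", {
  fn <- function(z) (z - 0.7)^2
  z <- initial_depth(manual_protein(c(0, 0, 0)), c(0, 0), "scan",
                     potential_fn = fn, z_range = c(-6, 6), z_steps = 61)
  expect_lte(abs(z - 0.7), 12 / 60)
})

test_that("initial double spacing recovers the constructed belt separation", {
  tab <- m3_table()
  fx <- make_fixture("double_belt", seed = 1, belt_separation = 10)
  p <- hydrophobicity_profile(find_surface_beads(fx$protein, seed = 1), tab)
  mem <- membrane_model(n_membranes = 2, spacing_D = 9)
  ctx <- prepare_potential(p, mem, tab)
  fn <- function(D) memorient:::eval_potential(
    ctx, placement(z = 0, v = c(0, 0, 1), D = D))$value
  D <- initial_double_spacing(p, c(0, 0), mem, fn)
  expect_lt(abs(D - 10), 0.5)
  expect_gt(D, 2 * (mem$core_half_width + mem$head_width))
  expect_identical(D, initial_double_spacing(p, c(0, 0), mem, fn))
})

test_that("AdaDelta finds the minimum of a quadratic bowl and fixes stationary points", {
  bowl <- function(par, want_grad = FALSE) {
    v <- sum((par[1] - 0.3)^2) + 0.5 * (par[2] - 0.1)^2
    g <- c(2 * (par[1] - 0.3), 1 * (par[2] - 0.1), 0, 0, 0, 0)
    # pad out the placement parametrization; only z and v1 used
    list(value = v, grad = g[1:6])
  }
  r <- minimize_config(placement(z = -1, v = c(-0.8, 0, 0.6)), bowl,
                       n_iters = 300)
  expect_lt(abs(r$final$z - 0.3), 1e-3)
  expect_lte(r$final_potential, bowl(c(-1, -0.8, 0, 0.6, 1, 0))$value + 1e-6)
  # a zero-gradient start stays put
  flat <- function(par, want_grad = FALSE) list(value = 1, grad = numeric(6))
  r0 <- minimize_config(placement(z = 0.5, v = c(0, 0, 1)), flat, n_iters = 50)
  expect_equal(r0$final$z, 0.5, tolerance = 1e-9)
})

test_that("iterative clustering follows the stated assignment rule", {
  mk <- function(z, tilt_deg) {
    th <- tilt_deg * pi / 180
    structure(list(start = NULL, final = placement(z = z,
                                                   v = c(sin(th), 0, cos(th))),
                   final_potential = 0, iterations_run = 1, converged = TRUE),
              class = "minimization_result")
  }
  same <- replicate(5, mk(0.1, 3), simplify = FALSE)
  expect_equal(max(cluster_configs(same)), 1)
  two <- c(replicate(3, mk(0, 0), simplify = FALSE),
           replicate(3, mk(0, 40), simplify = FALSE))
  expect_equal(max(cluster_configs(two, t_ang = 10)), 2)
  # chain: members 0.9 t apart merge into one cluster under the rule
  chain <- lapply(seq(0, 8) * 0.9 * 8, function(a) mk(0, a))
  expect_equal(max(cluster_configs(chain, t_ang = 8)), 1)
})

test_that("ranking balances potential and basin occupancy", {
  reps <- list(placement(z = 0), placement(z = 1))
  # equal potential: larger basin wins
  r <- rank_minima(reps, c(-100, -100), sizes = c(30, 6), n_grid = 36)
  expect_equal(r$cluster[r$rank == 1], 1)
  # single cluster is always rank 1
  expect_equal(rank_minima(reps[1], -5, 36, 36)$rank, 1)
  # much deeper minimum beats occupancy even at size 1
  r2 <- rank_minima(reps, c(-100, -150), sizes = c(35, 1), n_grid = 36,
                    lambda = 2)
  expect_equal(r2$cluster[r2$rank == 1], 2)
})

test_that("orientation pipeline recovers the belt fixture ground truth", {
  tab <- m3_table()
  fx <- make_fixture("helical_bundle", seed = 1)
  rr <- random_rotation(fx$protein, seed = 41)
  rep <- orient(rr$protein, tab, n_grid = 36, n_iters = 150, seed = 2)
  expect_lte(tilt_error(rep, rr$rotation), 5)
  expect_lte(abs(rep$placements[[1]]$z), 0.15)
  # fixed point: feeding back the rank-1 result reproduces it
  rep2 <- orient(rr$protein, tab, n_grid = 8, n_iters = 60, seed = 2)
  expect_lte(abs(rep2$placements[[1]]$z - rep$placements[[1]]$z), 0.3)
})

test_that("cluster representatives are stable under grid order permutation", {
  tab <- m3_table()
  fx <- make_fixture("helical_bundle", seed = 5)
  p <- hydrophobicity_profile(find_surface_beads(fx$protein, seed = 1), tab)
  ctx <- prepare_potential(p, membrane_model(), tab)
  fn <- function(par, want_grad = FALSE) {
    r <- memorient:::eval_potential(ctx, memorient:::par_to_placement(par),
                                    want_grad)
    if (!want_grad) r else list(value = r$value, grad = r$grad)
  }
  dirs <- fibonacci_directions(12)
  starts <- lapply(seq_len(12), function(i) {
    v <- memorient:::direction_to_v(dirs$theta[i], dirs$phi[i])
    placement(z = initial_depth(p, c(dirs$theta[i], dirs$phi[i]), "band"),
              v = v)
  })
  res <- lapply(starts, minimize_config, potential_fn = fn, n_iters = 100)
  ids <- cluster_configs(res)
  set.seed(1)
  perm <- sample(12)
  ids_p <- cluster_configs(res[perm])
  # same partition up to relabeling
  expect_equal(length(unique(ids)), length(unique(ids_p)))
  expect_true(all(table(ids) %in% table(ids_p)))
})

test_that("no spurious curvature is recovered for a planar-optimal fixture", {
  tab <- m3_table()
  fx <- make_fixture("helical_bundle", seed = 6)
  rr <- random_rotation(fx$protein, seed = 13)
  rep <- orient(rr$protein, tab, n_grid = 12, n_iters = 150,
                curvature = TRUE, seed = 2)
  expect_lte(abs(rep$placements[[1]]$c), 0.01)
})
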