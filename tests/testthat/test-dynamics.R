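test_that("activation is a sigmoid from 0 to 1 with the stated slope", {
  p <- model_params()
  expect_lt(activation(-1e6, p), 1e-9)
  expect_gt(activation(1e6, p), 1 - 1e-9)
  expect_equal(activation(p$f_threshold, p), 0.5)
  v <- seq(-2, 2, length.out = 200)
  expect_true(all(diff(activation(v, p)) > 0))
  # finite-difference slope at the midpoint equals 1/(4 eps)
  h <- 1e-6
  slope <- (activation(p$f_threshold + h, p) -
              activation(p$f_threshold - h, p)) / (2 * h)
  expect_equal(slope, 1 / (4 * p$f_steepness), tolerance = 1e-6)
})

test_that("ligand activity is a normalized monotone map on [0, 1]", {
  p <- model_params()
  expect_equal(ligand_activity(0, p), 0)
  expect_equal(ligand_activity(1, p), 1)
  u <- seq(-0.5, 1.5, length.out = 100)
  d <- ligand_activity(u, p)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("the extrinsic signal interpolates between its two profiles", {
  g <- gradient_params(t_start = 5, t_end = 15)
  x <- seq(0, 15, by = 0.5)
  early <- extrinsic_signal(x, 5, g)
  late <- extrinsic_signal(x, 15, g)
  expect_identical(extrinsic_signal(x, 0, g), early)
  expect_identical(extrinsic_signal(x, 100, g), late)
  expect_equal(extrinsic_signal(x, 10, g), (early + late) / 2)
  expect_true(all(early >= 0) && all(late >= 0))
  # periodic in x with the box width
  expect_equal(extrinsic_signal(x, 8, g), extrinsic_signal(x + 15, 8, g))
})

test_that("total signal decomposes exactly and matches a hand-set chain", {
  p <- model_params()
  lat <- lattice_from_positions(
    rbind(c(0.5, 0.5), c(1.5, 0.5), c(2.5, 0.5)), 6, 6)
  cp <- compute_coupling(lat, 1, strength = 1, cutoff_factor = 3)
  g <- flat_gradient(0.3, box_width = 6)
  u <- c(0.2, 0.5, 1.0)
  sig <- total_signal(u, lat, cp, g, t = 0, p)
  D <- ligand_activity(u, p)
  w12 <- exp(-1 / 2); w13 <- exp(-4 / 2)
  manual <- 0.3 + c(w12 * D[2] + w13 * D[3],
                    w12 * D[1] + w12 * D[3],
                    w13 * D[1] + w12 * D[2])
  expect_equal(sig$s, manual, tolerance = 1e-12)
  expect_identical(sig$s, sig$extrinsic + sig$cell_cell)
  # with all cells silent the signal is purely extrinsic
  sig0 <- total_signal(c(0, 0, 0), lat, cp, g, 0, p)
  expect_equal(sig0$s, rep(0.3, 3))
  expect_equal(sig0$cell_cell, rep(0, 3))
  # doubling the coupling strength doubles only the cell-cell part
  cp2 <- compute_coupling(lat, 1, strength = 2, cutoff_factor = 3)
  sig2 <- total_signal(u, lat, cp2, g, 0, p)
  expect_equal(sig2$cell_cell, 2 * sig$cell_cell)
  expect_equal(sig2$extrinsic, sig$extrinsic)
  expect_error(total_signal(c(0, 0), lat, cp, g, 0, p), "match")
})

test_that("single-cell fixed points match a brute-force scan", {
  p <- model_params()
  for (s in c(-0.5, 0, 0.2, 0.3, 0.45, 0.6, 2)) {
    fp <- single_cell_fixed_points(s, p)
    grid <- seq(-0.5, 1.5, length.out = 1e5)
    gv <- activation(grid - s, p) - grid
    flips <- which(gv[-1] * gv[-1e5] < 0)
    expect_identical(nrow(fp), length(flips))
    expect_equal(fp$u, grid[flips], tolerance = 1e-3)
  }
  # very strong signal leaves a single stable root near zero
  fp_hi <- single_cell_fixed_points(5, p)
  expect_identical(nrow(fp_hi), 1L)
  expect_true(fp_hi$stable)
  expect_lt(fp_hi$u, 0.01)
})

test_that("the bistable signal window is a single interval", {
  p <- model_params()
  bw <- bistability_window(p)
  expect_false(is.na(bw$s_lo))
  expect_lt(bw$s_lo, bw$s_hi)
  bi <- which(bw$n_stable == 2L)
  expect_identical(bi, seq(min(bi), max(bi)))
  # monostable-high below the window, monostable-low far above it
  expect_identical(unique(bw$n_stable[bw$s < bw$s_lo - 0.05]), 1L)
})

test_that("a cell at a stable fixed point stays there", {
  p <- model_params(noise_sigma = 0)
  lat <- lattice_from_positions(cbind(5, 5), 10, 10)
  cp <- compute_coupling(lat, 1, strength = 0, cutoff_factor = 3)
  g <- flat_gradient(0.3)
  fp <- single_cell_fixed_points(0.3, p)
  u_star <- max(fp$u[fp$stable])
  tr <- simulate_lattice(lat, cp, p, g, u0 = u_star, t_end = 5,
                         seed = 1)
  expect_true(all(abs(tr$u - u_star) < 1e-9))
})

test_that("a single noiseless cell converges to a fixed point", {
  p <- model_params(noise_sigma = 0)
  lat <- lattice_from_positions(cbind(5, 5), 10, 10)
  cp <- compute_coupling(lat, 1, strength = 0, cutoff_factor = 3)
  for (case in list(c(0.3, 0.1), c(0.3, 0.9), c(0, 0.02), c(0.6, 0.9))) {
    s0 <- case[1]; u0 <- case[2]
    tr <- simulate_lattice(lat, cp, p, flat_gradient(s0), u0 = u0,
                           t_end = 60, seed = 1)
    u_T <- tr$u[nrow(tr$u), 1]
    fp <- single_cell_fixed_points(s0, p)
    expect_lt(min(abs(fp$u[fp$stable] - u_T)), 1e-6)
  }
})

test_that("two strongly coupled cells adopt opposite fates", {
  p <- model_params(noise_sigma = 0)
  lat <- lattice_from_positions(rbind(c(4.5, 5), c(5.5, 5)), 10, 10)
  cp <- compute_coupling(lat, 1, strength = 2, cutoff_factor = 2)
  g <- flat_gradient(0)
  tr <- simulate_lattice(lat, cp, p, g, u0 = c(0.51, 0.49), t_end = 60,
                         seed = 1)
  u_T <- tr$u[nrow(tr$u), ]
  expect_gt(u_T[1], 0.8)
  expect_lt(u_T[2], 0.2)
  # agrees with a 10x finer integration
  tr_fine <- simulate_lattice(lat, cp, p, g, u0 = c(0.51, 0.49),
                              t_end = 60, dt = 0.002,
                              record_every = 250, seed = 1)
  expect_equal(u_T, tr_fine$u[nrow(tr_fine$u), ], tolerance = 1e-3)
})

test_that("noiseless trajectories started in [0,1] stay in [0,1]", {
  p <- model_params(noise_sigma = 0)
  lat <- build_disordered_lattice(64, 8, 8, disorder = 0.3, seed = 2)
  cp <- compute_coupling(lat, 1, strength = 2, cutoff_factor = 3)
  g <- gradient_params(early = list(plateau = 1,
                                    notch_centers = c(2, 6),
                                    notch_width = 1, notch_depth = 1),
                       late = NULL, t_start = 0, t_end = 0,
                       box_width = 8)
  set.seed(9)
  tr <- simulate_lattice(lat, cp, p, g, u0 = runif(64), t_end = 20,
                         seed = 3)
  expect_true(all(tr$u >= 0 & tr$u <= 1))
})

test_that("raising a uniform extrinsic signal never raises terminal u", {
  # coupling below the symmetry-breaking threshold: with patterning,
  # raising s0 can remove a winner and thereby relieve its neighbours
  p <- model_params(noise_sigma = 0)
  lat <- build_disordered_lattice(16, 4, 4, disorder = 0.3, seed = 4)
  cp <- compute_coupling(lat, 1, strength = 0.02, cutoff_factor = 3)
  set.seed(10); u0 <- runif(16, 0, 0.1)
  finals <- sapply(c(0, 0.05, 0.2, 0.4, 0.8), function(s0) {
    tr <- simulate_lattice(lat, cp, p, flat_gradient(s0, 4), u0 = u0,
                           t_end = 40, seed = 1)
    tr$u[nrow(tr$u), ]
  })
  expect_true(all(diff(t(finals)) <= 1e-9))
})

test_that("integration converges as dt shrinks", {
  p <- model_params(noise_sigma = 0)
  lat <- build_disordered_lattice(16, 4, 4, disorder = 0.3, seed = 4)
  cp <- compute_coupling(lat, 1, strength = 0.3, cutoff_factor = 3)
  set.seed(11); u0 <- runif(16, 0, 0.1)
  g <- flat_gradient(0.25, 4)
  coarse <- simulate_lattice(lat, cp, p, g, u0 = u0, t_end = 20,
                             dt = 0.02, record_every = 50, seed = 1)
  fine <- simulate_lattice(lat, cp, p, g, u0 = u0, t_end = 20,
                           dt = 0.002, record_every = 500, seed = 1)
  expect_equal(coarse$u[nrow(coarse$u), ], fine$u[nrow(fine$u), ],
               tolerance = 0.02)
})

test_that("seeded simulations are bit-identical and dt is guarded", {
  p <- model_params()
  lat <- build_disordered_lattice(36, 6, 6, disorder = 0.3, seed = 5)
  cp <- compute_coupling(lat, 1, strength = 2, cutoff_factor = 3)
  g <- flat_gradient(0.3, 6)
  a <- simulate_lattice(lat, cp, p, g, t_end = 5, seed = 42)
  b <- simulate_lattice(lat, cp, p, g, t_end = 5, seed = 42)
  expect_identical(a$u, b$u)
  expect_identical(a$s, b$s)
  c <- simulate_lattice(lat, cp, p, g, t_end = 5, seed = 43)
  expect_false(identical(a$u, c$u))
  expect_error(simulate_lattice(lat, cp, p, g, t_end = 5, dt = 0.5),
               "tau / 10")
})
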