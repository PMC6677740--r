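make_traj <- function(u_final, lattice) {
  # minimal trajectory wrapper around a prescribed terminal state
  structure(list(times = c(0, 1),
                 u = rbind(rep(0, length(u_final)), u_final),
                 s = matrix(0, 2, length(u_final)),
                 s_extrinsic = matrix(0, 2, length(u_final)),
                 params = model_params(), seed = 1L, dt = 0.02,
                 lattice = lattice),
            class = "trajectory")
}

test_that("fate calls threshold the terminal state", {
  lat <- build_disordered_lattice(16, 4, 4, disorder = 0.3, seed = 1)
  expect_identical(sum(call_fates(make_traj(rep(0, 16), lat))$sop), 0L)
  expect_identical(sum(call_fates(make_traj(rep(1, 16), lat))$sop), 16L)
  set.seed(3); u <- runif(16)
  fc <- call_fates(make_traj(u, lat))
  expect_identical(fc$sop, u > model_params()$fate_threshold)
  expect_error(call_fates(structure(list(u = matrix(0, 0, 0)),
                                    class = "trajectory")),
               "snapshot")
})

test_that("pattern statistics handle empty, paired and saturated cases", {
  lat <- build_disordered_lattice(16, 4, 4, disorder = 0, seed = 1)
  none <- pattern_stats(structure(list(sop = rep(FALSE, 16)),
                                  class = "fate_call"), lat)
  expect_identical(none$n_sop, 0L)
  expect_identical(none$nn_distances, numeric(0))
  expect_identical(none$adjacent_sop_pairs, 0L)

  lat2 <- lattice_from_positions(rbind(c(1, 5), c(9, 5), c(5, 2)), 10, 10)
  two <- pattern_stats(structure(list(sop = c(TRUE, TRUE, FALSE)),
                                 class = "fate_call"), lat2)
  expect_identical(two$n_sop, 2L)
  expect_equal(two$nn_distances, rep(periodic_distance(lat2, 1, 2), 2))
  expect_equal(two$sop_density, 2 / 100)

  all_sop <- pattern_stats(structure(list(sop = rep(TRUE, 16)),
                                     class = "fate_call"), lat)
  expect_identical(all_sop$adjacent_sop_pairs, nrow(lat$neighbor_pairs))
})

test_that("stripe profiles recover planted stripes", {
  lat <- build_disordered_lattice(400, 20, 20, disorder = 0.3, seed = 6)
  centers <- c(3, 10, 16)
  u <- planted_stripe_field(lat, centers, widths = 2, high = 1, low = 0)
  prof <- stripe_profile(u, lat, bin_width = 1)
  expect_identical(count_stripes(prof), 3L)
  # detected stripe centers lie within one bin of the planted ones
  thr <- (max(prof$mean_u) + min(prof$mean_u)) / 2
  hi <- prof$bin_center[prof$mean_u > thr]
  for (cen in centers) expect_lte(min(abs(hi - cen)), 1)

  # uniform fields give a flat profile and 0 or 1 stripes
  flat <- stripe_profile(rep(0.4, 400), lat, bin_width = 1)
  expect_true(all(abs(flat$mean_u - 0.4) < 1e-12))
  expect_identical(count_stripes(flat, threshold = 0.5), 0L)
  expect_identical(count_stripes(flat, threshold = 0.3), 1L)

  # full-coverage stripes give a uniform high field
  expect_true(all(planted_stripe_field(lat, c(5, 15), widths = 10) == 1))
  # no stripes gives uniform low
  expect_true(all(planted_stripe_field(lat, numeric(0), 1, low = 0.1)
                  == 0.1))
})

test_that("SOP stripe clustering separates rows from scattered defects", {
  lat <- build_disordered_lattice(400, 20, 20, disorder = 0.3, seed = 6)
  x <- lat$positions[, 1]
  # three planted SOP columns plus one isolated defect SOP
  sop <- (abs(x - 4) < 0.4) | (abs(x - 10) < 0.4) | (abs(x - 16) < 0.4)
  defect <- which(abs(x - 7) < 0.2)[1]
  sop[defect] <- TRUE
  st <- sop_stripes(sop, lat, gap = 0.9, min_size = 2)
  expect_identical(nrow(st), 3L)
  expect_true(all(st$narrow))
  expect_equal(sort(st$center), c(4, 10, 16), tolerance = 0.5)
  # no SOPs: empty table
  expect_identical(nrow(sop_stripes(rep(FALSE, 400), lat)), 0L)
})

test_that("binned time courses partition the stripe window", {
  cfg <- tiny_config(t_end = 5)
  r <- run_simulation(cfg, seed = 2)
  btc <- bin_time_courses(r$trajectory, r$lattice, 7.5, 1.5, n_bins = 3)
  memb <- btc$membership
  # every cell in the window is in exactly one bin
  W <- r$lattice$box_width
  dx <- abs(r$lattice$positions[, 1] - 7.5)
  dx <- pmin(dx, W - dx)
  expect_setequal(memb$cell, which(dx <= 1.5))
  expect_true(all(memb$bin %in% 1:3))
  # a single bin reproduces the global window mean
  one <- bin_time_courses(r$trajectory, r$lattice, 7.5, 1.5, n_bins = 2)
  allw <- rowMeans(r$trajectory$u[, memb$cell, drop = FALSE])
  n1 <- sum(one$membership$bin == 1); n2 <- sum(one$membership$bin == 2)
  expect_equal((one$mean_u[, 1] * n1 + one$mean_u[, 2] * n2) / (n1 + n2),
               allw, tolerance = 1e-12)
  expect_error(bin_time_courses(r$trajectory, r$lattice, 7.5, 1.5, 1),
               "at least 2")
})

test_that("regime comparison is deterministic and validates inputs", {
  cfg <- tiny_config(t_end = 5)
  regs <- list(wild_type = make_regime_config("wild_type", cfg),
               again = make_regime_config("wild_type", cfg))
  out <- compare_regimes(regs, seeds = c(1, 2))
  expect_identical(nrow(out), 2L)
  # identical regime listed twice gives identical rows
  expect_equal(out[1, -1], out[2, -1], ignore_attr = TRUE)
  out2 <- compare_regimes(regs, seeds = c(1, 2))
  expect_identical(out, out2)
  expect_error(compare_regimes(regs["wild_type"], seeds = 1), "2 regimes")
})
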