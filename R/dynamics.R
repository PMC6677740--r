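# Bistable lateral-inhibition dynamics.
#
# Each cell i carries a scalar proneural activity u_i obeying
#
#     tau * du_i/dt = f(u_i - s_i) - u_i + eta_i(t)
#
# where f is a sigmoid rising from 0 to 1 (self-activation opposed by
# inhibition), eta_i is Gaussian white noise, and the inhibitory signal
#
#     s_i = s0(x_i, t) + sum_{j != i} c_ij * Dstar(u_j)
#
# combines a time-dependent extrinsic gradient s0 along the
# medial-distal (x) axis with distance-weighted ligand activity
# Dstar(u_j) from surrounding cells.  Signalling is instantaneous.

#' Model parameters for the single-cell dynamics
#'
#' @param tau characteristic relaxation time (time unit of the model).
#' @param f_threshold midpoint offset of the activation sigmoid: the net
#'   drive `u - s` at which activation is half-maximal.
#' @param f_steepness width `eps` of the sigmoid transition; smaller
#'   values give a steeper, more switch-like response.  The defaults
#'   place an isolated cell in the bistable regime for intermediate
#'   signal levels while making the high state the only attractor at
#'   `s = 0`.
#' @param noise_sigma amplitude of the Gaussian white-noise term, in
#'   state units per sqrt(time); `0` gives deterministic dynamics.
#' @param d_mid,d_steepness midpoint and width of the ligand-activity
#'   sigmoid `Dstar(u)` (rescaled so `Dstar(0) = 0`, `Dstar(1) = 1`).
#' @param fate_threshold terminal `u` above which a cell is called a
#'   sensory organ precursor (SOP).  The default is the midpoint of the
#'   two stable branches at the center of the bistable signal window.
#' @return An object of class `model_params` (a validated list).
#' @export
model_params <- function(tau = 1, f_threshold = 0.2, f_steepness = 0.1,
                         noise_sigma = 0.02, d_mid = 0.5,
                         d_steepness = 0.1, fate_threshold = 0.5) {
  if (tau <= 0) stop("`tau` must be positive")
  if (f_steepness <= 0) stop("`f_steepness` must be positive")
  if (d_steepness <= 0) stop("`d_steepness` must be positive")
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative")
  structure(list(tau = tau, f_threshold = f_threshold,
                 f_steepness = f_steepness, noise_sigma = noise_sigma,
                 d_mid = d_mid, d_steepness = d_steepness,
                 fate_threshold = fate_threshold),
            class = "model_params")
}

#' Sigmoidal activation function
#'
#' Logistic balance of self-activation versus inhibition:
#' `f(v) = 1 / (1 + exp(-(v - f_threshold) / f_steepness))`, strictly
#' increasing with limits 0 and 1.
#'
#' @param v net drive `u - s` (any numeric vector).
#' @param params a [model_params()] object.
#' @return Activation in (0, 1), same shape as `v`.
#' @export
activation <- function(v, params) {
  1 / (1 + exp(-(v - params$f_threshold) / params$f_steepness))
}

#' Ligand activity produced by a cell
#'
#' Active-ligand output as a saturating, monotone function of the cell
#' state: a logistic in `u` rescaled so that `Dstar(0) = 0` and
#' `Dstar(1) = 1`, clamped to `[0, 1]` outside the unit interval.
#'
#' @param u cell state (numeric vector).
#' @param params a [model_params()] object.
#' @return Ligand activity in `[0, 1]`.
#' @export
ligand_activity <- function(u, params) {
  sig <- function(z) 1 / (1 + exp(-(z - params$d_mid) / params$d_steepness))
  s0 <- sig(0); s1 <- sig(1)
  pmin(1, pmax(0, (sig(u) - s0) / (s1 - s0)))
}

#' Extrinsic signalling gradient parameters
#'
#' The extrinsic signal `s0(x, t)` interpolates in time between an early
#' profile (proneural-independent Notch activity: a plateau with notches
#' at the template stripe positions, the "negative template") and a late
#' profile (inhibition emanating from the flank stripes 1 and 5: a wide
#' Gaussian halo around each source position minus a narrow core, so the
#' source row itself is not self-inhibited).  Both profiles are periodic
#' in `x` with the box width.
#'
#' @param early list describing the early profile:
#'   `list(plateau, notch_centers, notch_width, notch_depth)`; the
#'   profile is `plateau * (1 - notch_depth * sum_k exp(-d_k^2 / (2
#'   notch_width^2)))` with `d_k` the periodic x-distance to notch k,
#'   floored at 0.
#' @param late list describing the late profile:
#'   `list(centers, amplitude, width, core_width)`; the profile is
#'   `amplitude * sum_k (exp(-d_k^2 / (2 width^2)) - exp(-d_k^2 /
#'   (2 core_width^2)))`, floored at 0.  `NULL` keeps the early profile
#'   for all times (a static gradient, as in single-stripe resolution
#'   studies).
#' @param t_start,t_end start and end of the linear early-to-late
#'   transition (model time units); `t_start <= t_end`.
#' @param box_width spatial period of the profiles.
#' @return An object of class `gradient_params`.
#' @export
gradient_params <- function(early = list(plateau = 1,
                                         notch_centers = c(1.5, 7.5, 13.5),
                                         notch_width = 1, notch_depth = 1),
                            late = list(centers = c(1.5, 13.5),
                                        amplitude = 0.5, width = 1.2,
                                        core_width = 0.5),
                            t_start = 5, t_end = 15, box_width = 15) {
  if (t_start > t_end) stop("`t_start` must be <= `t_end`")
  if (box_width <= 0) stop("`box_width` must be positive")
  stopifnot(is.list(early), is.list(late) || is.null(late))
  structure(list(early = early, late = late, t_start = t_start,
                 t_end = t_end, box_width = box_width),
            class = "gradient_params")
}

# periodic x-distance to a set of centers: returns length(x) x
# length(centers) matrix
periodic_dx <- function(x, centers, W) {
  d <- outer(x, centers, "-")
  abs(d - W * round(d / W))
}

eval_early_profile <- function(x, g) {
  e <- g$early
  if (length(e$notch_centers) == 0L || e$notch_depth == 0) {
    return(rep(e$plateau, length(x)))
  }
  d <- periodic_dx(x, e$notch_centers, g$box_width)
  v <- e$plateau * (1 - e$notch_depth *
                      rowSums(exp(-d^2 / (2 * e$notch_width^2))))
  pmax(0, v)
}

eval_late_profile <- function(x, g) {
  l <- g$late
  if (length(l$centers) == 0L || l$amplitude == 0) {
    return(rep(0, length(x)))
  }
  d <- periodic_dx(x, l$centers, g$box_width)
  halo <- exp(-d^2 / (2 * l$width^2)) - exp(-d^2 / (2 * l$core_width^2))
  pmax(0, l$amplitude * rowSums(halo))
}

#' Evaluate the extrinsic signal
#'
#' Equals the early profile for `t <= t_start`, the late profile for
#' `t >= t_end`, and the linear interpolation in between.
#'
#' @param x cell positions along the medial-distal axis (vector).
#' @param t time (scalar).
#' @param g a [gradient_params()] object.
#' @return Extrinsic signal at each `x`.
#' @export
extrinsic_signal <- function(x, t, g) {
  early <- eval_early_profile(x, g)
  if (is.null(g$late) || t <= g$t_start) return(early)
  late <- eval_late_profile(x, g)
  if (t >= g$t_end) return(late)
  lam <- (t - g$t_start) / (g$t_end - g$t_start)
  (1 - lam) * early + lam * late
}

#' Total inhibitory signal received by each cell
#'
#' Computes `s_i = s0(x_i, t) + sum_{j != i} c_ij * Dstar(u_j)` from the
#' current state; signalling is instantaneous.  The extrinsic and
#' cell-cell parts are returned separately.
#'
#' @param u per-cell state vector.
#' @param lattice a `cell_lattice`.
#' @param coupling a `coupling_matrix`.
#' @param g a [gradient_params()] object.
#' @param t time.
#' @param params a [model_params()] object (for the ligand function).
#' @return A list with `s` (total), `extrinsic` and `cell_cell`
#'   components, each a vector over cells; `s = extrinsic + cell_cell`
#'   exactly.
#' @export
total_signal <- function(u, lattice, coupling, g, t, params) {
  n <- nrow(lattice$positions)
  if (length(u) != n) stop("length of `u` does not match the lattice")
  if (nrow(coupling$weights) != n)
    stop("coupling matrix does not match the lattice")
  extr <- extrinsic_signal(lattice$positions[, 1], t, g)
  cc <- as.numeric(coupling$weights %*% ligand_activity(u, params))
  list(s = extr + cc, extrinsic = extr, cell_cell = cc)
}

#' Simulate the lateral-inhibition dynamics
#'
#' Integrates the coupled stochastic dynamics by the Euler-Maruyama
#' scheme: `u <- u + (dt / tau) * (f(u - s) - u) + noise_sigma *
#' sqrt(dt) * N(0, 1)`, with the signal recomputed from the current
#' state at every step.  With `noise_sigma = 0` the trajectory is a
#' deterministic function of the inputs; otherwise all noise derives
#' from `seed`.
#'
#' @param lattice a `cell_lattice`.
#' @param coupling a `coupling_matrix` on the same lattice.
#' @param params a [model_params()] object.
#' @param g a [gradient_params()] object.
#' @param u0 initial state vector; default independent uniform on
#'   `[0, 0.1]` (low initial proneural activity), drawn from `seed`.
#' @param t_end end time.
#' @param dt time step; must satisfy `dt <= tau / 10` (default
#'   `tau / 50`).
#' @param record_every record a snapshot every this many steps.
#' @param seed integer seed controlling `u0` and the noise.
#' @return An object of class `trajectory`: list with `times`,
#'   `u` and `s` (snapshot matrices, time x cell), `s_extrinsic`,
#'   `params`, `gradient`, `seed`, `dt` and the `lattice`.
#' @export
simulate_lattice <- function(lattice, coupling, params, g, u0 = NULL,
                             t_end = 30, dt = params$tau / 50,
                             record_every = 25L, seed = 1L) {
  if (dt <= 0) stop("`dt` must be positive")
  if (dt > params$tau / 10)
    stop("`dt` must be at most tau / 10 for a stable integration")
  n <- nrow(lattice$positions)
  if (nrow(coupling$weights) != n)
    stop("coupling matrix does not match the lattice")
  set.seed(as.integer(seed))
  if (is.null(u0)) u0 <- runif(n, 0, 0.1)
  if (length(u0) != n) stop("`u0` length does not match the lattice")

  n_steps <- ceiling(t_end / dt)
  rec_idx <- unique(c(seq(0L, n_steps, by = as.integer(record_every)),
                      n_steps))
  n_rec <- length(rec_idx)
  u_snap <- matrix(NA_real_, n_rec, n)
  s_snap <- matrix(NA_real_, n_rec, n)
  e_snap <- matrix(NA_real_, n_rec, n)
  times <- rec_idx * dt

  u <- u0
  x <- lattice$positions[, 1]
  W <- coupling$weights
  sig <- params$noise_sigma
  sqdt <- sqrt(dt)
  rec <- 1L
  for (step in 0:n_steps) {
    t_now <- step * dt
    extr <- extrinsic_signal(x, t_now, g)
    s <- extr + as.numeric(W %*% ligand_activity(u, params))
    if (step == rec_idx[rec]) {
      u_snap[rec, ] <- u
      s_snap[rec, ] <- s
      e_snap[rec, ] <- extr
      rec <- rec + 1L
    }
    if (step == n_steps) break
    du <- (dt / params$tau) * (activation(u - s, params) - u)
    if (sig > 0) du <- du + sig * sqdt * rnorm(n)
    u <- u + du
    if (!all(is.finite(u)))
      stop("non-finite state at step ", step + 1L,
           " (t = ", format((step + 1L) * dt), "); first offending cell: ",
           which(!is.finite(u))[1])
  }
  structure(list(times = times, u = u_snap, s = s_snap,
                 s_extrinsic = e_snap, params = params, gradient = g,
                 seed = as.integer(seed), dt = dt, lattice = lattice),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", ncol(x$u), "cells,", length(x$times),
      "snapshots over t in [0,", max(x$times), "], seed", x$seed, "\n")
  invisible(x)
}

#' Fixed points of an isolated cell at constant signal
#'
#' Finds all roots of `f(u - s) - u` on `u` in `[-0.5, 1.5]` by a
#' sign-change scan refined with [stats::uniroot()], and classifies their
#' stability from the sign of the derivative `f'(u - s) - 1`.
#'
#' @param s constant signal level.
#' @param params a [model_params()] object.
#' @param n_grid number of scan points.
#' @return A data frame with columns `u` (sorted) and `stable` (logical).
#' @export
single_cell_fixed_points <- function(s, params, n_grid = 2001L) {
  gfun <- function(u) activation(u - s, params) - u
  grid <- seq(-0.5, 1.5, length.out = n_grid)
  gv <- gfun(grid)
  roots <- grid[gv == 0]
  sgn <- sign(gv)
  flip <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (k in flip) {
    r <- uniroot(gfun, c(grid[k], grid[k + 1]), tol = 1e-12)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L)
    return(data.frame(u = numeric(0), stable = logical(0)))
  eps <- params$f_steepness
  fprime <- function(u) {
    fv <- activation(u - s, params)
    fv * (1 - fv) / eps
  }
  data.frame(u = roots, stable = fprime(roots) - 1 < 0)
}

#' Bistable signal window of an isolated cell
#'
#' Scans constant signal levels and reports the interval of `s` over
#' which the single-cell dynamics have two stable fixed points.
#'
#' @param params a [model_params()] object.
#' @param s_range range of signal levels to scan.
#' @param n number of scan points.
#' @return A list with `s_lo`, `s_hi` (NA if never bistable) and the scan
#'   (`s`, `n_stable`).
#' @export
bistability_window <- function(params, s_range = c(-1, 1.5), n = 301L) {
  s_scan <- seq(s_range[1], s_range[2], length.out = n)
  n_stable <- vapply(s_scan, function(s) {
    sum(single_cell_fixed_points(s, params)$stable)
  }, integer(1))
  bi <- which(n_stable == 2L)
  list(s_lo = if (length(bi)) s_scan[min(bi)] else NA_real_,
       s_hi = if (length(bi)) s_scan[max(bi)] else NA_real_,
       s = s_scan, n_stable = n_stable)
}

#' Trajectory writer
#'
#' Writes one long-format CSV (`time`, `cell`, `u`, `s`, `s_extrinsic`)
#' plus a JSON manifest of all parameters and the seed.
#'
#' @param traj a `trajectory`.
#' @param csv_path output CSV path.
#' @param manifest_path optional JSON manifest path.
#' @return `csv_path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, csv_path, manifest_path = NULL) {
  n <- ncol(traj$u)
  df <- data.frame(
    time = rep(traj$times, each = n),
    cell = rep(seq_len(n), times = length(traj$times)),
    u = as.vector(t(traj$u)),
    s = as.vector(t(traj$s)),
    s_extrinsic = as.vector(t(traj$s_extrinsic)))
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(params = unclass(traj$params),
                     gradient = unclass(traj$gradient),
                     seed = traj$seed, dt = traj$dt,
                     n_cells = n,
                     box = c(traj$lattice$box_width,
                             traj$lattice$box_height),
                     package_version =
                       as.character(packageVersion("notumpattern")))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}
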