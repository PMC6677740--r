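# From trajectories to fates and pattern readouts: SOP calling, spacing
# statistics, stripe detection along the medial-distal axis, and
# position-binned time courses within a stripe.

#' Call cell fates from the terminal state
#'
#' Cells whose terminal proneural activity exceeds the fate threshold are
#' labelled sensory organ precursors (SOP); all others epidermal.
#'
#' @param traj a `trajectory`.
#' @param params a [model_params()] object supplying `fate_threshold`
#'   (defaults to the trajectory's own parameters).
#' @return An object of class `fate_call`: list with `labels` (factor
#'   `"SOP"`/`"epidermal"`), `sop` (logical vector), `threshold`, `time`.
#' @export
call_fates <- function(traj, params = traj$params) {
  if (is.null(traj$u) || nrow(traj$u) == 0L)
    stop("trajectory has no snapshots")
  u_final <- traj$u[nrow(traj$u), ]
  sop <- u_final > params$fate_threshold
  structure(list(labels = factor(ifelse(sop, "SOP", "epidermal"),
                                 levels = c("SOP", "epidermal")),
                 sop = sop, threshold = params$fate_threshold,
                 time = traj$times[length(traj$times)]),
            class = "fate_call")
}

#' Spacing and density statistics of an SOP pattern
#'
#' @param fates a `fate_call`.
#' @param lattice the `cell_lattice` the fates live on.
#' @return An object of class `pattern_stats`: `n_sop`, `sop_fraction`,
#'   `sop_density` (SOPs per unit area), `nn_distances` (periodic
#'   nearest-neighbour distances between SOPs), `spacing_cv`
#'   (sd/mean of `nn_distances`), `adjacent_sop_pairs` (Delaunay-adjacent
#'   SOP pairs).  With no SOPs, counts are zero and the distance list
#'   empty.
#' @export
pattern_stats <- function(fates, lattice) {
  n <- nrow(lattice$positions)
  if (length(fates$sop) != n)
    stop("fate labels do not match the lattice")
  sop_idx <- which(fates$sop)
  area <- lattice$box_width * lattice$box_height
  if (length(sop_idx) == 0L) {
    return(structure(list(n_sop = 0L, sop_fraction = 0, sop_density = 0,
                          nn_distances = numeric(0), spacing_cv = NA_real_,
                          adjacent_sop_pairs = 0L),
                     class = "pattern_stats"))
  }
  nn <- if (length(sop_idx) >= 2L) {
    d <- periodic_distance_matrix(
      lattice$positions[sop_idx, , drop = FALSE],
      lattice$box_width, lattice$box_height)
    diag(d) <- Inf
    apply(d, 1, min)
  } else numeric(0)
  np <- lattice$neighbor_pairs
  adj <- if (nrow(np)) sum(fates$sop[np[, 1]] & fates$sop[np[, 2]]) else 0L
  structure(list(n_sop = length(sop_idx),
                 sop_fraction = length(sop_idx) / n,
                 sop_density = length(sop_idx) / area,
                 nn_distances = nn,
                 spacing_cv = if (length(nn) >= 2L) sd(nn) / mean(nn)
                              else NA_real_,
                 adjacent_sop_pairs = as.integer(adj)),
            class = "pattern_stats")
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat("pattern_stats:", x$n_sop, "SOPs, density",
      format(x$sop_density, digits = 3), "per diameter^2, spacing CV",
      format(x$spacing_cv, digits = 3), "\n")
  invisible(x)
}

#' Mean state profile along the medial-distal axis
#'
#' Bins cells by `x` position (periodic) and returns the per-bin mean of
#' a state field; the standard readout for detecting proneural stripes.
#'
#' @param u per-cell state vector (or a `trajectory`, in which case its
#'   final snapshot is profiled).
#' @param lattice a `cell_lattice`.
#' @param bin_width bin width in cell diameters (> 0).
#' @return A data frame with `bin_center`, `mean_u` and `n_cells`; empty
#'   bins carry `NA` means.
#' @export
stripe_profile <- function(u, lattice, bin_width = 0.75) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (inherits(u, "trajectory")) u <- u$u[nrow(u$u), ]
  W <- lattice$box_width
  edges <- seq(0, W, by = bin_width)
  if (edges[length(edges)] < W) edges <- c(edges, W)
  x <- lattice$positions[, 1]
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  f <- factor(bin, levels = seq_len(length(edges) - 1L))
  data.frame(bin_center = (edges[-length(edges)] + edges[-1]) / 2,
             mean_u = as.numeric(tapply(u, f, mean)),
             n_cells = as.integer(table(f)))
}

#' Count stripes in a profile
#'
#' Counts contiguous super-threshold runs of the binned profile, with
#' periodic wraparound.  The default threshold is the midpoint of the
#' profile's range.
#'
#' @param profile a data frame from [stripe_profile()].
#' @param threshold detection level; default `(max + min) / 2` of the
#'   profile means.
#' @return Number of stripes (integer); 0 for an all-sub-threshold
#'   profile, 1 when every bin is super-threshold.
#' @export
count_stripes <- function(profile, threshold = NULL) {
  v <- profile$mean_u
  v[is.na(v)] <- -Inf
  if (is.null(threshold)) {
    fin <- v[is.finite(v)]
    threshold <- (max(fin) + min(fin)) / 2
  }
  hi <- v > threshold
  if (!any(hi)) return(0L)
  if (all(hi)) return(1L)
  # count rising edges on the cycle
  prev <- c(hi[length(hi)], hi[-length(hi)])
  as.integer(sum(hi & !prev))
}

#' Detect stripes from SOP positions
#'
#' Clusters the medial-distal (`x`) positions of SOPs on the periodic
#' axis: positions closer than `gap` belong to one cluster, and clusters
#' with fewer than `min_size` SOPs are discarded as isolated defects.
#' A cluster of x-extent at most `narrow_width` is a "stripe" in the
#' row-patterned sense; wider clusters indicate a broad unresolved
#' proneural domain.
#'
#' @param fates a `fate_call` (or a logical SOP vector).
#' @param lattice a `cell_lattice`.
#' @param gap minimum x separation between clusters (cell diameters).
#' @param min_size minimum SOPs per cluster.
#' @param narrow_width maximum x-extent for a cluster to count as a
#'   narrow stripe.
#' @return A data frame with one row per cluster: `center`, `width`,
#'   `n_sop`, `narrow` (logical).  Zero rows when there are no SOPs.
#' @export
sop_stripes <- function(fates, lattice, gap = 1.2, min_size = 2L,
                        narrow_width = 1.5) {
  sop <- if (inherits(fates, "fate_call")) fates$sop else as.logical(fates)
  W <- lattice$box_width
  sx <- sort(lattice$positions[sop, 1])
  n <- length(sx)
  empty <- data.frame(center = numeric(0), width = numeric(0),
                      n_sop = integer(0), narrow = logical(0))
  if (n == 0L) return(empty)
  if (n == 1L) {
    cl <- data.frame(center = sx, width = 0, n_sop = 1L, narrow = TRUE)
    return(cl[cl$n_sop >= min_size, , drop = FALSE])
  }
  gaps <- c(diff(sx), sx[1] + W - sx[n])      # gap after each point
  brk <- which(gaps > gap)
  if (length(brk) == 0L) {
    # single cluster covering the whole circumference
    return(data.frame(center = mean(sx), width = W, n_sop = n,
                      narrow = W <= narrow_width)[min_size <= n, ,
                                                  drop = FALSE])
  }
  # walk the circle starting just after the last break
  start <- (brk[length(brk)] %% n) + 1L
  ord <- ((start - 1L + 0:(n - 1L)) %% n) + 1L
  x0 <- sx[ord[1]]
  xs <- (sx[ord] - x0) %% W                   # unwrapped, increasing
  cl_id <- cumsum(c(1, diff(xs) > gap))
  out <- do.call(rbind, lapply(split(xs, cl_id), function(xc) {
    data.frame(center = (x0 + mean(range(xc))) %% W,
               width = diff(range(xc)), n_sop = length(xc))
  }))
  out$narrow <- out$width <= narrow_width
  out <- out[out$n_sop >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$center), , drop = FALSE]
}

#' Position-binned time courses within a stripe
#'
#' Selects the cells whose periodic x-distance to `stripe_center_x` is at
#' most `stripe_halfwidth`, splits them into `n_bins` bins of increasing
#' `|x - center|`, and averages the state `u` and signal `s` per bin over
#' time.  This is the standard view of stripe resolution: central cells
#' versus lateral cells.
#'
#' @param traj a `trajectory`.
#' @param lattice a `cell_lattice`.
#' @param stripe_center_x stripe center (cell diameters).
#' @param stripe_halfwidth half-width of the analysis window.
#' @param n_bins number of distance bins (>= 2).
#' @return An object of class `binned_time_course`: list with `times`,
#'   `mean_u` and `mean_s` (time x bin matrices; `NA` columns for empty
#'   bins), `bin_edges` (distances), and `membership` (per selected cell:
#'   index and bin).
#' @export
bin_time_courses <- function(traj, lattice, stripe_center_x,
                             stripe_halfwidth, n_bins = 3L) {
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  W <- lattice$box_width
  dx <- lattice$positions[, 1] - stripe_center_x
  dx <- abs(dx - W * round(dx / W))
  sel <- which(dx <= stripe_halfwidth)
  edges <- seq(0, stripe_halfwidth, length.out = n_bins + 1L)
  bin <- pmin(findInterval(dx[sel], edges, rightmost.closed = TRUE),
              n_bins)
  mean_by_bin <- function(mat) {
    out <- matrix(NA_real_, nrow(mat), n_bins)
    for (b in seq_len(n_bins)) {
      cells <- sel[bin == b]
      if (length(cells))
        out[, b] <- rowMeans(mat[, cells, drop = FALSE])
    }
    out
  }
  structure(list(times = traj$times,
                 mean_u = mean_by_bin(traj$u),
                 mean_s = mean_by_bin(traj$s),
                 bin_edges = edges,
                 membership = data.frame(cell = sel, bin = bin)),
            class = "binned_time_course")
}

#' Run a set of regimes over replicate seeds and summarize
#'
#' For each named regime configuration, runs the full
#' lattice-coupling-simulation-fates pipeline once per seed and returns
#' per-regime means and standard deviations of the pattern statistics.
#' Deterministic given the seed list.
#'
#' @param regimes named list of run configurations (see
#'   [default_config()] / [make_regime_config()]).
#' @param seeds integer vector of replicate seeds.
#' @return A data frame with one row per regime: replicate means and sds
#'   of SOP count, fraction, density, spacing CV and narrow-stripe count.
#' @export
compare_regimes <- function(regimes, seeds) {
  if (length(regimes) < 2L) stop("need at least 2 regimes")
  if (is.null(names(regimes)) || any(names(regimes) == ""))
    stop("`regimes` must be a named list")
  rows <- lapply(names(regimes), function(nm) {
    reps <- lapply(seeds, function(sd) {
      res <- run_simulation(regimes[[nm]], seed = sd)
      st <- res$stats
      data.frame(n_sop = st$n_sop, sop_fraction = st$sop_fraction,
                 sop_density = st$sop_density,
                 spacing_cv = st$spacing_cv,
                 n_stripes = sum(res$stripes$narrow))
    })
    reps <- do.call(rbind, reps)
    data.frame(regime = nm, n_replicates = length(seeds),
               n_sop_mean = mean(reps$n_sop), n_sop_sd = sd(reps$n_sop),
               sop_fraction_mean = mean(reps$sop_fraction),
               sop_density_mean = mean(reps$sop_density),
               sop_density_sd = sd(reps$sop_density),
               spacing_cv_mean = mean(reps$spacing_cv, na.rm = TRUE),
               n_stripes_mean = mean(reps$n_stripes),
               n_stripes_sd = sd(reps$n_stripes))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run one full simulation from a run configuration
#'
#' Convenience wrapper: builds the lattice and coupling, simulates, and
#' computes fates, pattern statistics and stripe clusters.
#'
#' @param config a run configuration list (see [default_config()]).
#' @param seed replicate seed; overrides the config's `simulation$seed`.
#'   The lattice seed is derived as `seed + 7919` so that replicate
#'   tissues differ as well.
#' @return A list with `trajectory`, `fates`, `stats`, `stripes`,
#'   `lattice`, `coupling` and the resolved `config`.
#' @export
run_simulation <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$simulation$seed
  lat_seed <- (as.integer(seed) + 7919L) %% .Machine$integer.max
  lc <- config$lattice
  lat <- build_disordered_lattice(lc$n_cells, lc$box_width, lc$box_height,
                                  disorder = lc$disorder, seed = lat_seed,
                                  n_lloyd = lc$n_lloyd)
  cc <- config$coupling
  cp <- compute_coupling(lat, cc$signaling_range, strength = cc$strength,
                         cutoff_factor = cc$cutoff_factor,
                         normalized = cc$normalized)
  params <- do.call(model_params, config$model)
  g <- do.call(gradient_params,
               c(config$gradient,
                 list(box_width = config$lattice$box_width)))
  sim <- config$simulation
  traj <- simulate_lattice(lat, cp, params, g, t_end = sim$t_end,
                           dt = sim$dt, record_every = sim$record_every,
                           seed = seed)
  fates <- call_fates(traj, params)
  list(trajectory = traj, fates = fates,
       stats = pattern_stats(fates, lat),
       stripes = sop_stripes(fates, lat),
       lattice = lat, coupling = cp, config = config)
}
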