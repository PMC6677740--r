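# Shared fixtures: all test inputs are generated in code.

# 7-cell hexagonal rosette (center + ring at unit distance) in a
# periodic box large enough that wraparound images are irrelevant.
rosette_lattice <- function(box = 10) {
  ang <- (0:5) * pi / 3
  pos <- rbind(c(box / 2, box / 2),
               cbind(box / 2 + cos(ang), box / 2 + sin(ang)))
  lattice_from_positions(pos, box, box)
}

# nearest-neighbour coupling on the rosette: unit-distance pairs only
rosette_coupling <- function(lat, strength = 1) {
  compute_coupling(lat, signaling_range = 1, strength = strength,
                   cutoff_factor = 1.1)
}

# flat extrinsic signal at a constant level
flat_gradient <- function(level = 0, box_width = 10) {
  gradient_params(early = list(plateau = level,
                               notch_centers = numeric(0),
                               notch_width = 1, notch_depth = 0),
                  late = NULL, t_start = 0, t_end = 0,
                  box_width = box_width)
}

# small wild-type-like configuration for fast pipeline tests
tiny_config <- function(t_end = 5) {
  cfg <- default_config(n_cells = 150L, box_height = 10)
  cfg$simulation$t_end <- t_end
  cfg
}

# independent, deliberately naive reimplementation of the profile
# computation: plain loops, no vectorization
naive_profile <- function(records, line, channel, bin_width = 2,
                          range_um = 20, threshold = 0.2,
                          statistic = "sum_minus_threshold") {
  edges <- seq(-range_um, range_um, by = bin_width)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  images <- unique(records$image_id)
  mat <- matrix(0, length(images), length(centers))
  nc <- paste0(channel, "_norm")
  for (ii in seq_along(images)) {
    rows <- records[records$image_id == images[ii], ]
    counts <- rep(0, length(centers))
    for (r in seq_len(nrow(rows))) {
      d <- signed_distance(rows$x_um[r], rows$y_um[r], line)
      v <- rows[[nc]][r]
      if (is.na(v) || v <= threshold) next
      for (b in seq_along(centers)) {
        if (d >= edges[b] && d < edges[b + 1]) {
          if (statistic == "sum_minus_threshold") {
            mat[ii, b] <- mat[ii, b] + (v - threshold)
          } else {
            mat[ii, b] <- mat[ii, b] + v
            counts[b] <- counts[b] + 1
          }
        }
      }
    }
    if (statistic == "mean_intensity") {
      for (b in seq_along(centers))
        if (counts[b] > 0) mat[ii, b] <- mat[ii, b] / counts[b]
    }
  }
  list(centers = centers, mean = colMeans(mat), per_image = mat)
}

# random small multi-image nucleus field with precomputed normalized
# intensities (uniform positions, no spatial structure needed)
random_norm_field <- function(n_images = 2, n_nuclei = 40, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_images), function(i) {
    data.frame(image_id = paste0("img", i),
               nucleus_id = seq_len(n_nuclei),
               x_um = runif(n_nuclei, 0, 40),
               y_um = runif(n_nuclei, 0, 40),
               ch_norm = runif(n_nuclei))
  }))
}
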