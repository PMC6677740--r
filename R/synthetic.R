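# Seeded generators for all pipeline inputs: synthetic imaging fields of
# segmented nuclei with the statistical structure of the study's
# confocal data, and planted state fields for stripe-detection tests.

#' Specification of a synthetic nucleus field
#'
#' Describes one or more synthetic "images" of segmented nuclei around a
#' horizontal proneural stripe, emulating the structure of the
#' quantified confocal data: a proneural (Ac-like) channel peaking at
#' the stripe center, an early-onset reporter (m3-like) peaking on the
#' stripe flanks with a central dip, and a late-onset reporter (m7-like)
#' forming a broad central bump that is switched off in SOPs.  Each
#' image gets its own multiplicative lognormal gain per channel (the
#' per-image scaling that normalization must remove) and additive
#' Gaussian noise.
#'
#' @param width_um,height_um image dimensions (micrometers).
#' @param n_nuclei nuclei per image.
#' @param min_spacing hard-core minimum distance between nucleus
#'   centers.
#' @param stripe_center_y,stripe_width stripe midline and Gaussian width
#'   of the proneural channel.
#' @param flank_offset,flank_width offset and width of the two m3-like
#'   flank peaks.
#' @param late_width width of the broad m7-like central bump.
#' @param sop_spacing,sop_jitter spacing (and uniform jitter) of SOP
#'   sites along the stripe midline; the nucleus nearest each site
#'   (within `min_spacing`) is the SOP.
#' @param gain_sdlog sdlog of the per-image, per-channel lognormal gain.
#' @param noise_sd additive Gaussian noise on raw intensities (clipped
#'   at zero).
#' @param n_images number of images.
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width_um = 80, height_um = 60, n_nuclei = 400,
                       min_spacing = 2.5, stripe_center_y = 30,
                       stripe_width = 4, flank_offset = 7,
                       flank_width = 3, late_width = 5,
                       sop_spacing = 8, sop_jitter = 1,
                       gain_sdlog = 0.3, noise_sd = 0.05,
                       n_images = 5L, seed = 1L) {
  if (width_um <= 0 || height_um <= 0) stop("image dimensions must be positive")
  if (n_nuclei < 1) stop("`n_nuclei` must be >= 1")
  if (min_spacing <= 0) stop("`min_spacing` must be positive")
  if (stripe_width <= 0 || flank_width <= 0 || late_width <= 0)
    stop("channel widths must be positive")
  if (noise_sd < 0 || gain_sdlog < 0)
    stop("noise amplitudes must be nonnegative")
  structure(list(width_um = width_um, height_um = height_um,
                 n_nuclei = as.integer(n_nuclei),
                 min_spacing = min_spacing,
                 stripe_center_y = stripe_center_y,
                 stripe_width = stripe_width,
                 flank_offset = flank_offset, flank_width = flank_width,
                 late_width = late_width, sop_spacing = sop_spacing,
                 sop_jitter = sop_jitter, gain_sdlog = gain_sdlog,
                 noise_sd = noise_sd, n_images = as.integer(n_images),
                 seed = as.integer(seed)),
            class = "field_spec")
}

# spatial mean of each channel as a function of the signed distance d to
# the stripe midline; SOP nuclei switch the late channel off
channel_means <- function(d, is_sop, spec) {
  ac <- exp(-d^2 / (2 * spec$stripe_width^2))
  m3 <- exp(-(d - spec$flank_offset)^2 / (2 * spec$flank_width^2)) +
        exp(-(d + spec$flank_offset)^2 / (2 * spec$flank_width^2))
  m7 <- exp(-d^2 / (2 * spec$late_width^2)) * (1 - as.numeric(is_sop))
  cbind(ac = ac, m3 = m3, m7 = m7)
}

#' Generate a synthetic field of segmented nuclei
#'
#' Places nuclei by a seeded hard-core (dart-throwing) point process,
#' marks SOP nuclei along the stripe midline, and sets each raw channel
#' intensity to `gain * spatial_mean + noise`, clipped at zero.  The
#' output uses the same CSV dialect the profiling pipeline consumes.
#'
#' @param spec a [field_spec()].
#' @return A data frame with columns `image_id`, `nucleus_id`, `x_um`,
#'   `y_um`, `is_sop`, and raw channels `ac`, `m3`, `m7`; one block of
#'   rows per image.
#' @export
generate_nucleus_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  out <- vector("list", spec$n_images)
  for (img in seq_len(spec$n_images)) {
    pos <- hard_core_points(spec$n_nuclei, spec$width_um, spec$height_um,
                            spec$min_spacing)
    # SOP sites: regular spacing along the midline plus jitter
    sx <- seq(spec$sop_spacing / 2, spec$width_um - spec$sop_spacing / 4,
              by = spec$sop_spacing)
    sx <- sx + runif(length(sx), -spec$sop_jitter, spec$sop_jitter)
    is_sop <- rep(FALSE, nrow(pos))
    for (s in sx) {
      d2 <- (pos[, 1] - s)^2 + (pos[, 2] - spec$stripe_center_y)^2
      j <- which.min(d2)
      if (d2[j] <= spec$min_spacing^2) is_sop[j] <- TRUE
    }
    d <- pos[, 2] - spec$stripe_center_y
    mu <- channel_means(d, is_sop, spec)
    gains <- rlnorm(ncol(mu), meanlog = 0, sdlog = spec$gain_sdlog)
    raw <- sweep(mu, 2, gains, "*") +
      matrix(rnorm(length(mu), sd = spec$noise_sd), nrow(mu), ncol(mu))
    raw <- pmax(raw, 0)
    out[[img]] <- data.frame(image_id = paste0("img", img),
                             nucleus_id = seq_len(nrow(pos)),
                             x_um = pos[, 1], y_um = pos[, 2],
                             is_sop = is_sop,
                             ac = raw[, "ac"], m3 = raw[, "m3"],
                             m7 = raw[, "m7"])
  }
  do.call(rbind, out)
}

# Sequential dart throwing with rejection; errors out when the requested
# density is infeasible under the hard-core constraint.
hard_core_points <- function(n, W, H, min_spacing, max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(runif(1, 0, W), runif(1, 0, H))
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - cand[1])^2 +
          (pts[seq_len(placed), 2] - cand[2])^2) >= min_spacing^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries >= max_tries * n)
        stop("cannot place ", n, " nuclei at minimum spacing ",
             min_spacing, " in a ", W, " x ", H,
             " image; reduce the density or the spacing")
    }
  }
  pts
}

#' Centerline of a synthetic field
#'
#' The horizontal midline the generator used, as a [centerline()]
#' (oriented in +x, so nuclei above the stripe get positive distances).
#'
#' @param spec a [field_spec()].
#' @return A `centerline`.
#' @export
synthetic_centerline <- function(spec) {
  centerline(rbind(c(0, spec$stripe_center_y),
                   c(spec$width_um, spec$stripe_center_y)))
}

#' Plant a stripe pattern into a state field
#'
#' Ground-truth generator for stripe-detection tests: the state is
#' `high` for cells whose periodic x position falls inside any stripe
#' window and `low` elsewhere.
#'
#' @param lattice a `cell_lattice`.
#' @param centers stripe center x positions.
#' @param widths full stripe widths (recycled against `centers`).
#' @param high,low state values (`high > low`).
#' @return Per-cell state vector.
#' @export
planted_stripe_field <- function(lattice, centers, widths, high = 1,
                                 low = 0) {
  if (high <= low) stop("`high` must exceed `low`")
  u <- rep(low, nrow(lattice$positions))
  if (length(centers) == 0L) return(u)
  widths <- rep_len(widths, length(centers))
  x <- lattice$positions[, 1]
  W <- lattice$box_width
  for (k in seq_along(centers)) {
    dx <- x - centers[k]
    dx <- abs(dx - W * round(dx / W))
    u[dx <= widths[k] / 2] <- high
  }
  u
}
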