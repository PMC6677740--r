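# Disordered periodic cell lattices and distance-decaying signalling kernels.
#
# The tissue is a fixed arrangement of cell centers on a 2-D torus
# (periodic box).  Geometry is static: only positions, tessellation areas
# and the Delaunay neighbour relation enter the dynamics.

#' Construct a disordered periodic cell lattice
#'
#' Generates `n_cells` cell-center positions in a periodic box of size
#' `box_width` x `box_height` (units: mean cell diameters).  A commensurate
#' hexagonal packing is jittered by `disorder` and then relaxed towards a
#' centroidal Voronoi tessellation by `n_lloyd` Lloyd iterations on the
#' torus, which restores near-uniform cell areas while keeping a disordered
#' neighbour topology.  `disorder = 0` returns the regular hexagonal
#' packing unchanged (and requires the box to be commensurate with one).
#'
#' @param n_cells number of cells (>= 1).
#' @param box_width,box_height box dimensions in cell diameters.
#' @param disorder jitter amplitude in `[0, 1]`, as a fraction of the mean
#'   cell spacing.
#' @param seed integer seed; identical inputs and seed give identical
#'   lattices.
#' @param n_lloyd number of Lloyd (centroidal Voronoi) relaxation steps
#'   applied after jittering when `disorder > 0`.
#' @return An object of class `cell_lattice`: a list with `positions`
#'   (n x 2 matrix), `box_width`, `box_height`, `areas` (Voronoi cell
#'   areas, summing to the box area), `neighbor_pairs` (m x 2 integer
#'   matrix of periodic Delaunay edges, `i < j`), `seed` and `disorder`.
#' @examples
#' lat <- build_disordered_lattice(64, 8, 8, disorder = 0.3, seed = 1)
#' sum(lat$areas)            # equals the box area
#' mean(table(lat$neighbor_pairs))  # mean degree 6 on the torus
#' @export
build_disordered_lattice <- function(n_cells, box_width, box_height,
                                     disorder = 0.3, seed = 1L,
                                     n_lloyd = 20L) {
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1 ||
      n_cells != round(n_cells))
    stop("`n_cells` must be a positive integer")
  if (box_width <= 0 || box_height <= 0)
    stop("box dimensions must be positive")
  if (disorder < 0 || disorder > 1)
    stop("`disorder` must lie in [0, 1]")
  n_cells <- as.integer(n_cells)

  if (n_cells == 1L) {
    lat <- structure(list(
      positions = matrix(c(box_width / 2, box_height / 2), 1, 2,
                         dimnames = list(NULL, c("x", "y"))),
      box_width = box_width, box_height = box_height,
      areas = box_width * box_height,
      neighbor_pairs = matrix(integer(0), 0, 2),
      seed = as.integer(seed), disorder = disorder),
      class = "cell_lattice")
    return(lat)
  }

  set.seed(as.integer(seed))
  hex <- hex_packing(n_cells, box_width, box_height)
  if (is.null(hex)) {
    if (disorder == 0)
      stop("box is not commensurate with a regular hexagonal packing of ",
           n_cells, " cells; use disorder > 0 or adjust the box")
    # no divisor pair gives a sane aspect ratio: start from random points
    pos <- cbind(runif(n_cells, 0, box_width),
                 runif(n_cells, 0, box_height))
  } else {
    pos <- hex
    if (disorder > 0) {
      spacing <- sqrt(box_width * box_height / n_cells)
      pos <- pos + matrix(rnorm(2 * n_cells, sd = 0.5 * disorder * spacing),
                          n_cells, 2)
      pos <- wrap_box(pos, box_width, box_height)
    }
  }

  if (disorder > 0 || is.null(hex)) {
    for (k in seq_len(n_lloyd)) {
      tess <- periodic_tessellation(pos, box_width, box_height,
                                    centroids = TRUE)
      pos <- wrap_box(tess$centroids, box_width, box_height)
    }
  }

  tess <- periodic_tessellation(pos, box_width, box_height)
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos,
                 box_width = box_width, box_height = box_height,
                 areas = tess$areas,
                 neighbor_pairs = tess$neighbor_pairs,
                 seed = as.integer(seed), disorder = disorder),
            class = "cell_lattice")
}

#' Build a lattice from explicit cell positions
#'
#' Fixes cell centers at user-given positions inside a periodic box and
#' computes the periodic Voronoi areas and Delaunay neighbour pairs.
#' Useful for hand-constructed geometries such as a hexagonal rosette.
#'
#' @param positions n x 2 matrix of positions inside the box.
#' @param box_width,box_height box dimensions.
#' @return A `cell_lattice` (see [build_disordered_lattice()]).
#' @export
lattice_from_positions <- function(positions, box_width, box_height) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("`positions` must be an n x 2 matrix")
  if (box_width <= 0 || box_height <= 0)
    stop("box dimensions must be positive")
  pos <- wrap_box(positions, box_width, box_height)
  colnames(pos) <- c("x", "y")
  if (nrow(pos) == 1L) {
    return(structure(list(positions = pos, box_width = box_width,
                          box_height = box_height,
                          areas = box_width * box_height,
                          neighbor_pairs = matrix(integer(0), 0, 2),
                          seed = NA_integer_, disorder = NA_real_),
                     class = "cell_lattice"))
  }
  tess <- periodic_tessellation(pos, box_width, box_height)
  structure(list(positions = pos, box_width = box_width,
                 box_height = box_height, areas = tess$areas,
                 neighbor_pairs = tess$neighbor_pairs,
                 seed = NA_integer_, disorder = NA_real_),
            class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat("cell_lattice:", nrow(x$positions), "cells in a",
      x$box_width, "x", x$box_height, "periodic box\n")
  cat("  mean Delaunay degree:",
      format(2 * nrow(x$neighbor_pairs) / nrow(x$positions), digits = 4),
      " mean area:", format(mean(x$areas), digits = 4), "\n")
  invisible(x)
}

#' Minimum-image periodic distance between two cells
#'
#' @param lattice a `cell_lattice`.
#' @param i,j cell indices.
#' @return The torus (minimum-image) distance, a nonnegative length never
#'   exceeding half the box diagonal.
#' @export
periodic_distance <- function(lattice, i, j) {
  n <- nrow(lattice$positions)
  if (any(c(i, j) < 1) || any(c(i, j) > n) ||
      any(c(i, j) != round(c(i, j))))
    stop("cell index out of range")
  dx <- lattice$positions[i, 1] - lattice$positions[j, 1]
  dy <- lattice$positions[i, 2] - lattice$positions[j, 2]
  dx <- dx - lattice$box_width * round(dx / lattice$box_width)
  dy <- dy - lattice$box_height * round(dy / lattice$box_height)
  unname(sqrt(dx^2 + dy^2))
}

#' Distance-decaying signalling kernel on a lattice
#'
#' Builds the symmetric coupling matrix `w[i, j] = strength *
#' exp(-d_ij^2 / (2 * signaling_range^2))` with `d_ij` the minimum-image
#' periodic distance, truncated to zero beyond
#' `cutoff_factor * signaling_range`, and with zero diagonal (a cell does
#' not signal to itself).  With `normalized = TRUE` each row is rescaled
#' to sum to `strength` (note that row scaling gives up exact symmetry on
#' disordered lattices).
#'
#' @param lattice a `cell_lattice`.
#' @param signaling_range Gaussian decay length of the kernel, in cell
#'   diameters (> 0).
#' @param strength overall coupling strength `a >= 0`.
#' @param cutoff_factor truncation radius in units of `signaling_range`
#'   (>= 1).
#' @param normalized rescale every row to sum to `strength`?
#' @return An object of class `coupling_matrix`: list with sparse
#'   `weights` ([Matrix::sparseMatrix]), `signaling_range`,
#'   `cutoff_radius`, `strength`, `normalized`.
#' @export
compute_coupling <- function(lattice, signaling_range, strength = 1,
                             cutoff_factor = 3, normalized = FALSE) {
  if (signaling_range <= 0) stop("`signaling_range` must be positive")
  if (cutoff_factor < 1) stop("`cutoff_factor` must be >= 1")
  if (strength < 0) stop("`strength` must be nonnegative")
  n <- nrow(lattice$positions)
  d <- periodic_distance_matrix(lattice$positions,
                                lattice$box_width, lattice$box_height)
  cutoff <- cutoff_factor * signaling_range
  w <- strength * exp(-d^2 / (2 * signaling_range^2))
  w[d > cutoff] <- 0
  diag(w) <- 0
  if (normalized) {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] * (strength / rs[nz])
  }
  structure(list(weights = Matrix::Matrix(w, sparse = TRUE),
                 signaling_range = signaling_range,
                 cutoff_radius = cutoff,
                 strength = strength,
                 normalized = normalized),
            class = "coupling_matrix")
}

#' Serialize a lattice to JSON
#'
#' Writes positions, box dimensions, areas, neighbour pairs and the
#' generation seed to a JSON file that [read_lattice_json()] restores
#' exactly.
#'
#' @param lattice a `cell_lattice`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lattice_json <- function(lattice, path) {
  obj <- list(positions = unclass(lattice$positions),
              box_width = lattice$box_width,
              box_height = lattice$box_height,
              areas = lattice$areas,
              neighbor_pairs = unclass(lattice$neighbor_pairs),
              seed = lattice$seed, disorder = lattice$disorder)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lattice written by [write_lattice_json()]
#' @param path JSON file path.
#' @return A `cell_lattice`.
#' @export
read_lattice_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- matrix(as.numeric(obj$positions), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  np <- matrix(as.integer(obj$neighbor_pairs), ncol = 2)
  structure(list(positions = pos, box_width = obj$box_width,
                 box_height = obj$box_height, areas = as.numeric(obj$areas),
                 neighbor_pairs = np,
                 seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
                 disorder = if (is.null(obj$disorder)) NA_real_
                            else obj$disorder),
            class = "cell_lattice")
}

# ---- internal helpers -------------------------------------------------

wrap_box <- function(pos, W, H) {
  pos[, 1] <- pos[, 1] %% W
  pos[, 2] <- pos[, 2] %% H
  pos
}

# All-pairs minimum-image distances (dense; lattices here are <= a few
# thousand cells).
periodic_distance_matrix <- function(pos, W, H) {
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dx <- dx - W * round(dx / W)
  dy <- dy - H * round(dy / H)
  sqrt(dx^2 + dy^2)
}

# Commensurate hexagonal packing: n = nx * ny with alternate rows offset
# by half a column spacing.  Returns NULL when no divisor pair gives a
# near-hexagonal aspect ratio (row/column spacing within a factor 2 of
# the ideal 2/sqrt(3)).
hex_packing <- function(n, W, H) {
  divs <- which(n %% seq_len(n) == 0)
  best <- NULL; best_score <- Inf
  for (ny in divs) {
    nx <- n %/% ny
    dx <- W / nx; dy <- H / ny
    score <- abs(log((dx / dy) / (2 / sqrt(3))))
    if (ny %% 2 == 1 && ny > 1) score <- score + 0.05  # seam penalty
    if (score < best_score) { best_score <- score; best <- c(nx, ny) }
  }
  if (is.null(best) || best_score > log(2)) return(NULL)
  nx <- best[1]; ny <- best[2]
  dx <- W / nx; dy <- H / ny
  j <- rep(seq_len(ny) - 1L, each = nx)
  i <- rep(seq_len(nx) - 1L, times = ny)
  cbind(x = (i + 0.25 + 0.5 * (j %% 2)) * dx,
        y = (j + 0.5) * dy)
}

# Periodic Voronoi/Delaunay through deldir on a tiled copy of the points.
# A margin band of periodic images (or the full 3x3 tiling for small
# boxes) surrounds the central copy so that the central cells'
# tessellation is that of the torus.
periodic_tessellation <- function(pos, W, H, centroids = FALSE) {
  n <- nrow(pos)
  spacing <- sqrt(W * H / n)
  margin <- 5 * spacing
  full <- (2 * margin >= min(W, H))

  shifts <- expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1))
  tiles <- lapply(seq_len(nrow(shifts)), function(k) {
    sx <- shifts$sx[k]; sy <- shifts$sy[k]
    p <- cbind(pos[, 1] + sx * W, pos[, 2] + sy * H)
    if (sx == 0 && sy == 0) {
      keep <- seq_len(n)
    } else if (full) {
      keep <- seq_len(n)
    } else {
      keep <- which(p[, 1] > -margin & p[, 1] < W + margin &
                    p[, 2] > -margin & p[, 2] < H + margin)
    }
    cbind(p[keep, , drop = FALSE], orig = keep,
          central = as.numeric(sx == 0 && sy == 0))
  })
  tiled <- do.call(rbind, tiles)
  # central copy occupies rows 1..n after reordering
  ord <- order(-tiled[, "central"])
  tiled <- tiled[ord, , drop = FALSE]

  rw <- c(range(tiled[, 1]) + c(-1, 1) * spacing,
          range(tiled[, 2]) + c(-1, 1) * spacing)
  dd <- deldir::deldir(tiled[, 1], tiled[, 2], rw = rw,
                       round = FALSE, suppressMsge = TRUE)

  e1 <- dd$delsgs$ind1; e2 <- dd$delsgs$ind2
  touches_central <- e1 <= n | e2 <= n
  o1 <- tiled[e1[touches_central], "orig"]
  o2 <- tiled[e2[touches_central], "orig"]
  keep <- o1 != o2
  pairs <- cbind(pmin(o1[keep], o2[keep]), pmax(o1[keep], o2[keep]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  storage.mode(pairs) <- "integer"

  # Voronoi areas and centroids of the central cells via a triangle fan
  # from each cell point over its tile's boundary segments (tiles are
  # star-shaped around their generating point, so no ordering is needed).
  ds <- dd$dirsgs
  idx <- c(ds$ind1, ds$ind2)
  x1 <- rep(ds$x1, 2); y1 <- rep(ds$y1, 2)
  x2 <- rep(ds$x2, 2); y2 <- rep(ds$y2, 2)
  sel <- idx <= n
  idx <- idx[sel]
  px <- tiled[idx, 1]; py <- tiled[idx, 2]
  ax <- x1[sel] - px; ay <- y1[sel] - py
  bx <- x2[sel] - px; by <- y2[sel] - py
  tri_a <- abs(ax * by - ay * bx) / 2
  areas <- as.numeric(tapply(tri_a, factor(idx, levels = seq_len(n)), sum))
  out <- list(neighbor_pairs = pairs, areas = areas)
  if (centroids) {
    # triangle centroid = (p + v1 + v2) / 3, area-weighted
    f <- factor(idx, levels = seq_len(n))
    cx <- as.numeric(tapply(tri_a * (px + x1[sel] + x2[sel]) / 3, f, sum))
    cy <- as.numeric(tapply(tri_a * (py + y1[sel] + y2[sel]) / 3, f, sum))
    out$centroids <- cbind(cx / areas, cy / areas)
  }
  out
}
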