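# Quantification of nuclear reporter intensities relative to a stripe
# centerline: per-image normalization, detection thresholding, signed
# distances to an annotated polyline, and binned expression profiles
# with across-image mean +/- SEM.

#' Construct a stripe centerline
#'
#' A polyline (in micrometers) tracing the center of a proneural stripe,
#' used as the distance reference for expression profiles.  The sign
#' convention for lateral offsets is the left-hand side of the polyline
#' direction; for a centerline drawn in the +x direction, nuclei on the
#' +y side get positive distances.
#'
#' @param vertices n x 2 numeric matrix of polyline vertices (>= 2 rows;
#'   consecutive vertices must be distinct).
#' @return An object of class `centerline`.
#' @export
centerline <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("a centerline needs at least 2 two-dimensional vertices")
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive centerline vertices must be distinct")
  structure(list(vertices = vertices), class = "centerline")
}

#' Per-image normalization of reporter intensities
#'
#' Rescales each channel of one image so its maximal level is of order
#' one: divides raw intensities by the per-image channel maximum
#' (`mode = "max"`) or by the channel's 99th percentile
#' (`mode = "percentile"`, robust to bright outliers).  Channels that
#' are zero everywhere in an image are left unnormalized and flagged.
#'
#' @param records data frame of segmented nuclei with columns
#'   `image_id`, `nucleus_id`, `x_um`, `y_um` and one nonnegative raw
#'   intensity column per channel.  May contain several images;
#'   normalization is always per image.
#' @param channels character vector of channel column names.
#' @param mode `"percentile"` (default) or `"max"`.
#' @return `records` with added columns `<channel>_norm`, plus an
#'   attribute `failed_channels` (data frame image_id/channel) listing
#'   any all-zero channels.
#' @export
normalize_image <- function(records, channels,
                            mode = c("percentile", "max")) {
  mode <- match.arg(mode)
  if (nrow(records) < 1L) stop("no nucleus records")
  missing <- setdiff(channels, names(records))
  if (length(missing))
    stop("missing channel column: ", paste(missing, collapse = ", "))
  if (any(vapply(channels,
                 function(ch) any(records[[ch]] < 0), logical(1))))
    stop("raw intensities must be nonnegative")
  failed <- NULL
  for (ch in channels) records[[paste0(ch, "_norm")]] <- NA_real_
  for (img in unique(records$image_id)) {
    rows <- records$image_id == img
    for (ch in channels) {
      v <- records[[ch]][rows]
      scale <- if (mode == "max") max(v) else
        quantile(v, 0.99, names = FALSE, type = 7)
      if (scale <= 0) {
        failed <- rbind(failed,
                        data.frame(image_id = img, channel = ch))
        next
      }
      records[[paste0(ch, "_norm")]][rows] <- v / scale
    }
  }
  attr(records, "failed_channels") <- failed
  records
}

#' Flag nuclei with detectable reporter expression
#'
#' A nucleus exhibits detectable expression of a reporter when its
#' normalized level strictly exceeds the detection threshold (default
#' 0.2).
#'
#' @param records data frame with `<channel>_norm` columns (see
#'   [normalize_image()]).
#' @param channels channel names.
#' @param threshold detection threshold on the normalized scale.
#' @return `records` with added logical columns `<channel>_detect`.
#' @export
flag_detectable <- function(records, channels, threshold = 0.2) {
  for (ch in channels) {
    nc <- paste0(ch, "_norm")
    if (is.null(records[[nc]]))
      stop("channel '", ch, "' has not been normalized")
    records[[paste0(ch, "_detect")]] <-
      !is.na(records[[nc]]) & records[[nc]] > threshold
  }
  records
}

#' Signed distance from nuclei to a centerline
#'
#' Perpendicular distance from each point to the nearest segment of the
#' polyline; the magnitude equals the Euclidean point-to-polyline
#' distance and the sign follows the centerline's orientation convention
#' (left of the walking direction is positive).
#'
#' @param x,y point coordinates (micrometers).
#' @param line a [centerline()].
#' @return Numeric vector of signed distances.
#' @export
signed_distance <- function(x, y, line) {
  v <- line$vertices
  n_seg <- nrow(v) - 1L
  d_best <- rep(Inf, length(x))
  s_best <- rep(1, length(x))
  for (k in seq_len(n_seg)) {
    a <- v[k, ]; b <- v[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- sqrt((x - px)^2 + (y - py)^2)
    cross <- ab[1] * (y - a[2]) - ab[2] * (x - a[1])
    upd <- d < d_best
    d_best[upd] <- d[upd]
    s_best[upd] <- ifelse(cross[upd] >= 0, 1, -1)
  }
  s_best * d_best
}

#' Binned expression profile relative to a stripe centerline
#'
#' For each image, nuclei are binned by signed distance to that image's
#' centerline over the symmetric range `[-range_um, range_um]`
#' (left-closed bins of width `bin_width`).  Two per-bin statistics are
#' available: `"sum_minus_threshold"` (default) sums, over detectable
#' nuclei, the normalized intensity minus the detection threshold;
#' `"mean_intensity"` averages the normalized intensity of detectable
#' nuclei.  The profile reports the across-image mean and standard error
#' per bin.  An image with no detectable nuclei contributes an all-zero
#' profile, not a missing one.
#'
#' @param records nucleus data frame (several images allowed).  If
#'   `<channel>_norm` columns are absent, [normalize_image()] is applied
#'   first with `norm_mode`.
#' @param lines a single [centerline()] used for every image, or a named
#'   list mapping each `image_id` to its centerline.
#' @param channel channel name to profile.
#' @param bin_width bin width in micrometers.
#' @param range_um half-range of the profile.
#' @param threshold detection threshold.
#' @param statistic `"sum_minus_threshold"` or `"mean_intensity"`.
#' @param norm_mode normalization mode if normalization is still needed.
#' @return An object of class `expression_profile`: a data frame with
#'   `bin_center`, `mean`, `sem` and `n_images`, with the per-image bin
#'   matrix and the settings as attributes.  `sem` is `NA` when fewer
#'   than 2 images are available.
#' @export
compute_profile <- function(records, lines, channel, bin_width = 2,
                            range_um = 20, threshold = 0.2,
                            statistic = c("sum_minus_threshold",
                                          "mean_intensity"),
                            norm_mode = "percentile") {
  statistic <- match.arg(statistic)
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (nrow(records) < 1L) stop("no nucleus records")
  nc <- paste0(channel, "_norm")
  if (is.null(records[[nc]]))
    records <- normalize_image(records, channel, mode = norm_mode)
  dc <- paste0(channel, "_detect")
  if (is.null(records[[dc]]))
    records <- flag_detectable(records, channel, threshold)

  edges <- seq(-range_um, range_um, by = bin_width)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  images <- unique(records$image_id)
  per_image <- matrix(0, length(images), length(centers),
                      dimnames = list(as.character(images), NULL))
  for (ii in seq_along(images)) {
    rows <- records[records$image_id == images[ii], , drop = FALSE]
    line <- if (inherits(lines, "centerline")) lines
            else lines[[as.character(images[ii])]]
    if (is.null(line))
      stop("no centerline supplied for image '", images[ii], "'")
    d <- signed_distance(rows$x_um, rows$y_um, line)
    det <- rows[[dc]]
    bin <- findInterval(d, edges)           # 0 or length(edges) = outside
    inside <- det & bin >= 1L & bin <= length(centers) & d < range_um
    if (!any(inside)) next                   # all-zero profile
    f <- factor(bin[inside], levels = seq_along(centers))
    if (statistic == "sum_minus_threshold") {
      vals <- tapply(rows[[nc]][inside] - threshold, f, sum)
      vals[is.na(vals)] <- 0
    } else {
      vals <- tapply(rows[[nc]][inside], f, mean)
      vals[is.na(vals)] <- 0
    }
    per_image[ii, ] <- as.numeric(vals)
  }
  n <- length(images)
  out <- data.frame(
    bin_center = centers,
    mean = colMeans(per_image),
    sem = if (n >= 2L) apply(per_image, 2, sd) / sqrt(n)
          else NA_real_,
    n_images = n)
  structure(out, class = c("expression_profile", "data.frame"),
            per_image = per_image, channel = channel,
            bin_width = bin_width, range_um = range_um,
            threshold = threshold, statistic = statistic)
}

#' Read a nuclei table from CSV
#'
#' Expects the dialect written by [write_nuclei_csv()]: comma-separated,
#' header row, columns `image_id`, `nucleus_id`, `x_um`, `y_um` and one
#' column per channel.
#'
#' @param path CSV path.
#' @param channels channel columns that must be present (optional).
#' @return A data frame of nucleus records.
#' @export
read_nuclei_csv <- function(path, channels = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image_id", "nucleus_id", "x_um", "y_um", channels)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("nuclei CSV lacks required column(s): ",
         paste(missing, collapse = ", "))
  xn <- suppressWarnings(as.numeric(df$x_um))
  yn <- suppressWarnings(as.numeric(df$y_um))
  bad <- which(is.na(xn) | is.na(yn))
  if (length(bad))
    stop("malformed nuclei CSV: non-numeric position at data row ",
         bad[1])
  df$x_um <- xn
  df$y_um <- yn
  df
}

#' Write a nuclei table to CSV
#' @param records nucleus data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nuclei_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write an expression profile to CSV
#'
#' Columns: `bin_center_um`, `mean`, `sem`, `n`.
#'
#' @param profile an `expression_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(bin_center_um = profile$bin_center,
                   mean = profile$mean, sem = profile$sem,
                   n = profile$n_images)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
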