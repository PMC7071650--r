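# Image containers, TIFF I/O, line profiles and masks shared by all
# measurement stages.
#
# Conventions used throughout the package:
#   * pixel coordinates are (x, y), 0-based, with pixel centers at integers;
#     pixel (x, y) lives at matrix element [y + 1, x + 1] (row = y, col = x);
#   * intensities are photon/ADU counts, stored as doubles;
#   * lines are sampled half-open, [p0, p1).

#' Construct a single-channel image
#'
#' The universal 2D carrier between pipeline stages: a non-negative pixel
#' matrix plus channel label, nominal bit depth and pixel size.
#'
#' @param pixels numeric matrix of counts (rows = y, columns = x). Must be
#'   finite, non-negative and at least 8x8.
#' @param channel character label, e.g. `"reporter"`, `"marker"`, `"er"`.
#' @param bit_depth nominal camera bit depth, 8 or 16. Controls TIFF scaling.
#' @param pixel_size physical pixel size in micrometres (metadata only).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = "gfp", bit_depth = 16,
                          pixel_size = 0.1) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("channel_image: pixel values must be finite")
  if (any(pixels < 0))
    stop("channel_image: pixel values must be non-negative")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("channel_image: image must be at least 8x8 pixels")
  if (!bit_depth %in% c(8L, 16L))
    stop("channel_image: bit_depth must be 8 or 16")
  structure(
    list(pixels = pixels, channel = as.character(channel)[1],
         bit_depth = as.integer(bit_depth), pixel_size = pixel_size),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> '%s': %d x %d px, %d-bit, %.3g um/px\n",
              x$channel, ncol(x$pixels), nrow(x$pixels),
              x$bit_depth, x$pixel_size))
  cat(sprintf("  counts: min %.4g, mean %.4g, max %.4g\n",
              min(x$pixels), mean(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Construct a time-lapse stack
#'
#' @param frames 3D numeric array (y, x, t) of counts, or a list of equally
#'   sized matrices/`channel_image`s in frame order.
#' @param timestamps numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame. Defaults to 0, 1, 2, ... s.
#' @param bleach_frame 1-based index of the first post-bleach frame, or `NULL`
#'   for stacks without a photobleaching event.
#' @param channel,bit_depth,pixel_size as in [channel_image()].
#' @return an object of class `time_series_stack` with elements `frames`
#'   (3D array), `timestamps` and `bleach_frame`.
#' @export
time_series_stack <- function(frames, timestamps = NULL, bleach_frame = NULL,
                              channel = "gfp", bit_depth = 16,
                              pixel_size = 0.1) {
  if (is.list(frames)) {
    mats <- lapply(frames, function(f) if (inherits(f, "channel_image")) f$pixels else as.matrix(f))
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1L) stop("time_series_stack: all frames must have the same shape")
    frames <- array(unlist(mats), dim = c(dims[[1]], length(mats)))
  }
  if (length(dim(frames)) != 3L)
    stop("time_series_stack: frames must be a (y, x, t) array or list of matrices")
  nt <- dim(frames)[3]
  if (is.null(timestamps)) timestamps <- seq_len(nt) - 1
  if (length(timestamps) != nt)
    stop("time_series_stack: one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("time_series_stack: timestamps must be strictly increasing")
  if (!is.null(bleach_frame)) {
    bleach_frame <- as.integer(bleach_frame)
    if (bleach_frame < 2L || bleach_frame > nt)
      stop("time_series_stack: bleach_frame must lie within the stack (>= 2)")
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         bleach_frame = bleach_frame, channel = channel,
         bit_depth = as.integer(bit_depth), pixel_size = pixel_size),
    class = "time_series_stack")
}

#' @export
print.time_series_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<time_series_stack> '%s': %d x %d px, %d frames (%.3g-%.3g s)%s\n",
              x$channel, d[2], d[1], d[3], min(x$timestamps), max(x$timestamps),
              if (is.null(x$bleach_frame)) ""
              else sprintf(", bleach at frame %d", x$bleach_frame)))
  invisible(x)
}

#' @export
length.time_series_stack <- function(x) dim(x$frames)[3]

# ---------------------------------------------------------------------------
# TIFF I/O

.tiff_scale <- function(bit_depth) 2^bit_depth - 1

#' Write an image or stack to TIFF
#'
#' Grayscale 8/16-bit TIFF; stacks become multi-page files in frame order.
#' Counts are stored losslessly for integer values in `[0, 2^bit_depth - 1]`.
#'
#' @param x a [channel_image] or [time_series_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path) {
  if (inherits(x, "channel_image")) {
    pages <- list(x$pixels)
    bd <- x$bit_depth
  } else if (inherits(x, "time_series_stack")) {
    pages <- lapply(seq_len(dim(x$frames)[3]), function(i) x$frames[, , i])
    bd <- x$bit_depth
  } else stop("write_tiff: x must be a channel_image or time_series_stack")
  sc <- .tiff_scale(bd)
  if (any(vapply(pages, max, 0) > sc))
    stop(sprintf("write_tiff: counts exceed %d-bit range", bd))
  pages <- lapply(pages, function(p) p / sc)
  tiff::writeTIFF(if (length(pages) == 1L) pages[[1]] else pages,
                  path, bits.per.sample = bd, compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF image or multi-page stack
#'
#' Single-page files return a [channel_image]; multi-page files return a
#' [time_series_stack] in page order (timestamps default to the frame index;
#' supply real timestamps separately). Pixel values are recovered bit-exactly
#' for integer counts. RGB/multi-sample TIFFs are rejected.
#'
#' @param path file path.
#' @param channel channel label to attach.
#' @param pixel_size pixel size metadata in micrometres.
#' @param timestamps optional timestamps (seconds) for multi-page files.
#' @return a [channel_image] or [time_series_stack].
#' @export
read_tiff <- function(path, channel = "gfp", pixel_size = 0.1,
                      timestamps = NULL) {
  if (!file.exists(path)) stop("read_tiff: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE)))
    stop("read_tiff: unsupported format (RGB or multi-sample TIFF); ",
         "grayscale 8/16-bit pages are required")
  bd <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bd)) bd <- 16L
  if (!bd %in% c(8L, 16L))
    stop("read_tiff: unsupported bit depth ", bd,
         " (8- or 16-bit grayscale required)")
  sc <- .tiff_scale(bd)
  mats <- lapply(pages, function(p) {
    m <- round(p * sc)
    attributes(m) <- list(dim = dim(m))    # drop TIFF metadata attributes
    m
  })
  if (length(mats) == 1L)
    channel_image(mats[[1]], channel = channel, bit_depth = bd,
                  pixel_size = pixel_size)
  else
    time_series_stack(mats, timestamps = timestamps, channel = channel,
                      bit_depth = bd, pixel_size = pixel_size)
}

# ---------------------------------------------------------------------------
# Line profiles

.as_pixels <- function(img) {
  if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
}

#' Sample an intensity profile along a line
#'
#' Bilinear interpolation at uniform spacing along the segment from `p0`
#' towards `p1`, sampled half-open: positions `0, spacing, 2*spacing, ...`
#' strictly less than the segment length. Matches the default (1-px wide,
#' bilinear) line-profile behaviour of common image-analysis tools.
#'
#' @param img a [channel_image] or numeric matrix.
#' @param p0,p1 line endpoints, `c(x, y)` in 0-based pixel coordinates; both
#'   must lie inside the image.
#' @param spacing sample spacing in pixels, must be <= 1.
#' @return an object of class `line_profile`: a list with `positions` (px
#'   along the line), `values` (counts) and `endpoints`.
#' @export
sample_line <- function(img, p0, p1, spacing = 0.5) {
  px <- .as_pixels(img)
  H <- nrow(px); W <- ncol(px)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  inside <- function(p) p[1] >= 0 && p[1] <= W - 1 && p[2] >= 0 && p[2] <= H - 1
  if (!inside(p0) || !inside(p1))
    stop("sample_line: endpoints must lie inside the image")
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("sample_line: zero-length line")
  if (spacing <= 0 || spacing > 1)
    stop("sample_line: spacing must be in (0, 1]")
  pos <- seq(0, len - 1e-12, by = spacing)
  ux <- (p1[1] - p0[1]) / len
  uy <- (p1[2] - p0[2]) / len
  x <- p0[1] + pos * ux
  y <- p0[2] + pos * uy
  vals <- .bilinear(px, x, y)
  structure(list(positions = pos, values = vals,
                 endpoints = rbind(p0 = p0, p1 = p1), spacing = spacing),
            class = "line_profile")
}

# vectorized bilinear interpolation at 0-based (x, y)
.bilinear <- function(px, x, y) {
  H <- nrow(px); W <- ncol(px)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  idx <- function(yy, xx) px[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.1f px (spacing %.2g)\n",
              length(x$positions), max(x$positions), x$spacing))
  invisible(x)
}

#' Robust noise standard deviation of a signal
#'
#' Estimated as `1.4826 * MAD(diff(v)) / sqrt(2)`: first differences cancel
#' slowly varying structure, the MAD resists outliers (peaks), and the
#' `sqrt(2)` undoes the variance doubling of differencing.
#'
#' @param v numeric vector or matrix of intensities.
#' @return estimated noise SD in counts.
#' @export
robust_noise_sd <- function(v) {
  v <- as.numeric(v)
  stats::mad(diff(v), constant = 1.4826) / sqrt(2)
}

#' Find peaks in a 1D intensity profile by topographic prominence
#'
#' A peak is an interior local maximum (plateaus count once, reported at the
#' integer-rounded plateau centroid) whose topographic prominence is at least
#' `min_prominence`. The prominence of a peak of height `h` is `h` minus the
#' higher of its two bases, where the base on each side is the minimum of the
#' profile between the peak and the nearest strictly higher sample on that
#' side (or the profile end if none exists). Profile endpoints are never
#' peaks, so a monotone profile yields no peaks.
#'
#' @param profile a `line_profile` from [sample_line()], or a numeric vector.
#' @param min_prominence minimum prominence in counts; default
#'   `3 * robust_noise_sd(values)`.
#' @return data frame with columns `position` (px along the profile, or index
#'   for bare vectors), `index`, `value` and `prominence`, sorted by position.
#' @export
find_profile_peaks <- function(profile, min_prominence = NULL) {
  if (inherits(profile, "line_profile")) {
    v <- profile$values; pos <- profile$positions
  } else {
    v <- as.numeric(profile); pos <- seq_along(v) - 1
  }
  if (length(v) == 0) stop("find_profile_peaks: empty profile")
  if (is.null(min_prominence)) min_prominence <- 3 * robust_noise_sd(v)
  pk <- .profile_peaks(v)
  if (nrow(pk) == 0)
    return(data.frame(position = numeric(0), index = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  keep <- pk$prominence >= min_prominence
  pk <- pk[keep, , drop = FALSE]
  out <- data.frame(position = pos[pk$index], index = pk$index,
                    value = pk$value, prominence = pk$prominence)
  out[order(out$position), , drop = FALSE]
}

# interior local maxima (plateau-aware) with prominences; index is the
# rounded plateau centroid
.profile_peaks <- function(v) {
  n <- length(v)
  if (n < 3)
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  idx <- integer(0); val <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {          # genuine (plateau) maximum
        idx <- c(idx, as.integer(round((i + j) / 2)))
        val <- c(val, v[i])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(seq_along(idx), function(k) {
    p <- idx[k]; h <- val[k]
    left <- if (p > 1L) {
      hi <- which(v[seq_len(p - 1L)] > h)
      lo <- if (length(hi)) max(hi) + 1L else 1L
      min(v[lo:p])
    } else h
    right <- if (p < n) {
      hi <- which(v[(p + 1L):n] > h)
      hi2 <- if (length(hi)) p + min(hi) - 1L else n
      min(v[p:hi2])
    } else h
    h - max(left, right)
  }, 0)
  data.frame(index = idx, value = val, prominence = prom)
}

# ---------------------------------------------------------------------------
# Masks

#' Binary mask of marker-positive pixels
#'
#' Thresholds a membrane/organelle marker channel to define regions of
#' interest, via Otsu's method (default) or a fixed threshold. Pixels strictly
#' above the threshold are in the mask.
#'
#' @param marker a [channel_image] or matrix of the marker channel.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold counts, required for `method = "fixed"`.
#' @return logical matrix of the same shape.
#' @export
pm_mask_from_marker <- function(marker, method = c("otsu", "fixed"),
                                threshold = NULL) {
  method <- match.arg(method)
  px <- .as_pixels(marker)
  rng <- range(px)
  if (method == "otsu") {
    if (rng[1] == rng[2])
      stop("pm_mask_from_marker: degenerate (constant) marker image")
    norm <- (px - rng[1]) / (rng[2] - rng[1])
    thr01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    threshold <- rng[1] + thr01 * (rng[2] - rng[1])
  } else if (is.null(threshold)) {
    stop("pm_mask_from_marker: threshold required for method = 'fixed'")
  }
  px > threshold
}

# binary erosion by a (2r+1) x (2r+1) box, border treated as background
.erode_box <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask))
  out <- EBImage::erode(m, EBImage::makeBrush(2 * r + 1, shape = "box"))
  out > 0.5
}
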