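# Intensity maxima detection, binary ER-association classification,
# thresholded pixel-overlap colocalization and marker-masked ROI means.

#' Find 2D intensity maxima by topographic prominence
#'
#' Reimplements the noise-tolerant maxima criterion of the ImageJ/Fiji "Find
#' Maxima" tool: a pixel `p` is accepted as a maximum iff there is no
#' 8-connected path from `p` to any strictly higher pixel along which the
#' intensity stays above `value(p) - noise_tolerance`. Image borders act as
#' missing neighbours, so edge pixels are eligible maxima. A plateau
#' (connected set of equal-valued accepted pixels) yields a single point at
#' its integer-rounded centroid; a plateau spanning the whole image (a
#' constant image) yields none.
#'
#' @param img a [channel_image] or numeric matrix.
#' @param noise_tolerance minimum topographic drop (counts) separating a
#'   maximum from higher terrain; must be > 0. Default:
#'   `3 * robust_noise_sd(img)`.
#' @return object of class `maxima_set`: list with `points` (data frame `x`,
#'   `y` 0-based, `value`), `noise_tolerance` and `channel`. May be empty.
#' @export
find_maxima <- function(img, noise_tolerance = NULL) {
  px <- .as_pixels(img)
  channel <- if (inherits(img, "channel_image")) img$channel else "image"
  if (is.null(noise_tolerance)) noise_tolerance <- 3 * robust_noise_sd(px)
  if (!is.finite(noise_tolerance) || noise_tolerance <= 0)
    stop("find_maxima: noise_tolerance must be > 0")
  pts <- .find_maxima_mat(px, noise_tolerance)
  structure(list(points = pts, noise_tolerance = noise_tolerance,
                 channel = channel), class = "maxima_set")
}

#' @export
print.maxima_set <- function(x, ...) {
  cat(sprintf("<maxima_set> %d maxima in channel '%s' (noise tolerance %.3g)\n",
              nrow(x$points), x$channel, x$noise_tolerance))
  invisible(x)
}

#' @export
length.maxima_set <- function(x) nrow(x$points)

# core maxima search. Strategy: weak local maxima are the only possible
# accepted pixels; group them into equal-value plateaus, then run one flood
# per plateau over {q : v(q) > v(p) - tol} with early exit on the first
# strictly higher pixel. Floods use preallocated stacks so large plateaus
# (e.g. a flat background) stay linear.
.find_maxima_mat <- function(v, tol) {
  H <- nrow(v); W <- ncol(v)
  n <- H * W
  # 8-neighbours of linear index i (column-major), border = absent
  nb_of <- function(i) {
    y <- (i - 1L) %% H + 1L
    res <- integer(0)
    if (y > 1L) res <- c(res, i - 1L)
    if (y < H) res <- c(res, i + 1L)
    left <- i - H; right <- i + H
    if (left >= 1L) {
      res <- c(res, left)
      if (y > 1L) res <- c(res, left - 1L)
      if (y < H) res <- c(res, left + 1L)
    }
    if (right <= n) {
      res <- c(res, right)
      if (y > 1L) res <- c(res, right - 1L)
      if (y < H) res <- c(res, right + 1L)
    }
    res
  }
  # weak local maxima via shifted comparisons
  ge_shift <- function(dy, dx) {
    out <- matrix(TRUE, H, W)
    ys <- seq_len(H); xs <- seq_len(W)
    sy <- ys + dy; sx <- xs + dx
    vy <- sy >= 1 & sy <= H; vx <- sx >= 1 & sx <= W
    out[ys[vy], xs[vx]] <- v[ys[vy], xs[vx]] >= v[sy[vy], sx[vx]]
    out
  }
  cand <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1)
    if (dy != 0 || dx != 0) cand <- cand & ge_shift(dy, dx)
  cand_idx <- which(cand)
  if (length(cand_idx) == 0L)
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))

  grouped <- logical(n)
  visited <- integer(n)   # flood stamp
  stamp <- 0L
  stack <- integer(n)     # shared preallocated DFS stack
  plat_buf <- integer(n)  # preallocated plateau member buffer
  res_x <- res_y <- res_v <- integer(0)

  for (p in cand_idx) {
    if (grouped[p]) next
    vp <- v[p]
    # flood the equal-value plateau containing p
    np <- 0L
    stack[1L] <- p; top <- 1L; grouped[p] <- TRUE
    has_lower <- FALSE; reject <- FALSE
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      np <- np + 1L; plat_buf[np] <- q
      for (nb in nb_of(q)) {
        if (v[nb] > vp) reject <- TRUE
        else if (v[nb] < vp) has_lower <- TRUE
        else if (!grouped[nb]) {
          grouped[nb] <- TRUE
          top <- top + 1L; stack[top] <- nb
        }
      }
    }
    plat <- plat_buf[seq_len(np)]
    if (reject || !has_lower) next   # adjacent higher terrain / global plateau
    # flood {v > vp - tol} outward from the plateau
    stamp <- stamp + 1L
    visited[plat] <- stamp
    np <- length(plat)
    stack[seq_len(np)] <- plat; top <- np
    accept <- TRUE
    while (top > 0L && accept) {
      q <- stack[top]; top <- top - 1L
      for (nb in nb_of(q)) {
        if (visited[nb] == stamp) next
        if (v[nb] > vp - tol) {
          if (v[nb] > vp) { accept <- FALSE; break }
          visited[nb] <- stamp
          top <- top + 1L; stack[top] <- nb
        }
      }
    }
    if (accept) {
      ys <- (plat - 1L) %% H + 1L; xs <- (plat - 1L) %/% H + 1L
      res_x <- c(res_x, as.integer(round(mean(xs))) - 1L)
      res_y <- c(res_y, as.integer(round(mean(ys))) - 1L)
      res_v <- c(res_v, vp)
    }
  }
  out <- data.frame(x = res_x, y = res_y, value = as.numeric(res_v))
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a binary ER-association threshold from specific and free regions
#'
#' Mirrors the manual two-measurement procedure: the dynamic range of the ER
#' marker inside the ER defines a minimal specific level, the marker level in
#' ER-free regions defines a maximal background, and the binary threshold is
#' placed between them. Percentile endpoints (rather than strict min/max)
#' resist single-pixel outliers.
#'
#' @param er_img ER-marker [channel_image] or matrix.
#' @param er_mask,free_mask logical masks of ER and ER-free pixels; must be
#'   nonempty and disjoint.
#' @param p_specific percentile (of ER-mask intensities) defining the minimal
#'   specific signal, default 0.01.
#' @param p_background percentile (of free-mask intensities) defining the
#'   maximal background, default 0.99.
#' @param factor interpolation factor between `background_max` (0) and
#'   `min_specific` (1); default 0.5, the midpoint.
#' @return list of class `binary_threshold`: `threshold`, `min_specific`,
#'   `background_max`. Errors if the two distributions are not separable
#'   (`min_specific <= background_max`).
#' @export
derive_binary_threshold <- function(er_img, er_mask, free_mask,
                                    p_specific = 0.01, p_background = 0.99,
                                    factor = 0.5) {
  px <- .as_pixels(er_img)
  if (!any(er_mask) || !any(free_mask))
    stop("derive_binary_threshold: both masks must be nonempty")
  if (any(er_mask & free_mask))
    stop("derive_binary_threshold: masks must be disjoint")
  min_specific <- as.numeric(stats::quantile(px[er_mask], p_specific))
  background_max <- as.numeric(stats::quantile(px[free_mask], p_background))
  if (min_specific <= background_max)
    stop(sprintf(paste0("derive_binary_threshold: non-separable intensity ",
                        "distributions (min specific %.4g <= background max %.4g)"),
                 min_specific, background_max))
  structure(list(threshold = background_max +
                   factor * (min_specific - background_max),
                 min_specific = min_specific,
                 background_max = background_max),
            class = "binary_threshold")
}

#' Classify maxima as ER-associated by a binary threshold
#'
#' A maximum is ER-associated iff the ER-marker intensity at its coordinate
#' is at least the threshold (>=, so maxima sitting exactly at the threshold
#' count as associated).
#'
#' @param maxima a [find_maxima()] result (must be nonempty).
#' @param er_img ER-marker [channel_image] or matrix.
#' @param threshold counts, or a `binary_threshold` object.
#' @return list of class `association_result`: `n_total`, `n_associated`,
#'   `fraction`, `threshold_used` (plus `min_specific`/`background_max` when
#'   a `binary_threshold` was supplied) and the per-maximum data frame
#'   `points` (`x`, `y`, `value`, `er_value`, `associated`).
#' @export
classify_association <- function(maxima, er_img, threshold) {
  if (!inherits(maxima, "maxima_set"))
    stop("classify_association: maxima must be a maxima_set")
  if (nrow(maxima$points) == 0)
    stop("classify_association: empty maxima set")
  thr_obj <- NULL
  if (inherits(threshold, "binary_threshold")) {
    thr_obj <- threshold
    threshold <- threshold$threshold
  }
  px <- .as_pixels(er_img)
  pts <- maxima$points
  er_val <- px[cbind(pts$y + 1L, pts$x + 1L)]
  assoc <- er_val >= threshold
  structure(list(n_total = nrow(pts), n_associated = sum(assoc),
                 fraction = mean(assoc), threshold_used = threshold,
                 min_specific = thr_obj$min_specific,
                 background_max = thr_obj$background_max,
                 points = cbind(pts, er_value = er_val, associated = assoc)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %d / %d maxima ER-associated (%.1f%%), threshold %.4g\n",
              x$n_associated, x$n_total, 100 * x$fraction, x$threshold_used))
  invisible(x)
}

#' Thresholded pixel-overlap colocalization
#'
#' Fraction of the pixel area above threshold in one channel that is also
#' above threshold in the other, and vice versa.
#'
#' @param img_a,img_b [channel_image]s or matrices of the same shape.
#' @param thr_a,thr_b thresholds in counts (pixels `>=` threshold count as
#'   positive).
#' @return list of class `coloc_result`: `frac_a_in_b`, `frac_b_in_a` (each
#'   `NA` when its denominator channel has no positive pixels), `thr_a`,
#'   `thr_b`, `n_a`, `n_b`, `n_both`.
#' @export
coloc_overlap <- function(img_a, img_b, thr_a, thr_b) {
  a <- .as_pixels(img_a); b <- .as_pixels(img_b)
  if (!all(dim(a) == dim(b)))
    stop("coloc_overlap: images must have the same shape")
  pos_a <- a >= thr_a; pos_b <- b >= thr_b
  n_a <- sum(pos_a); n_b <- sum(pos_b); n_both <- sum(pos_a & pos_b)
  structure(list(
    frac_a_in_b = if (n_a > 0) n_both / n_a else NA_real_,
    frac_b_in_a = if (n_b > 0) n_both / n_b else NA_real_,
    thr_a = thr_a, thr_b = thr_b, n_a = n_a, n_b = n_b, n_both = n_both),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> A-in-B %.3g, B-in-A %.3g (|A| = %d, |B| = %d px)\n",
              x$frac_a_in_b, x$frac_b_in_a, x$n_a, x$n_b))
  invisible(x)
}

#' Mean intensity of an image over a mask
#'
#' @param img [channel_image] or matrix.
#' @param roi_mask logical mask, nonempty.
#' @return mean counts over the mask.
#' @export
roi_mean_intensity <- function(img, roi_mask) {
  px <- .as_pixels(img)
  if (!any(roi_mask)) stop("roi_mean_intensity: empty mask")
  mean(px[roi_mask])
}
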