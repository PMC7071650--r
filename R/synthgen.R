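# Synthetic-data generators: every measurement stage in the package has a
# generator here that emits data with known ground truth, so each stage can be
# tested by parameter recovery. Ground truth is always returned alongside the
# data and is never consumed by the measurement code.
#
# Noise model (shared by the image generators): Poisson shot noise on the
# expected signal plus additive Gaussian read noise plus a constant
# background. With noise disabled (snr = Inf / noise_sd = 0) every generator
# returns exactly its deterministic mean image. Seeds are explicit parameter
# fields; global RNG state is saved and restored.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---------------------------------------------------------------------------
# Mother/daughter cell pair

#' Parameters for a synthetic mother/daughter cell pair
#'
#' Geometry: two axis-aligned ellipses side by side (mother left, daughter
#' right), their plasma membranes rendered as Gaussian-profiled rings; the two
#' neck-adjacent membranes are separated by `neck_offset` pixels so that a
#' horizontal line through both centers crosses exactly four membranes.
#' Integer default geometry places all four crossings at pixel centers.
#'
#' @param mother_axes,daughter_axes ellipse semi-axes `c(a, b)` in px; each
#'   daughter axis must be smaller than the corresponding mother axis.
#' @param neck_offset separation (px) between the two membranes at the neck;
#'   must be >= 1 (smaller values would overlap the cells beyond a neck).
#' @param pm_thickness membrane FWHM-like thickness in px (Gaussian sigma =
#'   `pm_thickness / 2`), >= 1.
#' @param ratio_true ground-truth daughter:mother ratio of the reporter's
#'   membrane amplitude (the quantity the polarity estimator must recover).
#' @param base_intensity reporter/marker membrane amplitude on the mother
#'   contour, counts.
#' @param background constant additive background, counts.
#' @param snr signal-to-noise ratio: Gaussian read noise SD is
#'   `base_intensity / snr`; `Inf` disables all noise (including shot noise).
#' @param seed integer RNG seed for this simulation.
#' @param img_size image size `c(width, height)` in px.
#' @return a validated list of class `cell_pair_params`.
#' @export
cell_pair_params <- function(mother_axes = c(26, 21), daughter_axes = c(16, 13),
                             neck_offset = 8, pm_thickness = 3,
                             ratio_true = 7.5, base_intensity = 2000,
                             background = 100, snr = 10, seed = 1,
                             img_size = c(256, 256)) {
  p <- list(mother_axes = as.numeric(mother_axes),
            daughter_axes = as.numeric(daughter_axes),
            neck_offset = neck_offset, pm_thickness = pm_thickness,
            ratio_true = ratio_true, base_intensity = base_intensity,
            background = background, snr = snr, seed = as.integer(seed),
            img_size = as.integer(img_size))
  if (p$ratio_true <= 0) stop("cell_pair_params: ratio_true must be > 0")
  if (p$pm_thickness < 1) stop("cell_pair_params: pm_thickness must be >= 1 px")
  if (!all(p$daughter_axes < p$mother_axes))
    stop("cell_pair_params: daughter axes must be smaller than mother axes")
  if (p$neck_offset < 1)
    stop("cell_pair_params: degenerate geometry - ellipses would overlap ",
         "beyond a neck (neck_offset must be >= 1 px)")
  W <- p$img_size[1]; H <- p$img_size[2]
  width <- 2 * p$mother_axes[1] + p$neck_offset + 2 * p$daughter_axes[1]
  if (width + 12 > W || 2 * p$mother_axes[2] + 12 > H)
    stop("cell_pair_params: geometry does not fit the image")
  class(p) <- "cell_pair_params"
  p
}

# signed radial distance of every pixel to an ellipse contour (approximate:
# measured along the ray from the center)
.ellipse_dist <- function(W, H, cx, cy, a, b) {
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  den <- sqrt(b^2 * dx^2 + a^2 * dy^2)
  re <- ifelse(den > 0, a * b * r / den, min(a, b))
  ifelse(r > 0, r - re, -min(a, b))
}

.apply_noise <- function(mean_img, snr, base) {
  if (!is.finite(snr)) return(mean_img)
  n <- length(mean_img)
  noisy <- stats::rpois(n, lambda = as.vector(mean_img)) +
    stats::rnorm(n, sd = base / snr)
  matrix(pmax(noisy, 0), nrow(mean_img))
}

#' Generate a two-channel synthetic cell pair
#'
#' Renders a `"marker"` channel with uniform membrane amplitude on both cells
#' and a `"reporter"` channel whose daughter membrane amplitude is
#' `ratio_true` times the mother amplitude, then applies Poisson shot noise
#' and Gaussian read noise (unless `snr = Inf`).
#'
#' @param params a [cell_pair_params()] object.
#' @return list with elements `reporter` and `marker` ([channel_image]s) and
#'   `geometry`, a `cell_pair_geometry` carrying the ground truth: cell
#'   centers/axes, the default measurement line (`line_p0`, `line_p1`), the
#'   mother/daughter intervals along that line (`segments`, neck excluded at
#'   its midpoint), the FWHM contour mask (`contour_mask`) and `ratio_true`.
#' @export
generate_cell_pair <- function(params) {
  if (!inherits(params, "cell_pair_params"))
    params <- do.call(cell_pair_params, params)
  p <- params
  W <- p$img_size[1]; H <- p$img_size[2]
  am <- p$mother_axes[1]; bm <- p$mother_axes[2]
  ad <- p$daughter_axes[1]; bd <- p$daughter_axes[2]
  width <- 2 * am + p$neck_offset + 2 * ad
  cxm <- round((W - width) / 2) + am
  cxd <- cxm + am + p$neck_offset + ad
  cy <- floor(H / 2)
  sigma <- p$pm_thickness / 2

  dm <- .ellipse_dist(W, H, cxm, cy, am, bm)
  dd <- .ellipse_dist(W, H, cxd, cy, ad, bd)
  ring_m <- exp(-dm^2 / (2 * sigma^2))
  ring_d <- exp(-dd^2 / (2 * sigma^2))
  marker_mean <- p$background + p$base_intensity * (ring_m + ring_d)
  reporter_mean <- p$background +
    p$base_intensity * (ring_m + p$ratio_true * ring_d)

  mats <- .with_seed(p$seed, list(
    reporter = .apply_noise(reporter_mean, p$snr, p$base_intensity),
    marker = .apply_noise(marker_mean, p$snr, p$base_intensity)))

  # default line: horizontal through both centers, a little beyond each cell
  x0 <- max(0, cxm - am - 6); x1 <- min(W - 1, cxd + ad + 6)
  neck_mid <- (cxm + am + p$neck_offset / 2) - x0
  geometry <- structure(list(
    mother_center = c(cxm, cy), daughter_center = c(cxd, cy),
    mother_axes = c(am, bm), daughter_axes = c(ad, bd),
    neck_offset = p$neck_offset, pm_sigma = sigma,
    line_p0 = c(x0, cy), line_p1 = c(x1, cy),
    segments = list(mother = c(0, neck_mid), daughter = c(neck_mid, x1 - x0)),
    contour_mask = (ring_m >= 0.5) | (ring_d >= 0.5),
    ratio_true = p$ratio_true, params = p), class = "cell_pair_geometry")

  list(reporter = channel_image(mats$reporter, "reporter"),
       marker = channel_image(mats$marker, "marker"),
       geometry = geometry)
}

#' @export
print.cell_pair_geometry <- function(x, ...) {
  cat(sprintf("<cell_pair_geometry> mother (%g,%g) axes %gx%g; daughter (%g,%g) axes %gx%g; ratio_true %g\n",
              x$mother_center[1], x$mother_center[2], x$mother_axes[1], x$mother_axes[2],
              x$daughter_center[1], x$daughter_center[2], x$daughter_axes[1],
              x$daughter_axes[2], x$ratio_true))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cortical field: ER network + puncta

#' Parameters for a synthetic cortical field
#'
#' A two-channel cortical section: an ER-network channel (reticulated mask
#' with on-pixel intensities in `er_intensity_range`, off-pixels below
#' `background_max`) and a puncta channel with `n_maxima` Gaussian spots, of
#' which `round(assoc_fraction_true * n_maxima)` are centered on ER pixels.
#'
#' @param n_maxima number of spots to place.
#' @param assoc_fraction_true ground-truth fraction of spots centered on the
#'   ER network, in `[0, 1]`.
#' @param er_coverage target fraction of the field covered by the ER mask.
#' @param er_intensity_range `c(min_specific, max)` counts for on-ER pixels;
#'   `min_specific` must exceed `background_max`.
#' @param background_max maximum intensity of ER-free pixels, counts.
#' @param puncta_amplitude spot peak amplitude above the puncta-channel
#'   baseline, counts.
#' @param spot_sigma Gaussian spot sigma, px.
#' @param min_separation minimum Chebyshev distance between spot centers, px.
#' @param noise_sd Gaussian noise SD added to the puncta channel (0 = none).
#' @param img_size image size `c(width, height)` px.
#' @param seed integer RNG seed.
#' @return a validated list of class `field_params`.
#' @export
field_params <- function(n_maxima = 300, assoc_fraction_true = 0.8,
                         er_coverage = 0.35, er_intensity_range = c(200, 400),
                         background_max = 100, puncta_amplitude = 300,
                         spot_sigma = 1.5, min_separation = 6, noise_sd = 5,
                         img_size = c(256, 256), seed = 1) {
  p <- list(n_maxima = as.integer(n_maxima),
            assoc_fraction_true = assoc_fraction_true,
            er_coverage = er_coverage, er_intensity_range = er_intensity_range,
            background_max = background_max,
            puncta_amplitude = puncta_amplitude, spot_sigma = spot_sigma,
            min_separation = min_separation, noise_sd = noise_sd,
            img_size = as.integer(img_size), seed = as.integer(seed))
  if (p$assoc_fraction_true < 0 || p$assoc_fraction_true > 1)
    stop("field_params: assoc_fraction_true must be in [0, 1]")
  if (p$er_intensity_range[1] <= p$background_max)
    stop("field_params: min specific ER intensity must exceed background_max")
  if (p$er_coverage < 0 || p$er_coverage >= 1)
    stop("field_params: er_coverage must be in [0, 1)")
  if (p$assoc_fraction_true > 0 && p$er_coverage == 0)
    stop("field_params: cannot associate spots with an empty ER network")
  class(p) <- "field_params"
  p
}

# reticulated ER mask: random-walk tubules (3 px wide) plus elliptical
# patches, grown until the target pixel coverage is reached
.er_network <- function(W, H, coverage) {
  mask <- matrix(FALSE, H, W)
  if (coverage <= 0) return(mask)
  target <- coverage * W * H
  stamp <- function(xs, ys, r) {
    for (ox in -r:r) for (oy in -r:r) {
      xx <- xs + ox; yy <- ys + oy
      ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
      mask[cbind(yy[ok], xx[ok])] <<- TRUE
    }
  }
  it <- 0L
  while (sum(mask) < target && it < 10000L) {
    it <- it + 1L
    if (stats::runif(1) < 0.15) {                     # ER patch (sheet)
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      a <- stats::runif(1, 4, 10); b <- stats::runif(1, 4, 10)
      xs <- round(seq(max(1, cx - a), min(W, cx + a)))
      for (x in xs) {
        half <- b * sqrt(max(0, 1 - ((x - cx) / a)^2))
        ys <- round(seq(max(1, cy - half), min(H, cy + half)))
        mask[ys, x] <- TRUE
      }
    } else {                                          # tubule random walk
      n <- sample(30:80, 1)
      th <- stats::runif(1, 0, 2 * pi)
      x <- stats::runif(1, 1, W); y <- stats::runif(1, 1, H)
      xs <- ys <- numeric(n)
      for (i in seq_len(n)) {
        th <- th + stats::rnorm(1, 0, 0.35)
        x <- x + cos(th); y <- y + sin(th)
        xs[i] <- x; ys[i] <- y
      }
      keep <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
      if (any(keep)) stamp(round(xs[keep]), round(ys[keep]), 1L)
    }
  }
  mask
}

.dilate_box <- function(mask, r) if (r <= 0) mask else !.erode_box(!mask, r)

#' Generate a synthetic cortical field with known ER association
#'
#' @param params a [field_params()] object.
#' @return list with `puncta` and `er` ([channel_image]s), `truth` (data frame
#'   `x`, `y`, `associated` per spot, 0-based center coordinates),
#'   `er_mask_truth` (logical matrix) and `params`. Errors if the requested
#'   number of spots cannot be placed without violating `min_separation`.
#' @export
generate_field <- function(params) {
  if (!inherits(params, "field_params")) params <- do.call(field_params, params)
  p <- params
  W <- p$img_size[1]; H <- p$img_size[2]
  .with_seed(p$seed, {
    er_mask <- .er_network(W, H, p$er_coverage)
    # ER channel: uniform specific intensities on the network, uniform
    # sub-background elsewhere
    er_img <- matrix(stats::runif(W * H, 0, p$background_max), H, W)
    n_on <- sum(er_mask)
    if (n_on > 0)
      er_img[er_mask] <- stats::runif(n_on, p$er_intensity_range[1],
                                      p$er_intensity_range[2])

    n_assoc <- round(p$assoc_fraction_true * p$n_maxima)
    n_free <- p$n_maxima - n_assoc
    margin <- ceiling(4 * p$spot_sigma) + 1L
    border <- matrix(TRUE, H, W)
    border[(margin + 1):(H - margin), (margin + 1):(W - margin)] <- FALSE
    # associated centers sit safely inside the network, free centers safely
    # outside it, so +/-1 px localization error cannot flip a label
    elig_assoc <- .erode_box(er_mask, 1L) & !border
    elig_free <- !.dilate_box(er_mask, 2L) & !border

    place <- function(n, eligible) {
      if (n == 0L) return(cbind(x = integer(0), y = integer(0)))
      avail <- eligible
      out <- matrix(0L, n, 2)
      sep <- as.integer(p$min_separation)
      for (i in seq_len(n)) {
        idx <- which(avail)
        if (length(idx) == 0L)
          stop("generate_field: requested spot count not placeable without ",
               "overlap (min_separation = ", sep, " px)")
        k <- idx[sample.int(length(idx), 1)]
        yy <- (k - 1L) %% H + 1L; xx <- (k - 1L) %/% H + 1L
        out[i, ] <- c(xx, yy)
        avail[max(1, yy - sep):min(H, yy + sep),
              max(1, xx - sep):min(W, xx + sep)] <- FALSE
      }
      colnames(out) <- c("x", "y")
      out
    }
    ctr_a <- place(n_assoc, elig_assoc)
    # keep free centers clear of already placed associated spots
    blocked <- matrix(FALSE, H, W)
    sep <- as.integer(p$min_separation)
    for (i in seq_len(nrow(ctr_a)))
      blocked[max(1, ctr_a[i, 2] - sep):min(H, ctr_a[i, 2] + sep),
              max(1, ctr_a[i, 1] - sep):min(W, ctr_a[i, 1] + sep)] <- TRUE
    ctr_f <- place(n_free, elig_free & !blocked)

    centers <- rbind(ctr_a, ctr_f)
    truth <- data.frame(x = centers[, "x"] - 1L, y = centers[, "y"] - 1L,
                        associated = rep(c(TRUE, FALSE), c(n_assoc, n_free)))

    puncta <- matrix(50, H, W)
    if (p$noise_sd > 0)
      puncta <- puncta + matrix(stats::rnorm(W * H, sd = p$noise_sd), H, W)
    w <- ceiling(4 * p$spot_sigma)
    off <- -w:w
    kern <- p$puncta_amplitude *
      exp(-(outer(off^2, off^2, "+")) / (2 * p$spot_sigma^2))
    for (i in seq_len(nrow(centers))) {
      ys <- centers[i, "y"] + off; xs <- centers[i, "x"] + off
      puncta[ys, xs] <- puncta[ys, xs] + kern
    }
    puncta <- pmax(puncta, 0)

    list(puncta = channel_image(puncta, "puncta"),
         er = channel_image(er_img, "er"),
         truth = truth, er_mask_truth = er_mask, params = p)
  })
}

# ---------------------------------------------------------------------------
# FRAP time-lapse

#' Parameters for a synthetic FRAP time-lapse
#'
#' Puncta are rendered as flat 5x5-px squares of `base_intensity` counts.
#' Bleached puncta follow the single-exponential recovery
#' `F(t) = F_inf - (F_inf - F_post) * exp(-k (t - t_bleach))` with
#' `F_post = 1 - bleach_depth` and
#' `F_inf = F_post + mobile_fraction_true * (1 - F_post)` (relative to the
#' pre-bleach level). The whole field additionally decays by
#' `exp(-incidental_rate * frame)` (incidental photobleaching), a spatially
#' graded camera bias is added to every frame, and never-bleached reference
#' puncta are included. A separate bias-only background stack is returned for
#' [correct_bias()].
#'
#' @param mobile_fraction_true ground-truth mobile fraction in `[0, 1]`.
#' @param rate_k recovery rate constant, 1/s (> 0).
#' @param bleach_depth fractional intensity loss at the bleach, in `(0, 1]`.
#' @param incidental_rate whole-field photobleach rate per frame.
#' @param pre_frames,post_frames frame counts before/after the bleach;
#'   `post_frames` must be >= 3 for the fit to be possible.
#' @param frame_interval seconds between frames.
#' @param noise_sd Gaussian pixel noise SD, counts (0 = none).
#' @param bias_level mean camera bias, counts (a +/-5 percent horizontal
#'   gradient emulates illumination inhomogeneity).
#' @param n_bleach,n_reference numbers of bleached and never-bleached puncta.
#' @param n_background frames in the bias-only background stack.
#' @param base_intensity punctum intensity, counts.
#' @param img_size image size `c(width, height)` px.
#' @param seed integer RNG seed.
#' @return a validated list of class `frap_sim_params`.
#' @export
frap_sim_params <- function(mobile_fraction_true = 0.2, rate_k = 0.1,
                            bleach_depth = 0.8, incidental_rate = 0.01,
                            pre_frames = 10, post_frames = 50,
                            frame_interval = 1, noise_sd = 0,
                            bias_level = 100, n_bleach = 10, n_reference = 6,
                            n_background = 100, base_intensity = 1000,
                            img_size = c(128, 128), seed = 1) {
  p <- list(mobile_fraction_true = mobile_fraction_true, rate_k = rate_k,
            bleach_depth = bleach_depth, incidental_rate = incidental_rate,
            pre_frames = as.integer(pre_frames),
            post_frames = as.integer(post_frames),
            frame_interval = frame_interval, noise_sd = noise_sd,
            bias_level = bias_level, n_bleach = as.integer(n_bleach),
            n_reference = as.integer(n_reference),
            n_background = as.integer(n_background),
            base_intensity = base_intensity, img_size = as.integer(img_size),
            seed = as.integer(seed))
  if (p$mobile_fraction_true < 0 || p$mobile_fraction_true > 1)
    stop("frap_sim_params: mobile_fraction_true must be in [0, 1]")
  if (p$rate_k <= 0) stop("frap_sim_params: rate_k must be > 0")
  if (p$bleach_depth <= 0 || p$bleach_depth > 1)
    stop("frap_sim_params: bleach_depth must be in (0, 1]")
  if (p$post_frames < 3)
    stop("frap_sim_params: post_frames must be >= 3 (fit impossible)")
  if (p$pre_frames < 1) stop("frap_sim_params: pre_frames must be >= 1")
  class(p) <- "frap_sim_params"
  p
}

#' Generate a synthetic FRAP time-lapse with known mobile fraction
#'
#' @param params a [frap_sim_params()] object.
#' @return list with `stack` (a [time_series_stack], `bleach_frame` at the
#'   first post-bleach frame), `background` (bias-only 3D array for
#'   [correct_bias()]), `bleach_points` and `reference_points` (data frames of
#'   0-based punctum centers) and `truth` (the parameters plus the normalized
#'   `F_post`/`F_inf` implied by them).
#' @export
generate_frap_series <- function(params) {
  if (!inherits(params, "frap_sim_params"))
    params <- do.call(frap_sim_params, params)
  p <- params
  W <- p$img_size[1]; H <- p$img_size[2]
  n_pts <- p$n_bleach + p$n_reference
  # punctum centers on a jittered grid, >= 12 px apart
  gx <- seq(6, W - 7, by = 12); gy <- seq(6, H - 7, by = 12)
  grid <- expand.grid(x = gx, y = gy)
  if (nrow(grid) < n_pts)
    stop("generate_frap_series: too many puncta for the image size")
  .with_seed(p$seed, {
    pick <- grid[sample.int(nrow(grid), n_pts), ]
    bleach_pts <- pick[seq_len(p$n_bleach), , drop = FALSE]
    ref_pts <- pick[p$n_bleach + seq_len(p$n_reference), , drop = FALSE]

    square <- function(pts) {
      m <- matrix(0, H, W)
      for (i in seq_len(nrow(pts)))
        m[pts$y[i] + 1 + (-2:2), pts$x[i] + 1 + (-2:2)] <- 1
      m
    }
    scene_b <- square(bleach_pts) * p$base_intensity
    scene_r <- square(ref_pts) * p$base_intensity

    xg <- matrix(0:(W - 1), H, W, byrow = TRUE)
    bias <- p$bias_level * (1 + 0.1 * (xg / (W - 1) - 0.5))

    nt <- p$pre_frames + p$post_frames
    ts <- (seq_len(nt) - 1) * p$frame_interval
    bleach_idx <- p$pre_frames + 1L
    f_post <- 1 - p$bleach_depth
    f_inf <- f_post + p$mobile_fraction_true * (1 - f_post)
    frames <- array(0, dim = c(H, W, nt))
    for (t in seq_len(nt)) {
      f <- if (t < bleach_idx) 1 else {
        dt <- ts[t] - ts[bleach_idx]
        f_inf - (f_inf - f_post) * exp(-p$rate_k * dt)
      }
      fr <- (scene_r + scene_b * f) * exp(-p$incidental_rate * (t - 1)) + bias
      if (p$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(W * H, sd = p$noise_sd), H, W)
      frames[, , t] <- pmax(fr, 0)
    }
    background <- array(0, dim = c(H, W, p$n_background))
    for (t in seq_len(p$n_background)) {
      bg <- bias
      if (p$noise_sd > 0)
        bg <- bg + matrix(stats::rnorm(W * H, sd = p$noise_sd), H, W)
      background[, , t] <- pmax(bg, 0)
    }
    rownames(bleach_pts) <- rownames(ref_pts) <- NULL
    list(stack = time_series_stack(frames, timestamps = ts,
                                   bleach_frame = bleach_idx),
         background = background,
         bleach_points = bleach_pts, reference_points = ref_pts,
         truth = c(unclass(p), list(F_post = f_post, F_inf = f_inf)))
  })
}

# ---------------------------------------------------------------------------
# Densitometry tables

#' Generate a synthetic sedimentation densitometry table
#'
#' Draws pellet (P) and supernatant (S) band intensities so that `P/(P+S)`
#' has mean `pellet_fraction_true` for each condition.
#'
#' @param n replicate rows per condition.
#' @param pellet_fraction_true named numeric vector of ground-truth pellet
#'   fractions; names are interpreted as temperatures in degrees C (e.g.
#'   `c("26" = 0.1, "42" = 0.9)`).
#' @param noise_cv coefficient of variation of the band intensities.
#' @param total_mean mean total band intensity P+S, arbitrary units.
#' @param seed integer RNG seed.
#' @return data frame with columns `sample_id`, `temperature_C`, `pellet`,
#'   `supernatant`, plus attribute `truth`.
#' @export
generate_densitometry <- function(n = 3, pellet_fraction_true = c("26" = 0.1,
                                                                  "42" = 0.9),
                                  noise_cv = 0.1, total_mean = 1000,
                                  seed = 1) {
  stopifnot(n >= 1, all(pellet_fraction_true >= 0),
            all(pellet_fraction_true <= 1), noise_cv >= 0)
  temps <- as.numeric(names(pellet_fraction_true))
  if (any(is.na(temps)))
    stop("generate_densitometry: names of pellet_fraction_true must be ",
         "temperatures in degrees C")
  .with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(pellet_fraction_true), function(i) {
      f <- pellet_fraction_true[i]
      pel <- pmax(f * total_mean *
                    (1 + noise_cv * stats::rnorm(n)), 0)
      sup <- pmax((1 - f) * total_mean *
                    (1 + noise_cv * stats::rnorm(n)), 0)
      data.frame(sample_id = sprintf("T%s_rep%d", names(pellet_fraction_true)[i],
                                     seq_len(n)),
                 temperature_C = temps[i], pellet = pel, supernatant = sup)
    }))
    rownames(rows) <- NULL
    attr(rows, "truth") <- pellet_fraction_true
    rows
  })
}

# ---------------------------------------------------------------------------
# Writers: TIFF channels + ground-truth JSON sidecar, densitometry CSV

#' Write a synthetic simulation to disk
#'
#' Cell pairs and fields are written as one 16-bit TIFF per channel, FRAP
#' simulations as multi-page TIFFs (`stack.tif`, `background.tif`); ground
#' truth and parameters go to a `truth.json` sidecar. Densitometry tables are
#' written as CSV with header `sample_id,temperature_C,pellet,supernatant`.
#'
#' @param sim result of [generate_cell_pair()], [generate_field()],
#'   [generate_frap_series()] or [generate_densitometry()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clip16 <- function(img) {
    img$pixels <- pmin(round(img$pixels), 65535)
    img
  }
  truth <- NULL
  if (is.data.frame(sim)) {                         # densitometry table
    utils::write.csv(sim, file.path(dir, "densitometry.csv"),
                     row.names = FALSE, quote = FALSE)
    truth <- list(pellet_fraction_true = attr(sim, "truth"))
  } else if (!is.null(sim$geometry)) {              # cell pair
    write_tiff(clip16(sim$reporter), file.path(dir, "reporter.tif"))
    write_tiff(clip16(sim$marker), file.path(dir, "marker.tif"))
    g <- sim$geometry
    truth <- g[setdiff(names(g), "contour_mask")]
    truth$params <- unclass(truth$params)
  } else if (!is.null(sim$er)) {                    # field
    write_tiff(clip16(sim$puncta), file.path(dir, "puncta.tif"))
    write_tiff(clip16(sim$er), file.path(dir, "er.tif"))
    truth <- list(params = unclass(sim$params), labels = sim$truth)
  } else if (!is.null(sim$stack)) {                 # FRAP
    st <- sim$stack
    st$frames <- pmin(round(st$frames), 65535)
    write_tiff(st, file.path(dir, "stack.tif"))
    bg <- time_series_stack(pmin(round(sim$background), 65535))
    write_tiff(bg, file.path(dir, "background.tif"))
    utils::write.csv(sim$bleach_points, file.path(dir, "template.csv"),
                     row.names = FALSE, quote = FALSE)
    truth <- sim$truth
    truth$timestamps <- st$timestamps
  } else stop("write_synthetic: unrecognized simulation object")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
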