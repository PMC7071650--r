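# FRAP pipeline: camera-bias correction, template-ROI construction,
# incidental-photobleach normalization, single-exponential recovery fitting
# and cohort aggregation.
#
# All traces handed to fit_recovery() are normalized so the pre-bleach mean
# is exactly 1; mobile and immobile fractions are defined relative to that
# pre-bleach level:
#   mobile = (F_inf - F_post) / (F_pre - F_post),  F_pre = 1.

#' Correct a time-lapse for camera bias and illumination inhomogeneity
#'
#' Subtracts the per-pixel mean of a bias-only background stack from every
#' frame (negative values are clipped to 0). Averaging many background frames
#' keeps the correction from injecting noise.
#'
#' @param stack a [time_series_stack].
#' @param background bias-only frames: a 3D array `(y, x, t)` or another
#'   `time_series_stack` of the same frame shape.
#' @param background_frames number of background frames to average (default
#'   100); if fewer are available a warning is issued and all are used.
#' @return the corrected [time_series_stack].
#' @export
correct_bias <- function(stack, background, background_frames = 100) {
  if (inherits(background, "time_series_stack")) background <- background$frames
  if (length(dim(background)) == 2L)
    background <- array(background, dim = c(dim(background), 1L))
  if (!all(dim(background)[1:2] == dim(stack$frames)[1:2]))
    stop("correct_bias: background frame shape does not match the stack")
  nb <- dim(background)[3]
  if (nb < background_frames) {
    warning(sprintf("correct_bias: only %d background frames available (%d requested)",
                    nb, background_frames))
    background_frames <- nb
  }
  bias <- apply(background[, , seq_len(background_frames), drop = FALSE],
                c(1, 2), mean)
  out <- stack
  for (t in seq_len(dim(stack$frames)[3]))
    out$frames[, , t] <- pmax(stack$frames[, , t] - bias, 0)
  out
}

#' Build square ROI masks around template points
#'
#' FRAP bleach templates mark single-pixel locations; since the laser
#' bleaches a larger area, each point is dilated to a `dilate_to` x
#' `dilate_to` square (cropped at the image border) before measurement.
#'
#' @param template_points data frame or matrix with `x`, `y` columns (0-based
#'   pixel coordinates, inside the image).
#' @param img_dim image dimensions `c(height, width)` (i.e. `dim(pixels)`).
#' @param dilate_to side of the square ROI in px, default 5.
#' @return list of logical masks, one per (unique) point; duplicated points
#'   are merged with a warning. Overlapping ROIs from distinct points are
#'   kept separate.
#' @export
build_bleach_rois <- function(template_points, img_dim, dilate_to = 5) {
  pts <- as.data.frame(template_points)
  if (!all(c("x", "y") %in% names(pts)))
    stop("build_bleach_rois: template needs x and y columns")
  H <- img_dim[1]; W <- img_dim[2]
  if (any(pts$x < 0 | pts$x > W - 1 | pts$y < 0 | pts$y > H - 1))
    stop("build_bleach_rois: template points must lie inside the image")
  dup <- duplicated(pts[, c("x", "y")])
  if (any(dup)) {
    warning(sprintf("build_bleach_rois: %d duplicate template point(s) merged",
                    sum(dup)))
    pts <- pts[!dup, , drop = FALSE]
  }
  half <- floor(dilate_to / 2)
  lapply(seq_len(nrow(pts)), function(i) {
    m <- matrix(FALSE, H, W)
    ys <- max(0, pts$y[i] - half):min(H - 1, pts$y[i] + half)
    xs <- max(0, pts$x[i] - half):min(W - 1, pts$x[i] + half)
    m[ys + 1, xs + 1] <- TRUE
    m
  })
}

#' Extract ROI and reference traces from a time-lapse
#'
#' @param stack a (bias-corrected) [time_series_stack].
#' @param roi_masks list of logical masks from [build_bleach_rois()].
#' @param reference_mask logical mask of never-bleached fluorescent area used
#'   for incidental-photobleach normalization.
#' @param bleach_frame 1-based index of the first post-bleach frame; defaults
#'   to the stack's own.
#' @return object of class `frap_series`: `roi_traces` (frames x ROIs
#'   matrix of mean counts), `reference_trace`, `timestamps`, `bleach_frame`,
#'   `pre_bleach_means`.
#' @export
frap_series <- function(stack, roi_masks, reference_mask,
                        bleach_frame = stack$bleach_frame) {
  if (is.null(bleach_frame))
    stop("frap_series: bleach_frame required")
  nt <- dim(stack$frames)[3]
  roi_traces <- vapply(roi_masks, function(m)
    vapply(seq_len(nt), function(t) mean(stack$frames[, , t][m]), 0),
    numeric(nt))
  reference_trace <- vapply(seq_len(nt),
                            function(t) mean(stack$frames[, , t][reference_mask]), 0)
  pre <- seq_len(bleach_frame - 1L)
  structure(list(roi_traces = roi_traces, reference_trace = reference_trace,
                 timestamps = stack$timestamps,
                 bleach_frame = as.integer(bleach_frame),
                 pre_bleach_means = colMeans(roi_traces[pre, , drop = FALSE])),
            class = "frap_series")
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf("<frap_series> %d ROIs, %d frames, bleach at frame %d\n",
              ncol(x$roi_traces), nrow(x$roi_traces), x$bleach_frame))
  invisible(x)
}

#' Normalize an ROI trace for incidental photobleaching
#'
#' Divides the ROI trace by the never-bleached reference trace (removing the
#' whole-field decay) and rescales so the pre-bleach mean of the normalized
#' trace equals 1 exactly:
#' `N(t) = (roi(t)/ref(t)) / mean_pre(roi/ref)`.
#'
#' @param roi_trace,reference_trace numeric vectors of equal length; the
#'   reference must be strictly positive.
#' @param pre_frames number of pre-bleach frames used for the rescaling.
#' @return normalized trace with pre-bleach mean 1.
#' @export
normalize_trace <- function(roi_trace, reference_trace, pre_frames) {
  if (length(roi_trace) != length(reference_trace))
    stop("normalize_trace: trace lengths differ")
  if (any(reference_trace <= 0))
    stop("normalize_trace: reference trace must be strictly positive")
  if (pre_frames < 1 || pre_frames >= length(roi_trace))
    stop("normalize_trace: invalid pre_frames")
  ratio <- roi_trace / reference_trace
  ratio / mean(ratio[seq_len(pre_frames)])
}

#' Fit single-exponential FRAP recovery and estimate the mobile fraction
#'
#' Fits `F(t) = F_inf - (F_inf - F_post) * exp(-k (t - t_bleach))` to the
#' post-bleach portion of a normalized trace by nonlinear least squares
#' (initialized at `F_post` = first post-bleach value, `F_inf` = mean of the
#' final 3 points, `k = ln 2 / (post-bleach duration / 2)`). The mobile
#' fraction is `(F_inf - F_post) / (1 - F_post)` with the pre-bleach level
#' fixed at 1 by normalization; values outside `[0, 1]` are clipped with a
#' warning. A model-free mode (`method = "endpoint"`) instead takes `F_inf`
#' as the mean of the last 20 percent of frames. Traces with (numerically)
#' constant post-bleach signal are handled by the endpoint estimator, since
#' the rate is then unidentifiable; fits that fail to converge are flagged
#' and excluded from cohort means.
#'
#' @param trace normalized intensity trace (see [normalize_trace()]).
#' @param timestamps acquisition times, s.
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param method `"exp"` (default) or `"endpoint"`.
#' @return object of class `frap_fit` with elements `F_post`, `F_inf`, `k`
#'   (1/s, `NA` for endpoint mode), `mobile_fraction`, `immobile_fraction`,
#'   `rss`, `method`, `flag` and the fitted data.
#' @export
fit_recovery <- function(trace, timestamps, bleach_frame,
                         method = c("exp", "endpoint")) {
  method <- match.arg(method)
  n <- length(trace)
  if (length(timestamps) != n)
    stop("fit_recovery: trace and timestamps lengths differ")
  if (n - bleach_frame + 1L < 3L)
    stop("fit_recovery: at least 3 post-bleach points required")
  post <- bleach_frame:n
  tt <- timestamps[post] - timestamps[bleach_frame]
  y <- trace[post]
  flag <- NA_character_
  f_post <- y[1]
  k <- NA_real_
  used <- method

  if (method == "exp" && stats::sd(y) > 1e-9 * max(abs(y), 1)) {
    start <- list(Fpost = f_post, Finf = mean(utils::tail(y, 3)),
                  k = log(2) / (max(tt) / 2))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Finf - (Finf - Fpost) * exp(-k * tt),
                        start = start,
                        lower = c(Fpost = 0, Finf = 0, k = 1e-8),
                        upper = c(Fpost = 1.5, Finf = 1.5, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      flag <- paste("fit did not converge:", conditionMessage(fit))
      f_inf <- mean(y[seq.int(max(1L, length(y) - max(3L, ceiling(0.2 * length(y))) + 1L),
                              length(y))])
      used <- "endpoint"
    } else {
      cf <- stats::coef(fit)
      f_post <- unname(cf["Fpost"]); f_inf <- unname(cf["Finf"])
      k <- unname(cf["k"])
      if (k * max(tt) < 1) {
        # less than one time constant observed: the plateau is extrapolation,
        # not measurement (k and F_inf are jointly unidentified on a near-flat
        # trace); use the model-free endpoint plateau instead
        m <- max(3L, ceiling(0.2 * length(y)))
        f_post <- y[1]
        f_inf <- mean(y[seq.int(length(y) - m + 1L, length(y))])
        k <- NA_real_
        used <- "endpoint"
      }
    }
  } else {
    m <- max(3L, ceiling(0.2 * length(y)))
    f_inf <- mean(y[seq.int(length(y) - m + 1L, length(y))])
    used <- "endpoint"
  }

  mobile <- if (f_post < 1) (f_inf - f_post) / (1 - f_post) else NA_real_
  if (is.na(mobile)) {
    if (is.na(flag)) flag <- "no bleach depth (F_post >= 1)"
  } else if (mobile < 0 || mobile > 1) {
    warning(sprintf("fit_recovery: mobile fraction %.3g clipped to [0, 1]", mobile))
    mobile <- min(max(mobile, 0), 1)
  }
  fitted_vals <- if (used == "exp" && !is.na(k))
    f_inf - (f_inf - f_post) * exp(-k * tt) else rep(f_inf, length(tt))
  structure(list(F_post = f_post, F_inf = f_inf, k = k,
                 mobile_fraction = mobile,
                 immobile_fraction = if (is.na(mobile)) NA_real_ else 1 - mobile,
                 rss = sum((y - fitted_vals)^2), method = used, flag = flag,
                 time = tt, observed = y, fitted_values = fitted_vals),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> (%s) F_post = %.3f, F_inf = %.3f, k = %s /s\n",
              x$method, x$F_post, x$F_inf,
              if (is.na(x$k)) "NA" else sprintf("%.3g", x$k)))
  cat(sprintf("  mobile fraction %.3f, immobile %.3f, rss %.3g%s\n",
              x$mobile_fraction, x$immobile_fraction, x$rss,
              if (is.na(x$flag)) "" else paste0(" [FLAGGED: ", x$flag, "]")))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(F_post = object$F_post, F_inf = object$F_inf, k = object$k,
    mobile_fraction = object$mobile_fraction)
}

#' @export
fitted.frap_fit <- function(object, ...) object$fitted_values

#' @export
residuals.frap_fit <- function(object, ...) object$observed - object$fitted_values

#' @export
predict.frap_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(object$fitted_values)
  if (is.na(object$k)) rep(object$F_inf, length(t))
  else object$F_inf - (object$F_inf - object$F_post) * exp(-object$k * t)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$time, x$observed, xlab = "time post-bleach (s)",
                 ylab = "normalized intensity", ...)
  graphics::lines(x$time, x$fitted_values, col = 2, lwd = 2)
  invisible(x)
}

#' Aggregate FRAP traces and fits into a cohort curve
#'
#' @param traces matrix (frames x ROIs) or list of equal-length normalized
#'   traces; at least 2.
#' @param fits optional list of [fit_recovery()] results (one per trace);
#'   flagged fits are excluded from the fraction means.
#' @param timestamps optional time vector carried into the result.
#' @return list of class `frap_cohort`: `mean_trace`, `sd_trace` (pointwise),
#'   `mean_mobile`, `mean_immobile`, `sd_mobile`, `n`, `n_flagged`.
#' @export
cohort_curve <- function(traces, fits = NULL, timestamps = NULL) {
  if (is.list(traces)) traces <- do.call(cbind, traces)
  if (ncol(traces) < 2) stop("cohort_curve: at least 2 traces required")
  mean_mobile <- sd_mobile <- mean_immobile <- NA_real_
  n_flagged <- 0L
  if (!is.null(fits)) {
    mob <- vapply(fits, function(f) f$mobile_fraction, 0)
    ok <- vapply(fits, function(f) is.na(f$flag), TRUE) & !is.na(mob)
    n_flagged <- sum(!ok)
    if (any(ok)) {
      mean_mobile <- mean(mob[ok])
      sd_mobile <- if (sum(ok) > 1) stats::sd(mob[ok]) else 0
      mean_immobile <- 1 - mean_mobile
    }
  }
  structure(list(mean_trace = rowMeans(traces),
                 sd_trace = apply(traces, 1, stats::sd),
                 timestamps = timestamps,
                 mean_mobile = mean_mobile, sd_mobile = sd_mobile,
                 mean_immobile = mean_immobile,
                 n = ncol(traces), n_flagged = n_flagged),
            class = "frap_cohort")
}

#' @export
print.frap_cohort <- function(x, ...) {
  cat(sprintf("<frap_cohort> %d traces (%d flagged): mean mobile fraction %.3f (SD %.3f)\n",
              x$n, x$n_flagged, x$mean_mobile, x$sd_mobile))
  invisible(x)
}

#' Run the full FRAP pipeline on a simulated (or assembled) experiment
#'
#' Convenience wrapper: bias correction, ROI construction from the bleach
#' template, reference-mask construction from the never-bleached puncta,
#' normalization, per-ROI recovery fits and cohort aggregation.
#'
#' @param sim a [generate_frap_series()] result, or a list with the same
#'   elements (`stack`, `background`, `bleach_points`, `reference_points`).
#' @param method fit mode passed to [fit_recovery()].
#' @return list with `series` (`frap_series`), `normalized` (frames x ROIs),
#'   `fits` (list of `frap_fit`) and `cohort` (`frap_cohort`).
#' @export
measure_frap_cohort <- function(sim, method = c("exp", "endpoint")) {
  method <- match.arg(method)
  corrected <- correct_bias(sim$stack, sim$background,
                            background_frames = dim(sim$background)[3])
  d <- dim(corrected$frames)[1:2]
  rois <- build_bleach_rois(sim$bleach_points, d)
  ref_rois <- build_bleach_rois(sim$reference_points, d)
  ref_mask <- Reduce(`|`, ref_rois)
  ser <- frap_series(corrected, rois, ref_mask)
  pre <- ser$bleach_frame - 1L
  normalized <- apply(ser$roi_traces, 2, normalize_trace,
                      reference_trace = ser$reference_trace, pre_frames = pre)
  fits <- lapply(seq_len(ncol(normalized)), function(i)
    fit_recovery(normalized[, i], ser$timestamps, ser$bleach_frame, method))
  list(series = ser, normalized = normalized, fits = fits,
       cohort = cohort_curve(normalized, fits, ser$timestamps))
}
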