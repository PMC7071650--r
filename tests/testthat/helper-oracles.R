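# Independent brute-force oracles used to check the fast implementations,
# plus small synthetic builders shared across test files. The oracles evaluate
# the defining criteria directly and share no code with the package internals.

# ---- 1D peak prominence oracle -------------------------------------------
# Interior local maxima (plateau-aware); prominence evaluated by explicit
# stepwise walks away from the peak.
oracle_profile_peaks <- function(v) {
  n <- length(v)
  peaks <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i])
        peaks[[length(peaks) + 1L]] <- c(idx = round((i + j) / 2), h = v[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks))
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  out <- do.call(rbind, lapply(peaks, function(pk) {
    p <- pk[["idx"]]; h <- pk[["h"]]
    lo_l <- h
    k <- p
    while (k > 1L) {
      k <- k - 1L
      if (v[k] > h) break
      if (v[k] < lo_l) lo_l <- v[k]
    }
    lo_r <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (v[k] > h) break
      if (v[k] < lo_r) lo_r <- v[k]
    }
    data.frame(index = p, value = h, prominence = h - max(lo_l, lo_r))
  }))
  out[order(out$index), , drop = FALSE]
}

# ---- 2D maxima path-criterion oracle -------------------------------------
# For every pixel p, computes the set reachable from p through pixels with
# value > v(p) - tol by iterative mask dilation (matrix shifts), and accepts
# p iff no reachable pixel is strictly higher. Accepted pixels are grouped
# into equal-value 8-connected plateaus (one point at the rounded centroid);
# a plateau with no strictly lower neighbour anywhere (constant image) is
# dropped.
oracle_find_maxima <- function(v, tol) {
  H <- nrow(v); W <- ncol(v)
  dilate8 <- function(m) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-H, ]
    out[-H, ] <- out[-H, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -W]
    out[, -W] <- out[, -W] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-H, -W]
    out[-H, -W] <- out[-H, -W] | m[-1, -1]
    out[-1, -W] <- out[-1, -W] | m[-H, -1]
    out[-H, -1] <- out[-H, -1] | m[-1, -W]
    out
  }
  reach_from <- function(seed, allowed) {
    r <- seed & allowed
    repeat {
      r2 <- dilate8(r) & allowed
      if (identical(r2, r)) return(r)
      r <- r2
    }
  }
  accepted <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    seed <- matrix(FALSE, H, W); seed[i, j] <- TRUE
    r <- reach_from(seed, v > v[i, j] - tol)
    accepted[i, j] <- !any(v[r] > v[i, j])
  }
  # plateau grouping among accepted pixels
  seen <- matrix(FALSE, H, W)
  res <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!accepted[i, j] || seen[i, j]) next
    seed <- matrix(FALSE, H, W); seed[i, j] <- TRUE
    plat <- reach_from(seed, v == v[i, j])
    seen <- seen | plat
    ring <- dilate8(plat) & !plat
    if (!any(ring)) next                     # plateau spans the whole image
    idx <- which(plat, arr.ind = TRUE)
    res <- rbind(res, data.frame(x = round(mean(idx[, 2])) - 1L,
                                 y = round(mean(idx[, 1])) - 1L,
                                 value = v[i, j]))
  }
  if (is.null(res))
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  res <- res[order(res$x, res$y), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- synthetic single cells for aggregation scoring ----------------------
# Disc-shaped cell with a diffuse level; optional interior and/or cortical
# spots of the given amplitude.
make_agg_cell <- function(size = 48, radius = 18, diffuse = 300,
                          background = 100, spot_amp = 600,
                          n_interior = 0, n_cortical = 0, band = 3,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- matrix(0:(size - 1), size, size, byrow = TRUE)
  ys <- matrix(0:(size - 1), size, size)
  c0 <- (size - 1) / 2
  r2 <- (xs - c0)^2 + (ys - c0)^2
  mask <- r2 <= radius^2
  img <- matrix(background, size, size)
  img[mask] <- diffuse
  put_spot <- function(img, x, y) {
    img[y + 1 + (-1:1), x + 1 + (-1:1)] <- diffuse + spot_amp * 0.6
    img[y + 1, x + 1] <- diffuse + spot_amp
    img
  }
  for (k in seq_len(n_interior)) {
    repeat {
      x <- sample(0:(size - 1), 1); y <- sample(0:(size - 1), 1)
      if ((x - c0)^2 + (y - c0)^2 <= (radius - band - 3)^2) break
    }
    img <- put_spot(img, x, y)
  }
  for (k in seq_len(n_cortical)) {
    th <- runif(1, 0, 2 * pi)
    x <- round(c0 + (radius - 1) * cos(th)); y <- round(c0 + (radius - 1) * sin(th))
    img <- put_spot(img, x, y)
  }
  list(img = img, mask = mask)
}
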