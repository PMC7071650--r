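test_that("TIFF round trips are bit-exact and preserve page order", {
  set.seed(11)
  img <- channel_image(matrix(sample(0:65535, 32 * 32, TRUE), 32), "gfp")
  f <- withr::local_tempfile(fileext = ".tif")
  write_tiff(img, f)
  back <- read_tiff(f)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$bit_depth, 16L)

  f2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff(channel_image(matrix(500, 16, 16)), f2)
  expect_true(all(read_tiff(f2)$pixels == 500))

  frames <- lapply(1:5, function(i) matrix(i * 100, 16, 16))
  f3 <- withr::local_tempfile(fileext = ".tif")
  write_tiff(time_series_stack(frames), f3)
  st <- read_tiff(f3)
  expect_s3_class(st, "time_series_stack")
  expect_equal(dim(st$frames)[3], 5L)
  expect_equal(st$frames[1, 1, ], (1:5) * 100)
})

test_that("RGB TIFFs are rejected with an explicit error", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(16 * 16 * 3), c(16, 16, 3)), f)
  expect_error(read_tiff(f), "unsupported format")
})

test_that("sample_line is exact on constant and planar intensity fields", {
  const <- channel_image(matrix(7, 32, 32))
  pr <- sample_line(const, c(2, 3), c(29, 27), spacing = 0.5)
  expect_equal(pr$values, rep(7, length(pr$values)), tolerance = 1e-12)

  # column x has value x: horizontal profile returns the sampled positions
  ramp <- matrix(0:31, 32, 32, byrow = TRUE)
  pr2 <- sample_line(ramp, c(0, 10), c(31, 10), spacing = 0.5)
  expect_equal(pr2$values, pr2$positions, tolerance = 1e-12)

  # bilinear interpolation reproduces any planar field exactly, any direction
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, -5, 5); b <- runif(1, -2, 2); cc <- runif(1, -2, 2)
    x <- matrix(0:31, 32, 32, byrow = TRUE); y <- matrix(0:31, 32, 32)
    plane <- 100 + a + b * x + cc * y
    p0 <- runif(2, 1, 14); p1 <- runif(2, 16, 30)
    pr3 <- sample_line(channel_image(plane - min(plane)), p0, p1, spacing = 0.7)
    ux <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    expected <- 100 + a + b * (p0[1] + pr3$positions * ux[1]) +
      cc * (p0[2] + pr3$positions * ux[2]) - min(plane)
    expect_equal(pr3$values, expected, tolerance = 1e-9)
  }

  expect_error(sample_line(const, c(2, 2), c(2, 2)), "zero-length")
  expect_error(sample_line(const, c(-1, 2), c(5, 5)), "inside the image")
})

test_that("a line across a circular membrane yields peaks at the analytic crossings", {
  # ring of radius 10 centered at (32, 32); diagonal line crosses the circle
  # where the distance from the center equals the radius
  x <- matrix(0:63, 64, 64, byrow = TRUE); y <- matrix(0:63, 64, 64)
  r <- sqrt((x - 32)^2 + (y - 32)^2)
  ring <- channel_image(1000 * exp(-(r - 10)^2 / 2))
  pr <- sample_line(ring, c(12, 12), c(52, 52), spacing = 0.25)
  pks <- find_profile_peaks(pr, min_prominence = 400)
  center_t <- sqrt(2) * 20
  expect_equal(nrow(pks), 2L)
  expect_equal(sort(pks$position), c(center_t - 10, center_t + 10),
               tolerance = 0.25 / 2 + 1e-9)
})

test_that("profile peaks match hand-computable cases", {
  expect_equal(nrow(find_profile_peaks(1:50, 0.1)), 0L)
  pk <- find_profile_peaks(c(0, 5, 0, 9, 0), min_prominence = 4)
  expect_equal(pk$position, c(1, 3))
  expect_equal(pk$value, c(5, 9))
  # plateau reported once, at its centroid
  pk2 <- find_profile_peaks(c(0, 3, 3, 3, 0), min_prominence = 1)
  expect_equal(pk2$position, 2)
})

test_that("profile peak detection equals the brute-force prominence oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(16:64, 1)
    v <- cumsum(rnorm(n))
    if (rep %% 3 == 0) v <- round(v)              # force plateaus/ties
    if (rep %% 4 == 0) v <- v + 5 * sin(seq(0, 6, length.out = n))
    got <- find_profile_peaks(v, min_prominence = 1e-9)
    want <- oracle_profile_peaks(v)
    expect_equal(got$index, want$index)
    expect_equal(got$value, want$value)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    # and with a real threshold
    tol <- runif(1, 0.5, 3)
    got_t <- find_profile_peaks(v, min_prominence = tol)
    expect_equal(got_t$index, want$index[want$prominence >= tol])
  }
})

test_that("marker masking is exact on bimodal images and errors on constants", {
  img <- matrix(10, 32, 32)
  img[10:20, 12:22] <- 1000
  mask <- pm_mask_from_marker(channel_image(img))
  expect_identical(mask, img == 1000)
  expect_error(pm_mask_from_marker(channel_image(matrix(5, 16, 16))),
               "degenerate")
  # fixed threshold mode
  expect_identical(pm_mask_from_marker(channel_image(img), "fixed", 500),
                   img > 500)
})

test_that("marker mask of a synthetic cell pair matches the rendered contour area", {
  p <- cell_pair_params(snr = 10, seed = 7)
  sim <- generate_cell_pair(p)
  truth_area <- sum(sim$geometry$contour_mask)   # FWHM band of the membrane
  # thresholding at half the membrane amplitude targets exactly that band
  half_amp <- p$background + p$base_intensity / 2
  mask <- pm_mask_from_marker(sim$marker, "fixed", half_amp)
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.15)
  # Otsu picks a usable threshold unsupervised: it covers the contour without
  # ballooning far beyond it
  otsu_mask <- pm_mask_from_marker(sim$marker)
  expect_gt(sum(otsu_mask & sim$geometry$contour_mask) / truth_area, 0.8)
  expect_lt(sum(otsu_mask), 2 * truth_area)
})

test_that("masking is idempotent for region statistics", {
  sim <- generate_cell_pair(cell_pair_params(snr = 20, seed = 2))
  mask <- pm_mask_from_marker(sim$marker)
  masked <- sim$reporter$pixels * mask
  expect_equal(roi_mean_intensity(masked, mask),
               roi_mean_intensity(sim$reporter, mask))
})
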