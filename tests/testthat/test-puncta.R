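test_that("maxima detection handles the hand-checkable cases", {
  expect_equal(nrow(find_maxima(matrix(5, 16, 16), 1)$points), 0L)

  # single Gaussian spot, amplitude 100 over 0 background, tolerance 50
  x <- matrix(0:31, 32, 32, byrow = TRUE); y <- matrix(0:31, 32, 32)
  spot <- 100 * exp(-((x - 15)^2 + (y - 17)^2) / (2 * 1.5^2))
  mx <- find_maxima(spot, 50)
  expect_equal(nrow(mx$points), 1L)
  expect_lte(max(abs(c(mx$points$x - 15, mx$points$y - 17))), 1)

  # two spots separated by a deep valley are both found; tolerance above the
  # smaller peak's prominence suppresses only that peak
  img <- matrix(0, 16, 16)
  img[4, 4] <- 100; img[12, 12] <- 60
  expect_equal(nrow(find_maxima(img, 30)$points), 2L)
  mx2 <- find_maxima(img, 80)
  expect_equal(nrow(mx2$points), 1L)
  expect_equal(mx2$points$value, 100)
})

test_that("maxima detection matches the exhaustive path-criterion oracle", {
  set.seed(7)
  for (rep in 1:150) {
    n <- sample(6:8, 1)
    v <- matrix(sample(0:4, n * n, TRUE), n)
    tol <- sample(c(1, 2, 3, 5), 1)
    got <- find_maxima(v, tol)$points
    want <- oracle_find_maxima(v, tol)
    expect_equal(got, want,
                 label = sprintf("rep %d (n=%d, tol=%g)", rep, n, tol))
  }
})

test_that("maxima are shift invariant and scale equivariant", {
  set.seed(8)
  for (rep in 1:20) {
    v <- matrix(sample(0:20, 100, TRUE), 10)
    tol <- sample(2:6, 1)
    base <- find_maxima(v, tol)$points
    shifted <- find_maxima(v + 137, tol)$points
    expect_equal(shifted[c("x", "y")], base[c("x", "y")])
    scaled <- find_maxima(v * 3.5, tol * 3.5)$points
    expect_equal(scaled[c("x", "y")], base[c("x", "y")])
  }
})

test_that("binary threshold derivation is midpoint arithmetic on clean data", {
  er_img <- matrix(0, 32, 32)
  er_mask <- matrix(FALSE, 32, 32); er_mask[1:16, ] <- TRUE
  free_mask <- !er_mask
  er_img[er_mask] <- seq(200, 400, length.out = sum(er_mask))
  er_img[free_mask] <- seq(0, 100, length.out = sum(free_mask))
  # with min/max endpoints the threshold is the exact midpoint 150
  thr <- derive_binary_threshold(er_img, er_mask, free_mask,
                                 p_specific = 0, p_background = 1)
  expect_equal(thr$threshold, 150)
  expect_equal(thr$min_specific, 200)
  expect_equal(thr$background_max, 100)
  # default percentile endpoints stay within a few counts of the midpoint
  thr2 <- derive_binary_threshold(er_img, er_mask, free_mask)
  expect_lt(abs(thr2$threshold - 150), 5)

  # overlapping distributions are rejected
  er_img[free_mask] <- seq(0, 300, length.out = sum(free_mask))
  expect_error(derive_binary_threshold(er_img, er_mask, free_mask),
               "non-separable")
  expect_error(derive_binary_threshold(er_img, er_mask, matrix(FALSE, 32, 32)),
               "nonempty")
})

test_that("the generator's intensity design reproduces the expected threshold", {
  fld <- generate_field(field_params(n_maxima = 100, seed = 21))
  thr <- derive_binary_threshold(fld$er, fld$er_mask_truth, !fld$er_mask_truth)
  expect_lt(abs(thr$threshold - 150), 5)   # 200/100 design -> midpoint 150
})

test_that("association classification obeys threshold limits and monotonicity", {
  fld <- generate_field(field_params(n_maxima = 60, seed = 13))
  mx <- find_maxima(fld$puncta, fld$params$puncta_amplitude / 2)
  expect_equal(classify_association(mx, fld$er, 1e-9)$fraction, 1)
  expect_equal(classify_association(mx, fld$er,
                                    max(fld$er$pixels) + 1)$fraction, 0)
  fr <- vapply(seq(0, 500, by = 25),
               function(t) classify_association(mx, fld$er, t)$fraction, 0)
  expect_true(all(diff(fr) <= 0))
  expect_error(classify_association(
    structure(list(points = data.frame()), class = "maxima_set"), fld$er, 1),
    "empty")
})

test_that("the full classifier chain recovers a known association fraction", {
  fld <- generate_field(field_params(n_maxima = 300, assoc_fraction_true = 0.8,
                                     img_size = c(320, 320), seed = 5))
  mx <- find_maxima(fld$puncta, fld$params$puncta_amplitude / 2)
  er_mask <- pm_mask_from_marker(fld$er)
  thr <- derive_binary_threshold(fld$er, er_mask, !er_mask)
  res <- classify_association(mx, fld$er, thr)
  se3 <- 3 * sqrt(0.8 * 0.2 / 300)
  expect_lt(abs(res$fraction - 0.8), se3)
})

test_that("colocalization fractions follow set arithmetic", {
  set.seed(9)
  a <- matrix(runif(400, 0, 100), 20)
  same <- coloc_overlap(a, a, 50, 50)
  expect_equal(same$frac_a_in_b, 1)
  expect_equal(same$frac_b_in_a, 1)

  b <- matrix(0, 20, 20); b[1:5, 1:5] <- 100
  cc <- matrix(0, 20, 20); cc[10:14, 10:14] <- 100
  disj <- coloc_overlap(b, cc, 50, 50)
  expect_equal(disj$frac_a_in_b, 0)
  expect_equal(disj$frac_b_in_a, 0)

  # A positive on 100 px, B on a 50-px subset -> (0.5, 1.0)
  A <- matrix(0, 20, 20); A[1:10, 1:10] <- 100
  B <- matrix(0, 20, 20); B[1:5, 1:10] <- 100
  part <- coloc_overlap(A, B, 50, 50)
  expect_equal(part$frac_a_in_b, 0.5)
  expect_equal(part$frac_b_in_a, 1)

  # empty denominator reported as missing, not zero
  none <- coloc_overlap(matrix(0, 20, 20), B, 50, 50)
  expect_true(is.na(none$frac_a_in_b))
  expect_equal(none$frac_b_in_a, 0)
})

test_that("colocalization is invariant under joint translation", {
  set.seed(10)
  a <- matrix(runif(900, 0, 100), 30)
  b <- matrix(runif(900, 0, 100), 30)
  ref <- coloc_overlap(a, b, 60, 40)
  roll <- function(m, dy, dx) {
    m[( (seq_len(nrow(m)) - 1 - dy) %% nrow(m) ) + 1,
      ( (seq_len(ncol(m)) - 1 - dx) %% ncol(m) ) + 1]
  }
  tr <- coloc_overlap(roll(a, 7, 3), roll(b, 7, 3), 60, 40)
  expect_equal(tr$frac_a_in_b, ref$frac_a_in_b)
  expect_equal(tr$frac_b_in_a, ref$frac_b_in_a)
})

test_that("ROI means are exact and recover cortical intensity under noise", {
  expect_equal(roi_mean_intensity(matrix(7, 16, 16),
                                  matrix(c(TRUE, FALSE), 16, 16)), 7)
  m <- matrix(0, 16, 16); msk <- matrix(FALSE, 16, 16)
  m[3, 4] <- 10; m[8, 9] <- 30; msk[3, 4] <- msk[8, 9] <- TRUE
  expect_equal(roi_mean_intensity(m, msk), 20)
  expect_error(roi_mean_intensity(m, matrix(FALSE, 16, 16)), "empty mask")

  # cortical mean of a noisy reporter vs the noise-free truth, within 5%
  p_clean <- cell_pair_params(ratio_true = 3, snr = Inf, seed = 6)
  p_noisy <- cell_pair_params(ratio_true = 3, snr = 10, seed = 6)
  clean <- generate_cell_pair(p_clean); noisy <- generate_cell_pair(p_noisy)
  mask <- clean$geometry$contour_mask
  truth_mean <- roi_mean_intensity(clean$reporter, mask)
  expect_lt(abs(roi_mean_intensity(noisy$reporter, mask) - truth_mean) /
              truth_mean, 0.05)
})
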