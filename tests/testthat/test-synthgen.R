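test_that("generators are deterministic under a fixed seed", {
  p <- cell_pair_params(snr = 10, seed = 123)
  a <- generate_cell_pair(p); b <- generate_cell_pair(p)
  expect_identical(a$reporter$pixels, b$reporter$pixels)
  expect_identical(a$marker$pixels, b$marker$pixels)

  fp <- field_params(n_maxima = 50, seed = 99)
  fa <- generate_field(fp); fb <- generate_field(fp)
  expect_identical(fa$puncta$pixels, fb$puncta$pixels)
  expect_identical(fa$truth, fb$truth)

  sp <- frap_sim_params(noise_sd = 20, n_bleach = 3, n_reference = 2,
                        n_background = 10, seed = 5)
  sa <- generate_frap_series(sp); sb <- generate_frap_series(sp)
  expect_identical(sa$stack$frames, sb$stack$frames)
})

test_that("cell-pair parameter invariants are enforced", {
  expect_error(cell_pair_params(ratio_true = 0), "ratio_true")
  expect_error(cell_pair_params(pm_thickness = 0.5), "pm_thickness")
  expect_error(cell_pair_params(daughter_axes = c(30, 22)), "daughter axes")
  expect_error(cell_pair_params(neck_offset = 0), "degenerate geometry")
})

test_that("noiseless cell pair has the exact constructed peak ratio", {
  p <- cell_pair_params(ratio_true = 7.5, snr = Inf)
  sim <- generate_cell_pair(p)
  g <- sim$geometry
  # reporter intensity at the outer membrane crossings of the center line
  cy <- g$mother_center[2] + 1
  vm <- sim$reporter$pixels[cy, g$mother_center[1] - g$mother_axes[1] + 1]
  vd <- sim$reporter$pixels[cy, g$daughter_center[1] + g$daughter_axes[1] + 1]
  bg <- p$background
  expect_equal((vd - bg) / (vm - bg), 7.5, tolerance = 1e-6)
  # marker channel is symmetric between the two cells
  mm <- sim$marker$pixels[cy, g$mother_center[1] - g$mother_axes[1] + 1]
  md <- sim$marker$pixels[cy, g$daughter_center[1] + g$daughter_axes[1] + 1]
  expect_equal(mm, md, tolerance = 1e-6)
})

test_that("at ratio 1 the two contours have equal mean intensity within noise", {
  p <- cell_pair_params(ratio_true = 1, snr = 10, seed = 31)
  sim <- generate_cell_pair(p)
  g <- sim$geometry
  # rebuild per-cell contour masks from the geometry (FWHM band)
  dist_m <- flarequant:::.ellipse_dist(ncol(sim$reporter$pixels),
                                       nrow(sim$reporter$pixels),
                                       g$mother_center[1], g$mother_center[2],
                                       g$mother_axes[1], g$mother_axes[2])
  dist_d <- flarequant:::.ellipse_dist(ncol(sim$reporter$pixels),
                                       nrow(sim$reporter$pixels),
                                       g$daughter_center[1], g$daughter_center[2],
                                       g$daughter_axes[1], g$daughter_axes[2])
  half <- g$pm_sigma * sqrt(2 * log(2))
  on_m <- abs(dist_m) <= half; on_d <- abs(dist_d) <= half & !on_m
  mu_m <- mean(sim$reporter$pixels[on_m])
  mu_d <- mean(sim$reporter$pixels[on_d])
  n <- min(sum(on_m), sum(on_d))
  expect_lt(abs(mu_d - mu_m) / mean(c(mu_m, mu_d)), 3 / sqrt(n))
})

test_that("field ground-truth labels follow the requested association fraction", {
  f1 <- generate_field(field_params(n_maxima = 40, assoc_fraction_true = 1,
                                    seed = 1))
  expect_true(all(f1$truth$associated))

  f0 <- generate_field(field_params(n_maxima = 40, assoc_fraction_true = 0,
                                    er_coverage = 0.3, seed = 2))
  expect_false(any(f0$truth$associated))
  centers <- f0$er$pixels[cbind(f0$truth$y + 1, f0$truth$x + 1)]
  expect_true(all(centers <= f0$params$background_max))

  f8 <- generate_field(field_params(n_maxima = 1000, assoc_fraction_true = 0.8,
                                    img_size = c(512, 512), seed = 3))
  expect_equal(sum(f8$truth$associated), 800L)
  expect_equal(nrow(f8$truth), 1000L)
})

test_that("an unplaceable spot request errors", {
  expect_error(
    generate_field(field_params(n_maxima = 2000, img_size = c(64, 64),
                                seed = 1)),
    "not placeable")
})

test_that("FRAP traces follow the closed-form recovery and decay", {
  # immobile, noiseless: normalized post-bleach trace is constant
  sim <- generate_frap_series(frap_sim_params(
    mobile_fraction_true = 0, noise_sd = 0, incidental_rate = 0.02,
    n_bleach = 3, n_reference = 2, n_background = 5, seed = 1))
  res <- measure_frap_cohort(sim)
  post <- sim$stack$bleach_frame:length(sim$stack$timestamps)
  expect_lt(max(apply(res$normalized[post, , drop = FALSE], 2, sd)), 1e-9)

  # fully mobile with fast kinetics returns to the pre-bleach level
  sim2 <- generate_frap_series(frap_sim_params(
    mobile_fraction_true = 1, rate_k = 5, noise_sd = 0,
    n_bleach = 3, n_reference = 2, n_background = 5, seed = 2))
  res2 <- suppressWarnings(measure_frap_cohort(sim2))
  nt <- nrow(res2$normalized)
  expect_equal(unname(res2$normalized[nt, ]), rep(1, 3), tolerance = 1e-3)

  # incidental decay: reference trace ratio over 100 frames equals e^-1
  sim3 <- generate_frap_series(frap_sim_params(
    incidental_rate = 0.01, pre_frames = 10, post_frames = 91,
    noise_sd = 0, n_bleach = 2, n_reference = 3, n_background = 5, seed = 3))
  corrected <- correct_bias(sim3$stack, sim3$background, background_frames = 5)
  ref_mask <- Reduce(`|`, build_bleach_rois(sim3$reference_points,
                                            dim(corrected$frames)[1:2]))
  ser <- frap_series(corrected, list(ref_mask), ref_mask)
  ref <- ser$reference_trace
  expect_equal(ref[101] / ref[1], exp(-1), tolerance = 1e-9)
})

test_that("frap parameter invariants are enforced", {
  expect_error(frap_sim_params(mobile_fraction_true = 1.2), "mobile_fraction")
  expect_error(frap_sim_params(rate_k = 0), "rate_k")
  expect_error(frap_sim_params(post_frames = 2), "fit impossible")
})

test_that("densitometry tables hit the requested pellet fraction", {
  t0 <- generate_densitometry(5, c("26" = 0.5), noise_cv = 0, seed = 1)
  expect_equal(t0$pellet, t0$supernatant)
  t1 <- generate_densitometry(5, c("42" = 1), noise_cv = 0.1, seed = 2)
  expect_true(all(t1$supernatant == 0))
  # CLT: 1000 rows at cv 0.1 recover the mean fraction within 0.01
  t2 <- generate_densitometry(1000, c("42" = 0.9), noise_cv = 0.1, seed = 3)
  expect_equal(mean(t2$pellet / (t2$pellet + t2$supernatant)), 0.9,
               tolerance = 0.01 / 0.9)
})

test_that("write_synthetic writes channels plus a truth sidecar that round-trips", {
  dir <- withr::local_tempdir()
  sim <- generate_cell_pair(cell_pair_params(snr = 10, seed = 4))
  write_synthetic(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("reporter.tif", "marker.tif",
                                               "truth.json")))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$ratio_true, sim$geometry$ratio_true)
  back <- read_tiff(file.path(dir, "reporter.tif"))
  expect_equal(back$pixels, round(sim$reporter$pixels), tolerance = 1e-12)

  dir2 <- withr::local_tempdir()
  tab <- generate_densitometry(3, c("26" = 0.1, "42" = 0.9), seed = 5)
  write_synthetic(tab, dir2)
  back2 <- read_densitometry(file.path(dir2, "densitometry.csv"))
  expect_equal(back2$pellet, tab$pellet, tolerance = 1e-6)
})
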