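test_that("phantom truth area and radius follow from the semi-axes", {
  spec <- phantom_spec(shape = 64, spacing = 0.75, semi_axes = c(12, 10),
                       lv_radius = 13, aorta_length = 8, lv_depth = 10)
  ph <- generate_phantom(spec)
  expect_equal(ph$truth$area, 120 * pi)
  expect_equal(ph$truth$r_true, sqrt(120), tolerance = 1e-12)
  expect_equal(ph$truth$r_true, sqrt(ph$truth$area / pi), tolerance = 1e-9)
})

test_that("phantom spec validation catches impossible geometry", {
  expect_error(phantom_spec(semi_axes = c(5, 8)), "a >= b")
  expect_error(phantom_spec(semi_axes = c(12, 10), lv_radius = 10), "lv_radius")
  expect_error(phantom_spec(shape = 24, spacing = 1, semi_axes = c(12, 10),
                            lv_radius = 13), "exceeds volume bounds")
})

test_that("all five classes appear and LA/OCS stay clear of the LV-Ao interface", {
  ph <- generate_phantom(phantom_spec(shape = 96, spacing = 0.5,
                                      semi_axes = c(8, 6), lv_radius = 9,
                                      aorta_length = 8, lv_depth = 10,
                                      include_la_ocs = TRUE))
  codes <- sort(unique(as.vector(ph$volume$grid)))
  expect_equal(codes, 0:4)
  # boundary extraction is unaffected by the extra structures
  pts <- extract_boundary_points(ph$volume)
  d <- abs(as.matrix(pts) %*% ph$truth$normal - sum(ph$truth$center * ph$truth$normal))
  expect_lt(max(d), sqrt(sum(ph$volume$spacing^2)) / 2 + 1e-9)
})

test_that("tilted phantoms: fitted plane recovers the generating normal within 2 degrees", {
  ph <- small_phantom(normal = c(1, 0, 2), spacing = 0.5)
  pts <- extract_boundary_points(ph$volume)
  pl <- fit_plane_pca(pts)
  expect_lt(angle_between_deg(pl$normal, ph$truth$normal), 2)
})

test_that("voxelized annulus area converges to pi*a*b as spacing shrinks", {
  errs <- vapply(c(1.0, 0.5, 0.25), function(sp) {
    ph <- small_phantom(normal = c(2, 1, 4), spacing = sp, extent = 40)
    est <- estimate_annulus(extract_boundary_points(ph$volume))
    abs(est$area - ph$truth$area) / ph$truth$area
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.01)
  expect_lt(errs[3], 0.03)
})

test_that("noise-free simulated detections yield two 32x32 ROIs per frame", {
  truth <- annulus_truth(c(0, 0, 0), c(0, 0, 1), c(12, 10))
  frames <- make_slice_frames(truth$plane, pixel_mm = 0.5)
  dets <- simulate_detections(truth, frames)
  expect_equal(nrow(dets), 360)
  expect_true(all(dets$w == 32 & dets$h == 32))
  expect_equal(sort(unique(dets$angle_deg)), as.numeric(1:180))
})

test_that("detection simulation is reproducible under a seed and honors rates", {
  truth <- annulus_truth(c(0, 0, 0), c(1, 1, 6), c(12, 10))
  frames <- make_slice_frames(truth$plane, pixel_mm = 0.5)
  a <- simulate_detections(truth, frames, jitter_mm = 0.5, p_miss = 0.2,
                           fp_per_slice = 0.4, seed = 99)
  b <- simulate_detections(truth, frames, jitter_mm = 0.5, p_miss = 0.2,
                           fp_per_slice = 0.4, seed = 99)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_detections(truth, frames, jitter_mm = 0.5, p_miss = 0.2,
                            fp_per_slice = 0.4, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))

  # empirical miss fraction near p_miss (3 sigma binomial, n = 360)
  miss <- 1 - sum(a$source == "annulus") / 360
  expect_lt(abs(miss - 0.2), 3 * sqrt(0.2 * 0.8 / 360))
  # spurious count near Poisson mean
  n_fp <- sum(a$source == "spurious")
  expect_lt(abs(n_fp - 0.4 * 180), 3 * sqrt(0.4 * 180))
  expect_error(simulate_detections(truth, frames, p_miss = 1.5), "p_miss")
})

test_that("spurious ROIs are flagged FP by IoU matching against the true ROIs", {
  truth <- annulus_truth(c(0, 0, 0), c(0, 1, 3), c(12, 10))
  frames <- make_slice_frames(truth$plane, angles = seq(10, 180, by = 10),
                              pixel_mm = 0.5)
  gt <- simulate_detections(truth, frames)
  noisy <- simulate_detections(truth, frames, fp_per_slice = 0.5, seed = 3)
  res <- match_detections(noisy, gt)
  n_spur <- sum(noisy$source == "spurious")
  # spurious boxes dropped far from the ring essentially never reach IoU 0.5
  expect_gte(res$fp, n_spur - 1)
  expect_equal(res$tp + res$fp, nrow(noisy))
})

test_that("frames that cannot meet the ellipse are refused", {
  truth <- annulus_truth(c(0, 0, 0), c(0, 0, 1), c(12, 10))
  off_plane <- plane_frame(c(0, 0, 40), c(1, 0, 0))  # axis in the truth plane
  frames <- make_slice_frames(off_plane, angles = 90, pixel_mm = 0.5)
  expect_error(simulate_detections(truth, frames), "ellipse")
})
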