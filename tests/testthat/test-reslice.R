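test_that("default frame set covers 1 to 180 degrees and rotates the in-plane basis", {
  pl <- plane_frame(c(10, 10, 10), c(0, 0, 1))
  frames <- make_slice_frames(pl, pixel_mm = 0.5)
  expect_equal(length(frames), 180)
  expect_equal(frames$angles, as.numeric(1:180))

  f90 <- slice_frame(frames, 90)
  expect_lt(abs(sum(f90$dir_u * pl$basis_e1)), 1e-9)
  # 180 degrees: same plane as e1, direction negated
  f180 <- slice_frame(frames, 180)
  expect_equal(f180$dir_u, -pl$basis_e1, tolerance = 1e-9)
  # every frame contains the axis as its v direction
  expect_equal(f90$dir_v, pl$normal)
  expect_lt(abs(sum(f90$dir_u * f90$dir_v)), 1e-12)

  expect_error(make_slice_frames(pl, angles = numeric(0)), "empty")
  expect_error(make_slice_frames(pl, angles = c(10, 190)), "0, 180")
  expect_error(slice_frame(frames, 90.5), "no frame")
})

test_that("world/pixel mappings are mutually inverse to 1e-9 mm", {
  pl <- plane_frame(c(3, -2, 8), c(1, 2, 5))
  frames <- make_slice_frames(pl, angles = c(13, 77, 141), pixel_mm = 0.37,
                              width = 96, height = 80)
  set.seed(6)
  for (a in frames$angles) {
    fr <- slice_frame(frames, a)
    cx <- runif(10, 0, 96); cy <- runif(10, 0, 80)
    w <- pixel_to_world(fr, cx, cy)
    px <- world_to_pixel(fr, w)
    expect_equal(px$cx, cx, tolerance = 1e-9)
    expect_equal(px$cy, cy, tolerance = 1e-9)
  }
})

test_that("constant volumes reslice to constant images", {
  g <- array(3L, dim = c(20, 20, 20))
  vol <- label_volume(g, label_map = c(Ao = 3L))
  pl <- plane_frame(c(9.5, 9.5, 9.5), c(1, 1, 1))
  fr <- slice_frame(make_slice_frames(pl, angles = 45, pixel_mm = 1,
                                      width = 12, height = 12), 45)
  img <- reslice_volume(vol, fr)
  expect_true(all(img == 3))
  img_tl <- reslice_volume(vol, fr, interpolation = "trilinear")
  expect_true(all(abs(img_tl - 3) < 1e-9))
})

test_that("a frame fully outside the volume is an error", {
  vol <- two_block_volume(4)
  pl <- plane_frame(c(1000, 1000, 1000), c(0, 0, 1))
  fr <- slice_frame(make_slice_frames(pl, angles = 90, pixel_mm = 1,
                                      width = 8, height = 8), 90)
  expect_error(reslice_volume(vol, fr), "outside the volume")
})

test_that("slices of a circular annulus phantom agree across angles", {
  ph <- small_phantom(normal = c(0, 0, 1), spacing = 0.5, semi_axes = c(8, 8))
  frames <- make_slice_frames(ph$truth$plane, angles = c(45, 90, 135, 180),
                              pixel_mm = 0.5, width = 72, height = 72)
  counts <- vapply(frames$angles, function(a) {
    sum(reslice_volume(ph$volume, slice_frame(frames, a)) == 3)
  }, numeric(1))
  # rotational symmetry: Ao cross-section area stable over angle
  expect_lt(diff(range(counts)) / mean(counts), 0.05)
})

test_that("a slice shows two boundary crossings matching the analytic chord", {
  ph <- small_phantom(normal = c(0, 0, 1), spacing = 0.5, semi_axes = c(8, 6))
  frames <- make_slice_frames(ph$truth$plane, angles = c(30, 90, 160),
                              pixel_mm = 0.5, width = 80, height = 80)
  dets <- simulate_detections(ph$truth, frames)
  for (a in frames$angles) {
    fr <- slice_frame(frames, a)
    img <- reslice_volume(ph$volume, fr)
    # row just above the annulus plane (dir_v is the normal)
    j <- ceiling(fr$height / 2) + 1
    runs <- rle(img[, j] == 3)
    expect_equal(sum(runs$values), 1)  # a single Ao chord
    ao_cols <- which(img[, j] == 3)
    # chord endpoints within a voxel of the simulated ROI centers
    d <- dets[dets$angle_deg == a, ]
    centers_px <- sort(d$x + d$w / 2)
    expect_lt(abs(min(ao_cols) - 1 - centers_px[1]), 2)
    expect_lt(abs(max(ao_cols) - 1 - centers_px[2]), 2)
  }
})

test_that("ROI centers back-project to the expected world points", {
  pl <- plane_frame(c(5, 6, 7), c(2, -1, 4))
  frames <- make_slice_frames(pl, angles = 1:180, pixel_mm = 0.5,
                              width = 128, height = 128)
  # box centered at the grid center maps to the centroid
  dets <- tibble::tibble(angle_deg = 37, x = 64 - 16, y = 64 - 16,
                         w = 32, h = 32, confidence = 1)
  pt <- backproject_roi_centers(dets, frames)
  expect_equal(as.numeric(pt), c(5, 6, 7), tolerance = 1e-9)

  # one ROI per angle: count preserved, order preserved
  many <- tibble::tibble(angle_deg = 1:180, x = 10, y = 20, w = 32, h = 32,
                         confidence = 0.9)
  cloud <- backproject_roi_centers(many, frames)
  expect_equal(nrow(cloud), 180)

  # unknown angle is an error
  bad <- tibble::tibble(angle_deg = 200, x = 0, y = 0, w = 1, h = 1,
                        confidence = 1)
  expect_error(backproject_roi_centers(bad, frames), "without a matching frame")
})

test_that("marked world points return to themselves through the slice geometry", {
  truth <- annulus_truth(c(20, 20, 20), c(1, 1, 5), c(10, 8))
  frames <- make_slice_frames(truth$plane, pixel_mm = 0.25)
  dets <- simulate_detections(truth, frames)
  cloud <- as.matrix(backproject_roi_centers(dets, frames))
  # every back-projected center lies on the truth ellipse: plane distance 0
  d <- cloud %*% truth$normal - sum(truth$center * truth$normal)
  expect_lt(max(abs(d)), 1e-9)
  uv <- project_to_plane(cloud, truth$plane)
  val <- (uv$u / truth$semi_axes[1])^2 + (uv$v / truth$semi_axes[2])^2
  expect_equal(val, rep(1, nrow(uv)), tolerance = 1e-9)
})

test_that("collinear detections cannot define an annulus", {
  pl <- plane_frame(c(0, 0, 0), c(0, 0, 1))
  frames <- make_slice_frames(pl, angles = 90, pixel_mm = 1)
  dets <- tibble::tibble(angle_deg = 90, x = c(10, 20, 30), y = 50,
                         w = 32, h = 32, confidence = 1)
  expect_error(estimate_annulus_from_detections(dets, frames),
               class = "annulaR_degenerate_error")
})

test_that("frame geometry round-trips through the JSON sidecar", {
  pl <- plane_frame(c(1, 2, 3), c(3, 1, 9))
  frames <- make_slice_frames(pl, angles = seq(5, 180, by = 5), pixel_mm = 0.4,
                              width = 64, height = 72)
  p <- withr::local_tempfile(fileext = ".json")
  write_frames_json(frames, p)
  back <- read_frames_json(p)
  expect_equal(back$angles, frames$angles)
  expect_equal(back$dir_u, frames$dir_u, tolerance = 1e-12)
  expect_equal(back$origin, frames$origin)
  expect_equal(back$pixel_mm, frames$pixel_mm)
  expect_equal(back$width, frames$width)
})
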