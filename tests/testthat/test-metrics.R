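test_that("voxel Dice matches closed forms", {
  a <- array(FALSE, dim = c(5, 5, 4)); a[1:2, , ] <- TRUE
  expect_equal(dice_voxel(a, a), 1.0)
  b <- array(FALSE, dim = c(5, 5, 4)); b[4:5, , ] <- TRUE
  expect_equal(dice_voxel(a, b), 0.0)
  # |A| = |B| = 100, |A & B| = 80
  a2 <- c(rep(TRUE, 100), rep(FALSE, 40))
  b2 <- c(rep(TRUE, 80), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 20))
  expect_equal(dice_voxel(a2, b2), 0.8)
  expect_equal(dice_voxel(logical(5), logical(5)), 1.0)
  expect_error(dice_voxel(a, array(FALSE, dim = c(5, 5, 5))), "shape")
})

test_that("box IoU matches closed-form rectangle overlap", {
  expect_equal(iou_box(c(0, 0, 2, 3), c(0, 0, 2, 3)), 1.0)
  expect_equal(iou_box(c(0, 0, 1, 1), c(5, 5, 1, 1)), 0.0)
  expect_equal(iou_box(c(0, 0, 1, 1), c(0.5, 0, 1, 1)), 1 / 3)
  expect_equal(iou_box(c(0, 0, 4, 2), c(2, 1, 4, 2)), 2 / 14)
  expect_error(iou_box(c(0, 0, 0, 1), c(0, 0, 1, 1)), "positive")
})

test_that("matching resolves canonical small instances", {
  gt <- tibble::tibble(angle_deg = 1, x = 0, y = 0, w = 10, h = 10)
  d1 <- tibble::tibble(angle_deg = 1, x = 2, y = 0, w = 10, h = 10,
                       confidence = 0.9)
  r1 <- match_detections(d1, gt)
  expect_equal(c(r1$tp, r1$fp, r1$fn), c(1, 0, 0))

  # two detections on one ground truth: one-to-one matching
  d2 <- tibble::tibble(angle_deg = 1, x = c(1, 2), y = 0, w = 10, h = 10,
                       confidence = c(0.9, 0.8))
  r2 <- match_detections(d2, gt)
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(1, 1, 0))

  # missed ground truths
  gt2 <- tibble::tibble(angle_deg = c(1, 2), x = 0, y = 0, w = 10, h = 10)
  r3 <- match_detections(d1[0, ], gt2)
  expect_equal(c(r3$tp, r3$fp, r3$fn), c(0, 0, 2))
})

test_that("bookkeeping identities hold and greedy matching equals exhaustive assignment", {
  set.seed(77)
  for (rep in 1:25) {
    n_gt <- sample(0:4, 1); n_det <- sample(0:4, 1)
    gt <- tibble::tibble(angle_deg = 1, x = runif(n_gt, 0, 40),
                         y = runif(n_gt, 0, 40), w = runif(n_gt, 5, 15),
                         h = runif(n_gt, 5, 15))
    dets <- tibble::tibble(angle_deg = 1, x = runif(n_det, 0, 40),
                           y = runif(n_det, 0, 40), w = runif(n_det, 5, 15),
                           h = runif(n_det, 5, 15),
                           confidence = runif(n_det))
    res <- match_detections(dets, gt)
    expect_equal(res$tp + res$fn, n_gt)
    expect_equal(res$tp + res$fp, n_det)
    oracle <- brute_best_tp(dets[, c("x", "y", "w", "h")],
                            gt[, c("x", "y", "w", "h")])
    expect_equal(res$tp, oracle)
  }
})

test_that("AP is the single-threshold precision TP / (TP + FP)", {
  gt <- tibble::tibble(angle_deg = 1:10, x = 0, y = 0, w = 10, h = 10)
  dets <- tibble::tibble(angle_deg = 1:10, x = c(rep(0, 9), 50),
                         y = 0, w = 10, h = 10, confidence = 0.9)
  res <- match_detections(dets, gt)
  expect_equal(c(res$tp, res$fp), c(9, 1))
  expect_equal(average_precision(res), 0.9)

  all_wrong <- dplyr::mutate(dets, x = 100)
  expect_equal(average_precision(match_detections(all_wrong, gt)), 0.0)
  expect_error(average_precision(match_detections(dets[0, ], gt)), "no detections")
})

test_that("average miss rate is the mean per-slice missed fraction", {
  gt <- tibble::tibble(angle_deg = rep(1:4, each = 2),
                       x = rep(c(0, 20), 4), y = 0, w = 10, h = 10)
  hit_all <- tibble::tibble(angle_deg = rep(1:4, each = 2),
                            x = rep(c(0, 20), 4), y = 0, w = 10, h = 10,
                            confidence = 0.9)
  expect_equal(average_miss_rate(match_detections(hit_all, gt)), 0.0)
  expect_equal(average_miss_rate(match_detections(hit_all[0, ], gt)), 1.0)
  # half the slices fully missed, half fully found
  half <- hit_all[hit_all$angle_deg <= 2, ]
  expect_equal(average_miss_rate(match_detections(half, gt)), 0.5)
})

test_that("raster DSC and voxel Dice agree on the same binary raster", {
  # two overlapping axis-aligned squares rasterized identically by hand
  plane <- plane_frame(c(0, 0, 0), c(0, 0, 1))
  a <- annulus_estimate(plane, data.frame(u = c(0, 4, 4, 0), v = c(0, 0, 4, 4)))
  b <- annulus_estimate(plane, data.frame(u = c(2, 6, 6, 2), v = c(0, 0, 4, 4)))
  px <- 0.1
  gx <- seq(0 + px / 2, 6, by = px); gy <- seq(0 + px / 2, 4, by = px)
  grid <- expand.grid(x = gx, y = gy)
  mask_a <- grid$x < 4 & grid$y < 4
  mask_b <- grid$x > 2 & grid$y < 4
  expect_equal(area_dsc_2d(a, b, raster_mm = px), dice_voxel(mask_a, mask_b),
               tolerance = 0.01)
})

test_that("fold summaries use the sample SD and reproduce the reported convention", {
  s <- summarize_folds(c(0.729, 0.646, 0.800, 0.726, 0.664))
  expect_equal(s$mean, 0.713)
  expect_lte(abs(s$mean - 0.711), 0.005)  # printed rounding of the source table
  expect_equal(s$sd, stats::sd(c(0.729, 0.646, 0.800, 0.726, 0.664)))
  expect_equal(s$sd, 0.06, tolerance = 0.1)

  s2 <- summarize_folds(c(0.853, 0.726, 0.848, 0.777, 0.847))
  expect_equal(s2$mean, 0.8102)

  expect_equal(summarize_folds(rep(0.5, 4))$sd, 0)
  expect_error(summarize_folds(0.7), "at least 2")

  pop <- summarize_folds(c(1, 2, 3), population = TRUE)
  expect_equal(pop$sd, sqrt(2 / 3))
  expect_true(s$mean >= min(s$per_fold) && s$mean <= max(s$per_fold))
})
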