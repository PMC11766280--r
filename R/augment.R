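#' Rotation/scale augmentation grid
#'
#' Produces one augmented image per (angle, scale) pair: rotation about the
#' image center followed by isotropic scaling, bilinear interpolation, same
#' canvas, zeros outside. The default grids — rotations in 5-degree
#' increments from -30 to 30 degrees (13 angles) and scales in 0.1
#' increments from 0.8 to 1.2 (5 scales) — give the 65-fold expansion used
#' for training-set augmentation; rotation alone gives the 13-fold
#' expansion.
#'
#' @param image Numeric matrix (a 2D image).
#' @param angles_deg Rotation angles in degrees; default
#'   `seq(-30, 30, by = 5)`.
#' @param scales Isotropic scale factors; default `seq(0.8, 1.2, by = 0.1)`.
#' @return Tibble with columns `angle_deg`, `scale` and a list-column
#'   `image`, one row per pair (angles vary fastest).
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' nrow(augment_grid(img))                      # 65
#' nrow(augment_grid(img, scales = 1))          # 13
#' @export
augment_grid <- function(image, angles_deg = seq(-30, 30, by = 5),
                         scales = seq(0.8, 1.2, by = 0.1)) {
  if (!is.matrix(image) || !is.numeric(image)) abort_input("image must be a numeric matrix")
  if (length(angles_deg) == 0 || length(scales) == 0) abort_input("empty augmentation grid")
  grid <- tibble::tibble(
    angle_deg = rep(angles_deg, times = length(scales)),
    scale = rep(scales, each = length(angles_deg))
  )
  grid$image <- purrr::map2(grid$angle_deg, grid$scale,
                            function(a, s) warp_rotate_scale(image, a, s))
  grid
}

# Inverse-mapped rotation about the center then isotropic scale; bilinear
# sampling, zero fill outside the source canvas.
warp_rotate_scale <- function(image, angle_deg, scale) {
  h <- nrow(image); w <- ncol(image)
  if (abs(angle_deg) < 1e-12 && abs(scale - 1) < 1e-12) return(image)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- -angle_deg * pi / 180  # inverse rotation
  yy <- (rep(seq_len(h), times = w) - cy) / scale
  xx <- (rep(seq_len(w), each = h) - cx) / scale
  sx <- cos(th) * xx - sin(th) * yy + cx
  sy <- sin(th) * xx + cos(th) * yy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- numeric(length(sx))
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    xc <- x0 + corner[1]; yc <- y0 + corner[2]
    wgt <- (if (corner[1] == 1) fx else 1 - fx) * (if (corner[2] == 1) fy else 1 - fy)
    ok <- xc >= 1 & xc <= w & yc >= 1 & yc <= h & wgt > 0
    val[ok] <- val[ok] + wgt[ok] * image[cbind(yc[ok], xc[ok])]
  }
  matrix(val, nrow = h, ncol = w)
}

#' Cross-validation image-count arithmetic under augmentation
#'
#' Given the per-fold test-image counts of a patient-level k-fold split and
#' an augmentation factor, reconstructs the fold-wise raw and augmented
#' training-image counts. The folds partition the cohort, so the total raw
#' image count is the sum of the per-fold test counts, and each fold trains
#' on `(total - n_test) * factor` augmented images.
#'
#' @param test_counts Integer vector of test images per fold.
#' @param factor Augmentation multiplier (e.g.
#'   `augmentation_factor()` = 65, or 13 for rotation only).
#' @return Tibble with columns `fold`, `n_test`, `n_train_raw`,
#'   `n_train_augmented`.
#' @examples
#' fold_image_counts(c(3712, 3922, 3216, 3472, 3472), factor = 65)
#' @export
fold_image_counts <- function(test_counts, factor = 65) {
  test_counts <- as.numeric(test_counts)
  if (length(test_counts) < 2 || any(test_counts <= 0)) {
    abort_input("need per-fold test counts (positive, >= 2 folds)")
  }
  total <- sum(test_counts)
  tibble::tibble(
    fold = seq_along(test_counts),
    n_test = test_counts,
    n_train_raw = total - test_counts,
    n_train_augmented = (total - test_counts) * factor
  )
}

#' Augmentation factor of a rotation/scale grid
#'
#' @inheritParams augment_grid
#' @return Number of augmented images produced per original.
#' @export
augmentation_factor <- function(angles_deg = seq(-30, 30, by = 5),
                                scales = seq(0.8, 1.2, by = 0.1)) {
  if (length(angles_deg) == 0 || length(scales) == 0) abort_input("empty augmentation grid")
  length(angles_deg) * length(scales)
}
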