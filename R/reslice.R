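#' Build rotated slice frames about the annulus normal
#'
#' Sections are reconstructed about the rotation axis formed by the plane
#' normal through the cloud's center of gravity. The slice at angle theta is
#' spanned by `dir_u = d(theta)` — `basis_e1` rotated about the normal by
#' theta (Rodrigues; `d(0) = basis_e1`) — and `dir_v =` the normal itself,
#' so every slice contains the rotation axis and the annulus ring appears
#' as two cross-sections per slice. Angles run over (0, 180] degrees;
#' theta and theta + 180 span the same plane, which is why a half-turn
#' covers the full revolution.
#'
#' @param plane A `fitted_plane` whose centroid/normal define the axis.
#' @param angles Angles in degrees, each in (0, 180]. Default `1:180`.
#' @param pixel_mm Sampling pitch of the slice grid in mm (default 0.5; use
#'   the volume's minimum voxel spacing when reslicing a volume).
#' @param width,height Slice grid size in pixels (default 128 x 128),
#'   centered on the centroid.
#' @return A `slice_frames` object; individual frames via [slice_frame()].
#' @export
make_slice_frames <- function(plane, angles = 1:180, pixel_mm = 0.5,
                              width = 128L, height = 128L) {
  validate_plane(plane)
  angles <- as.numeric(angles)
  if (length(angles) == 0) abort_input("empty angle list")
  if (any(!is.finite(angles)) || any(angles <= 0 | angles > 180)) {
    abort_input("angles must lie in (0, 180] degrees")
  }
  if (pixel_mm <= 0) abort_input("pixel_mm must be positive")
  th <- angles * pi / 180
  # n . e1 = 0, so Rodrigues reduces to d = e1 cos(th) + e2 sin(th)
  u <- outer(cos(th), plane$basis_e1) + outer(sin(th), plane$basis_e2)
  structure(
    list(angles = angles, dir_u = u, origin = plane$centroid,
         axis = plane$normal, pixel_mm = pixel_mm,
         width = as.integer(width), height = as.integer(height)),
    class = "slice_frames"
  )
}

#' @export
print.slice_frames <- function(x, ...) {
  cat(sprintf("<slice_frames> %d frames, %d x %d px at %.3g mm/px, axis %s\n",
              length(x$angles), x$width, x$height, x$pixel_mm,
              paste(signif(x$axis, 4), collapse = ", ")))
  invisible(x)
}

#' @export
length.slice_frames <- function(x) length(x$angles)

#' Extract a single slice frame
#'
#' @param frames A `slice_frames` object.
#' @param angle_deg Angle to extract; matched exactly (tolerance 1e-6
#'   degrees).
#' @return List with `angle_deg`, `origin`, `dir_u`, `dir_v`, `pixel_mm`,
#'   `width`, `height`.
#' @export
slice_frame <- function(frames, angle_deg) {
  stopifnot(inherits(frames, "slice_frames"))
  k <- which(abs(frames$angles - angle_deg) <= 1e-6)
  if (length(k) == 0) abort_input(paste0("no frame at angle ", angle_deg, " degrees"))
  k <- k[1]
  list(angle_deg = frames$angles[k], origin = frames$origin,
       dir_u = frames$dir_u[k, ], dir_v = frames$axis,
       pixel_mm = frames$pixel_mm, width = frames$width, height = frames$height)
}

# Continuous pixel coordinates (cx, cy) of world points in a frame, using
# 0-based pixel indices: world = origin + (cx - width/2) * pixel_mm * dir_u
#                                + (cy - height/2) * pixel_mm * dir_v.
world_to_pixel <- function(frame, points) {
  m <- as_xyz_matrix(points)
  q <- sweep(m, 2, frame$origin)
  tibble::tibble(
    cx = as.numeric(q %*% frame$dir_u) / frame$pixel_mm + frame$width / 2,
    cy = as.numeric(q %*% frame$dir_v) / frame$pixel_mm + frame$height / 2
  )
}

pixel_to_world <- function(frame, cx, cy) {
  s <- (cx - frame$width / 2) * frame$pixel_mm
  t <- (cy - frame$height / 2) * frame$pixel_mm
  w <- matrix(frame$origin, nrow = length(cx), ncol = 3, byrow = TRUE) +
    s %o% frame$dir_u + t %o% frame$dir_v
  xyz_tibble(w)
}

#' Reslice a volume along a rotated frame
#'
#' Samples the volume on the frame's pixel grid. Pixel `(i, j)` (0-based)
#' samples the world point
#' `origin + (i - width/2) * pixel_mm * dir_u + (j - height/2) * pixel_mm * dir_v`.
#' Samples outside the volume return 0 (background). Label volumes default
#' to nearest-neighbor sampling; `trilinear` is available for scalar
#' volumes.
#'
#' @param vol A [label_volume()] or a plain 3D array (unit spacing, zero
#'   origin).
#' @param frame A single frame from [slice_frame()].
#' @param interpolation `"nearest"` (default) or `"trilinear"`.
#' @return `width x height` numeric matrix; `[i, j]` is pixel
#'   `(i-1, j-1)`.
#' @export
reslice_volume <- function(vol, frame, interpolation = c("nearest", "trilinear")) {
  interpolation <- match.arg(interpolation)
  if (inherits(vol, "label_volume")) {
    g <- vol$grid; spacing <- vol$spacing; origin <- vol$origin
  } else if (is.array(vol) && length(dim(vol)) == 3) {
    g <- vol; spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  } else {
    abort_input("vol must be a label_volume or a 3D array")
  }
  w <- frame$width; h <- frame$height
  i0 <- rep(seq_len(w) - 1, times = h)
  j0 <- rep(seq_len(h) - 1, each = w)
  world <- pixel_to_world(frame, i0, j0)
  idx <- sweep(sweep(as_xyz_matrix(world), 2, origin), 2, spacing, "/")
  d <- dim(g)
  vals <- numeric(length(i0))
  if (interpolation == "nearest") {
    r <- round(idx)
    ok <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
      r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
      r[, 3] >= 0 & r[, 3] <= d[3] - 1
    if (!any(ok)) abort_input("frame lies fully outside the volume")
    lin <- r[ok, 1] + d[1] * (r[ok, 2] + d[2] * r[ok, 3]) + 1
    vals[ok] <- g[lin]
  } else {
    f <- floor(idx)
    frac <- idx - f
    any_in <- rep(FALSE, length(i0))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      cx <- f[, 1] + dx; cy <- f[, 2] + dy; cz <- f[, 3] + dz
      wgt <- (if (dx == 1) frac[, 1] else 1 - frac[, 1]) *
        (if (dy == 1) frac[, 2] else 1 - frac[, 2]) *
        (if (dz == 1) frac[, 3] else 1 - frac[, 3])
      ok <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 &
        cz >= 0 & cz <= d[3] - 1
      any_in <- any_in | (ok & wgt > 0)
      lin <- cx[ok] + d[1] * (cy[ok] + d[2] * cz[ok]) + 1
      vals[ok] <- vals[ok] + wgt[ok] * g[lin]
    }
    if (!any(any_in)) abort_input("frame lies fully outside the volume")
  }
  matrix(vals, nrow = w, ncol = h)
}

#' Back-project ROI centers into 3D
#'
#' Converts per-slice bounding-box detections into one 3D point cloud: each
#' box's center `(x + w/2, y + h/2)` in pixel units is mapped through its
#' slice frame's geometry back to world mm. Slices that yielded two annulus
#' ROIs (the usual case — a section through the ring cuts it twice)
#' contribute both points.
#'
#' @param dets Detection tibble (see [read_detections()]).
#' @param frames A `slice_frames` object; every detection's `angle_deg`
#'   must have a matching frame (tolerance 1e-6 degrees).
#' @return Tibble with columns `x, y, z` (mm), one row per detection, in
#'   input order.
#' @export
backproject_roi_centers <- function(dets, frames) {
  dets <- validate_detections(dets)
  stopifnot(inherits(frames, "slice_frames"))
  if (nrow(dets) == 0) return(xyz_tibble(matrix(numeric(0), ncol = 3)))
  k <- vapply(dets$angle_deg, function(a) {
    hit <- which(abs(frames$angles - a) <= 1e-6)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (any(is.na(k))) {
    abort_input(paste0("detection angle(s) without a matching frame: ",
                       paste(unique(dets$angle_deg[is.na(k)]), collapse = ", ")))
  }
  cx <- dets$x + dets$w / 2
  cy <- dets$y + dets$h / 2
  s <- (cx - frames$width / 2) * frames$pixel_mm
  t <- (cy - frames$height / 2) * frames$pixel_mm
  w <- matrix(frames$origin, nrow = nrow(dets), ncol = 3, byrow = TRUE) +
    s * frames$dir_u[k, , drop = FALSE] +
    t %o% frames$axis
  xyz_tibble(w)
}

#' Estimate the annulus from per-slice detections
#'
#' The detection-path composition: back-project ROI centers to a 3D cloud,
#' fit a second PCA plane to that cloud, project, trace the peripheral
#' contour and compute area and equivalent radius.
#'
#' @inheritParams backproject_roi_centers
#' @inheritParams peripheral_contour
#' @return An `annulus_estimate`.
#' @export
estimate_annulus_from_detections <- function(dets, frames,
                                             method = c("convex_hull", "alpha_shape"),
                                             alpha_scale = 2.0) {
  pts <- backproject_roi_centers(dets, frames)
  if (nrow(pts) < 3) abort_degenerate("degenerate cloud: fewer than 3 back-projected points")
  estimate_annulus(pts, method = method, alpha_scale = alpha_scale)
}

#' Write / read slice-frame geometry as JSON
#'
#' The sidecar needed to interpret per-slice detections: origin, rotation
#' axis, the angle list and the pixel grid. `read_frames_json()` rebuilds
#' the `slice_frames` object exactly.
#'
#' @param frames A `slice_frames` object.
#' @param path JSON file path.
#' @return `path` (write) or a `slice_frames` (read).
#' @export
write_frames_json <- function(frames, path) {
  stopifnot(inherits(frames, "slice_frames"))
  # e1 is the frame at the smallest stored angle rotated back to 0 degrees
  obj <- list(origin = frames$origin, axis = frames$axis,
              angles = frames$angles,
              dir_u = apply(frames$dir_u, 1, function(r) r, simplify = FALSE),
              pixel_mm = frames$pixel_mm,
              width = frames$width, height = frames$height)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frames_json
#' @export
read_frames_json <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  obj <- jsonlite::fromJSON(path)
  u <- if (is.list(obj$dir_u)) {
    do.call(rbind, lapply(obj$dir_u, as.numeric))
  } else {
    matrix(as.numeric(obj$dir_u), ncol = 3)
  }
  structure(
    list(angles = as.numeric(obj$angles), dir_u = u,
         origin = as.numeric(obj$origin), axis = as.numeric(obj$axis),
         pixel_mm = as.numeric(obj$pixel_mm),
         width = as.integer(obj$width), height = as.integer(obj$height)),
    class = "slice_frames"
  )
}

#' Export a slice stack as TIFF
#'
#' Writes all frames as a multi-page TIFF (values rescaled to \[0, 1\] by
#' the maximum label code) together with the JSON geometry sidecar required
#' to interpret detections made on the stack.
#'
#' @param vol A [label_volume()].
#' @param frames A `slice_frames` object.
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.frames.json`.
#' @param interpolation Passed to [reslice_volume()].
#' @return `path`, invisibly.
#' @export
export_slices_tiff <- function(vol, frames, path, interpolation = "nearest") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort_input("the 'tiff' package is required for TIFF export")
  }
  mx <- max(1, max(vol$grid))
  pages <- lapply(frames$angles, function(a) {
    t(reslice_volume(vol, slice_frame(frames, a), interpolation)) / mx
  })
  tiff::writeTIFF(pages, path)
  write_frames_json(frames, paste0(path, ".frames.json"))
  invisible(path)
}
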