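#' Specify a synthetic cardiac phantom
#'
#' The phantom emulates the anatomy the pipeline consumes: a tilted aortic
#' tube (elliptical cylinder) meeting a left-ventricular half-ellipsoid so
#' that the LV-Ao interface is a planar elliptical disk of analytically
#' known area `pi * a * b`. Optional LA/OCS blobs exercise the multi-class
#' label handling without touching that interface. The phantom is purely
#' geometric (labels, not Hounsfield intensities): the pipeline under test
#' consumes labels and detections only.
#'
#' Defaults — a 160^3 grid at 0.5 mm with semi-axes 12 x 10 mm — put the
#' annulus at adult anatomical scale (area 120 pi ~ 377 mm^2, equivalent
#' radius ~11 mm).
#'
#' @param shape Voxels per axis (length 3 or scalar).
#' @param spacing mm per voxel (length 3 or scalar).
#' @param annulus_center Annulus disk center, mm; default the volume
#'   center.
#' @param annulus_normal Annulus plane normal (normalized internally).
#' @param semi_axes `c(a, b)` ellipse semi-axes in mm, `a >= b > 0`.
#' @param aorta_length Tube extent along +normal, mm.
#' @param lv_radius In-plane radius of the LV half-ellipsoid, mm; must be
#'   >= `a` so the LV face contains the whole disk.
#' @param lv_depth Extent of the LV cap along -normal, mm.
#' @param include_la_ocs Add LA and OCS blobs away from the interface.
#' @param seed Integer recorded with the phantom description and used by
#'   consumers that draw random quantities from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(160, 160, 160), spacing = c(0.5, 0.5, 0.5),
                         annulus_center = NULL, annulus_normal = c(0, 0, 1),
                         semi_axes = c(12, 10), aorta_length = 20,
                         lv_radius = 18, lv_depth = 22,
                         include_la_ocs = TRUE, seed = 1L) {
  if (length(shape) == 1) shape <- rep(shape, 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(annulus_center)) annulus_center <- (shape - 1) * spacing / 2
  a <- semi_axes[1]; b <- semi_axes[2]
  if (!(a >= b && b > 0)) abort_input("semi_axes must satisfy a >= b > 0")
  if (lv_radius < a) abort_input("lv_radius must be >= the major semi-axis a")
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               annulus_center = as.numeric(annulus_center),
               annulus_normal = unit(as.numeric(annulus_normal)),
               semi_axes = c(a = a, b = b), aorta_length = aorta_length,
               lv_radius = lv_radius, lv_depth = lv_depth,
               include_la_ocs = isTRUE(include_la_ocs), seed = as.integer(seed))
  extent <- spec$shape * spec$spacing
  margin <- a + max(spec$spacing)
  if (any(spec$annulus_center - margin < 0) ||
      any(spec$annulus_center + margin > extent)) {
    abort_input("annulus disk exceeds volume bounds")
  }
  structure(spec, class = "phantom_spec")
}

#' Ground-truth annulus geometry
#'
#' Analytic truth for a phantom: the annulus plane (center, oriented
#' normal, deterministic in-plane basis), ellipse semi-axes, exact area
#' `pi * a * b` and the true equivalent-circle radius
#' `Rt = sqrt(a * b) = sqrt(area / pi)`.
#'
#' @param center,normal Annulus plane, mm / unit vector.
#' @param semi_axes `c(a, b)` in mm.
#' @return An `annulus_truth` object.
#' @export
annulus_truth <- function(center, normal, semi_axes) {
  plane <- plane_frame(center, normal)
  a <- unname(semi_axes[1]); b <- unname(semi_axes[2])
  structure(
    list(plane = plane, center = plane$centroid, normal = plane$normal,
         semi_axes = c(a = unname(a), b = unname(b)),
         area = pi * a * b, r_true = sqrt(a * b)),
    class = "annulus_truth"
  )
}

#' @export
print.annulus_truth <- function(x, ...) {
  cat(sprintf("<annulus_truth> ellipse %g x %g mm, area %.2f mm^2, Rt %.3f mm\n",
              x$semi_axes[1], x$semi_axes[2], x$area, x$r_true))
  invisible(x)
}

#' Truth annulus as a polygon estimate
#'
#' Samples the true ellipse as a closed polygon in the truth plane's frame,
#' for raster overlap against estimates.
#'
#' @param truth An [annulus_truth()].
#' @param n Number of polygon vertices (default 360).
#' @return An `annulus_estimate` in the truth frame.
#' @export
truth_contour <- function(truth, n = 360) {
  stopifnot(inherits(truth, "annulus_truth"))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  annulus_estimate(truth$plane,
                   cbind(u = truth$semi_axes[1] * cos(th),
                         v = truth$semi_axes[2] * sin(th)))
}

#' Generate a labeled phantom volume with known annulus truth
#'
#' Voxel classification in the annulus frame (`d` signed distance to the
#' plane, `(u, v)` in-plane coordinates):
#' * Ao — `0 <= d <= aorta_length` inside the ellipse `(u/a)^2 + (v/b)^2 <= 1`;
#' * LV — `d < 0` inside the half-ellipsoid of in-plane radius `lv_radius`
#'   and depth `lv_depth`;
#' * optional LA / OCS spheres written into background only, placed clear
#'   of the LV-Ao interface;
#' * BG elsewhere.
#'
#' The LV-Ao contact surface is exactly the elliptical disk (up to
#' voxelization), so `extract_boundary_points()` on the result samples the
#' annulus plane.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (a [label_volume()]) and `truth`
#'   (an [annulus_truth()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = 48, spacing = 1,
#'                                     semi_axes = c(8, 6),
#'                                     aorta_length = 10, lv_radius = 10,
#'                                     lv_depth = 12))
#' ph$truth$area  # 48 pi
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- annulus_truth(spec$annulus_center, spec$annulus_normal, spec$semi_axes)
  n <- truth$normal; e1 <- truth$plane$basis_e1; e2 <- truth$plane$basis_e2
  d <- spec$shape
  ax <- lapply(1:3, function(k) (seq_len(d[k]) - 1) * spec$spacing[k] - truth$center[k])
  # separable frame coordinates: f = f1[i] + f2[j] + f3[k]
  frame_coord <- function(vec) {
    outer(outer(ax[[1]] * vec[1], ax[[2]] * vec[2], "+"), ax[[3]] * vec[3], "+")
  }
  dd <- frame_coord(n)
  uu <- frame_coord(e1)
  vv <- frame_coord(e2)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  in_ell <- (uu / a)^2 + (vv / b)^2 <= 1
  grid <- array(0L, dim = d)
  lv <- dd < 0 &
    (uu^2 + vv^2) / spec$lv_radius^2 + (dd / spec$lv_depth)^2 <= 1
  ao <- dd >= 0 & dd <= spec$aorta_length & in_ell
  grid[lv] <- 1L
  grid[ao] <- 3L
  if (spec$include_la_ocs) {
    # spheres clear of the interface: nearest approach to the disk edge
    # leaves > 2 voxel spacings of background
    sp_max <- max(spec$spacing)
    la_c <- truth$center + (b + 10) * e2 - 4 * n
    ocs_c <- truth$center + (a + 12) * e1 - 6 * n
    for (blob in list(list(c = la_c, r = 6, code = 2L),
                      list(c = ocs_c, r = 6, code = 4L))) {
      r2 <- (uu - sum((blob$c - truth$center) * e1))^2 +
        (vv - sum((blob$c - truth$center) * e2))^2 +
        (dd - sum((blob$c - truth$center) * n))^2
      sel <- r2 <= blob$r^2 & grid == 0L
      grid[sel] <- blob$code
    }
    rm(sp_max)
  }
  vol <- label_volume(grid, spacing = spec$spacing, origin = c(0, 0, 0))
  list(volume = vol, truth = truth)
}

#' Write / read annulus ground truth as JSON
#'
#' @param truth An [annulus_truth()].
#' @param path JSON file path.
#' @return `path` (write) or an `annulus_truth` (read).
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "annulus_truth"))
  obj <- list(center = truth$center, normal = truth$normal,
              semi_axes = as.numeric(truth$semi_axes),
              area_mm2 = truth$area, r_true_mm = truth$r_true)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  obj <- jsonlite::fromJSON(path)
  annulus_truth(as.numeric(obj$center), as.numeric(obj$normal),
                as.numeric(obj$semi_axes))
}

#' Simulate per-slice ROI detections of the annulus
#'
#' For each slice frame the two analytic intersections of the slice plane
#' with the true annulus ellipse become square ROIs centered on the
#' intersections (32 x 32 pixels by default, the detector's ROI
#' convention). Detector imperfections are layered on top: isotropic
#' Gaussian jitter of the ROI centers (mm), independent per-ROI misses with
#' probability `p_miss`, and Poisson-distributed spurious boxes placed
#' uniformly over each slice canvas. True ROIs carry confidences drawn from
#' U(0.7, 1), spurious ones from U(0.1, 0.7), emulating a detector that
#' ranks real structure above clutter.
#'
#' @param truth An [annulus_truth()].
#' @param frames A `slice_frames` object (see [make_slice_frames()]);
#'   frames need not share the truth plane's exact axis, but each slice
#'   plane must intersect the ellipse.
#' @param jitter_mm SD of the isotropic center jitter, mm (default 0).
#' @param p_miss Per-ROI drop probability in \[0, 1\] (default 0).
#' @param fp_per_slice Expected spurious boxes per slice (Poisson rate,
#'   default 0).
#' @param roi_px ROI side length in pixels (default 32).
#' @param seed Integer seed; identical seeds give identical detections and
#'   the caller's RNG state is untouched.
#' @return Detection tibble (`angle_deg, x, y, w, h, confidence`) plus a
#'   `source` column (`"annulus"` or `"spurious"`), dropped on write.
#' @export
simulate_detections <- function(truth, frames, jitter_mm = 0, p_miss = 0,
                                fp_per_slice = 0, roi_px = 32, seed = NULL) {
  stopifnot(inherits(truth, "annulus_truth"), inherits(frames, "slice_frames"))
  if (p_miss < 0 || p_miss > 1) abort_input("p_miss must lie in [0, 1]")
  if (jitter_mm < 0) abort_input("jitter_mm must be >= 0")
  if (fp_per_slice < 0) abort_input("fp_per_slice must be >= 0")
  n <- truth$normal; e1 <- truth$plane$basis_e1; e2 <- truth$plane$basis_e2
  a <- truth$semi_axes[1]; b <- truth$semi_axes[2]
  with_local_seed(seed, {
    recs <- purrr::map_dfr(seq_along(frames$angles), function(k) {
      fr <- slice_frame(frames, frames$angles[k])
      o <- fr$origin - truth$center
      un <- sum(fr$dir_u * n); vn <- sum(fr$dir_v * n); on_ <- sum(o * n)
      # line of intersection of the slice plane with the truth plane,
      # parametrized by s along dir_u (t along dir_v eliminated)
      if (abs(vn) > 1e-9) {
        # t(s) = -(on_ + s * un) / vn
        lin_u <- c(sum(fr$dir_u * e1) - un / vn * sum(fr$dir_v * e1),
                   sum(fr$dir_u * e2) - un / vn * sum(fr$dir_v * e2))
        off_u <- c(sum(o * e1) - on_ / vn * sum(fr$dir_v * e1),
                   sum(o * e2) - on_ / vn * sum(fr$dir_v * e2))
      } else if (abs(un) > 1e-9) {
        abort_input("frame axis lies in the truth plane; cannot intersect the ellipse band")
      } else {
        abort_input("frame not intersecting the ellipse plane band")
      }
      # ellipse: (U/a)^2 + (V/b)^2 = 1 with U = off_u[1] + s lin_u[1], ...
      A <- (lin_u[1] / a)^2 + (lin_u[2] / b)^2
      B <- 2 * (off_u[1] * lin_u[1] / a^2 + off_u[2] * lin_u[2] / b^2)
      C <- (off_u[1] / a)^2 + (off_u[2] / b)^2 - 1
      disc <- B^2 - 4 * A * C
      if (A < 1e-12 || disc < 0) {
        abort_input(sprintf("frame at %g degrees does not intersect the ellipse",
                            fr$angle_deg))
      }
      s_roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      t_roots <- -(on_ + s_roots * un) / vn
      cx <- fr$width / 2 + s_roots / fr$pixel_mm
      cy <- fr$height / 2 + t_roots / fr$pixel_mm
      if (jitter_mm > 0) {
        cx <- cx + rnorm(2, sd = jitter_mm / fr$pixel_mm)
        cy <- cy + rnorm(2, sd = jitter_mm / fr$pixel_mm)
      }
      keep <- runif(2) >= p_miss
      out <- tibble::tibble(
        angle_deg = fr$angle_deg,
        x = cx[keep] - roi_px / 2, y = cy[keep] - roi_px / 2,
        w = roi_px, h = roi_px,
        confidence = runif(sum(keep), 0.7, 1.0),
        source = "annulus"
      )
      nfp <- if (fp_per_slice > 0) rpois(1, fp_per_slice) else 0L
      if (nfp > 0) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          angle_deg = fr$angle_deg,
          x = runif(nfp, 0, fr$width) - roi_px / 2,
          y = runif(nfp, 0, fr$height) - roi_px / 2,
          w = roi_px, h = roi_px,
          confidence = runif(nfp, 0.1, 0.7),
          source = "spurious"
        ))
      }
      out
    })
    recs
  })
}
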