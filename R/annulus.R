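#' Assemble an annulus estimate from a plane and a contour
#'
#' Bundles a fitted plane with its in-plane peripheral contour, the enclosed
#' area and the equivalent-circle radius. Invariants enforced: positive
#' area, `r_equiv = sqrt(area / pi)`, simple counterclockwise contour.
#'
#' @param plane A `fitted_plane` (see [fit_plane_pca()], [plane_frame()]).
#' @param contour Ordered closed polygon vertices `u, v` (mm) in the plane's
#'   frame.
#' @return An object of class `annulus_estimate` with fields `plane`,
#'   `contour`, `area` (mm^2) and `r_equiv` (mm).
#' @export
annulus_estimate <- function(plane, contour) {
  validate_plane(plane)
  m <- ensure_ccw(as_uv_matrix(contour))
  area <- polygon_area(m)
  structure(
    list(plane = plane, contour = uv_tibble(m), area = area,
         r_equiv = equivalent_radius(area)),
    class = "annulus_estimate"
  )
}

#' Estimate the annulus from a 3D point cloud
#'
#' The core segmentation-path composition: PCA plane fit of the cloud,
#' projection onto the plane, peripheral contour of the projected points,
#' then area and equivalent radius.
#'
#' @param points Data frame with `x, y, z` columns or an n x 3 matrix (mm),
#'   e.g. from [extract_boundary_points()] or [backproject_roi_centers()].
#' @inheritParams peripheral_contour
#' @return An `annulus_estimate`.
#' @export
estimate_annulus <- function(points, method = c("convex_hull", "alpha_shape"),
                             alpha_scale = 2.0) {
  plane <- fit_plane_pca(points)
  uv <- project_to_plane(points, plane)
  contour <- peripheral_contour(uv, method = method, alpha_scale = alpha_scale)
  annulus_estimate(plane, contour)
}

#' @export
print.annulus_estimate <- function(x, ...) {
  cat(sprintf("<annulus_estimate> area %.2f mm^2, equivalent radius %.3f mm, %d contour vertices\n",
              x$area, x$r_equiv, nrow(x$contour)))
  invisible(x)
}

#' @rdname annulus_estimate
#' @param x An `annulus_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.annulus_estimate <- function(x, ...) x$contour

#' @rdname annulus_estimate
#' @exportS3Method generics::glance
glance.annulus_estimate <- function(x, ...) {
  tibble::tibble(area_mm2 = x$area, r_equiv_mm = x$r_equiv,
                 n_vertices = nrow(x$contour),
                 plane_rms_mm = sqrt(x$plane$eigenvalues[3]))
}

# 3D world coordinates of the contour vertices.
contour_points_3d <- function(est) {
  stopifnot(inherits(est, "annulus_estimate"))
  plane_to_world(est$contour, est$plane)
}

#' Absolute equivalent-radius error |Rt - Re|
#'
#' The sizing-error measure: absolute difference between the true and the
#' estimated equivalent-circle radii.
#'
#' @param est Estimated annulus (`annulus_estimate`).
#' @param truth Ground-truth annulus (`annulus_estimate` or
#'   [annulus_truth()]).
#' @return Error in mm.
#' @export
radius_error <- function(est, truth) {
  re <- r_equiv_of(est)
  rt <- r_equiv_of(truth)
  abs(rt - re)
}

r_equiv_of <- function(x) {
  if (inherits(x, "annulus_estimate")) return(x$r_equiv)
  if (inherits(x, "annulus_truth")) return(x$r_true)
  abort_input("expected an annulus_estimate or annulus_truth")
}

#' Dice similarity of two annulus areas on a shared raster
#'
#' Both contours are brought into a common plane frame (the truth plane is
#' the reference: the estimated contour is lifted to 3D and re-projected
#' into the truth frame), rasterized on a shared pixel grid covering their
#' joint bounding box, and compared as filled pixel sets:
#' `DSC = 2 |A & B| / (|A| + |B|)`.
#'
#' @param est Estimated annulus (`annulus_estimate`).
#' @param truth Reference annulus (`annulus_estimate` or [annulus_truth()],
#'   converted via [truth_contour()]).
#' @param raster_mm Pixel size of the shared raster in mm (default 0.1).
#' @return DSC in \[0, 1\].
#' @export
area_dsc_2d <- function(est, truth, raster_mm = 0.1) {
  stopifnot(inherits(est, "annulus_estimate"))
  if (inherits(truth, "annulus_truth")) truth <- truth_contour(truth)
  stopifnot(inherits(truth, "annulus_estimate"))
  if (!is.numeric(raster_mm) || raster_mm <= 0) abort_input("raster_mm must be positive")
  ref <- truth$plane
  est_uv <- as_uv_matrix(project_to_plane(contour_points_3d(est), ref))
  tru_uv <- as_uv_matrix(truth$contour)
  both <- rbind(est_uv, tru_uv)
  xr <- range(both[, 1]); yr <- range(both[, 2])
  gx <- seq(xr[1] + raster_mm / 2, xr[2], by = raster_mm)
  gy <- seq(yr[1] + raster_mm / 2, yr[2], by = raster_mm)
  if (length(gx) == 0 || length(gy) == 0) {
    abort_input("empty rasterization: raster_mm too coarse for the contours")
  }
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  in_a <- mgcv::in.out(close_loop(est_uv), grid)
  in_b <- mgcv::in.out(close_loop(tru_uv), grid)
  if (!any(in_a) && !any(in_b)) abort_input("empty rasterization: raster_mm too coarse")
  2 * sum(in_a & in_b) / (sum(in_a) + sum(in_b))
}

close_loop <- function(m) rbind(m, m[1, , drop = FALSE])

#' Write / read an annulus estimate as JSON
#'
#' Serializes the plane (centroid, normal, in-plane basis), the contour
#' vertices, the area and the equivalent radius. `read_annulus_json()` is
#' the exact inverse.
#'
#' @param est An `annulus_estimate`.
#' @param path JSON file path.
#' @return `path` (write) or an `annulus_estimate` (read), invisibly for
#'   write.
#' @export
write_annulus_json <- function(est, path) {
  stopifnot(inherits(est, "annulus_estimate"))
  obj <- list(
    plane = list(centroid = est$plane$centroid, normal = est$plane$normal,
                 basis_e1 = est$plane$basis_e1, basis_e2 = est$plane$basis_e2,
                 eigenvalues = est$plane$eigenvalues),
    contour = list(u = est$contour$u, v = est$contour$v),
    area_mm2 = est$area,
    r_equiv_mm = est$r_equiv
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_annulus_json
#' @export
read_annulus_json <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  obj <- jsonlite::fromJSON(path)
  ev <- as.numeric(obj$plane$eigenvalues)
  plane <- new_fitted_plane(as.numeric(obj$plane$centroid),
                            as.numeric(obj$plane$normal),
                            eigenvalues = ev)
  annulus_estimate(plane, cbind(u = as.numeric(obj$contour$u),
                                v = as.numeric(obj$contour$v)))
}

#' @rdname annulus_estimate
#' @param object An `annulus_estimate`.
#' @exportS3Method ggplot2::autoplot
autoplot.annulus_estimate <- function(object, ...) {
  df <- object$contour
  circ <- tibble::tibble(
    u = object$r_equiv * cos(seq(0, 2 * pi, length.out = 181)),
    v = object$r_equiv * sin(seq(0, 2 * pi, length.out = 181))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_path(data = circ, linetype = "dashed", colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "u (mm)", y = "v (mm)",
      title = sprintf("Annulus contour: area %.1f mm^2, Re %.2f mm",
                      object$area, object$r_equiv),
      subtitle = "dashed: equivalent-area circle"
    )
}
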