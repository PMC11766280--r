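# Deterministic sign convention for a plane normal: prefer +z, then +y,
# then +x, so repeated runs and symmetric inputs give the same frame.
orient_normal <- function(n) {
  for (k in c(3, 2, 1)) {
    if (abs(n[k]) >= 1e-6) {
      if (n[k] < 0) n <- -n
      return(n)
    }
  }
  n
}

# Right-handed orthonormal in-plane basis: e1 is the normalized projection
# of world +x onto the plane (fallback +y when x is nearly parallel to the
# normal), e2 = n x e1 so that (e1 x e2) . n = +1.
plane_basis <- function(normal) {
  ref <- c(1, 0, 0)
  if (vnorm(ref - sum(ref * normal) * normal) < 1e-6) ref <- c(0, 1, 0)
  e1 <- unit(ref - sum(ref * normal) * normal)
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2)
}

new_fitted_plane <- function(centroid, normal, eigenvalues = c(NA_real_, NA_real_, NA_real_),
                             n_points = NA_integer_) {
  normal <- orient_normal(unit(normal))
  b <- plane_basis(normal)
  structure(
    list(centroid = as.numeric(centroid), normal = normal,
         basis_e1 = b$e1, basis_e2 = b$e2,
         eigenvalues = as.numeric(eigenvalues), n_points = n_points),
    class = "fitted_plane"
  )
}

#' Construct a plane frame from a point and a normal
#'
#' Builds the same deterministic frame (oriented normal plus right-handed
#' in-plane basis) that [fit_plane_pca()] attaches to fitted planes, for use
#' with analytically known planes such as phantom ground truth.
#'
#' @param centroid 3-vector, mm.
#' @param normal 3-vector; normalized and sign-oriented internally.
#' @return A `fitted_plane` with `NA` eigenvalues.
#' @export
plane_frame <- function(centroid, normal) new_fitted_plane(centroid, normal)

#' Fit the optimal plane of a 3D point cloud by PCA
#'
#' The annulus plane is taken to be the least-squares plane of the boundary
#' point cloud: the plane through the cloud's center of gravity whose normal
#' is the eigenvector of the smallest eigenvalue of the (population,
#' mean-centered) covariance matrix. This minimizes the sum of squared
#' point-to-plane distances; the sum of squared residuals equals
#' `n * lambda_3`.
#'
#' The normal's sign is fixed deterministically (towards +z, then +y, then
#' +x) and the in-plane basis `basis_e1`, `basis_e2` is the deterministic
#' right-handed frame of [plane_frame()], so 2D coordinates are reproducible
#' across runs. A near-tie between the two smallest eigenvalues (normal
#' direction ambiguous within the eigenspace) is broken by picking the
#' lexicographically largest sign-normalized eigenvector and flagged with a
#' message.
#'
#' @param points Data frame with columns `x, y, z` (mm) or an n x 3 matrix;
#'   at least 3 non-collinear points.
#' @return An object of class `fitted_plane` with fields `centroid`,
#'   `normal`, `basis_e1`, `basis_e2`, `eigenvalues` (descending) and
#'   `n_points`.
#' @examples
#' pts <- expand.grid(x = 0:3, y = 0:3)
#' plane <- fit_plane_pca(data.frame(pts, z = 5))
#' plane$normal       # (0, 0, 1)
#' plane$centroid[3]  # 5
#' @export
fit_plane_pca <- function(points) {
  m <- as_xyz_matrix(points)
  n <- nrow(m)
  if (n < 3) abort_degenerate("degenerate cloud: need at least 3 points")
  centroid <- colMeans(m)
  x <- sweep(m, 2, centroid)
  cv <- crossprod(x) / n        # population covariance: SSR = n * lambda3
  e <- eigen(cv, symmetric = TRUE)
  vals <- e$values
  vals[vals < 0] <- 0           # clamp tiny negative eigenvalues
  if (vals[2] <= max(vals[1], 1e-300) * 1e-12) {
    abort_degenerate("degenerate cloud: points are collinear")
  }
  nv <- e$vectors[, 3]
  gap <- vals[2] - vals[3]
  if (gap <= 1e-9 * max(vals[1], 1e-300)) {
    # eigen-tie: the thin directions are interchangeable; deterministic pick
    cand <- lapply(2:3, function(k) {
      v <- e$vectors[, k]
      nz <- which(abs(v) > 1e-12)[1]
      if (v[nz] < 0) -v else v
    })
    ord <- order(vapply(cand, function(v) paste(sprintf("%+.12f", v), collapse = ","),
                        character(1)), decreasing = TRUE)
    nv <- cand[[ord[1]]]
    message("fit_plane_pca: eigenvalue tie between the two smallest eigenvalues; ",
            "normal chosen by deterministic tie-break")
  }
  p <- new_fitted_plane(centroid, nv, eigenvalues = vals, n_points = n)
  p
}

#' @export
print.fitted_plane <- function(x, ...) {
  cat("<fitted_plane>\n")
  cat("  centroid:", paste(signif(x$centroid, 6), collapse = ", "), "mm\n")
  cat("  normal:  ", paste(signif(x$normal, 6), collapse = ", "), "\n")
  if (!all(is.na(x$eigenvalues))) {
    cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_plane_pca
#' @param x A `fitted_plane`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fitted_plane <- function(x, ...) {
  m <- rbind(x$centroid, x$normal, x$basis_e1, x$basis_e2)
  tibble::tibble(component = c("centroid", "normal", "basis_e1", "basis_e2"),
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

#' @rdname fit_plane_pca
#' @exportS3Method generics::glance
glance.fitted_plane <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$eigenvalues[1], lambda2 = x$eigenvalues[2],
    lambda3 = x$eigenvalues[3],
    rms_plane_distance = sqrt(x$eigenvalues[3]),
    n_points = x$n_points
  )
}

validate_plane <- function(plane) {
  if (!inherits(plane, "fitted_plane")) abort_input("plane must be a fitted_plane")
  ok <- abs(vnorm(plane$normal) - 1) < 1e-9 &&
    abs(sum(plane$basis_e1 * plane$basis_e2)) < 1e-9 &&
    abs(sum(plane$basis_e1 * plane$normal)) < 1e-9 &&
    abs(sum(plane$basis_e2 * plane$normal)) < 1e-9
  if (!ok) abort_input("invalid plane: basis is not orthonormal")
  invisible(plane)
}

#' Project a 3D point cloud onto a fitted plane
#'
#' Returns in-plane coordinates `u = (p - centroid) . e1`,
#' `v = (p - centroid) . e2` for each point, in input order. Restricted to
#' points lying on the plane the projection is an isometry.
#'
#' @param points Data frame with `x, y, z` columns or an n x 3 matrix (mm).
#' @param plane A `fitted_plane`.
#' @return Tibble with columns `u, v` (mm).
#' @export
project_to_plane <- function(points, plane) {
  validate_plane(plane)
  m <- as_xyz_matrix(points)
  x <- sweep(m, 2, plane$centroid)
  uv_tibble(cbind(x %*% plane$basis_e1, x %*% plane$basis_e2))
}

# Lift in-plane (u, v) coordinates back to 3D world mm.
plane_to_world <- function(uv, plane) {
  validate_plane(plane)
  m <- as_uv_matrix(uv)
  w <- matrix(plane$centroid, nrow = nrow(m), ncol = 3, byrow = TRUE) +
    m[, 1] %o% plane$basis_e1 + m[, 2] %o% plane$basis_e2
  xyz_tibble(w)
}
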