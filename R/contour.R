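shoelace_signed <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(m) {
  if (shoelace_signed(m) < 0) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

# TRUE when no two non-adjacent edges of the closed polygon properly
# intersect (shared endpoints between adjacent edges are allowed).
is_simple_polygon <- function(m) {
  n <- nrow(m)
  if (n < 3) return(FALSE)
  p1 <- m
  p2 <- m[c(2:n, 1), , drop = FALSE]
  orient <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges adjacent to edge i
    if (length(js) == 0) next
    a <- p1[rep(i, length(js)), , drop = FALSE]
    b <- p2[rep(i, length(js)), , drop = FALSE]
    c_ <- p1[js, , drop = FALSE]
    d <- p2[js, , drop = FALSE]
    o1 <- orient(a, b, c_); o2 <- orient(a, b, d)
    o3 <- orient(c_, d, a); o4 <- orient(c_, d, b)
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(FALSE)
  }
  TRUE
}

#' Peripheral contour of a projected point cloud
#'
#' The periphery of the projected boundary cloud is taken to be the aortic
#' valve annulus contour. Two outermost-point definitions are offered:
#'
#' * `convex_hull` (default): the 2D convex hull — parameter-free and
#'   robust, exact for convex (elliptical) annuli.
#' * `alpha_shape`: the alpha-shape boundary with
#'   `alpha = alpha_scale * median nearest-neighbor distance`, which can
#'   follow concave outlines that a hull would bridge.
#'
#' The returned polygon is closed (first vertex implicitly follows the
#' last), simple, counterclockwise in `(u, v)`, and its vertices are a
#' subset of the input points.
#'
#' @param points2d Data frame with `u, v` columns or an n x 2 matrix (mm).
#' @param method `"convex_hull"` or `"alpha_shape"`.
#' @param alpha_scale Positive factor applied to the median nearest-neighbor
#'   distance to form alpha (default 2.0). Ignored for the convex hull.
#' @return Tibble of ordered contour vertices `u, v`.
#' @examples
#' sq <- data.frame(u = c(0, 1, 1, 0, 0.5), v = c(0, 0, 1, 1, 0.5))
#' peripheral_contour(sq)  # the 4 corners, counterclockwise
#' @export
peripheral_contour <- function(points2d, method = c("convex_hull", "alpha_shape"),
                               alpha_scale = 2.0) {
  method <- match.arg(method)
  m <- as_uv_matrix(points2d)
  m <- m[!duplicated(m), , drop = FALSE]
  if (nrow(m) < 3) abort_degenerate("degenerate input: need at least 3 distinct points")
  hull_idx <- grDevices::chull(m)
  if (length(hull_idx) < 3) abort_degenerate("degenerate input: points are collinear")
  if (method == "convex_hull") {
    poly <- m[hull_idx, , drop = FALSE]
  } else {
    if (!is.numeric(alpha_scale) || alpha_scale <= 0) {
      abort_input("alpha_scale must be a positive number")
    }
    nn <- median_nn_distance(m)
    idx <- alpha_shape_boundary(m, alpha = alpha_scale * nn)
    poly <- m[idx, , drop = FALSE]
  }
  poly <- ensure_ccw(poly)
  if (!is_simple_polygon(poly)) {
    abort_degenerate("extracted contour is self-intersecting; increase alpha_scale")
  }
  uv_tibble(poly)
}

median_nn_distance <- function(m) {
  n <- nrow(m)
  if (n > 4000) {  # subsample for the scale estimate only
    m <- m[seq(1, n, length.out = 4000), , drop = FALSE]
    n <- nrow(m)
  }
  d <- as.matrix(dist(m))
  diag(d) <- Inf
  median(apply(d, 1, min))
}

#' Area enclosed by a simple polygon
#'
#' Shoelace area of a closed simple polygon given as ordered vertices (the
#' closing edge from last to first vertex is implied).
#'
#' @param polygon Data frame with `u, v` columns or an n x 2 matrix (mm).
#' @return Positive area in mm^2.
#' @export
polygon_area <- function(polygon) {
  m <- as_uv_matrix(polygon)
  if (nrow(m) < 3) abort_input("polygon needs at least 3 vertices")
  if (!is_simple_polygon(m)) abort_input("polygon is self-intersecting")
  abs(shoelace_signed(m))
}

#' Equivalent-circle radius of an area
#'
#' Radius of the circle whose area equals the given annulus area:
#' `sqrt(area / pi)`. Applied to an estimated area this is the estimated
#' radius Re; applied to ground truth it is the true radius Rt.
#'
#' @param area Area in mm^2; must be positive.
#' @return Radius in mm.
#' @examples
#' equivalent_radius(100 * pi)  # 10
#' @export
equivalent_radius <- function(area) {
  if (!is.numeric(area) || length(area) != 1 || !is.finite(area) || area <= 0) {
    abort_input("area must be a single positive number")
  }
  sqrt(area / pi)
}
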