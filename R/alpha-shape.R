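# 2D Delaunay triangulation (Bowyer-Watson) and alpha-shape boundary
# extraction. Written in-package: the pre-installed stack has no 2D alpha
# shape, and the triangulation needed here (a few thousand projected
# boundary points) is small enough for an O(n * T) incremental build.

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(NULL)  # collinear triangle
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Returns an integer matrix of triangle vertex rows into pts.
# Cocircular degeneracies (common for grid-aligned projected points) are
# broken by a tiny deterministic perturbation used for the triangulation
# only; emitted indices always refer to the original coordinates.
delaunay_triangulation <- function(pts) {
  n <- nrow(pts)
  if (n < 3) abort_degenerate("degenerate input: need at least 3 points")
  span <- max(apply(pts, 2, function(c) diff(range(c))), 1e-9)
  jit <- span * 1e-7
  set.seed(20260101)  # local, deterministic; caller RNG is restored below
  p <- pts + matrix(runif(2 * n, -jit, jit), ncol = 2)

  # super-triangle comfortably containing all points
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  m <- 10 * span
  sv <- rbind(c(cx - 2 * m, cy - m), c(cx + 2 * m, cy - m), c(cx, cy + 2 * m))
  p <- rbind(p, sv)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tris <- matrix(c(s1, s2, s3), ncol = 3)
  cc <- matrix(0, nrow = 1, ncol = 3)  # cx, cy, r2 per triangle
  ccirc <- circumcircle(p[s1, ], p[s2, ], p[s3, ])
  cc[1, ] <- c(ccirc$center, ccirc$r2)

  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    if (!any(bad)) next  # numerically outside all circumcircles; skip
    bad_tris <- tris[bad, , drop = FALSE]
    # polygonal hole boundary: edges of bad triangles appearing exactly once
    edges <- rbind(bad_tris[, c(1, 2)], bad_tris[, c(2, 3)], bad_tris[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- key %in% names(which(table(key) == 1))
    hole <- edges[once, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    if (nrow(hole) == 0) next
    newt <- cbind(hole, i)
    newcc <- matrix(NA_real_, nrow = nrow(newt), ncol = 3)
    keep <- logical(nrow(newt))
    for (r in seq_len(nrow(newt))) {
      ci <- circumcircle(p[newt[r, 1], ], p[newt[r, 2], ], p[newt[r, 3], ])
      if (!is.null(ci)) {
        keep[r] <- TRUE
        newcc[r, ] <- c(ci$center, ci$r2)
      }
    }
    tris <- rbind(tris, newt[keep, , drop = FALSE])
    cc <- rbind(cc, newcc[keep, , drop = FALSE])
  }
  real <- rowSums(tris > n) == 0
  tris <- tris[real, , drop = FALSE]
  if (nrow(tris) == 0) abort_degenerate("degenerate input: no valid triangulation")
  tris
}

# Alpha-shape boundary: keep Delaunay triangles with circumradius <= alpha,
# take edges used by exactly one kept triangle, and chain them into closed
# loops. Returns the loop enclosing the largest area, as ordered vertex
# indices into pts.
alpha_shape_boundary <- function(pts, alpha) {
  rng_state <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
  })
  tris <- delaunay_triangulation(pts)
  r2 <- apply(tris, 1, function(t) {
    ci <- circumcircle(pts[t[1], ], pts[t[2], ], pts[t[3], ])
    if (is.null(ci)) Inf else ci$r2
  })
  kept <- tris[r2 <= alpha^2, , drop = FALSE]
  if (nrow(kept) == 0) {
    abort_degenerate("alpha too small: no triangle has circumradius <= alpha; increase alpha_scale")
  }
  edges <- rbind(kept[, c(1, 2)], kept[, c(2, 3)], kept[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- key %in% names(which(table(key) == 1))
  bnd <- edges[once, , drop = FALSE]
  if (nrow(bnd) < 3) abort_degenerate("alpha shape has no closed boundary; increase alpha_scale")

  # chain boundary edges into loops
  adj <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  used <- rep(FALSE, nrow(bnd))
  ekey <- paste(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2]))
  loops <- list()
  for (s in seq_len(nrow(bnd))) {
    if (used[s]) next
    loop <- c(bnd[s, 1], bnd[s, 2])
    used[s] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nbrs) {
        k <- paste(min(cur, cand), max(cur, cand))
        hit <- which(ekey == k & !used)
        if (length(hit) > 0) {
          used[hit[1]] <- TRUE
          nxt <- cand
          break
        }
      }
      if (is.na(nxt) || nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  if (length(loops) == 0) abort_degenerate("alpha shape boundary could not be chained into a loop")
  areas <- vapply(loops, function(l) abs(shoelace_signed(pts[l, , drop = FALSE])), numeric(1))
  loops[[which.max(areas)]]
}
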