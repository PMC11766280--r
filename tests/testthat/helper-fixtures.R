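# Small in-code fixtures and independent brute-force oracles.

# Two abutting blocks: LV occupies z-slices 1..nz/2, Ao the rest.
two_block_volume <- function(n = 4, spacing = 1, gap = 0) {
  nz <- 2 * n + gap
  g <- array(0L, dim = c(n, n, nz))
  g[, , 1:n] <- 1L
  g[, , (n + gap + 1):nz] <- 3L
  label_volume(g, spacing = rep(spacing, 3))
}

# Brute-force count of adjacent (code_a, code_b) voxel pairs and their
# midpoints, by exhaustive scan over all voxel pairs. Oracle for
# extract_boundary_points on tiny grids.
brute_boundary_midpoints <- function(vol, code_a, code_b, connectivity = 6) {
  g <- vol$grid
  d <- dim(g)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3), ,
               drop = FALSE]
  mids <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (g[i, j, k] != code_a) next
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (g[ii, jj, kk] == code_b) {
        mid <- (c(i, j, k) + c(ii, jj, kk)) / 2 - 1
        mids[[length(mids) + 1]] <- mid * vol$spacing + vol$origin
      }
    }
  }
  m <- do.call(rbind, mids)
  if (is.null(m)) return(m)
  m <- m[!duplicated(m), , drop = FALSE]
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Exhaustive optimal one-to-one assignment of detections to ground truth:
# the maximum number of pairs with IoU >= threshold. Oracle for the greedy
# matcher on instances with few boxes.
brute_best_tp <- function(det_boxes, gt_boxes, iou_thresh = 0.5) {
  nd <- nrow(det_boxes); ng <- nrow(gt_boxes)
  if (nd == 0 || ng == 0) return(0L)
  iou <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    iou[i, j] <- iou_box(as.numeric(det_boxes[i, ]), as.numeric(gt_boxes[j, ]))
  }
  best <- 0L
  # enumerate all injective partial assignments det -> gt
  assign_rec <- function(i, used, tp) {
    if (tp + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, tp); return() }
    assign_rec(i + 1, used, tp)  # detection i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && iou[i, j] >= iou_thresh) {
        used[j] <- TRUE
        assign_rec(i + 1, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, ng), 0L)
  best
}

# A quick phantom small enough for per-test use.
small_phantom <- function(normal = c(0, 0, 1), spacing = 1, semi_axes = c(8, 6),
                          extent = 44, include_la_ocs = FALSE) {
  shape <- round(extent / spacing)
  generate_phantom(phantom_spec(
    shape = rep(shape, 3), spacing = rep(spacing, 3),
    annulus_normal = normal, semi_axes = semi_axes,
    aorta_length = 10, lv_radius = 10, lv_depth = 12,
    include_la_ocs = include_la_ocs
  ))
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / (vnorm_t(a) * vnorm_t(b)))) * 180 / pi
}
vnorm_t <- function(v) sqrt(sum(v^2))
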