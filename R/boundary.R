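# Neighbor offset sets for 6/18/26-connectivity, one representative per
# unordered voxel pair (first nonzero component positive).
half_offsets <- function(connectivity) {
  all <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all <- all[rowSums(abs(all)) > 0, , drop = FALSE]
  ord <- rowSums(abs(all))
  keep <- switch(as.character(connectivity),
    "6" = ord == 1,
    "18" = ord <= 2,
    "26" = ord <= 3,
    abort_input("connectivity must be 6, 18 or 26")
  )
  all <- all[keep, , drop = FALSE]
  # keep one of each +/- pair
  pos <- apply(all, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  all[pos, , drop = FALSE]
}

#' Extract the boundary point cloud between two classes
#'
#' Finds every adjacent voxel pair where one voxel belongs to `class_a` and
#' its neighbor (under the chosen connectivity) to `class_b`, and emits the
#' midpoint of the two voxel centers in world mm. This yields a sub-voxel
#' point cloud of the shared interface — for the LV/Ao pair, a discrete
#' representation of the aortic valve annulus region. Voxels of any other
#' class sitting between the two break adjacency: only direct contacts
#' count.
#'
#' Duplicate midpoints (possible under 18/26-connectivity where two
#' distinct diagonal pairs share a midpoint) are removed, and the cloud is
#' returned in deterministic lexicographic `(x, y, z)` order. The result is
#' symmetric in `(class_a, class_b)`.
#'
#' @param vol A [label_volume()].
#' @param class_a,class_b Class names from the volume's label map
#'   (default the left ventricle and the aorta).
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full Moore
#'   neighborhood). Default 6.
#' @return Tibble with columns `x, y, z` (mm, world frame).
#' @examples
#' g <- array(0L, dim = c(4, 4, 8))
#' g[, , 1:4] <- 1L  # LV
#' g[, , 5:8] <- 3L  # Ao
#' vol <- label_volume(g)
#' pts <- extract_boundary_points(vol)  # 16 points on the shared face
#' @export
extract_boundary_points <- function(vol, class_a = "LV", class_b = "Ao",
                                    connectivity = 6) {
  stopifnot(inherits(vol, "label_volume"))
  ca <- label_code(vol, class_a)
  cb <- label_code(vol, class_b)
  g <- vol$grid
  if (!any(g == ca)) abort_input(paste0("class not present: no '", class_a, "' voxels in volume"))
  if (!any(g == cb)) abort_input(paste0("class not present: no '", class_b, "' voxels in volume"))
  d <- dim(g)
  offs <- half_offsets(connectivity)
  pts <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    i1 <- seq.int(1 + max(-o[1], 0), d[1] - max(o[1], 0))
    j1 <- seq.int(1 + max(-o[2], 0), d[2] - max(o[2], 0))
    k1 <- seq.int(1 + max(-o[3], 0), d[3] - max(o[3], 0))
    a_sub <- g[i1, j1, k1, drop = FALSE]
    b_sub <- g[i1 + o[1], j1 + o[2], k1 + o[3], drop = FALSE]
    hit <- which((a_sub == ca & b_sub == cb) | (a_sub == cb & b_sub == ca))
    if (length(hit) == 0) next
    idx <- arrayInd(hit, dim(a_sub))
    # 0-based voxel index of the first member of each pair
    v0 <- cbind(idx[, 1] + i1[1] - 2, idx[, 2] + j1[1] - 2, idx[, 3] + k1[1] - 2)
    mid <- sweep(v0, 2, o / 2, "+")                       # pair midpoint, voxels
    mid <- sweep(sweep(mid, 2, vol$spacing, "*"), 2, vol$origin, "+")
    pts[[r]] <- mid
  }
  m <- do.call(rbind, pts)
  if (is.null(m) || nrow(m) == 0) abort_input("no shared boundary between the two classes")
  m <- m[!duplicated(m), , drop = FALSE]
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  xyz_tibble(m)
}
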