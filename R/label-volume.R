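#' Default five-class cardiac label scheme
#'
#' Class codes for the multi-class cardiac segmentation consumed by the
#' pipeline: background (BG), left ventricle (LV), left atrium (LA), aorta
#' (Ao) and other cardiac structures (OCS; right atrium, right ventricle and
#' myocardium pooled). The codes are a package convention; any mapping of
#' names to integer codes can be supplied instead.
#'
#' @return Named integer vector of class codes.
#' @export
default_label_map <- function() {
  c(BG = 0L, LV = 1L, LA = 2L, Ao = 3L, OCS = 4L)
}

#' Construct a labeled volume
#'
#' A `label_volume` is a 3D integer class grid with physical geometry:
#' isotropic or anisotropic voxel spacing in mm and the world position (mm)
#' of the center of voxel `(0, 0, 0)` (0-based indexing). All package
#' geometry uses voxel-center world coordinates in mm.
#'
#' @param grid 3D array of small non-negative integer class codes.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, mm, world position of the center of voxel
#'   `(0, 0, 0)`.
#' @param label_map Named integer vector mapping class names to codes; every
#'   code present in `grid` must appear here.
#' @return An object of class `label_volume`.
#' @examples
#' g <- array(0L, dim = c(4, 4, 4))
#' g[, , 1:2] <- 1L
#' vol <- label_volume(g, spacing = c(0.5, 0.5, 0.5))
#' vol
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         label_map = default_label_map()) {
  if (length(dim(grid)) != 3L) abort_input("non-3D image: grid must be a 3D array")
  if (any(dim(grid) < 2L)) abort_input("grid must have at least 2 voxels along every axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_input("spacing must be 3 positive finite numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort_input("origin must be 3 finite numbers (mm)")
  }
  if (is.null(names(label_map)) || any(!nzchar(names(label_map)))) {
    abort_input("label_map must be a fully named integer vector")
  }
  label_map <- vapply(label_map, as.integer, integer(1))
  if (is.double(grid) && max(abs(grid - round(grid))) > 1e-6) {
    abort_input("voxel values are not integers within tolerance 1e-6")
  }
  grid <- array(as.integer(round(grid)), dim = dim(grid))  # strip any attrs
  codes <- sort(unique(as.integer(grid)))
  missing <- setdiff(codes, unname(label_map))
  if (length(missing) > 0) {
    abort_input(paste0("grid contains codes absent from label_map: ",
                       paste(missing, collapse = ", ")))
  }
  structure(
    list(grid = grid, spacing = spacing, origin = origin, label_map = label_map),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  tab <- table(factor(as.vector(x$grid), levels = unname(x$label_map),
                      labels = names(x$label_map)))
  cat("  voxels per class:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$grid)

label_code <- function(vol, class_name) {
  if (!class_name %in% names(vol$label_map)) {
    abort_input(paste0("class not present: '", class_name, "' is not in the label map"))
  }
  unname(vol$label_map[[class_name]])
}

#' Read a label volume from a NIfTI-1 file
#'
#' Voxel codes are preserved exactly (values must be integers within 1e-6).
#' Spacing and origin are taken from the file's sform/qform affine; the
#' affine must be axis-aligned (diagonal scales plus translation), which is
#' what [write_label_volume()] produces and what segmentation tools emit for
#' resampled axial volumes.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label_map Class-name mapping to attach; defaults to the five-class
#'   cardiac scheme extended with any extra codes found in the file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_map = default_label_map()) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) abort_input("non-3D image")
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  offdiag <- rot - diag(diag(rot))
  if (max(abs(offdiag)) > 1e-4 * max(spacing)) {
    warning("oblique NIfTI affine: using per-axis scales only; orientation ignored")
  }
  origin <- aff[1:3, 4]
  extra <- setdiff(sort(unique(as.integer(round(a)))), unname(label_map))
  if (length(extra) > 0) {
    add <- stats::setNames(as.integer(extra), paste0("class_", extra))
    label_map <- c(label_map, add)
  }
  label_volume(a, spacing = abs(spacing), origin = origin, label_map = label_map)
}

#' Write a label volume to a NIfTI-1 file
#'
#' The inverse of [read_label_volume()]: codes round-trip exactly and the
#' geometry (spacing, origin) round-trips within 1e-6 mm via the sform
#' affine.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  if (!dir.exists(dirname(path))) abort_input(paste0("directory does not exist: ", dirname(path)))
  img <- RNifti::asNifti(vol$grid, datatype = "int16")
  aff <- diag(4)
  aff[1, 1] <- vol$spacing[1]
  aff[2, 2] <- vol$spacing[2]
  aff[3, 3] <- vol$spacing[3]
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# World coordinates (mm) of voxel centers along each axis, 0-based indices.
axis_coords <- function(vol) {
  d <- dim(vol$grid)
  lapply(1:3, function(k) (seq_len(d[k]) - 1) * vol$spacing[k] + vol$origin[k])
}
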