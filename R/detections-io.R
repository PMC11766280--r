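#' Read per-angle ROI detections
#'
#' Detections are per-slice bounding boxes with confidence scores, one row
#' per box: `angle_deg` (rotation angle of the source slice, degrees),
#' `x, y` (top-left corner, pixel units, y increasing downward), `w, h`
#' (box size, pixels) and `confidence` in \[0, 1\]. Accepted formats are CSV
#' with exactly that header, or a JSON array of objects with the same keys.
#' Row order is preserved.
#'
#' @param path CSV or JSON file of detections.
#' @return A tibble with columns `angle_deg, x, y, w, h, confidence`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) {
      df <- data.frame(angle_deg = numeric(), x = numeric(), y = numeric(),
                       w = numeric(), h = numeric(), confidence = numeric())
    }
    df <- as.data.frame(df)
  } else {
    df <- read.csv(path)
  }
  validate_detections(df)
}

validate_detections <- function(df) {
  required <- c("angle_deg", "x", "y", "w", "h", "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_input(paste0("missing detection column(s): ", paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[, required, drop = FALSE])
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.numeric))
  if (nrow(df) == 0) return(df)
  if (any(!is.finite(as.matrix(df)))) abort_input("detections contain non-finite values")
  if (any(df$w <= 0) || any(df$h <= 0)) abort_input("detection boxes must have w > 0 and h > 0")
  if (any(df$confidence < 0 | df$confidence > 1)) {
    abort_input("confidence must lie in [0, 1]")
  }
  df
}

#' Write per-angle ROI detections
#'
#' Inverse of [read_detections()]; format chosen by extension (`.csv` or
#' `.json`). Extra columns beyond the canonical six are dropped; row order
#' is preserved.
#'
#' @param dets Data frame of detections (see [read_detections()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  dets <- validate_detections(dets)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(dets, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(dets, path, row.names = FALSE)
  }
  invisible(path)
}

#' Export a 3D point cloud
#'
#' Writes a point cloud as CSV (`x,y,z` in mm) or ASCII PLY, chosen by
#' extension.
#'
#' @param points Data frame with columns `x, y, z` (mm) or a 3-column matrix.
#' @param path Output path ending in `.csv` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_pointcloud <- function(points, path) {
  m <- as_xyz_matrix(points)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(m)),
                 "property double x", "property double y", "property double z",
                 "end_header"), con)
    writeLines(apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  } else {
    write.csv(as.data.frame(m), path, row.names = FALSE)
  }
  invisible(path)
}
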