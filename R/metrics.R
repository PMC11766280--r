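#' Dice similarity coefficient of two voxel masks
#'
#' `DSC = 2 |A & B| / (|A| + |B|)` over voxel (or raster pixel) sets.
#' Defined as 1 when both masks are empty.
#'
#' @param a,b Logical or 0/1 arrays of identical shape.
#' @return DSC in \[0, 1\].
#' @export
dice_voxel <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      (is.null(dim(a)) && length(a) != length(b))) {
    abort_input("mask shapes differ")
  }
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `(x, y, w, h)` with `(x, y)` the top-left corner in pixel
#' units.
#'
#' @param b1,b2 Numeric length-4 vectors `c(x, y, w, h)` with positive
#'   `w, h`.
#' @return IoU in \[0, 1\].
#' @examples
#' iou_box(c(0, 0, 1, 1), c(0.5, 0, 1, 1))  # 1/3
#' @export
iou_box <- function(b1, b2) {
  if (b1[3] <= 0 || b1[4] <= 0 || b2[3] <= 0 || b2[4] <= 0) {
    abort_input("boxes must have positive width and height")
  }
  ix <- max(0, min(b1[1] + b1[3], b2[1] + b2[3]) - max(b1[1], b2[1]))
  iy <- max(0, min(b1[2] + b1[4], b2[2] + b2[4]) - max(b1[2], b2[2]))
  inter <- ix * iy
  union <- b1[3] * b1[4] + b2[3] * b2[4] - inter
  inter / union
}

#' Match detections to ground-truth boxes
#'
#' Per slice, detections are sorted by descending confidence and each is
#' matched greedily to the still-unmatched ground-truth box of highest IoU.
#' A match with IoU at or above the threshold counts as a true positive and
#' consumes the ground-truth box; otherwise the detection is a false
#' positive. Ground-truth boxes left unmatched are false negatives. Counts
#' are aggregated over slices; slices present in only one of the two inputs
#' still contribute (their boxes are all FP or all FN).
#'
#' @param dets Detection tibble with columns
#'   `angle_deg, x, y, w, h, confidence`.
#' @param gts Ground-truth tibble with columns `angle_deg, x, y, w, h`.
#' @param iou_thresh IoU threshold for a correct detection (default 0.5).
#' @return A `detection_eval` object with fields `tp, fp, fn, ap, am` and a
#'   `per_slice` tibble; see [average_precision()] and
#'   [average_miss_rate()].
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  dets <- validate_detections(dets)
  req <- c("angle_deg", "x", "y", "w", "h")
  if (!all(req %in% names(gts))) {
    abort_input("ground truth must have columns angle_deg, x, y, w, h")
  }
  gts <- tibble::as_tibble(gts)
  slices <- sort(unique(c(dets$angle_deg, gts$angle_deg)))
  empty <- tibble::tibble(angle_deg = numeric(), n_gt = integer(),
                          n_det = integer(), tp = integer(), fp = integer(),
                          fn = integer())
  per <- purrr::map_dfr(slices, function(s) {
    d <- dets[abs(dets$angle_deg - s) <= 1e-6, , drop = FALSE]
    g <- gts[abs(gts$angle_deg - s) <= 1e-6, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    matched <- rep(FALSE, nrow(g))
    tp <- 0L; fp <- 0L
    for (i in seq_len(nrow(d))) {
      best <- 0; best_j <- 0L
      for (j in seq_len(nrow(g))) {
        if (matched[j]) next
        iou <- iou_box(as.numeric(d[i, c("x", "y", "w", "h")]),
                       as.numeric(g[j, c("x", "y", "w", "h")]))
        if (iou > best) { best <- iou; best_j <- j }
      }
      if (best_j > 0L && best >= iou_thresh) {
        tp <- tp + 1L
        matched[best_j] <- TRUE
      } else {
        fp <- fp + 1L
      }
    }
    tibble::tibble(angle_deg = s, n_gt = nrow(g), n_det = nrow(d),
                   tp = tp, fp = fp, fn = nrow(g) - sum(matched))
  })
  if (nrow(per) == 0) per <- empty
  res <- structure(
    list(tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
         per_slice = per, iou_thresh = iou_thresh),
    class = "detection_eval"
  )
  res$ap <- if (res$tp + res$fp > 0) res$tp / (res$tp + res$fp) else NA_real_
  with_gt <- per[per$n_gt > 0, , drop = FALSE]
  res$am <- if (nrow(with_gt) > 0) mean(with_gt$fn / with_gt$n_gt) else NA_real_
  res
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> TP %d, FP %d, FN %d | AP %.3f, AM %.3f (IoU >= %.2f)\n",
              x$tp, x$fp, x$fn, x$ap, x$am, x$iou_thresh))
  invisible(x)
}

#' @rdname match_detections
#' @param x A `detection_eval`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.detection_eval <- function(x, ...) x$per_slice

#' @rdname match_detections
#' @exportS3Method generics::glance
glance.detection_eval <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, ap = x$ap, am = x$am,
                 iou_thresh = x$iou_thresh)
}

#' Average precision at a fixed IoU threshold
#'
#' Single-operating-point precision `AP = TP / (TP + FP)` — the fraction of
#' emitted boxes that are correct detections at the matching threshold.
#' This is not a precision-recall-curve area.
#'
#' @param res A `detection_eval` from [match_detections()].
#' @return AP in \[0, 1\]; errors when no detections were made
#'   (`TP + FP = 0`).
#' @export
average_precision <- function(res) {
  stopifnot(inherits(res, "detection_eval"))
  if (res$tp + res$fp == 0) abort_input("AP undefined: no detections (TP + FP = 0)")
  res$tp / (res$tp + res$fp)
}

#' Average miss rate
#'
#' Mean over slices of the per-slice missed fraction
#' `FN_slice / GT_slice`; slices without ground truth are excluded.
#'
#' @param res A `detection_eval` from [match_detections()].
#' @return AM in \[0, 1\]; errors when no slice has ground truth.
#' @export
average_miss_rate <- function(res) {
  stopifnot(inherits(res, "detection_eval"))
  per <- res$per_slice[res$per_slice$n_gt > 0, , drop = FALSE]
  if (nrow(per) == 0) abort_input("AM undefined: no ground truth in any slice")
  mean(per$fn / per$n_gt)
}

#' Per-fold mean and standard deviation
#'
#' Cross-validation summary: arithmetic mean and, by default, the sample
#' standard deviation (denominator n - 1) of a metric across folds. The
#' population convention (denominator n) is available via `population`.
#'
#' @param values Numeric vector of per-fold values (>= 2).
#' @param population Use the population SD instead of the sample SD.
#' @return A `fold_summary` with fields `per_fold`, `mean`, `sd`, `n`.
#' @examples
#' summarize_folds(c(0.729, 0.646, 0.800, 0.726, 0.664))
#' @export
summarize_folds <- function(values, population = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2) abort_input("need at least 2 fold values")
  if (any(!is.finite(values))) abort_input("fold values must be finite")
  s <- stats::sd(values)
  if (population) s <- s * sqrt((length(values) - 1) / length(values))
  structure(
    list(per_fold = values, mean = mean(values), sd = s, n = length(values),
         population = population),
    class = "fold_summary"
  )
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf("<fold_summary> %s | mean %.4f +/- %.4f (%s SD, n=%d)\n",
              paste(signif(x$per_fold, 4), collapse = " "),
              x$mean, x$sd, if (x$population) "population" else "sample", x$n))
  invisible(x)
}

#' @rdname summarize_folds
#' @param x A `fold_summary`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fold_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n)
}

#' @rdname match_detections
#' @param object A `detection_eval`.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_eval <- function(object, ...) {
  df <- tidyr_longer_counts(object$per_slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$count,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "slice angle (degrees)", y = "boxes",
                  title = sprintf("Detection outcomes: AP %.3f, AM %.3f",
                                  object$ap, object$am))
}

tidyr_longer_counts <- function(per) {
  purrr::map_dfr(c("tp", "fp", "fn"), function(col) {
    tibble::tibble(angle_deg = per$angle_deg, outcome = toupper(col),
                   count = per[[col]])
  })
}
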