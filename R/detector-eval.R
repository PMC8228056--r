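#' Intersection over Union of two normalized bounding boxes
#'
#' Boxes are given in normalized center format (`cx`, `cy`, `w`, `h`).
#' Corners are clipped to the unit square before the areas are computed, so
#' a box whose center sits near an image edge is scored by its visible part.
#'
#' @param a,b A box: a named numeric vector, list, or single-row data.frame
#'   with entries `cx`, `cy`, `w`, `h`.
#' @return IoU in `[0, 1]`; symmetric in its arguments; 1 exactly for
#'   identical rectangles, 0 when the rectangles share no area.
#' @export
#' @examples
#' box_iou(c(cx = 0.5, cy = 0.5, w = 0.2, h = 0.2),
#'         c(cx = 0.6, cy = 0.5, w = 0.2, h = 0.2))  # 1/3
box_iou <- function(a, b) {
  a <- box_corners(a)
  b <- box_corners(b)
  ix <- max(0, min(a[["x2"]], b[["x2"]]) - max(a[["x1"]], b[["x1"]]))
  iy <- max(0, min(a[["y2"]], b[["y2"]]) - max(a[["y1"]], b[["y1"]]))
  inter <- ix * iy
  union <- a[["area"]] + b[["area"]] - inter
  inter / union
}

# clip to the unit square; errors on zero-area boxes
box_corners <- function(box) {
  box <- as.list(box)
  if (!all(c("cx", "cy", "w", "h") %in% names(box))) {
    stop_fw("a box needs entries cx, cy, w, h")
  }
  if (box$w <= 0 || box$h <= 0) stop_fw("zero-area bounding box")
  x1 <- max(0, box$cx - box$w / 2); x2 <- min(1, box$cx + box$w / 2)
  y1 <- max(0, box$cy - box$h / 2); y2 <- min(1, box$cy + box$h / 2)
  area <- (x2 - x1) * (y2 - y1)
  if (area <= 0) stop_fw("bounding box has zero area inside the unit square")
  c(x1 = x1, x2 = x2, y1 = y1, y2 = y2, area = area)
}

#' Match ranked detections against ground truth
#'
#' Greedy one-to-one assignment in confidence order (the PASCAL VOC
#' convention): each detection, taken from highest to lowest confidence, is
#' a true positive if its best-IoU *unmatched* ground-truth box in the same
#' image and class reaches `iou_threshold`, otherwise a false positive.
#' Each ground-truth box can be matched at most once, so duplicate
#' detections of one object become false positives. Ground-truth boxes left
#' unmatched — including all boxes of images with no detections at all —
#' are the false negatives.
#'
#' @param detections Data.frame with columns `image_id`, `class_id`, `cx`,
#'   `cy`, `w`, `h`, `confidence`.
#' @param ground_truth Data.frame with columns `image_id`, `class_id`,
#'   `cx`, `cy`, `w`, `h`.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return List with `detections`: the input rows in rank order (confidence
#'   descending, ties by `image_id` then input order) plus logical `tp` and
#'   numeric `matched_iou` columns; and `fn`: the false-negative count.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  det_req <- c("image_id", "class_id", "cx", "cy", "w", "h", "confidence")
  gt_req <- c("image_id", "class_id", "cx", "cy", "w", "h")
  if (nrow(detections) > 0 && !all(det_req %in% names(detections))) {
    stop_fw("detections must have columns %s", paste(det_req, collapse = ", "))
  }
  if (nrow(ground_truth) > 0 && !all(gt_req %in% names(ground_truth))) {
    stop_fw("ground_truth must have columns %s", paste(gt_req, collapse = ", "))
  }
  if (nrow(detections) == 0) {
    empty <- cbind(detections, tp = logical(0), matched_iou = numeric(0))
    return(list(detections = empty, fn = nrow(ground_truth)))
  }
  ord <- order(-detections$confidence, detections$image_id, seq_len(nrow(detections)))
  det <- detections[ord, , drop = FALSE]
  rownames(det) <- NULL
  gt_taken <- rep(FALSE, nrow(ground_truth))
  tp <- logical(nrow(det))
  matched_iou <- rep(NA_real_, nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(!gt_taken &
                    ground_truth$image_id == det$image_id[[i]] &
                    ground_truth$class_id == det$class_id[[i]])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) box_iou(det[i, ], ground_truth[j, ]), numeric(1))
    best <- which.max(ious)
    if (ious[[best]] >= iou_threshold) {
      tp[[i]] <- TRUE
      matched_iou[[i]] <- ious[[best]]
      gt_taken[[cand[[best]]]] <- TRUE
    }
  }
  det$tp <- tp
  det$matched_iou <- matched_iou
  list(detections = det, fn = sum(!gt_taken))
}

#' Precision-recall curve with interpolated precision
#'
#' Point `k` of the curve uses the true/false-positive counts accumulated
#' over the `k` highest-ranked detections; recall divides by the total
#' number of ground-truth boxes. The interpolated precision at a recall
#' level is the maximum precision attained at that recall or any higher
#' one, which removes the sawtooth of the raw curve.
#'
#' @param tp_flags Logical vector, `TRUE` for a true positive, in rank
#'   order (confidence descending).
#' @param n_ground_truth Number of ground-truth boxes (recall denominator).
#' @return Data.frame with columns `recall`, `precision`,
#'   `precision_interp`, one row per detection rank.
#' @export
precision_recall_curve <- function(tp_flags, n_ground_truth) {
  stopifnot(is.logical(tp_flags), is_count(n_ground_truth))
  if (length(tp_flags) == 0) {
    return(data.frame(recall = numeric(0), precision = numeric(0),
                      precision_interp = numeric(0)))
  }
  if (n_ground_truth == 0) {
    stop_fw("recall is undefined: detections present but no ground-truth boxes")
  }
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  precision <- cum_tp / (cum_tp + cum_fp)
  recall <- cum_tp / n_ground_truth
  suffix_max <- rev(cummax(rev(precision)))
  first_at_recall <- match(recall, recall)  # first rank reaching each recall level
  data.frame(recall = recall, precision = precision,
             precision_interp = suffix_max[first_at_recall])
}

#' 11-point interpolated average precision
#'
#' The average of the interpolated precision over the recall grid
#' `{0, 0.1, ..., 1}`: at each grid value the maximum precision among all
#' curve points with at least that recall is taken (0 where no point
#' reaches the grid recall).
#'
#' @param curve Output of [precision_recall_curve()].
#' @return AP in `[0, 1]`; an empty curve gives 0.
#' @export
interpolated_ap <- function(curve) {
  if (nrow(curve) == 0) return(0)
  grid <- seq(0, 1, by = 0.1)
  p_at <- vapply(grid, function(r) {
    ok <- curve$recall >= r - 1e-12
    if (any(ok)) max(curve$precision[ok]) else 0
  }, numeric(1))
  mean(p_at)
}

#' Evaluate a detector against ground-truth annotations
#'
#' The full evaluation chain: rank detections by confidence, assign
#' TP/FP/FN per class with [match_detections()], build per-class
#' precision-recall curves, average precision by 11-point interpolation,
#' and summarize. With a single class the mAP equals that class's AP.
#' `average_iou` is the mean IoU over true-positive matches.
#'
#' @inheritParams match_detections
#' @return Object of class `"detector_eval"`: a list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `ap` (named per-class vector), `map`,
#'   `average_iou` and `n_classes`.
#' @export
evaluate_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  if (nrow(ground_truth) == 0) stop_fw("no ground-truth annotations to evaluate against")
  classes <- sort(unique(ground_truth$class_id))
  tp <- fp <- fn <- 0L
  ious <- numeric(0)
  ap <- stats::setNames(numeric(length(classes)), as.character(classes))
  for (cl in classes) {
    det_c <- detections[detections$class_id == cl, , drop = FALSE]
    gt_c <- ground_truth[ground_truth$class_id == cl, , drop = FALSE]
    m <- match_detections(det_c, gt_c, iou_threshold)
    tp <- tp + sum(m$detections$tp)
    fp <- fp + sum(!m$detections$tp)
    fn <- fn + m$fn
    ious <- c(ious, m$detections$matched_iou[m$detections$tp])
    curve <- precision_recall_curve(m$detections$tp, nrow(gt_c))
    ap[[as.character(cl)]] <- interpolated_ap(curve)
  }
  # detections of classes absent from the ground truth are false positives
  stray <- detections[!detections$class_id %in% classes, , drop = FALSE]
  fp <- fp + nrow(stray)
  out <- list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ap = ap,
    map = mean(ap),
    average_iou = if (length(ious)) mean(ious) else NA_real_,
    n_classes = length(classes)
  )
  class(out) <- "detector_eval"
  out
}

#' @export
print.detector_eval <- function(x, ...) {
  cat("Detector evaluation (", x$n_classes, " class",
      if (x$n_classes != 1) "es", ")\n", sep = "")
  cat(sprintf("  recall:      %6.2f %%\n", 100 * x$recall))
  cat(sprintf("  precision:   %6.2f %%\n", 100 * x$precision))
  cat(sprintf("  average IoU: %6.2f %%\n", 100 * x$average_iou))
  cat(sprintf("  mAP:         %6.2f %%\n", 100 * x$map))
  cat(sprintf("  TP %d / FP %d / FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Write a detector-evaluation report
#'
#' Flat key:value report of the summary statistics, as JSON or plain text.
#'
#' @param summary A `"detector_eval"` object from [evaluate_detections()].
#' @param path Output file path.
#' @param format `"json"` or `"txt"`.
#' @export
write_eval_report <- function(summary, path, format = c("json", "txt")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "detector_eval"))
  flat <- list(recall = summary$recall, precision = summary$precision,
               average_iou = summary$average_iou, map = summary$map,
               tp = summary$tp, fp = summary$fp, fn = summary$fn,
               n_classes = summary$n_classes)
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("%s: %s", names(flat), unlist(flat)), path)
  }
  invisible(path)
}
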