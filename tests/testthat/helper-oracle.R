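# Independent brute-force oracles, written as plain loops straight from the
# definitions so they share no code path with the package implementation.

oracle_iou <- function(a, b) {
  corners <- function(bx) {
    x1 <- max(bx[["cx"]] - bx[["w"]] / 2, 0); x2 <- min(bx[["cx"]] + bx[["w"]] / 2, 1)
    y1 <- max(bx[["cy"]] - bx[["h"]] / 2, 0); y2 <- min(bx[["cy"]] + bx[["h"]] / 2, 1)
    c(x1, x2, y1, y2)
  }
  ca <- corners(a); cb <- corners(b)
  iw <- min(ca[2], cb[2]) - max(ca[1], cb[1])
  ih <- min(ca[4], cb[4]) - max(ca[3], cb[3])
  inter <- if (iw > 0 && ih > 0) iw * ih else 0
  area_a <- (ca[2] - ca[1]) * (ca[4] - ca[3])
  area_b <- (cb[2] - cb[1]) * (cb[4] - cb[3])
  inter / (area_a + area_b - inter)
}

# full evaluation by literal definitions: rank, greedy match, accumulate,
# 11-point interpolation, average over ground-truth classes
oracle_evaluate <- function(detections, ground_truth, iou_threshold = 0.5) {
  classes <- sort(unique(ground_truth$class_id))
  total_tp <- 0; total_fp <- 0; total_fn <- 0
  tp_ious <- c()
  aps <- c()
  for (cl in classes) {
    det <- detections[detections$class_id == cl, , drop = FALSE]
    gt <- ground_truth[ground_truth$class_id == cl, , drop = FALSE]
    ord <- order(-det$confidence, det$image_id, seq_len(nrow(det)))
    det <- det[ord, , drop = FALSE]
    used <- rep(FALSE, nrow(gt))
    flags <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      best_iou <- -1; best_j <- 0
      for (j in seq_len(nrow(gt))) {
        if (used[j]) next
        if (gt$image_id[j] != det$image_id[i]) next
        v <- oracle_iou(det[i, ], gt[j, ])
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0 && best_iou >= iou_threshold) {
        flags[i] <- TRUE
        used[best_j] <- TRUE
        tp_ious <- c(tp_ious, best_iou)
      }
    }
    total_tp <- total_tp + sum(flags)
    total_fp <- total_fp + sum(!flags)
    total_fn <- total_fn + sum(!used)
    # precision/recall at each rank, then the 11-point interpolated AP
    ap <- 0
    for (r in seq(0, 1, by = 0.1)) {
      best_p <- 0
      tp_cum <- 0
      for (i in seq_along(flags)) {
        tp_cum <- tp_cum + flags[i]
        rec <- tp_cum / nrow(gt)
        prec <- tp_cum / i
        if (rec >= r - 1e-12 && prec > best_p) best_p <- prec
      }
      ap <- ap + best_p / 11
    }
    aps <- c(aps, ap)
  }
  total_fp <- total_fp + sum(!detections$class_id %in% classes)
  list(tp = total_tp, fp = total_fp, fn = total_fn,
       precision = if (total_tp + total_fp > 0) total_tp / (total_tp + total_fp) else NA_real_,
       recall = if (total_tp + total_fn > 0) total_tp / (total_tp + total_fn) else NA_real_,
       map = mean(aps),
       average_iou = if (length(tp_ious)) mean(tp_ious) else NA_real_)
}

# windowed trailing mean by explicit loop; denominator counts positions
# overlapping the series
oracle_windowed_mean <- function(values, k, min_coverage) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- values[max(1, i - k + 1):i]
    n_positions <- min(i, k)
    present <- win[!is.na(win)]
    if (length(present) > 0 && length(present) / n_positions >= min_coverage) {
      out[i] <- mean(present)
    }
  }
  out
}

# the 4-branch camera-fusion decision tree, one sample at a time
oracle_fuse <- function(a, b) {
  mapply(function(x, y) {
    if (is.na(x) && is.na(y)) return(NA_real_)
    if (is.na(x)) return(y)
    if (is.na(y)) return(x)
    if (x == y) x else max(x, y)
  }, a, b)
}
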