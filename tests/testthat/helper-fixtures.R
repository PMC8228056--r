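# Random generators for fixtures; everything is built in code at test time.

random_box <- function() {
  w <- runif(1, 0.05, 0.4)
  h <- runif(1, 0.05, 0.4)
  c(cx = runif(1, w / 2, 1 - w / 2), cy = runif(1, h / 2, 1 - h / 2), w = w, h = h)
}

random_annotations <- function(n, n_classes = 3) {
  boxes <- t(vapply(seq_len(n), function(i) random_box(), numeric(4)))
  data.frame(class_id = sample.int(n_classes, n, replace = TRUE) - 1L,
             cx = boxes[, 1], cy = boxes[, 2], w = boxes[, 3], h = boxes[, 4])
}

# a small random detection-evaluation instance (<= max_boxes boxes per side)
random_eval_instance <- function(max_boxes = 6, n_images = 3, n_classes = 2) {
  n_gt <- sample.int(max_boxes, 1)
  gt <- random_annotations(n_gt, n_classes)
  gt$image_id <- sample(paste0("img", seq_len(n_images)), n_gt, replace = TRUE)
  n_det <- sample.int(max_boxes + 1, 1) - 1L
  det <- if (n_det > 0) {
    # mix of perturbed ground-truth boxes and unrelated boxes
    rows <- lapply(seq_len(n_det), function(i) {
      if (runif(1) < 0.6 && n_gt > 0) {
        src <- gt[sample.int(n_gt, 1), ]
        src$cx <- min(max(src$cx + rnorm(1, 0, 0.05), 0.01), 1)
        src$cy <- min(max(src$cy + rnorm(1, 0, 0.05), 0.01), 1)
        src
      } else {
        b <- random_box()
        data.frame(class_id = sample(unique(gt$class_id), 1),
                   cx = b[["cx"]], cy = b[["cy"]], w = b[["w"]], h = b[["h"]],
                   image_id = sample(paste0("img", seq_len(n_images)), 1))
      }
    })
    out <- do.call(rbind, rows)
    out$confidence <- runif(n_det)
    out
  } else {
    data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0), image_id = character(0),
               confidence = numeric(0))
  }
  list(detections = det, ground_truth = gt)
}

# a per-second motion series with a random missingness pattern
random_series <- function(n = 120, p_missing = 0.2) {
  v <- runif(n, 0, 0.3)
  v[runif(n) < p_missing] <- NA
  motion_series(seq_len(n) - 1, v)
}

# one-camera detection stream built directly from positions
stream_from_centers <- function(cx, cy, camera_id = "camA", fps = 5) {
  n <- length(cx)
  data.frame(camera_id = camera_id, frame_index = 0:(n - 1),
             time_s = (0:(n - 1)) / fps,
             cx = cx, cy = cy,
             w = ifelse(is.na(cx), NA_real_, 0.1),
             h = ifelse(is.na(cx), NA_real_, 0.1),
             confidence = ifelse(is.na(cx), NA_real_, 0.9))
}

scripted_half_hour <- data.frame(
  level = c("high_active", "active", "inactive"),
  duration_s = c(550, 550, 700)
)
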