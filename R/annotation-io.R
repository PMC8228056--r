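#' Parse YOLO/LabelImg annotation text
#'
#' Reads the one-file-per-image plain-text annotation dialect used by
#' LabelImg and the Darknet tooling: one labeled object per line,
#' `"<class> <cx> <cy> <w> <h>"`, whitespace-separated, with the box stored
#' as its normalized center, width and height (fractions of the image
#' dimensions, each in `(0, 1]`). Coordinates use the image convention:
#' origin top-left, y increasing downward.
#'
#' @param text Character vector: either a single string holding the whole
#'   file content, or one element per line.
#' @param lenient If `TRUE`, coordinates outside `(0, 1]` are clipped into
#'   `[1e-6, 1]` instead of raising an error (useful for real-world label
#'   files with slight overshoot).
#' @return A data.frame with columns `class_id` (integer), `cx`, `cy`, `w`,
#'   `h` (numeric), one row per labeled object, input order preserved. An
#'   empty file yields zero rows.
#' @seealso [format_yolo_annotations()] for the inverse.
#' @export
#' @examples
#' parse_yolo_annotations("0 0.5 0.5 0.2 0.1")
parse_yolo_annotations <- function(text, lenient = FALSE) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) != 5) {
      stop_fw("annotation line %d: expected 5 tokens, got %d", i, length(tok))
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) stop_fw("annotation line %d: non-numeric token", i)
    cls <- vals[[1]]
    if (cls < 0 || cls != floor(cls)) {
      stop_fw("annotation line %d: class id must be a non-negative integer", i)
    }
    box <- vals[2:5]
    if (any(box <= 0) || any(box > 1)) {
      if (lenient) {
        box <- pmin(pmax(box, 1e-6), 1)
      } else {
        stop_fw("annotation line %d: coordinates must lie in (0, 1]", i)
      }
    }
    out[nrow(out) + 1L, ] <- list(as.integer(cls), box[[1]], box[[2]], box[[3]], box[[4]])
  }
  out
}

#' Format annotations as YOLO/LabelImg text
#'
#' Inverse of [parse_yolo_annotations()]: `parse(format(a))` reproduces `a`
#' exactly (full double precision is written).
#'
#' @param annotations Data.frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @return A single string; `""` for zero annotations.
#' @export
format_yolo_annotations <- function(annotations) {
  req <- c("class_id", "cx", "cy", "w", "h")
  if (!all(req %in% names(annotations))) {
    stop_fw("annotations must have columns %s", paste(req, collapse = ", "))
  }
  if (nrow(annotations) == 0) return("")
  box <- as.matrix(annotations[, c("cx", "cy", "w", "h")])
  if (any(!is.finite(box)) || any(box <= 0) || any(box > 1)) {
    stop_fw("box coordinates must lie in (0, 1]")
  }
  if (any(annotations$class_id < 0 | annotations$class_id != floor(annotations$class_id))) {
    stop_fw("class ids must be non-negative integers")
  }
  paste(sprintf("%d %.17g %.17g %.17g %.17g",
                as.integer(annotations$class_id),
                annotations$cx, annotations$cy, annotations$w, annotations$h),
        collapse = "\n")
}

#' @rdname parse_yolo_annotations
#' @param path File path of a `.txt` annotation file.
#' @export
read_yolo_annotations <- function(path, lenient = FALSE) {
  parse_yolo_annotations(readLines(path, warn = FALSE), lenient = lenient)
}

#' @rdname format_yolo_annotations
#' @param path File path to write to.
#' @export
write_yolo_annotations <- function(annotations, path) {
  writeLines(format_yolo_annotations(annotations), path)
  invisible(path)
}

#' Write an image list file (train.txt / test.txt)
#'
#' One image path per line, the listing format the Darknet training tooling
#' expects for its train/test manifests.
#'
#' @param paths Character vector of image paths.
#' @param file Output file path.
#' @export
write_image_list <- function(paths, file) {
  stopifnot(is.character(paths))
  writeLines(paths, file)
  invisible(file)
}

#' Stratified train/test split with largest-remainder allocation
#'
#' Splits items into a training and a test set while preserving the
#' proportions of the strata (e.g. day vs night scenes). The total training
#' size is `floor(train_fraction * N)`; each stratum receives the floor of
#' its proportional quota and the remaining seats go to the strata with the
#' largest fractional remainders (ties broken by stratum size, then label).
#' Membership within each stratum is randomized under `seed`.
#'
#' @param items Vector of items (paths, ids, ...).
#' @param strata Vector of stratum labels, same length as `items`.
#' @param train_fraction Fraction in (0, 1) of items assigned to training.
#' @param seed Integer seed for the within-stratum randomization, or `NULL`
#'   to use the current RNG state.
#' @return List with elements `train` and `test` (disjoint subsets of
#'   `items` whose union is `items`), plus attribute `"allocation"`: a
#'   data.frame of per-stratum train counts.
#' @export
#' @examples
#' s <- stratified_split(1:10, rep(c("day", "night"), 5), 0.5, seed = 1)
#' lengths(s)
stratified_split <- function(items, strata, train_fraction, seed = NULL) {
  n <- length(items)
  if (n == 0) stop_fw("cannot split an empty item list")
  if (length(strata) != n) stop_fw("items and strata must have equal length")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_fw("train_fraction must lie strictly between 0 and 1")
  }
  strata <- as.character(strata)
  n_train <- floor(train_fraction * n)
  sizes <- table(strata)
  quota <- train_fraction * as.numeric(sizes)
  base <- floor(quota)
  rem <- quota - base
  deficit <- n_train - sum(base)
  alloc <- base
  if (deficit > 0) {
    ord <- order(-rem, -as.numeric(sizes), names(sizes))
    topup <- ord[seq_len(deficit)]
    alloc[topup] <- alloc[topup] + 1
  }
  names(alloc) <- names(sizes)
  train_idx <- integer(0)
  with_seed(seed, {
    for (s in names(sizes)) {
      idx <- which(strata == s)
      k <- alloc[[s]]
      train_idx <- c(train_idx, if (k > 0) sample(idx, k) else integer(0))
    }
  })
  train_idx <- sort(train_idx)
  out <- list(train = items[train_idx], test = items[setdiff(seq_len(n), train_idx)])
  attr(out, "allocation") <- data.frame(stratum = names(alloc),
                                        n_total = as.integer(sizes),
                                        n_train = as.integer(alloc),
                                        row.names = NULL)
  out
}

#' Darknet configuration arithmetic
#'
#' The derived values a Darknet-style single-stage detector configuration
#' needs for a given number of object classes: `max_batches` is
#' `2000 * n_classes`, the learning-rate `steps` are 80% and 90% of
#' `max_batches`, and the pre-head convolutional `filters` count is
#' `(n_classes + 5) * 3` (three anchors, each predicting 4 box coordinates,
#' 1 objectness score and the class scores).
#'
#' @param n_classes Positive integer number of detection classes.
#' @return List with integer elements `max_batches`, `steps`
#'   (length-2 vector) and `filters`.
#' @export
#' @examples
#' darknet_config_values(1)
darknet_config_values <- function(n_classes) {
  if (!is_count(n_classes) || n_classes < 1) {
    stop_fw("n_classes must be a positive integer")
  }
  max_batches <- 2000L * as.integer(n_classes)
  list(max_batches = max_batches,
       steps = as.integer(c(0.8 * max_batches, 0.9 * max_batches)),
       filters = (as.integer(n_classes) + 5L) * 3L)
}

detection_stream_cols <- c("camera_id", "frame_index", "time_s",
                           "cx", "cy", "w", "h", "confidence")

# shared validation for in-memory detection streams
validate_detection_stream <- function(records) {
  miss <- setdiff(detection_stream_cols, names(records))
  if (length(miss)) stop_fw("detection stream lacks column(s): %s", paste(miss, collapse = ", "))
  key <- paste(records$camera_id, records$frame_index)
  if (anyDuplicated(key)) {
    stop_fw("duplicate (camera_id, frame_index) pair: %s", key[anyDuplicated(key)])
  }
  box <- records[, c("cx", "cy", "w", "h")]
  box_na <- is.na(box)
  partial <- rowSums(box_na) %in% c(1L, 2L, 3L)
  if (any(partial)) stop_fw("partially specified bounding box in row %d", which(partial)[1])
  absent <- box_na[, 1]
  if (any(absent & !is.na(records$confidence))) {
    stop_fw("confidence present for a row without a bounding box")
  }
  present <- !absent
  if (any(present)) {
    vals <- as.matrix(box[present, ])
    if (any(vals <= 0) || any(vals > 1)) {
      stop_fw("bounding-box coordinates must lie in (0, 1]")
    }
  }
  conf <- records$confidence[!is.na(records$confidence)]
  if (any(conf < 0 | conf > 1)) stop_fw("confidence must lie in [0, 1]")
  invisible(records)
}

#' Read a per-frame detection stream
#'
#' A detection stream is a CSV table with one row per (camera, frame):
#' columns `camera_id`, `frame_index`, `time_s`, `cx`, `cy`, `w`, `h`,
#' `confidence`. Frames on which the detector found nothing leave the box
#' and confidence fields empty. Rows are returned sorted by
#' `(camera_id, frame_index)`.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @return Data.frame of detection records; absent boxes are `NA`.
#' @export
read_detection_stream <- function(path) {
  records <- utils::read.csv(path, colClasses = c(camera_id = "character"),
                             stringsAsFactors = FALSE)
  for (col in c("frame_index", "time_s", "cx", "cy", "w", "h", "confidence")) {
    if (col %in% names(records)) records[[col]] <- as.numeric(records[[col]])
  }
  records$frame_index <- as.integer(records$frame_index)
  validate_detection_stream(records)
  records <- records[order(records$camera_id, records$frame_index), detection_stream_cols]
  rownames(records) <- NULL
  records
}

#' @rdname read_detection_stream
#' @param records Data.frame of detection records.
#' @export
write_detection_stream <- function(records, path) {
  validate_detection_stream(records)
  records <- records[order(records$camera_id, records$frame_index), detection_stream_cols]
  out <- records
  for (col in c("time_s", "cx", "cy", "w", "h", "confidence")) {
    x <- records[[col]]
    out[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
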