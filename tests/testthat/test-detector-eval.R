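box <- function(cx, cy, w, h) c(cx = cx, cy = cy, w = w, h = h)

test_that("IoU handles identity, disjoint and partial-overlap cases", {
  b <- box(0.5, 0.5, 0.2, 0.1)
  expect_equal(box_iou(b, b), 1)
  expect_equal(box_iou(box(0.2, 0.2, 0.1, 0.1), box(0.8, 0.8, 0.1, 0.1)), 0)
  # intersection 0.1 x 0.2 = 0.02; union 0.04 + 0.04 - 0.02 = 0.06
  expect_equal(box_iou(box(0.5, 0.5, 0.2, 0.2), box(0.6, 0.5, 0.2, 0.2)), 1 / 3)
  expect_error(box_iou(box(0.5, 0.5, 0, 0.1), b), "zero-area")
})

test_that("IoU is symmetric, bounded and translation invariant", {
  set.seed(31)
  for (i in 1:50) {
    a <- random_box()
    b <- random_box()
    v <- box_iou(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, box_iou(b, a))
    expect_equal(v, oracle_iou(a, b))
    # shift both boxes by the same interior-safe offset
    d <- runif(2, -0.02, 0.02)
    a2 <- a + c(d, 0, 0); b2 <- b + c(d, 0, 0)
    if (all(c(a2[1] - a2[3]/2, b2[1] - b2[3]/2) >= 0) &&
        all(c(a2[1] + a2[3]/2, b2[1] + b2[3]/2) <= 1) &&
        all(c(a2[2] - a2[4]/2, b2[2] - b2[4]/2) >= 0) &&
        all(c(a2[2] + a2[4]/2, b2[2] + b2[4]/2) <= 1)) {
      expect_equal(box_iou(a2, b2), v, tolerance = 1e-12)
    }
  }
})

test_that("greedy one-to-one matching assigns TP, FP and FN as specified", {
  gt <- data.frame(image_id = "i1", class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  det1 <- data.frame(image_id = "i1", class_id = 0L, cx = 0.51, cy = 0.5,
                     w = 0.2, h = 0.2, confidence = 0.9)
  m <- match_detections(det1, gt)
  expect_equal(sum(m$detections$tp), 1)
  expect_equal(m$fn, 0)

  none <- det1[0, ]
  m0 <- match_detections(none, gt)
  expect_equal(m0$fn, 1)

  # two detections of the same single object: second becomes FP
  det2 <- rbind(det1, transform(det1, cx = 0.53, confidence = 0.8))
  m2 <- match_detections(det2, gt)
  expect_equal(m2$detections$tp, c(TRUE, FALSE))
  expect_equal(m2$fn, 0)
})

test_that("matching respects image and class boundaries", {
  gt <- data.frame(image_id = c("i1", "i2"), class_id = c(0L, 1L),
                   cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  det <- data.frame(image_id = c("i2", "i2"), class_id = c(0L, 1L),
                    cx = 0.5, cy = 0.5, w = 0.2, h = 0.2,
                    confidence = c(0.9, 0.8))
  m <- match_detections(det, gt)
  # class-0 detection sits on image i2 whose only box is class 1
  expect_equal(m$detections$tp[m$detections$class_id == 0L], FALSE)
  expect_equal(m$detections$tp[m$detections$class_id == 1L], TRUE)
  expect_equal(m$fn, 1)
})

test_that("precision-recall curve accumulates rank by rank", {
  expect_equal(precision_recall_curve(TRUE, 1),
               data.frame(recall = 1, precision = 1, precision_interp = 1))
  expect_equal(precision_recall_curve(FALSE, 1),
               data.frame(recall = 0, precision = 0, precision_interp = 0))
  cv <- precision_recall_curve(c(TRUE, FALSE, TRUE), 2)
  expect_equal(cv$recall, c(0.5, 0.5, 1))
  expect_equal(cv$precision, c(1, 0.5, 2 / 3))
  expect_equal(cv$precision_interp, c(1, 1, 2 / 3))
  # interpolated precision never increases with recall
  expect_true(all(diff(cv$precision_interp) <= 1e-12))
  expect_error(precision_recall_curve(c(TRUE, FALSE), 0), "no ground-truth")
})

test_that("11-point AP matches hand-computed grids", {
  perfect <- precision_recall_curve(rep(TRUE, 4), 4)
  expect_equal(interpolated_ap(perfect), 1)
  allfp <- precision_recall_curve(rep(FALSE, 3), 2)
  expect_equal(interpolated_ap(allfp), 0)
  cv <- precision_recall_curve(c(TRUE, FALSE, TRUE), 2)
  expect_equal(interpolated_ap(cv), (6 * 1 + 5 * 2 / 3) / 11)
  expect_equal(interpolated_ap(precision_recall_curve(logical(0), 3)), 0)
})

test_that("AP ignores rank-trailing false positives beyond the last recall gain", {
  set.seed(13)
  for (i in 1:20) {
    flags <- runif(8) < 0.5
    n_gt <- sum(flags) + sample.int(3, 1)
    base <- interpolated_ap(precision_recall_curve(flags, n_gt))
    extended <- interpolated_ap(precision_recall_curve(c(flags, FALSE, FALSE), n_gt))
    expect_equal(extended, base)
  }
})

test_that("perfect single-class detections score 100% across the board", {
  set.seed(5)
  gt <- random_annotations(5, n_classes = 1)
  gt$image_id <- paste0("img", 1:5)
  det <- gt
  det$confidence <- runif(5, 0.8, 1)
  ev <- evaluate_detections(det, gt)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$map, 1)
  expect_equal(ev$average_iou, 1)
  expect_equal(unname(ev$ap), 1)        # single class: mAP equals AP
  expect_equal(ev$map, unname(ev$ap))
  expect_error(evaluate_detections(det, gt[0, ]), "no ground-truth")
})

test_that("evaluation agrees with the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:200) {
    inst <- random_eval_instance()
    got <- evaluate_detections(inst$detections, inst$ground_truth)
    want <- oracle_evaluate(inst$detections, inst$ground_truth)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$map, want$map, tolerance = 1e-12)
    expect_equal(got$average_iou, want$average_iou, tolerance = 1e-12)
  }
})

test_that("a duplicate detection at lower rank never raises precision at fixed recall", {
  set.seed(23)
  gt <- random_annotations(3, n_classes = 1)
  gt$image_id <- "img1"
  det <- gt
  det$confidence <- c(0.9, 0.8, 0.7)
  base <- evaluate_detections(det, gt)
  dup <- rbind(det, transform(det[1, ], confidence = 0.6))
  with_dup <- evaluate_detections(dup, gt)
  expect_lte(with_dup$precision, base$precision)
  expect_equal(with_dup$recall, base$recall)
})

test_that("evaluation reports serialize as flat key:value files", {
  gt <- data.frame(image_id = "i", class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  det <- transform(gt, confidence = 0.95)
  ev <- evaluate_detections(det, gt)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, jpath)
  back <- jsonlite::read_json(jpath)
  expect_equal(back$map, 1)
  expect_equal(back$recall, 1)
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_eval_report(ev, tpath, format = "txt")
  expect_true(any(grepl("^map: 1$", readLines(tpath))))
})
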