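# Evaluation metrics: IoU, greedy matching, AP oracles, mAP monotonicity,
# and agreement with an independent 101-point interpolated evaluator.

det_df <- function(boxes, cls, score) {
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], class_id = cls, score = score)
}
truth_df <- function(boxes, cls) {
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], class_id = cls)
}

test_that("IoU basics and the rasterization oracle agree", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 1e-12)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               ref_iou_raster(c(0, 0, 2, 2), c(1, 1, 3, 3))$iou,
               tolerance = 1e-3)
})

test_that("greedy matching flags duplicates and counts misses", {
  tr <- truth_df(matrix(c(0, 0, 10, 10), 1, 4), 1L)
  de <- det_df(matrix(c(1, 1, 10, 10), 1, 4), 1L, 0.9)
  m <- match_at_threshold(de, tr, 0.5)
  expect_equal(sum(m$tp), 1); expect_equal(sum(m$fp), 0)
  expect_equal(m$n_fn, 0)
  # two detections on one truth: second is a duplicate false positive
  de2 <- det_df(matrix(c(0, 0, 10, 10, 1, 1, 10, 10), 2, 4, byrow = TRUE),
                c(1L, 1L), c(0.9, 0.8))
  m2 <- match_at_threshold(de2, tr, 0.5)
  expect_equal(sum(m2$tp), 1); expect_equal(sum(m2$fp), 1)
  # class mismatch is never matched
  de3 <- det_df(matrix(c(0, 0, 10, 10), 1, 4), 2L, 0.9)
  m3 <- match_at_threshold(de3, tr, 0.5)
  expect_equal(sum(m3$tp), 0); expect_equal(m3$n_fn, 1)
})

test_that("average precision reproduces hand-computed sweeps", {
  # all correct covering all truths
  c1 <- pr_curve(c(.9, .8), c(TRUE, TRUE), 2)
  expect_equal(average_precision(c1), 1)
  # nothing correct
  c0 <- pr_curve(c(.9, .8), c(FALSE, FALSE), 2)
  expect_equal(average_precision(c0), 0)
  # scores .9 TP, .8 FP, .7 TP on 2 truths: AP = 1*0.5 + (2/3)*0.5
  c2 <- pr_curve(c(.9, .8, .7), c(TRUE, FALSE, TRUE), 2)
  expect_equal(average_precision(c2), 1 * 0.5 + (2 / 3) * 0.5,
               tolerance = 1e-12)
})

test_that("a perfect detector scores 1 everywhere; a single class owns mAP50", {
  tr <- list(`1` = truth_df(matrix(c(5, 5, 20, 20, 30, 30, 50, 60), 2, 4,
                                   byrow = TRUE), c(1L, 1L)))
  de <- list(`1` = det_df(matrix(c(5, 5, 20, 20, 30, 30, 50, 60), 2, 4,
                                 byrow = TRUE), c(1L, 1L), c(.9, .8)))
  ev <- evaluate_detections(de, tr)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_95, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(unname(ev$per_class_ap50["1"]), ev$map50)
  expect_error(evaluate_detections(de, list(`1` = truth_df(
    matrix(numeric(), 0, 4), integer()))), "no ground-truth")
})

test_that("a worked two-class fixture matches hand-computed precision/recall/AP", {
  # class 1: two truths, dets .9 TP, .8 FP, .7 TP -> AP50 = 5/6
  # class 2: one truth, det .6 TP -> AP50 = 1
  tr <- list(img = truth_df(matrix(c(0, 0, 10, 10,
                                     20, 20, 30, 30,
                                     40, 40, 50, 50), 3, 4, byrow = TRUE),
                            c(1L, 1L, 2L)))
  de <- list(img = det_df(matrix(c(0, 0, 10, 10,
                                   60, 60, 70, 70,
                                   20, 20, 30, 30,
                                   40, 40, 50, 50), 4, 4, byrow = TRUE),
                          c(1L, 1L, 1L, 2L), c(.9, .8, .7, .6)))
  ev <- evaluate_detections(de, tr)
  expect_equal(unname(ev$per_class_ap50), c(5 / 6, 1), tolerance = 1e-12)
  expect_equal(ev$map50, (5 / 6 + 1) / 2, tolerance = 1e-12)
  expect_equal(ev$precision, 3 / 4)   # 3 TP, 1 FP at score cut 0.5
  expect_equal(ev$recall, 1)          # all 3 truths found
})

test_that("mAP50-95 never exceeds mAP50", {
  set.seed(6)
  for (rep in 1:5) {
    tr <- list(); de <- list()
    for (im in 1:3) {
      nb <- sample(1:3, 1)
      tb <- cbind(runif(nb, 0, 40), runif(nb, 0, 40), 0, 0)
      tb[, 3] <- tb[, 1] + runif(nb, 5, 20)
      tb[, 4] <- tb[, 2] + runif(nb, 5, 20)
      cls <- sample(2, nb, replace = TRUE)
      tr[[as.character(im)]] <- truth_df(tb, cls)
      jit <- tb + matrix(rnorm(nb * 4, 0, 2), nb, 4)
      jit[, 3] <- pmax(jit[, 3], jit[, 1] + 1)
      jit[, 4] <- pmax(jit[, 4], jit[, 2] + 1)
      de[[as.character(im)]] <- det_df(jit, cls, runif(nb))
    }
    ev <- evaluate_detections(de, tr)
    expect_lte(ev$map50_95, ev$map50 + 1e-12)
    expect_true(all(diff(ev$map_by_iou) <= 1e-12))
  }
})

test_that("101-point mode agrees with an independent interpolated evaluator", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- list(); de <- list()
    for (im in 1:2) {
      nb <- sample(1:4, 1)
      tb <- cbind(runif(nb, 0, 50), runif(nb, 0, 50), 0, 0)
      tb[, 3] <- tb[, 1] + runif(nb, 5, 25)
      tb[, 4] <- tb[, 2] + runif(nb, 5, 25)
      cls <- sample(2, nb, replace = TRUE)
      tr[[as.character(im)]] <- truth_df(tb, cls)
      nd <- sample(1:5, 1)
      keep <- sample(nb, min(nd, nb), replace = TRUE)
      db <- tb[keep, , drop = FALSE] +
        matrix(rnorm(length(keep) * 4, 0, 3), length(keep), 4)
      db[, 3] <- pmax(db[, 3], db[, 1] + 1)
      db[, 4] <- pmax(db[, 4], db[, 2] + 1)
      de[[as.character(im)]] <- det_df(db, cls[keep],
                                       runif(length(keep)))
    }
    ev <- evaluate_detections(de, tr, ap_mode = "coco101")
    for (cl in as.integer(names(ev$per_class_ap50))) {
      ra <- ref_coco_ap(de, tr, cl, 0.5)
      if (!is.na(ra))
        expect_equal(unname(ev$per_class_ap50[as.character(cl)]), ra,
                     tolerance = 0.01,
                     label = sprintf("rep %d class %d", rep, cl))
    }
  }
})

test_that("the FPS formula is a reciprocal law", {
  expect_equal(fps(10, 5, 5), 50)
  expect_equal(fps(500, 400, 100), 1)
  expect_equal(fps(4, 4, 2), 2 * fps(8, 8, 4))
  expect_error(fps(0, 0, 0), "positive")
  expect_error(fps(-1, 5, 5), "non-negative")
})
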