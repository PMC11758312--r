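# Detection evaluation: IoU matching, precision/recall, average precision
# (rectangle-sum by default, optional 101-point interpolation for
# cross-tool comparison), mAP50 / mAP50-95, and an FPS utility.

#' Intersection over union of two boxes
#'
#' @param a,b corner-form boxes `(x1, y1, x2, y2)`.
#' @return IoU in `[0,1]`.
#' @export
iou <- function(a, b) {
  iou_pairs(matrix(a, 1, 4), matrix(b, 1, 4))[1, 1]
}

#' Greedy score-ordered matching at an IoU threshold
#'
#' Detections are taken in descending score order; each is a true positive
#' if its best-IoU not-yet-matched same-class truth reaches the threshold,
#' otherwise a false positive. Each truth can be matched once; leftover
#' truths are false negatives.
#'
#' @param dets data.frame with `x1,y1,x2,y2,class_id,score`.
#' @param truths data.frame with `x1,y1,x2,y2,class_id`.
#' @param iou_thr IoU threshold (the conventional default is 0.5).
#' @return list with `order` (permutation sorting dets by descending
#'   score), `tp`, `fp` (logical flags in that order), `n_fn`.
#' @export
match_at_threshold <- function(dets, truths, iou_thr = 0.5) {
  nd <- nrow(dets)
  ord <- if (nd > 0) order(-dets$score) else integer()
  tp <- logical(nd); fp <- logical(nd)
  used <- logical(nrow(truths))
  for (k in seq_len(nd)) {
    i <- ord[k]
    cand <- which(!used & truths$class_id == dets$class_id[i])
    if (length(cand) == 0) { fp[k] <- TRUE; next }
    ious <- iou_pairs(matrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                             1, 4),
                      as.matrix(truths[cand, c("x1", "y1", "x2", "y2")]))[1, ]
    best <- which.max(ious)
    if (ious[best] >= iou_thr) {
      tp[k] <- TRUE
      used[cand[best]] <- TRUE
    } else fp[k] <- TRUE
  }
  list(order = ord, tp = tp, fp = fp, n_fn = sum(!used))
}

#' Precision-recall curve from matched flags
#'
#' @param scores detection scores (any order).
#' @param tp logical true-positive flags aligned with `scores`.
#' @param n_truths number of ground-truth instances.
#' @return data.frame with descending `threshold`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, tp, n_truths) {
  ord <- order(-scores)
  tp <- tp[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  data.frame(threshold = scores[ord],
             precision = ctp / (ctp + cfp),
             recall = if (n_truths > 0) ctp / n_truths else rep(0,
                                                                length(tp)))
}

#' Average precision of a precision-recall curve
#'
#' The default is the discrete rectangle sum `sum(P(s) * dR(s))` over the
#' score-ordered detections. `mode = "coco101"` instead applies the
#' 101-point interpolation protocol (precision envelope sampled at recalls
#' 0, 0.01, ..., 1) for comparability with the common COCO tooling.
#'
#' @param curve data.frame from [pr_curve()].
#' @param mode `"rectangle"` or `"coco101"`.
#' @return AP in `[0,1]`.
#' @export
average_precision <- function(curve, mode = c("rectangle", "coco101")) {
  mode <- match.arg(mode)
  if (nrow(curve) == 0) return(0)
  if (mode == "rectangle") {
    dr <- diff(c(0, curve$recall))
    return(sum(curve$precision * dr))
  }
  # precision envelope, right to left
  prec <- rev(cummax(rev(curve$precision)))
  rc <- curve$recall
  sample_at <- seq(0, 1, by = 0.01)
  idx <- findInterval(sample_at, rc, left.open = TRUE) + 1
  p <- ifelse(idx <= length(prec), prec[idx], 0)
  mean(p)
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP at IoU 0.5, mAP50, mAP50-95 (mean over IoU
#' thresholds 0.50 to 0.95 in steps of 0.05), and dataset-level
#' precision/recall at IoU 0.5 for detections above `score_cut`. Classes
#' without any ground-truth instance are excluded from the means.
#'
#' @param dets_by_image named list of detection data.frames
#'   (`x1,y1,x2,y2,class_id,score`), one per image.
#' @param truths_by_image named list of truth data.frames
#'   (`x1,y1,x2,y2,class_id`), same names.
#' @param score_cut operating score threshold for the precision/recall
#'   summary (default 0.5).
#' @param ap_mode passed to [average_precision()].
#' @return list with `per_class_ap50`, `map50`, `map50_95`, `precision`,
#'   `recall`, and the per-threshold mAP vector `map_by_iou`.
#' @export
evaluate_detections <- function(dets_by_image, truths_by_image,
                                score_cut = 0.5,
                                ap_mode = c("rectangle", "coco101")) {
  ap_mode <- match.arg(ap_mode)
  ids <- names(truths_by_image)
  n_truth_total <- sum(vapply(truths_by_image, nrow, numeric(1)))
  if (n_truth_total == 0) stop("no ground-truth instances to evaluate")
  classes <- sort(unique(unlist(lapply(truths_by_image,
                                       function(t) t$class_id))))
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap_tab <- matrix(NA_real_, length(classes), length(thrs),
                   dimnames = list(as.character(classes), NULL))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (ti in seq_along(thrs)) {
      scores <- numeric(); tp <- logical(); ntr <- 0L
      for (id in ids) {
        tr <- truths_by_image[[id]]
        tr <- tr[tr$class_id == cl, , drop = FALSE]
        de <- dets_by_image[[id]]
        de <- if (is.null(de)) NULL else de[de$class_id == cl, ,
                                            drop = FALSE]
        ntr <- ntr + nrow(tr)
        if (!is.null(de) && nrow(de) > 0) {
          mm <- match_at_threshold(de, tr, thrs[ti])
          scores <- c(scores, de$score[mm$order])
          tp <- c(tp, mm$tp)
        }
      }
      if (ntr == 0) next
      ap_tab[ci, ti] <- average_precision(pr_curve(scores, tp, ntr),
                                          ap_mode)
    }
  }
  valid <- rowSums(!is.na(ap_tab)) > 0
  per_class_ap50 <- ap_tab[, 1]
  map_by_iou <- colMeans(ap_tab[valid, , drop = FALSE])
  # dataset-level precision/recall at IoU 0.5 and the operating score cut
  tp_n <- 0L; fp_n <- 0L; fn_n <- 0L
  for (id in ids) {
    de <- dets_by_image[[id]]
    de <- if (is.null(de)) data.frame() else de[de$score >= score_cut, ,
                                                drop = FALSE]
    tr <- truths_by_image[[id]]
    if (nrow(de) == 0) { fn_n <- fn_n + nrow(tr); next }
    mm <- match_at_threshold(de, tr, 0.5)
    tp_n <- tp_n + sum(mm$tp)
    fp_n <- fp_n + sum(mm$fp)
    fn_n <- fn_n + mm$n_fn
  }
  list(per_class_ap50 = per_class_ap50,
       map50 = unname(map_by_iou[1]),
       map50_95 = mean(map_by_iou),
       precision = if (tp_n + fp_n > 0) tp_n / (tp_n + fp_n) else 0,
       recall = if (tp_n + fn_n > 0) tp_n / (tp_n + fn_n) else 0,
       map_by_iou = unname(map_by_iou))
}

#' Frames-per-second utility
#'
#' `1000 / (preprocess + inference + NMS)` with stage times in
#' milliseconds. A throughput formula only, not a benchmark.
#'
#' @param t_preprocess_ms,t_inference_ms,t_nms_ms stage times (ms, >= 0).
#' @return frames per second.
#' @export
fps <- function(t_preprocess_ms, t_inference_ms, t_nms_ms = 0) {
  if (any(c(t_preprocess_ms, t_inference_ms, t_nms_ms) < 0))
    stop("stage times must be non-negative")
  total <- t_preprocess_ms + t_inference_ms + t_nms_ms
  if (total <= 0) stop("total time must be positive")
  1000 / total
}
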