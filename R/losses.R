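# Composite training objective: VariFocal classification loss, GIoU box
# loss and L1 box loss, summed with unit weights by default.

#' Convert boxes between center and corner form
#'
#' @param boxes numeric matrix `[n,4]` (or length-4 vector) of
#'   (cx, cy, w, h) respectively (x1, y1, x2, y2) coordinates.
#' @return matrix `[n,4]` in the other convention.
#' @export
box_cxcywh_to_xyxy <- function(boxes) {
  b <- matrix(boxes, ncol = 4)
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' @rdname box_cxcywh_to_xyxy
#' @export
box_xyxy_to_cxcywh <- function(boxes) {
  b <- matrix(boxes, ncol = 4)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

# pairwise IoU between corner-form box sets [n,4] and [m,4]
iou_pairs <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    xx1 <- pmax(a[, 1], b[j, 1]); yy1 <- pmax(a[, 2], b[j, 2])
    xx2 <- pmin(a[, 3], b[j, 3]); yy2 <- pmin(a[, 4], b[j, 4])
    inter <- pmax(xx2 - xx1, 0) * pmax(yy2 - yy1, 0)
    ua <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
      (b[j, 3] - b[j, 1]) * (b[j, 4] - b[j, 2]) - inter
    out[, j] <- ifelse(ua > 0, inter / ua, 0)
  }
  out
}

# pairwise GIoU between corner-form box sets
giou_pairs <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    xx1 <- pmax(a[, 1], b[j, 1]); yy1 <- pmax(a[, 2], b[j, 2])
    xx2 <- pmin(a[, 3], b[j, 3]); yy2 <- pmin(a[, 4], b[j, 4])
    inter <- pmax(xx2 - xx1, 0) * pmax(yy2 - yy1, 0)
    un <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
      (b[j, 3] - b[j, 1]) * (b[j, 4] - b[j, 2]) - inter
    ex1 <- pmin(a[, 1], b[j, 1]); ey1 <- pmin(a[, 2], b[j, 2])
    ex2 <- pmax(a[, 3], b[j, 3]); ey2 <- pmax(a[, 4], b[j, 4])
    ec <- (ex2 - ex1) * (ey2 - ey1)
    out[, j] <- inter / un - (ec - un) / ec
  }
  out
}

#' VariFocal classification loss
#'
#' IoU-aware asymmetric focal loss: a positive element with target quality
#' `q > 0` contributes `-q * (q log p + (1 - q) log(1 - p))`; a negative
#' element (`q = 0`) contributes `-alpha * p^gamma * log(1 - p)`. The batch
#' value is the element sum divided by the number of positives (clamped to
#' at least 1).
#'
#' @param pred_iacs predicted IoU-aware classification scores in `[0,1]`.
#' @param target_q target qualities in `[0,1]` (matched: IoU with the
#'   assigned truth; negatives: 0).
#' @param alpha negative-sample weight (default 0.75).
#' @param gamma negative-sample focusing exponent (default 2).
#' @param eps clipping bound for the logarithms.
#' @return scalar loss.
#' @export
varifocal_loss <- function(pred_iacs, target_q, alpha = 0.75, gamma = 2,
                           eps = 1e-7) {
  if (alpha < 0 || gamma < 0) stop("alpha and gamma must be >= 0")
  p <- pmin(pmax(pred_iacs, eps), 1 - eps)
  q <- target_q
  pos <- -q * (q * log(p) + (1 - q) * log(1 - p))
  neg <- ifelse(q > 0, 0, -alpha * p^gamma * log(1 - p))
  sum(pos + neg) / max(1, sum(q > 0))
}

#' GIoU loss for one box pair
#'
#' `1 - IoU + (area(enclosing) - area(union)) / area(enclosing)`;
#' 0 for identical boxes, approaching 2 for far-separated boxes.
#'
#' @param pred,truth corner-form boxes `(x1, y1, x2, y2)` with positive
#'   area.
#' @return scalar in `[0, 2)`.
#' @export
giou_loss <- function(pred, truth) {
  for (b in list(pred, truth)) {
    if (b[3] <= b[1] || b[4] <= b[2])
      stop("degenerate (non-positive-area) box")
  }
  1 - giou_pairs(matrix(pred, 1), matrix(truth, 1))[1, 1]
}

#' Mean absolute error between box coordinate vectors
#'
#' @param preds,truths `[N,4]` matrices (normalized cx, cy, w, h).
#' @return mean of `|preds - truths|` over all entries.
#' @export
l1_box_loss <- function(preds, truths) {
  p <- matrix(preds, ncol = 4); t <- matrix(truths, ncol = 4)
  if (nrow(p) != nrow(t)) stop("length mismatch between preds and truths")
  mean(abs(p - t))
}

#' Default loss configuration
#' @param alpha,gamma VariFocal negative-branch parameters.
#' @param weights term weights (unit by default).
#' @param eps log clipping bound.
#' @return config list for [total_loss()].
#' @export
loss_config <- function(alpha = 0.75, gamma = 2,
                        weights = c(vfl = 1, giou = 1, l1 = 1),
                        eps = 1e-7) {
  list(alpha = alpha, gamma = gamma, weights = weights, eps = eps)
}

#' Composite set-prediction loss
#'
#' VariFocal over every query/class element (matched queries target their
#' assigned truth's IoU at the truth's class, everything else 0); GIoU and
#' L1 over matched pairs only, averaged over the number of positives.
#'
#' @param predictions list with `scores` (`[K, n_classes]` sigmoid scores)
#'   and `boxes` (`[K,4]` normalized cx, cy, w, h).
#' @param truths list with `labels` (1-based ids) and `boxes` (`[m,4]`
#'   normalized cx, cy, w, h); `m = 0` allowed.
#' @param match result of [hungarian_match()] for these inputs.
#' @param config from [loss_config()].
#' @return list with `l_vfl`, `l_giou`, `l_l1`, `total`.
#' @export
total_loss <- function(predictions, truths, match, config = loss_config()) {
  K <- nrow(predictions$scores)
  nc <- ncol(predictions$scores)
  target <- matrix(0, K, nc)
  np <- nrow(match$pairs)
  if (np > 0) {
    pi <- match$pairs[, "pred"]; ti <- match$pairs[, "truth"]
    pxy <- box_cxcywh_to_xyxy(predictions$boxes[pi, , drop = FALSE])
    txy <- box_cxcywh_to_xyxy(truths$boxes[ti, , drop = FALSE])
    ious <- diag(iou_pairs(pxy, txy))
    target[cbind(pi, truths$labels[ti])] <- ious
    l_giou <- sum(vapply(seq_len(np), function(k)
      1 - giou_pairs(pxy[k, , drop = FALSE],
                     txy[k, , drop = FALSE])[1, 1], numeric(1))) / np
    l_l1 <- sum(abs(predictions$boxes[pi, , drop = FALSE] -
                      truths$boxes[ti, , drop = FALSE])) / (4 * np)
  } else {
    l_giou <- 0
    l_l1 <- 0
  }
  l_vfl <- varifocal_loss(predictions$scores, target,
                          config$alpha, config$gamma, config$eps)
  w <- config$weights
  list(l_vfl = l_vfl, l_giou = l_giou, l_l1 = l_l1,
       total = w[["vfl"]] * l_vfl + w[["giou"]] * l_giou +
         w[["l1"]] * l_l1)
}

# ---- tape-level loss for training -------------------------------------

# scores/boxes are ag matrices from decoder_run_ag; match is detached
loss_run_ag <- function(scores, boxes, truths, match,
                        config = loss_config()) {
  K <- nrow(scores$val); nc <- ncol(scores$val)
  np <- nrow(match$pairs)
  target <- matrix(0, K, nc)
  npos <- max(1, np)
  if (np > 0) {
    pi <- match$pairs[, "pred"]; ti <- match$pairs[, "truth"]
    pxy <- box_cxcywh_to_xyxy(boxes$val[pi, , drop = FALSE])
    txy <- box_cxcywh_to_xyxy(truths$boxes[ti, , drop = FALSE])
    target[cbind(pi, truths$labels[ti])] <- diag(iou_pairs(pxy, txy))
  }
  p <- ag_clamp(scores, config$eps, 1 - config$eps)
  lp <- ag_log(p)
  l1m <- ag_log(ag_crsub(1, p))
  pos <- ag_cmul(ag_add(ag_cmul(lp, target), ag_cmul(l1m, 1 - target)),
                 -target)
  negmask <- (target == 0) * config$alpha
  neg <- ag_cmul(ag_mul(ag_pow_const(p, config$gamma), ag_neg(l1m)),
                 negmask)
  l_vfl <- ag_cmul(ag_sum(ag_add(pos, neg)), 1 / npos)
  if (np > 0) {
    pb <- ag_index_rows(boxes, match$pairs[, "pred"])
    tb <- truths$boxes[match$pairs[, "truth"], , drop = FALSE]
    txy <- box_cxcywh_to_xyxy(tb)
    cx <- ag_index_cols(pb, 1L); cy <- ag_index_cols(pb, 2L)
    w2 <- ag_cmul(ag_index_cols(pb, 3L), 0.5)
    h2 <- ag_cmul(ag_index_cols(pb, 4L), 0.5)
    px1 <- ag_sub(cx, w2); px2 <- ag_add(cx, w2)
    py1 <- ag_sub(cy, h2); py2 <- ag_add(cy, h2)
    xx1 <- ag_cpmax(px1, txy[, 1]); yy1 <- ag_cpmax(py1, txy[, 2])
    xx2 <- ag_cpmin(px2, txy[, 3]); yy2 <- ag_cpmin(py2, txy[, 4])
    inter <- ag_mul(ag_cpmax(ag_sub(xx2, xx1), 0),
                    ag_cpmax(ag_sub(yy2, yy1), 0))
    ap <- ag_mul(ag_sub(px2, px1), ag_sub(py2, py1))
    at <- (txy[, 3] - txy[, 1]) * (txy[, 4] - txy[, 2])
    un <- ag_sub(ag_cadd(ap, at), inter)
    iou <- ag_div(inter, un)
    ex1 <- ag_cpmin(px1, txy[, 1]); ey1 <- ag_cpmin(py1, txy[, 2])
    ex2 <- ag_cpmax(px2, txy[, 3]); ey2 <- ag_cpmax(py2, txy[, 4])
    ec <- ag_mul(ag_sub(ex2, ex1), ag_sub(ey2, ey1))
    giou_vec <- ag_add(ag_crsub(1, iou), ag_div(ag_sub(ec, un), ec))
    l_giou <- ag_cmul(ag_sum(giou_vec), 1 / np)
    l_l1 <- ag_cmul(ag_sum(ag_abs(ag_cadd(pb, -tb))), 1 / (4 * np))
  } else {
    l_giou <- ag_const(scores$tape, 0)
    l_l1 <- ag_const(scores$tape, 0)
  }
  w <- config$weights
  total <- ag_add(ag_cmul(l_vfl, w[["vfl"]]),
                  ag_add(ag_cmul(l_giou, w[["giou"]]),
                         ag_cmul(l_l1, w[["l1"]])))
  list(l_vfl = l_vfl, l_giou = l_giou, l_l1 = l_l1, total = total)
}
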