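# Independent oracles used across the test files. These are deliberately
# written as plain straight-line R (naive loops, no shared code with the
# package's compute paths) so they can serve as references.

# naive direct convolution on a [C,H,W] array
ref_conv2d <- function(x, w, b = NULL, stride = 1, pad = c(0, 0)) {
  pad <- rep(pad, length.out = 2)
  d <- dim(x); Cin <- d[1]; H <- d[2]; W <- d[3]
  wd <- dim(w); Cout <- wd[1]; kh <- wd[3]; kw <- wd[4]
  xp <- array(0, c(Cin, H + 2 * pad[1], W + 2 * pad[2]))
  xp[, pad[1] + seq_len(H), pad[2] + seq_len(W)] <- x
  H2 <- (dim(xp)[2] - kh) %/% stride + 1
  W2 <- (dim(xp)[3] - kw) %/% stride + 1
  y <- array(0, c(Cout, H2, W2))
  for (oc in seq_len(Cout)) {
    for (i in seq_len(H2)) for (j in seq_len(W2)) {
      acc <- 0
      for (ic in seq_len(Cin)) for (a in seq_len(kh)) for (bb in seq_len(kw)) {
        acc <- acc + w[oc, ic, a, bb] *
          xp[ic, (i - 1) * stride + a, (j - 1) * stride + bb]
      }
      y[oc, i, j] <- acc + if (is.null(b)) 0 else b[oc]
    }
  }
  y
}

ref_bn <- function(x, bn) {
  C <- dim(x)[1]
  for (c in seq_len(C)) {
    x[c, , ] <- (x[c, , ] - bn$buffers$mean[c]) /
      sqrt(bn$buffers$var[c] + bn$eps) * bn$params$weight[c] +
      bn$params$bias[c]
  }
  x
}

ref_silu <- function(x) x / (1 + exp(-x))
ref_sigmoid <- function(x) 1 / (1 + exp(-x))

ref_bconv <- function(x, m, stride = NULL) {
  s <- if (is.null(stride)) m$conv$stride else stride
  y <- ref_conv2d(x, m$conv$params$weight, m$conv$params$bias, s,
                  m$conv$pad)
  y <- ref_bn(y, m$bn)
  switch(m$act, silu = ref_silu(y), relu = pmax(y, 0), none = y)
}

# straight-line transcription of the three-direction attention chain
ref_mcca <- function(x, m) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  zh <- apply(x, c(1, 2), mean)                    # [C,H]
  zw <- apply(x, c(1, 3), mean)                    # [C,W]
  zch <- apply(x, 1, sum)                          # [C]
  zcat <- array(0, c(C, H + W, 1))
  zcat[, seq_len(H), 1] <- zh
  zcat[, H + seq_len(W), 1] <- zw
  f1 <- ref_bconv(zcat, m$bconv)
  r1 <- ref_conv2d(f1, m$restore$params$weight, m$restore$params$bias)
  f2 <- ref_sigmoid(r1)
  zch3 <- array(zch, c(C, 1, 1))
  g <- apply(ref_bn(f2, m$bn_f2), 1, mean)
  cc <- ref_conv2d(zch3, m$conv_ch$params$weight, m$conv_ch$params$bias)
  f3 <- g * cc[, 1, 1]
  out <- array(0, dim(x))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    att <- r1[c, i, 1] * r1[c, H + j, 1] * f2[c, i, 1] * f2[c, H + j, 1] *
      f3[c]
    out[c, i, j] <- x[c, i, j] * att
  }
  out
}

ref_upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2),
    drop = FALSE]
}

# straight-line transcription of the three-input aggregation block
ref_fuse <- function(m, f_up, f_mid, f_down) {
  f1 <- ref_bconv(ref_bconv(f_up, m$bconv_up), m$down)
  f2 <- ref_bconv(f_mid, m$bconv_mid)
  f3 <- ref_upsample2(f_down)
  third <- if (m$literal_eq8) f2 else f3
  cat_in <- array(0, c(dim(f1)[1] * 3, dim(f1)[2], dim(f1)[3]))
  cat_in[seq_len(dim(f1)[1]), , ] <- f1 + f2
  cat_in[dim(f1)[1] + seq_len(dim(f1)[1]), , ] <- f1
  cat_in[2 * dim(f1)[1] + seq_len(dim(f1)[1]), , ] <- third
  ref_bconv(cat_in, m$bconv_out)
}

# exhaustive minimum-cost assignment for small matrices
ref_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  best <- Inf; best_asg <- NULL
  rowsets <- utils::combn(n, k, simplify = FALSE)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  colsets <- utils::combn(m, k, simplify = FALSE)
  for (rs in rowsets) for (cs in colsets) for (cp in perm_rec(cs)) {
    tot <- sum(cost[cbind(rs, cp)])
    if (tot < best - 1e-12) {
      best <- tot
      best_asg <- cbind(rs, cp)
    }
  }
  list(cost = best, pairs = best_asg)
}

# rasterization IoU / GIoU on a fine grid
ref_iou_raster <- function(a, b, step = 0.01) {
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- seq(x0 + step / 2, x1 - step / 2, by = step)
  ys <- seq(y0 + step / 2, y1 - step / 2, by = step)
  ina <- outer(ys >= a[2] & ys < a[4], xs >= a[1] & xs < a[3], `&`)
  inb <- outer(ys >= b[2] & ys < b[4], xs >= b[1] & xs < b[3], `&`)
  cell <- step^2
  inter <- sum(ina & inb) * cell
  union <- sum(ina | inb) * cell
  enclose <- (x1 - x0) * (y1 - y0)
  list(iou = inter / union, giou_loss = 1 - inter / union +
         (enclose - union) / enclose)
}

# independent 101-point interpolated COCO-style evaluator for one class
ref_coco_ap <- function(dets_by_image, truths_by_image, class_id, iou_thr) {
  recs <- NULL
  n_truth <- 0
  for (id in names(truths_by_image)) {
    tr <- truths_by_image[[id]]
    tr <- tr[tr$class_id == class_id, , drop = FALSE]
    n_truth <- n_truth + nrow(tr)
    de <- dets_by_image[[id]]
    if (is.null(de)) next
    de <- de[de$class_id == class_id, , drop = FALSE]
    if (nrow(de) == 0) next
    de <- de[order(-de$score), , drop = FALSE]
    taken <- logical(nrow(tr))
    for (i in seq_len(nrow(de))) {
      bi <- 0; bv <- -1
      for (j in seq_len(nrow(tr))) {
        if (taken[j]) next
        ix1 <- max(de$x1[i], tr$x1[j]); iy1 <- max(de$y1[i], tr$y1[j])
        ix2 <- min(de$x2[i], tr$x2[j]); iy2 <- min(de$y2[i], tr$y2[j])
        it <- max(ix2 - ix1, 0) * max(iy2 - iy1, 0)
        un <- (de$x2[i] - de$x1[i]) * (de$y2[i] - de$y1[i]) +
          (tr$x2[j] - tr$x1[j]) * (tr$y2[j] - tr$y1[j]) - it
        v <- it / un
        if (v > bv) { bv <- v; bi <- j }
      }
      hit <- bi > 0 && bv >= iou_thr
      if (hit) taken[bi] <- TRUE
      recs <- rbind(recs, data.frame(score = de$score[i], tp = hit))
    }
  }
  if (n_truth == 0) return(NA_real_)
  if (is.null(recs)) return(0)
  recs <- recs[order(-recs$score), , drop = FALSE]
  tp <- cumsum(recs$tp); fp <- cumsum(!recs$tp)
  prec <- tp / (tp + fp); rec <- tp / n_truth
  for (i in rev(seq_along(prec))[-1]) prec[i] <- max(prec[i], prec[i + 1])
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pr <- prec[rec >= r - 1e-12]
    ap <- ap + (if (length(pr) > 0) pr[1] else 0)
  }
  ap / 101
}

# independent enumeration of trainable scalars: walks the raw list
# structure looking for numeric arrays under elements literally named
# "params"
ref_count_params <- function(x) {
  if (!is.list(x)) return(0)
  n <- 0
  nms <- names(x)
  for (k in seq_along(x)) {
    el <- x[[k]]
    if (!is.null(nms) && identical(nms[k], "params") && is.list(el)) {
      n <- n + sum(vapply(el, function(p) length(unclass(p)), numeric(1)))
    } else if (!is.null(nms) && identical(nms[k], "buffers")) {
      next
    } else if (is.list(el) && !inherits(el, "ag")) {
      n <- n + ref_count_params(el)
    }
  }
  n
}

# give every frozen batch norm non-trivial statistics and affine terms so
# that re-parameterization is exercised beyond the identity case
randomize_bn_stats <- function(m, seed = 1) {
  set.seed(seed)
  walk <- function(x) {
    if (inherits(x, "nn_bn2d")) {
      c <- length(x$buffers$mean)
      x$buffers$mean <- rnorm(c, 0, 0.2)
      x$buffers$var <- runif(c, 0.5, 1.5)
      x$params$weight <- runif(c, 0.5, 1.5)
      x$params$bias <- rnorm(c, 0, 0.2)
      return(x)
    }
    if (is.list(x) && !inherits(x, "ag")) {
      for (k in seq_along(x)) if (is.list(x[[k]])) x[[k]] <- walk(x[[k]])
    }
    x
  }
  walk(m)
}

# toy scenes reused by several files
make_toy_scenes <- function(n = 3, size = 64, seed = 100) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_spec(image_size = c(size, size), n_objects = 2,
                              seed = seed + i)))
}

toy_model_cfg <- function(seed = 7) {
  model_config(n_classes = 6, d = 32, heads = 2, queries = 10,
               dec_layers = 1,
               backbone = backbone_config(stem_channels = 8,
                                          stage_channels = c(8, 16, 32, 32),
                                          repncspelan4_hidden = 16,
                                          repncspelan4_blocks = 1),
               aifi_ffn = 64, dec_ffn = 64, dfam_n = 1, dfam_hidden = 32,
               seed = seed)
}
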