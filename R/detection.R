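# Detector plumbing: intra-scale self-attention on the deep map (AIFI),
# a query-based set-prediction decoder, and Hungarian matching.

# ---- attention primitives ---------------------------------------------

nn_mhsa <- function(d, heads) {
  if (d %% heads != 0) stop("model dim must be divisible by heads")
  nn_module("mhsa",
            wq = nn_linear(d, d), wk = nn_linear(d, d),
            wv = nn_linear(d, d), wo = nn_linear(d, d),
            d = d, heads = heads, dh = d %/% heads)
}

fwd_mhsa <- function(m, xq, xk, xv) {
  q <- fwd_linear(m$wq, xq)
  k <- fwd_linear(m$wk, xk)
  v <- fwd_linear(m$wv, xv)
  outs <- vector("list", m$heads)
  for (h in seq_len(m$heads)) {
    cols <- (h - 1L) * m$dh + seq_len(m$dh)
    qh <- ag_index_cols(q, cols)
    kh <- ag_index_cols(k, cols)
    vh <- ag_index_cols(v, cols)
    att <- ag_softmax_rows(ag_cmul(ag_matmul(qh, ag_t(kh)), 1 / sqrt(m$dh)))
    outs[[h]] <- ag_matmul(att, vh)
  }
  fwd_linear(m$wo, ag_cbind2(outs))
}

nn_encoder_layer <- function(d, heads, ffn) {
  nn_module("encoder_layer",
            attn = nn_mhsa(d, heads),
            ln1 = nn_layernorm(d),
            lin1 = nn_linear(d, ffn),
            lin2 = nn_linear(ffn, d),
            ln2 = nn_layernorm(d),
            d = d)
}

# post-norm transformer encoder layer; `pos` (const matrix or NULL) is added
# to queries and keys only
fwd_encoder_layer <- function(m, x, pos = NULL) {
  xqk <- if (is.null(pos)) x else ag_cadd(x, pos)
  a <- fwd_mhsa(m$attn, xqk, xqk, x)
  y <- fwd_layernorm(m$ln1, ag_add(x, a))
  f <- fwd_linear(m$lin2, ag_relu(fwd_linear(m$lin1, y)))
  fwd_layernorm(m$ln2, ag_add(y, f))
}

nn_decoder_layer <- function(d, heads, ffn) {
  nn_module("decoder_layer",
            self_attn = nn_mhsa(d, heads),
            ln1 = nn_layernorm(d),
            cross_attn = nn_mhsa(d, heads),
            ln2 = nn_layernorm(d),
            lin1 = nn_linear(d, ffn),
            lin2 = nn_linear(ffn, d),
            ln3 = nn_layernorm(d))
}

fwd_decoder_layer <- function(m, q, memory) {
  a <- fwd_mhsa(m$self_attn, q, q, q)
  q <- fwd_layernorm(m$ln1, ag_add(q, a))
  c <- fwd_mhsa(m$cross_attn, q, memory, memory)
  q <- fwd_layernorm(m$ln2, ag_add(q, c))
  f <- fwd_linear(m$lin2, ag_relu(fwd_linear(m$lin1, q)))
  fwd_layernorm(m$ln3, ag_add(q, f))
}

# ---- AIFI --------------------------------------------------------------

#' Build the intra-scale interaction (AIFI) layer
#'
#' One standard multi-head self-attention encoder layer applied to the
#' flattened deep feature map with 2-D sinusoidal positional encoding.
#'
#' @param d model/channel dimension (must equal the deep map's channels).
#' @param heads attention heads.
#' @param ffn feed-forward width.
#' @param use_pos disable to make the layer permutation-equivariant.
#' @param seed optional seed.
#' @return an `nn_module` of type `aifi`.
#' @export
build_aifi <- function(d, heads = 8L, ffn = 4L * d, use_pos = TRUE,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn_module("aifi", layer = nn_encoder_layer(d, heads, ffn),
            d = d, use_pos = isTRUE(use_pos))
}

aifi_run_ag <- function(m, x) {
  d <- dim(x$val); C <- d[1]; H <- d[2]; W <- d[3]
  if (C != m$d) stop("channel count must equal the configured model dim")
  tokens <- ag_t(ag_reshape(x, c(C, H * W)))           # [T, C]
  pos <- if (m$use_pos) sincos_position_2d(H, W, C) else NULL
  y <- fwd_encoder_layer(m$layer, tokens, pos)
  ag_reshape(ag_t(y), c(C, H, W))
}

#' Self-attention over the deep feature map
#'
#' @param s7 `[C,H,W]` array (deep pyramid level).
#' @param aifi module from [build_aifi()].
#' @return array of the same shape.
#' @export
aifi_forward <- function(s7, aifi) {
  m <- eval_wrap(aifi)
  aifi_run_ag(m, ag_const(NULL, s7))$val
}

# ---- decoder -----------------------------------------------------------

#' Build the query-based detection decoder
#'
#' Learned object queries attend to the flattened multi-scale memory over
#' `layers` standard decoder layers; per-query sigmoid class scores and
#' sigmoid-normalized (cx, cy, w, h) boxes are emitted without NMS.
#'
#' @param d model dimension (pyramid levels must arrive at this width).
#' @param n_classes number of object classes.
#' @param queries number of object queries K.
#' @param layers decoder depth L.
#' @param heads attention heads.
#' @param ffn feed-forward width.
#' @param seed optional seed.
#' @return an `nn_module` of type `decoder`.
#' @export
build_decoder <- function(d, n_classes, queries = 300L, layers = 3L,
                          heads = 8L, ffn = 4L * d, seed = NULL) {
  if (queries < 1 || layers < 1) stop("queries and layers must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nn_module("decoder",
            query_embed = nn_embedding(queries, d),
            dec_layers = lapply(seq_len(layers), function(i)
              nn_decoder_layer(d, heads, ffn)),
            class_head = nn_linear(d, n_classes),
            box_head = nn_module("box_mlp",
                                 l1 = nn_linear(d, d),
                                 l2 = nn_linear(d, d),
                                 l3 = nn_linear(d, 4L)),
            d = d, n_classes = as.integer(n_classes),
            queries = as.integer(queries), layers = as.integer(layers))
}

# flatten pyramid levels into one [T,d] token matrix
pyramid_tokens_ag <- function(pyr) {
  parts <- lapply(pyr, function(p) {
    dd <- dim(p$val)
    ag_t(ag_reshape(p, c(dd[1], dd[2] * dd[3])))
  })
  if (length(parts) == 1) parts[[1]] else {
    # row-concatenate token matrices
    nr <- vapply(parts, function(p) nrow(p$val), numeric(1))
    offs <- cumsum(c(0, nr))
    v <- do.call(rbind, lapply(parts, ag_value))
    new_op(parts[[1]]$tape, v, parts, function(g) {
      lapply(seq_along(parts), function(k)
        g[offs[k] + seq_len(nr[k]), , drop = FALSE])
    })
  }
}

decoder_run_ag <- function(m, pyr) {
  memory <- pyramid_tokens_ag(pyr)
  q <- m$query_embed$params$weight
  if (!is_ag(q)) stop("decoder must be tape-wrapped before running")
  for (lay in m$dec_layers) q <- fwd_decoder_layer(lay, q, memory)
  logits <- fwd_linear(m$class_head, q)                   # [K, n_classes]
  h <- ag_relu(fwd_linear(m$box_head$l1, q))
  h <- ag_relu(fwd_linear(m$box_head$l2, h))
  boxes <- ag_sigmoid(fwd_linear(m$box_head$l3, h))       # [K, 4] cxcywh
  list(logits = logits, scores = ag_sigmoid(logits), boxes = boxes)
}

#' Decode a feature pyramid into detections
#'
#' @param pyramid list of `[d,H,W]` arrays (aggregation-module outputs).
#' @param decoder module from [build_decoder()].
#' @param image_size `c(H, W)` of the input image in pixels.
#' @return data.frame with one row per query: pixel corner-form box
#'   (`x1,y1,x2,y2`, clamped to image bounds), `class_id`, `score`.
#' @export
decode <- function(pyramid, decoder, image_size) {
  m <- eval_wrap(decoder)
  out <- decoder_run_ag(m, lapply(pyramid, function(p) ag_const(NULL, p)))
  scores <- out$scores$val
  boxes <- out$boxes$val
  cls <- max.col(scores, ties.method = "first")
  sc <- scores[cbind(seq_len(nrow(scores)), cls)]
  xy <- box_cxcywh_to_xyxy(boxes)
  H <- image_size[1]; W <- image_size[2]
  det <- data.frame(x1 = pmin(pmax(xy[, 1] * W, 0), W - 1e-3),
                    y1 = pmin(pmax(xy[, 2] * H, 0), H - 1e-3),
                    x2 = pmin(pmax(xy[, 3] * W, 1e-3), W),
                    y2 = pmin(pmax(xy[, 4] * H, 1e-3), H),
                    class_id = cls, score = sc)
  det$x2 <- pmax(det$x2, det$x1 + 1e-3)
  det$y2 <- pmax(det$y2, det$y1 + 1e-3)
  det
}

# ---- Hungarian matching ------------------------------------------------

#' Minimum-cost assignment
#'
#' Solves the rectangular linear assignment problem with the O(n^3)
#' shortest-augmenting-path (Jonker-Volgenant style) algorithm.
#'
#' @param cost numeric matrix (rows = predictions, cols = truths).
#' @return integer vector `a` of length `nrow(cost)`: `a[i]` is the column
#'   matched to row `i`, or `NA` if row `i` is unmatched.
#' @export
assignment_solve <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0 || m0 == 0) return(rep(NA_integer_, n0))
  n <- max(n0, m0)
  a <- matrix(0, n, n)
  a[seq_len(n0), seq_len(m0)] <- cost
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- a[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L           # columns (0-based) in the tree
      u[p[usedj + 1L]] <- u[p[usedj + 1L]] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  res <- rep(NA_integer_, n0)
  for (j in seq_len(n)) {
    r <- p[j + 1L]
    if (r >= 1 && r <= n0 && j <= m0) res[r] <- j
  }
  res
}

#' Match predictions to ground truths for set-prediction training
#'
#' Cost per pair = `w_class * (-score of the truth's class) +
#' w_l1 * mean|box difference| + w_giou * (-GIoU)`, minimized by an optimal
#' one-to-one assignment.
#'
#' @param pred_boxes `[K,4]` matrix of normalized (cx, cy, w, h) boxes.
#' @param pred_scores `[K, n_classes]` matrix of sigmoid class scores.
#' @param truth_boxes `[m,4]` matrix of normalized (cx, cy, w, h) boxes.
#' @param truth_labels integer class ids (1-based), length m.
#' @param cost_weights named vector with `class`, `l1`, `giou`.
#' @return list with `pairs` (2-column matrix: prediction index, truth
#'   index), `unmatched_predictions`, `unmatched_truths`.
#' @export
hungarian_match <- function(pred_boxes, pred_scores, truth_boxes,
                            truth_labels,
                            cost_weights = c(class = 2, l1 = 5, giou = 2)) {
  K <- nrow(pred_boxes)
  m <- if (is.null(truth_boxes)) 0L else nrow(truth_boxes)
  if (m == 0L) {
    return(list(pairs = matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("pred", "truth"))),
                unmatched_predictions = seq_len(K),
                unmatched_truths = integer()))
  }
  cls_cost <- -pred_scores[, truth_labels, drop = FALSE]
  l1_cost <- matrix(0, K, m)
  for (j in seq_len(m)) {
    l1_cost[, j] <- rowMeans(abs(pred_boxes -
                                   matrix(truth_boxes[j, ], K, 4,
                                          byrow = TRUE)))
  }
  g <- giou_pairs(box_cxcywh_to_xyxy(pred_boxes),
                  box_cxcywh_to_xyxy(truth_boxes))
  cost <- cost_weights[["class"]] * cls_cost +
    cost_weights[["l1"]] * l1_cost +
    cost_weights[["giou"]] * (-g)
  asg <- assignment_solve(cost)
  matched <- which(!is.na(asg))
  pairs <- cbind(pred = matched, truth = asg[matched])
  list(pairs = pairs,
       unmatched_predictions = setdiff(seq_len(K), matched),
       unmatched_truths = setdiff(seq_len(m), pairs[, "truth"]))
}
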