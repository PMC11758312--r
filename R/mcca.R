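# Multi-channel coordinate attention.
#
# The deep feature map is pooled along three spatial directions: a
# width-averaged column Z(h) [C,H,1], a height-averaged row Z(w) [C,1,W],
# and an (unnormalized) global spatial sum Z(ch) [C,1,1]. The H and W
# encodings are concatenated, passed through a 3x1 conv + BN + SiLU, split
# back, sigmoid-gated after channel restoration, and combined with a
# channel gate derived from Z(ch). The product of the five directional
# factors forms an attention tensor applied multiplicatively to the input.

#' Build a multi-channel coordinate attention module
#'
#' @param channels number of input/output channels C.
#' @param reduced internal channel count C' of the concatenated-branch
#'   convolution; defaults to `max(8, channels %/% 32)`, the usual
#'   coordinate-attention reduction.
#' @param literal_eq5 if `TRUE` the module returns the bare attention
#'   product (which discards the input map) instead of input x attention.
#'   Off by default: a purely multiplicative attention output would drop
#'   all input information, so the product is applied to the input as in
#'   the channel-attention literature.
#' @param seed optional seed for parameter initialization.
#' @return an `nn_module` of type `mcca`.
#' @export
build_mcca <- function(channels, reduced = NULL, literal_eq5 = FALSE,
                       seed = NULL) {
  if (channels <= 0) stop("channels must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reduced)) reduced <- max(8L, channels %/% 32L)
  nn_module("mcca",
            bconv = nn_bconv(channels, reduced, k = c(3L, 1L)),
            restore = nn_conv2d(reduced, channels, k = 1L, bias = TRUE),
            bn_f2 = nn_bn2d(channels),
            conv_ch = nn_conv2d(channels, channels, k = 1L, bias = TRUE),
            channels = channels, reduced = reduced,
            literal_eq5 = isTRUE(literal_eq5))
}

# ---- tape-level pipeline ----------------------------------------------

mcca_pools_ag <- function(x) {
  d <- dim(x$val)
  if (length(d) != 3) stop("expected a [C,H,W] feature map")
  if (d[2] < 1 || d[3] < 1) stop("spatial dimensions must be non-empty")
  list(z_h = ag_pool_w(x), z_w = ag_pool_h(x), z_ch = ag_pool_sum_hw(x))
}

mcca_branches_ag <- function(m, pools) {
  C <- m$channels
  H <- dim(pools$z_h$val)[2]
  W <- dim(pools$z_w$val)[3]
  if (dim(pools$z_h$val)[1] != C)
    stop("channel mismatch between pools and module parameters")
  zcat <- ag_concat_h(list(pools$z_h, ag_swap_hw(pools$z_w)))  # [C,H+W,1]
  f1 <- fwd_bconv(m$bconv, zcat)                               # [C',H+W,1]
  r1 <- fwd_conv2d(m$restore, f1)                              # [C,H+W,1]
  f2 <- ag_sigmoid(r1)
  list(f1 = f1,
       f1_h = ag_narrow(f1, 2L, 1L, H),
       f1_w = ag_narrow(f1, 2L, H + 1L, W),
       r1_h = ag_narrow(r1, 2L, 1L, H),
       r1_w = ag_narrow(r1, 2L, H + 1L, W),
       f2 = f2,
       f2_h = ag_narrow(f2, 2L, 1L, H),
       f2_w = ag_narrow(f2, 2L, H + 1L, W),
       H = H, W = W)
}

mcca_channel_gate_ag <- function(m, f2, z_ch) {
  g <- ag_pool_mean_hw(fwd_bn2d(m$bn_f2, f2))   # [C,1,1]
  c1 <- fwd_conv2d(m$conv_ch, z_ch)             # [C,1,1]
  ag_mul(g, c1)
}

mcca_run_ag <- function(m, x) {
  pools <- mcca_pools_ag(x)
  br <- mcca_branches_ag(m, pools)
  f3 <- mcca_channel_gate_ag(m, br$f2, pools$z_ch)
  tgt <- c(m$channels, br$H, br$W)
  # five directional factors of the attention product, broadcast to [C,H,W];
  # the H/W factors from the pre-sigmoid branch are channel-restored so all
  # factors share the input's channel count
  a1 <- ag_expand(br$r1_h, tgt)
  a2 <- ag_expand(ag_swap_hw(br$r1_w), tgt)
  a3 <- ag_expand(br$f2_h, tgt)
  a4 <- ag_expand(ag_swap_hw(br$f2_w), tgt)
  a5 <- ag_expand(f3, tgt)
  att <- ag_mul(ag_mul(ag_mul(a1, a2), ag_mul(a3, a4)), a5)
  out <- if (m$literal_eq5) att else ag_mul(x, att)
  list(out = out, attention = att, pools = pools, branches = br, f3 = f3)
}

# ---- user-facing array API --------------------------------------------

#' Directional pooling of a feature map
#'
#' Pools a `[C,H,W]` map along three directions: mean over width (`z_h`,
#' `[C,H,1]`), mean over height (`z_w`, `[C,1,W]`), and the raw sum over
#' both spatial axes (`z_ch`, `[C,1,1]`). Note `z_ch` is a sum, not a mean.
#'
#' @param x numeric array `[C,H,W]`.
#' @return list with `z_h`, `z_w`, `z_ch`.
#' @export
directional_pool <- function(x) {
  p <- mcca_pools_ag(ag_const(NULL, x))
  list(z_h = p$z_h$val, z_w = p$z_w$val, z_ch = p$z_ch$val)
}

#' Coordinate branch of the attention module
#'
#' Concatenates the height and width encodings, applies the 3x1
#' conv + BN + SiLU, splits back at height H, restores the channel count
#' with a 1x1 convolution and applies the sigmoid gate.
#'
#' @param pools output of [directional_pool()].
#' @param mcca module from [build_mcca()].
#' @return list with `f1`, `f1_h`, `f1_w` (reduced channels) and `f2`,
#'   `f2_h`, `f2_w` (restored channels, values in (0,1)).
#' @export
coordinate_branch <- function(pools, mcca) {
  m <- eval_wrap(mcca)
  p <- list(z_h = ag_const(NULL, pools$z_h),
            z_w = ag_const(NULL, pools$z_w),
            z_ch = ag_const(NULL, pools$z_ch))
  br <- mcca_branches_ag(m, p)
  list(f1 = br$f1$val, f1_h = br$f1_h$val, f1_w = br$f1_w$val,
       f2 = br$f2$val, f2_h = br$f2_h$val, f2_w = br$f2_w$val)
}

#' Channel branch of the attention module
#'
#' Computes the per-channel gate `f3`: the global average of the
#' batch-normalized sigmoid branch multiplied by a 1x1 convolution of the
#' global-sum encoding.
#'
#' @param f2 sigmoid branch `[C,H+W,1]` (from [coordinate_branch()]).
#' @param z_ch global-sum encoding `[C,1,1]`.
#' @param mcca module from [build_mcca()].
#' @return array `[C,1,1]`.
#' @export
channel_branch <- function(f2, z_ch, mcca) {
  m <- eval_wrap(mcca)
  mcca_channel_gate_ag(m, ag_const(NULL, f2), ag_const(NULL, z_ch))$val
}

#' Apply multi-channel coordinate attention to a feature map
#'
#' @param x numeric array `[C,H,W]` (the deep pyramid level).
#' @param mcca module from [build_mcca()].
#' @return attention-refined array of the same shape.
#' @export
mcca_forward <- function(x, mcca) {
  if (length(dim(x)) != 3) stop("mcca_forward expects a [C,H,W] array")
  m <- eval_wrap(mcca)
  mcca_run_ag(m, ag_const(NULL, x))$out$val
}
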