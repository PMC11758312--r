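# Multi-dimension feature aggregation.
#
# The Fuse block aggregates three adjacent pyramid levels at the middle
# level's scale: the shallow map is 1x1-projected and downsampled, the
# middle map is 1x1-projected, the deep map is nearest-upsampled; the sum
# of the first two is concatenated with the projected shallow map and the
# upsampled deep map and passed through a final 1x1 projection. Each Fuse
# is followed by a RepC3 block: a channel-adjusting 1x1 convolution feeding
# a chain of re-parameterizable RepConv units, summed with a 1x1 shortcut.

#' Build a three-input aggregation (Fuse) block
#'
#' @param cin_up,cin_mid,cin_down input channel counts; the deep input must
#'   already be at the working width (it enters the concatenation without a
#'   projection).
#' @param channels working width of the block.
#' @param literal_eq8 if `TRUE`, the concatenation is
#'   `(f1 + f2, f1, f2)` — the form that never consumes the upsampled deep
#'   map; the default `(f1 + f2, f1, f3)` realizes cross-scale fusion.
#' @return an `nn_module` of type `fuse`.
#' @export
build_fuse <- function(cin_up, cin_mid, cin_down, channels,
                       literal_eq8 = FALSE) {
  if (cin_down != channels)
    stop("deep input must already have the working channel width")
  nn_module("fuse",
            bconv_up = nn_bconv(cin_up, channels, k = 1L),
            down = nn_bconv(channels, channels, k = 3L, stride = 2L),
            bconv_mid = nn_bconv(cin_mid, channels, k = 1L),
            bconv_out = nn_bconv(3L * channels, channels, k = 1L),
            channels = channels, literal_eq8 = isTRUE(literal_eq8))
}

fuse_run_ag <- function(m, f_up, f_mid, f_down) {
  du <- dim(f_up$val); dm <- dim(f_mid$val); dd <- dim(f_down$val)
  if (!all(du[2:3] == 2L * dm[2:3]))
    stop(sprintf("f_up must be 2x the middle scale (got %dx%d vs %dx%d)",
                 du[2], du[3], dm[2], dm[3]))
  if (!all(dm[2:3] == 2L * dd[2:3]))
    stop(sprintf("f_down must be half the middle scale (got %dx%d vs %dx%d)",
                 dd[2], dd[3], dm[2], dm[3]))
  f1 <- fwd_bconv(m$down, fwd_bconv(m$bconv_up, f_up))
  f2 <- fwd_bconv(m$bconv_mid, f_mid)
  f3 <- ag_upsample2(f_down)
  third <- if (m$literal_eq8) f2 else f3
  fwd_bconv(m$bconv_out, ag_concat_c(list(ag_add(f1, f2), f1, third)))
}

#' Aggregate three pyramid levels at the middle scale
#'
#' @param inputs list with `f_up` (2x spatial), `f_middle` (reference
#'   scale), `f_down` (half spatial), each a `[C,H,W]` array.
#' @param fuse_mod module from [build_fuse()].
#' @return array at `f_middle`'s scale with the block's working width.
#' @export
fuse <- function(inputs, fuse_mod) {
  m <- eval_wrap(fuse_mod)
  fuse_run_ag(m, ag_const(NULL, inputs$f_up),
              ag_const(NULL, inputs$f_middle),
              ag_const(NULL, inputs$f_down))$val
}

#' Build a RepC3 convolution block
#'
#' @param cin input channels.
#' @param channels output channels.
#' @param n number of RepConv units in the main path (>= 1).
#' @param hidden working width of the RepConv chain (defaults to
#'   `channels`); when it differs, a final 1x1 projection restores the
#'   output width.
#' @return an `nn_module` of type `repc3`.
#' @export
build_repc3 <- function(cin, channels, n = 3L, hidden = channels) {
  if (n < 1) stop("n must be >= 1")
  nn_module("repc3",
            cv1 = nn_bconv(cin, hidden, k = 1L),
            reps = lapply(seq_len(n), function(i) nn_repconv(hidden,
                                                             hidden)),
            cv2 = nn_bconv(cin, hidden, k = 1L),
            cv3 = if (hidden != channels) nn_bconv(hidden, channels,
                                                   k = 1L) else NULL,
            n = as.integer(n))
}

repc3_run_ag <- function(m, x) {
  a <- fwd_bconv(m$cv1, x)
  for (r in m$reps) a <- fwd_repconv_any(r, a)
  y <- ag_add(a, fwd_bconv(m$cv2, x))
  if (!is.null(m$cv3)) y <- fwd_bconv(m$cv3, y) else y
}

#' Run a RepC3 block
#'
#' @param x `[C,H,W]` array with `C` equal to the block's input width.
#' @param repc3 module from [build_repc3()].
#' @return array at the block's working width, spatial dims preserved.
#' @export
repc3_forward <- function(x, repc3) {
  if (dim(x)[1] != repc3$cv1$conv$cin)
    stop("input channel count does not match the block")
  m <- eval_wrap(repc3)
  repc3_run_ag(m, ag_const(NULL, x))$val
}

# dispatch between train-form and fused RepConv units
fwd_repconv_any <- function(m, x) {
  if (inherits(m, "nn_repconv_fused")) {
    ag_silu(fwd_conv2d(m$conv, x))
  } else {
    fwd_repconv(m, x)
  }
}

#' Fuse the branches of a RepConv unit into one 3x3 convolution
#'
#' Algebraically merges the 3x3, 1x1 and (when present) identity branches,
#' each with its frozen batch-norm affine, into a single biased 3x3
#' convolution followed by the same activation. Eval-mode outputs agree
#' with the multi-branch form to numerical precision and the parameter
#' count strictly decreases.
#'
#' @param unit an `nn_module` of type `repconv`.
#' @return an `nn_module` of type `repconv_fused`.
#' @export
repconv_reparameterize <- function(unit) {
  if (!inherits(unit, "nn_repconv")) stop("expected a repconv unit")
  bn_terms <- function(bn) {
    if (any(!is.finite(bn$buffers$var)) || any(bn$buffers$var < 0))
      stop("batch-norm statistics are unset")
    s <- bn$params$weight / sqrt(bn$buffers$var + bn$eps)
    list(scale = s, shift = bn$params$bias - bn$buffers$mean * s)
  }
  cin <- unit$cin; cout <- unit$cout
  t3 <- bn_terms(unit$bn3)
  t1 <- bn_terms(unit$bn1)
  w <- unit$conv3$params$weight * rep(t3$scale, cin * 9L)
  w1 <- unit$conv1$params$weight * rep(t1$scale, cin)
  w[, , 2, 2] <- w[, , 2, 2] + w1[, , 1, 1]
  b <- t3$shift + t1$shift
  if (!is.null(unit$bnid)) {
    tid <- bn_terms(unit$bnid)
    for (oc in seq_len(cout)) w[oc, oc, 2, 2] <- w[oc, oc, 2, 2] +
        tid$scale[oc]
    b <- b + tid$shift
  }
  conv <- nn_conv2d(cin, cout, k = 3L, bias = TRUE)
  conv$params$weight <- w
  conv$params$bias <- b
  nn_module("repconv_fused", conv = conv, cin = cin, cout = cout)
}

#' Re-parameterize every RepConv unit in a module tree
#'
#' @param model any module tree.
#' @return the tree with each multi-branch RepConv replaced by its fused
#'   single-convolution form.
#' @export
reparameterize_module <- function(model) {
  if (inherits(model, "nn_repconv")) return(repconv_reparameterize(model))
  if (inherits(model, "nn_module") || (is.list(model) && !is_ag(model))) {
    for (k in seq_along(model)) {
      if (is_module_tree(model[[k]]))
        model[[k]] <- reparameterize_module(model[[k]])
    }
  }
  model
}

# ---- full aggregation path --------------------------------------------

#' Default aggregation-path configuration
#'
#' @param channels working width of every Fuse/RepC3 junction.
#' @param in_channels channel counts of the three incoming pyramid levels
#'   (shallow, intermediate, deep).
#' @param n_repconvs RepConv units per RepC3 block.
#' @param repc3_hidden working width inside the RepC3 chains (see
#'   [build_repc3()]).
#' @param literal_eq8 passed to the Fuse blocks.
#' @param bypass if `TRUE` the module reduces to its input projections
#'   (the "without aggregation" ablation wiring).
#' @return a config list for [build_dfam()].
#' @export
dfam_config <- function(channels = 256L,
                        in_channels = c(128L, 256L, 512L),
                        n_repconvs = 3L,
                        repc3_hidden = channels,
                        literal_eq8 = FALSE,
                        bypass = FALSE) {
  list(channels = as.integer(channels),
       in_channels = as.integer(in_channels),
       n_repconvs = as.integer(n_repconvs),
       repc3_hidden = as.integer(repc3_hidden),
       literal_eq8 = isTRUE(literal_eq8),
       bypass = isTRUE(bypass))
}

#' Build the multi-scale aggregation module
#'
#' Wiring: all three levels are 1x1-projected to the working width; a
#' top-down junction fuses (shallow, intermediate, deep) at the
#' intermediate scale, a top-down edge junction refines the shallow level
#' with the upsampled result, a bottom-up junction fuses again at the
#' intermediate scale, and a bottom-up edge junction refines the deep
#' level. Every junction ends in a RepC3 block.
#'
#' @param config from [dfam_config()].
#' @param seed optional seed for parameter initialization.
#' @return an `nn_module` of type `dfam`.
#' @export
build_dfam <- function(config = dfam_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c <- config$channels
  ic <- config$in_channels
  n <- config$n_repconvs
  h <- config$repc3_hidden
  nn_module("dfam",
            proj4 = nn_bconv(ic[1], c, k = 1L),
            proj5 = nn_bconv(ic[2], c, k = 1L),
            proj7 = nn_bconv(ic[3], c, k = 1L),
            fuse_td = build_fuse(c, c, c, c, config$literal_eq8),
            repc3_td5 = build_repc3(c, c, n, h),
            agg_td4 = nn_bconv(2L * c, c, k = 1L),
            repc3_td4 = build_repc3(c, c, n, h),
            fuse_bu = build_fuse(c, c, c, c, config$literal_eq8),
            repc3_bu5 = build_repc3(c, c, n, h),
            down_bu7 = nn_bconv(c, c, k = 3L, stride = 2L),
            agg_bu7 = nn_bconv(2L * c, c, k = 1L),
            repc3_bu7 = build_repc3(c, c, n, h),
            config = config)
}

dfam_run_ag <- function(m, s4, s5, s7) {
  p4 <- fwd_bconv(m$proj4, s4)
  p5 <- fwd_bconv(m$proj5, s5)
  p7 <- fwd_bconv(m$proj7, s7)
  if (m$config$bypass) return(list(s4 = p4, s5 = p5, s7 = p7))
  t5 <- repc3_run_ag(m$repc3_td5, fuse_run_ag(m$fuse_td, p4, p5, p7))
  t4 <- repc3_run_ag(m$repc3_td4,
                     fwd_bconv(m$agg_td4,
                               ag_concat_c(list(p4, ag_upsample2(t5)))))
  b5 <- repc3_run_ag(m$repc3_bu5, fuse_run_ag(m$fuse_bu, t4, t5, p7))
  b7 <- repc3_run_ag(m$repc3_bu7,
                     fwd_bconv(m$agg_bu7,
                               ag_concat_c(list(p7, fwd_bconv(m$down_bu7,
                                                              b5)))))
  list(s4 = t4, s5 = b5, s7 = b7)
}

#' Run the aggregation module over a feature pyramid
#'
#' @param s4,s5,s7_attended the three pyramid levels (`[C,H,W]` arrays);
#'   `s7_attended` is the attention/AIFI-processed deep map.
#' @param dfam module from [build_dfam()].
#' @return list of refined maps `s4`, `s5`, `s7` at the input scales.
#' @export
dfam_forward <- function(s4, s5, s7_attended, dfam) {
  m <- eval_wrap(dfam)
  out <- dfam_run_ag(m, ag_const(NULL, s4), ag_const(NULL, s5),
                     ag_const(NULL, s7_attended))
  lapply(out, function(v) v$val)
}
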