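# Improved ResNet-18 feature extractor.
#
# Stages 1-3 follow the standard ResNet-18 basic-block layout; the terminal
# stage is either the original pair of 512-channel basic blocks or a
# lightweight GELAN-style RepNCSPELAN4 block (CSP split, two
# re-parameterizable sub-branches, concatenation, transition convolution).
# Taps: s4 = stage-2 output (stride 8), s5 = stage 3 (stride 16),
# s7 = terminal stage (stride 32).

# ---- building blocks ---------------------------------------------------

nn_basic_block <- function(cin, cout, stride = 1L) {
  down <- NULL
  if (stride != 1L || cin != cout) {
    down <- nn_module("downsample",
                      conv = nn_conv2d(cin, cout, k = 1L, stride = stride,
                                       bias = FALSE),
                      bn = nn_bn2d(cout))
  }
  nn_module("basic_block",
            conv1 = nn_conv2d(cin, cout, k = 3L, stride = stride,
                              bias = FALSE),
            bn1 = nn_bn2d(cout),
            conv2 = nn_conv2d(cout, cout, k = 3L, bias = FALSE),
            bn2 = nn_bn2d(cout),
            down = down)
}

fwd_basic_block <- function(m, x) {
  y <- ag_relu(fwd_bn2d(m$bn1, fwd_conv2d(m$conv1, x)))
  y <- fwd_bn2d(m$bn2, fwd_conv2d(m$conv2, y))
  s <- if (is.null(m$down)) x
       else fwd_bn2d(m$down$bn, fwd_conv2d(m$down$conv, x))
  ag_relu(ag_add(y, s))
}

# re-parameterizable convolution: 3x3 + 1x1 (+ identity) branches with
# frozen BN, summed, then SiLU
nn_repconv <- function(cin, cout, identity = (cin == cout)) {
  nn_module("repconv",
            conv3 = nn_conv2d(cin, cout, k = 3L, bias = FALSE),
            bn3 = nn_bn2d(cout),
            conv1 = nn_conv2d(cin, cout, k = 1L, bias = FALSE),
            bn1 = nn_bn2d(cout),
            bnid = if (identity) nn_bn2d(cout) else NULL,
            cin = cin, cout = cout, identity = identity)
}

fwd_repconv <- function(m, x) {
  y <- ag_add(fwd_bn2d(m$bn3, fwd_conv2d(m$conv3, x)),
              fwd_bn2d(m$bn1, fwd_conv2d(m$conv1, x)))
  if (!is.null(m$bnid)) y <- ag_add(y, fwd_bn2d(m$bnid, x))
  ag_silu(y)
}

# CSP block with re-parameterizable bottlenecks (GELAN sub-branch)
nn_repncsp <- function(cin, cout, n = 1L) {
  ch <- max(1L, cout %/% 2L)
  nn_module("repncsp",
            cv1 = nn_bconv(cin, ch, k = 1L),
            cv2 = nn_bconv(cin, ch, k = 1L),
            cv3 = nn_bconv(2L * ch, cout, k = 1L),
            bottlenecks = lapply(seq_len(n), function(i) {
              nn_module("rep_bottleneck",
                        rep = nn_repconv(ch, ch),
                        conv = nn_bconv(ch, ch, k = 3L))
            }),
            n = as.integer(n))
}

fwd_repncsp <- function(m, x) {
  a <- fwd_bconv(m$cv1, x)
  for (b in m$bottlenecks) {
    a <- ag_add(a, fwd_bconv(b$conv, fwd_repconv_any(b$rep, a)))
  }
  b <- fwd_bconv(m$cv2, x)
  fwd_bconv(m$cv3, ag_concat_c(list(a, b)))
}

# RepNCSPELAN4: 1x1 transition, CSP split into two halves, two sequential
# re-parameterizable sub-branches, concatenation of all four streams, 1x1
# transition to the output width
nn_repncspelan4 <- function(cin, cout, c3, c4, n = 1L) {
  if (c3 %% 2L != 0L) stop("hidden width c3 must be even")
  nn_module("repncspelan4",
            cv1 = nn_bconv(cin, c3, k = 1L),
            cv2 = nn_module("branch",
                            csp = nn_repncsp(c3 %/% 2L, c4, n),
                            conv = nn_bconv(c4, c4, k = 3L)),
            cv3 = nn_module("branch",
                            csp = nn_repncsp(c4, c4, n),
                            conv = nn_bconv(c4, c4, k = 3L)),
            cv4 = nn_bconv(c3 + 2L * c4, cout, k = 1L),
            c3 = c3, c4 = c4)
}

fwd_repncspelan4 <- function(m, x) {
  y <- fwd_bconv(m$cv1, x)
  h <- m$c3 %/% 2L
  y1 <- ag_narrow(y, 1L, 1L, h)
  y2 <- ag_narrow(y, 1L, h + 1L, h)
  y3 <- fwd_bconv(m$cv2$conv, fwd_repncsp(m$cv2$csp, y2))
  y4 <- fwd_bconv(m$cv3$conv, fwd_repncsp(m$cv3$csp, y3))
  fwd_bconv(m$cv4, ag_concat_c(list(y1, y2, y3, y4)))
}

# ---- backbone ----------------------------------------------------------

#' Default backbone configuration
#'
#' ResNet-18 widths: 64-channel stem, stages (64, 128, 256, 512). The
#' terminal stage is the GELAN-style block by default; `terminal_stage =
#' "resnet"` restores the original pair of basic blocks. `repncspelan4_hidden`
#' is the CSP transition width c3 (the sub-branch width c4 is half of it).
#'
#' @param stem_channels stem width.
#' @param stage_channels integer vector of 4 stage widths.
#' @param repncspelan4_hidden transition width of the terminal GELAN block.
#' @param repncspelan4_blocks bottlenecks per CSP sub-branch.
#' @param terminal_stage `"repncspelan4"` or `"resnet"`.
#' @return a config list for [build_backbone()].
#' @export
backbone_config <- function(stem_channels = 64L,
                            stage_channels = c(64L, 128L, 256L, 512L),
                            repncspelan4_hidden = 256L,
                            repncspelan4_blocks = 1L,
                            terminal_stage = c("repncspelan4", "resnet")) {
  if (length(stage_channels) != 4L) stop("stage_channels must have length 4")
  if (any(c(stem_channels, stage_channels, repncspelan4_hidden) <= 0))
    stop("channel counts must be positive")
  list(stem_channels = as.integer(stem_channels),
       stage_channels = as.integer(stage_channels),
       repncspelan4_hidden = as.integer(repncspelan4_hidden),
       repncspelan4_blocks = as.integer(repncspelan4_blocks),
       terminal_stage = match.arg(terminal_stage))
}

#' Build the feature-extraction backbone
#'
#' @param config from [backbone_config()].
#' @param seed optional seed for parameter initialization.
#' @return an `nn_module` whose forward ([backbone_forward()]) maps a
#'   `[3,H,W]` image to three pyramid levels at strides 8/16/32.
#' @export
build_backbone <- function(config = backbone_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- config$stage_channels
  if (any(sc <= 0) || config$stem_channels <= 0)
    stop("channel counts must be positive")
  stem <- nn_module("stem",
                    conv = nn_conv2d(3L, config$stem_channels, k = 7L,
                                     stride = 2L, pad = 3L, bias = FALSE),
                    bn = nn_bn2d(config$stem_channels))
  stage <- function(cin, cout, stride) {
    nn_module("stage",
              b1 = nn_basic_block(cin, cout, stride),
              b2 = nn_basic_block(cout, cout, 1L))
  }
  terminal <- if (config$terminal_stage == "resnet") {
    stage(sc[3], sc[4], 2L)
  } else {
    c3 <- config$repncspelan4_hidden
    nn_module("gelan_stage",
              down = nn_bconv(sc[3], sc[3], k = 3L, stride = 2L),
              gelan = nn_repncspelan4(sc[3], sc[4], c3, c3 %/% 2L,
                                      config$repncspelan4_blocks))
  }
  nn_module("backbone",
            stem = stem,
            stage1 = stage(config$stem_channels, sc[1], 1L),
            stage2 = stage(sc[1], sc[2], 2L),
            stage3 = stage(sc[2], sc[3], 2L),
            stage4 = terminal,
            config = config)
}

fwd_stage <- function(m, x) {
  if (inherits(m, "nn_gelan_stage")) {
    fwd_repncspelan4(m$gelan, fwd_bconv(m$down, x))
  } else {
    fwd_basic_block(m$b2, fwd_basic_block(m$b1, x))
  }
}

backbone_run_ag <- function(m, x) {
  y <- ag_relu(fwd_bn2d(m$stem$bn, fwd_conv2d(m$stem$conv, x)))
  y <- ag_maxpool2d(y, k = 3L, stride = 2L, pad = 1L)
  y <- fwd_stage(m$stage1, y)
  s4 <- fwd_stage(m$stage2, y)
  s5 <- fwd_stage(m$stage3, s4)
  s7 <- fwd_stage(m$stage4, s5)
  list(s4 = s4, s5 = s5, s7 = s7)
}

#' Run the backbone on an image
#'
#' @param backbone module from [build_backbone()].
#' @param x numeric array `[3,H,W]`, values in `[0,1]`, H and W divisible
#'   by 32.
#' @return list of pyramid levels `s4` (stride 8), `s5` (16), `s7` (32).
#' @export
backbone_forward <- function(backbone, x) {
  if (length(dim(x)) != 3 || dim(x)[1] != 3)
    stop("expected a [3,H,W] image array")
  m <- eval_wrap(backbone)
  p <- backbone_run_ag(m, ag_const(NULL, x))
  lapply(p, function(v) v$val)
}
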