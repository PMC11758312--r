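# Full detector assembly: backbone -> (coordinate attention || AIFI) on the
# deep map -> multi-scale aggregation -> query decoder.

#' Model configuration
#'
#' All architectural hyperparameters in one list. The defaults are the
#' calibration configuration documented in the methods vignette; toy
#' configurations for CPU training scale `d`, `queries` and the backbone
#' widths down.
#'
#' @param n_classes number of object classes.
#' @param d model dimension (decoder / aggregation width).
#' @param variant `"full"`, `"improved_decoder"` (no attention/aggregation
#'   modules), or `"resnet18_decoder"` (additionally the original terminal
#'   stage).
#' @param backbone from [backbone_config()].
#' @param mcca_reduced reduced width C' of the coordinate attention.
#' @param deep_branches `"parallel"` sums the attention and AIFI branches
#'   of the deep map; `"serial"` composes attention then AIFI.
#' @param aifi_ffn,dec_ffn feed-forward widths.
#' @param heads attention heads.
#' @param queries object queries K.
#' @param dec_layers decoder depth L.
#' @param dfam_n,dfam_hidden aggregation-path RepConv count and RepC3
#'   hidden width.
#' @param use_mcca,use_dfam ablation switches (both TRUE for `"full"`).
#' @param loss from [loss_config()].
#' @param match_weights Hungarian cost weights.
#' @param seed seed used when building the model.
#' @return config list for [build_model()].
#' @export
model_config <- function(n_classes = 6L, d = 256L,
                         variant = c("full", "improved_decoder",
                                     "resnet18_decoder"),
                         backbone = backbone_config(),
                         mcca_reduced = NULL,
                         deep_branches = c("parallel", "serial"),
                         aifi_ffn = 4L * d, dec_ffn = 4L * d,
                         heads = 8L, queries = 300L, dec_layers = 3L,
                         dfam_n = 3L, dfam_hidden = d,
                         use_mcca = NULL, use_dfam = NULL,
                         loss = loss_config(),
                         match_weights = c(class = 2, l1 = 5, giou = 2),
                         seed = 0L) {
  variant <- match.arg(variant)
  if (variant == "resnet18_decoder") backbone$terminal_stage <- "resnet"
  full <- variant == "full"
  list(n_classes = as.integer(n_classes), d = as.integer(d),
       variant = variant, backbone = backbone,
       mcca_reduced = mcca_reduced,
       deep_branches = match.arg(deep_branches),
       aifi_ffn = as.integer(aifi_ffn), dec_ffn = as.integer(dec_ffn),
       heads = as.integer(heads), queries = as.integer(queries),
       dec_layers = as.integer(dec_layers),
       dfam_n = as.integer(dfam_n), dfam_hidden = as.integer(dfam_hidden),
       use_mcca = if (is.null(use_mcca)) full else isTRUE(use_mcca),
       use_dfam = if (is.null(use_dfam)) full else isTRUE(use_dfam),
       loss = loss, match_weights = match_weights,
       seed = as.integer(seed))
}

#' Calibration configuration
#'
#' The documented configuration at which the three model variants reach
#' their published sizes: decoder dim 256 with 8 heads, 3 decoder layers,
#' 300 queries and feed-forward width 960 (shared by AIFI); GELAN terminal
#' stage with transition width 192; aggregation path at width 256 with 3
#' RepConvs per RepC3 and RepC3 hidden width 236.
#'
#' @param variant passed through to [model_config()].
#' @return config list for [build_model()].
#' @export
calibrated_config <- function(variant = c("full", "improved_decoder",
                                          "resnet18_decoder")) {
  model_config(n_classes = 6L, d = 256L, variant = match.arg(variant),
               backbone = backbone_config(repncspelan4_hidden = 192L,
                                          repncspelan4_blocks = 1L),
               aifi_ffn = 960L, dec_ffn = 960L,
               heads = 8L, queries = 300L, dec_layers = 3L,
               dfam_n = 3L, dfam_hidden = 236L)
}

#' Build the detector
#'
#' @param config from [model_config()] or [calibrated_config()].
#' @return an `nn_module` of type `detr`.
#' @export
build_model <- function(config = model_config()) {
  set.seed(config$seed)
  d <- config$d
  sc <- config$backbone$stage_channels
  backbone <- build_backbone(config$backbone)
  proj7 <- nn_bconv(sc[4], d, k = 1L, act = "none")
  proj4 <- proj5 <- NULL
  if (!config$use_dfam) {
    proj4 <- nn_bconv(sc[2], d, k = 1L, act = "none")
    proj5 <- nn_bconv(sc[3], d, k = 1L, act = "none")
  }
  mcca <- if (config$use_mcca)
    build_mcca(d, reduced = config$mcca_reduced) else NULL
  aifi <- build_aifi(d, heads = config$heads, ffn = config$aifi_ffn)
  dfam <- if (config$use_dfam)
    build_dfam(dfam_config(channels = d,
                           in_channels = c(sc[2], sc[3], d),
                           n_repconvs = config$dfam_n,
                           repc3_hidden = config$dfam_hidden)) else NULL
  decoder <- build_decoder(d, config$n_classes, queries = config$queries,
                           layers = config$dec_layers,
                           heads = config$heads, ffn = config$dec_ffn)
  nn_module("detr", backbone = backbone, proj4 = proj4, proj5 = proj5,
            proj7 = proj7, mcca = mcca, aifi = aifi, dfam = dfam,
            decoder = decoder, config = config)
}

model_run_ag <- function(m, x) {
  cfg <- m$config
  pyr <- backbone_run_ag(m$backbone, x)
  p7 <- fwd_bconv(m$proj7, pyr$s7)
  deep <- if (!is.null(m$mcca)) {
    if (cfg$deep_branches == "serial") {
      aifi_run_ag(m$aifi, mcca_run_ag(m$mcca, p7)$out)
    } else {
      ag_add(mcca_run_ag(m$mcca, p7)$out, aifi_run_ag(m$aifi, p7))
    }
  } else {
    aifi_run_ag(m$aifi, p7)
  }
  pyrd <- if (!is.null(m$dfam)) {
    dfam_run_ag(m$dfam, pyr$s4, pyr$s5, deep)
  } else {
    list(s4 = fwd_bconv(m$proj4, pyr$s4),
         s5 = fwd_bconv(m$proj5, pyr$s5),
         s7 = deep)
  }
  decoder_run_ag(m$decoder, pyrd)
}

#' Run the detector on an image
#'
#' @param model from [build_model()].
#' @param image `[3,H,W]` array in `[0,1]` (H, W divisible by 32) or an
#'   `[H,W,3]` image array, which is converted.
#' @param score_threshold drop detections below this confidence
#'   (default 0: mAP evaluation integrates over scores).
#' @return detection data.frame (see [decode()]).
#' @export
predict_detections <- function(model, image, score_threshold = 0) {
  if (length(dim(image)) == 3 && dim(image)[3] == 3 && dim(image)[1] != 3)
    image <- aperm(image, c(3, 1, 2))
  m <- eval_wrap(model)
  out <- model_run_ag(m, ag_const(NULL, image))
  scores <- out$scores$val
  boxes <- out$boxes$val
  cls <- max.col(scores, ties.method = "first")
  sc <- scores[cbind(seq_len(nrow(scores)), cls)]
  H <- dim(image)[2]; W <- dim(image)[3]
  xy <- box_cxcywh_to_xyxy(boxes)
  det <- data.frame(x1 = pmin(pmax(xy[, 1] * W, 0), W - 1e-3),
                    y1 = pmin(pmax(xy[, 2] * H, 0), H - 1e-3),
                    x2 = pmin(pmax(xy[, 3] * W, 1e-3), W),
                    y2 = pmin(pmax(xy[, 4] * H, 1e-3), H),
                    class_id = cls, score = sc)
  det$x2 <- pmax(det$x2, det$x1 + 1e-3)
  det$y2 <- pmax(det$y2, det$y1 + 1e-3)
  det[det$score >= score_threshold, , drop = FALSE]
}

#' Parameter counts of the model variants
#'
#' Builds each requested variant at a config and reports exact trainable
#' parameter counts, counts in millions (one decimal), and the relative
#' reduction of the improved backbone over the original.
#'
#' @param config_fn function(variant) returning a config; defaults to
#'   [calibrated_config()].
#' @param variants character vector of variants to build.
#' @return data.frame with `variant`, `parameters`, `millions`.
#' @export
parameter_report <- function(config_fn = calibrated_config,
                             variants = c("resnet18_decoder",
                                          "improved_decoder", "full")) {
  counts <- vapply(variants, function(v) {
    count_parameters(build_model(config_fn(v)))
  }, numeric(1))
  data.frame(variant = variants,
             parameters = counts,
             millions = round(counts / 1e6, 1),
             row.names = NULL)
}
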