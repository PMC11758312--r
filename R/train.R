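# AdamW training of the set-prediction objective with Hungarian matching.

truths_to_targets <- function(truths, H, W) {
  if (is.null(truths) || nrow(truths) == 0)
    return(list(labels = integer(), boxes = NULL))
  xy <- as.matrix(truths[, c("x1", "y1", "x2", "y2")])
  c4 <- box_xyxy_to_cxcywh(xy)
  c4[, c(1, 3)] <- c4[, c(1, 3)] / W
  c4[, c(2, 4)] <- c4[, c(2, 4)] / H
  list(labels = as.integer(truths$class_id), boxes = c4)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Train a detector on a fixed set of scenes
#'
#' Full-batch AdamW on the composite VariFocal + GIoU + L1 objective with
#' per-step Hungarian matching. Deterministic given the model's initial
#' parameters (matching and the forward pass involve no sampling).
#'
#' @param model from [build_model()].
#' @param scenes list of `list(image, truths)` (see [generate_scene()]).
#' @param steps optimization steps.
#' @param lr peak learning rate.
#' @param weight_decay decoupled weight decay.
#' @param schedule `"cosine"` (default; linear warmup over the first 5% of
#'   steps, then cosine decay to a tenth of the peak) or `"constant"`.
#' @param verbose print the loss every 25 steps.
#' @return list with the trained `model` and a `log` data.frame
#'   (`step`, `l_vfl`, `l_giou`, `l_l1`, `total`); row `step = 0` holds
#'   the pre-training loss.
#' @export
train_model <- function(model, scenes, steps = 300L, lr = 1e-2,
                        weight_decay = 1e-4,
                        schedule = c("cosine", "constant"),
                        verbose = FALSE) {
  schedule <- match.arg(schedule)
  warm <- max(1, round(0.05 * steps))
  lr_at <- function(t) {
    if (schedule == "constant") return(lr)
    if (t <= warm) return(lr * t / warm)
    frac <- (t - warm) / max(1, steps - warm)
    lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
  }
  cfg <- model$config
  imgs <- lapply(scenes, function(s) {
    x <- s$image
    if (dim(x)[1] != 3) x <- aperm(x, c(3, 1, 2))
    x
  })
  tgts <- lapply(scenes, function(s)
    truths_to_targets(s$truths, dim(s$image)[1], dim(s$image)[2]))
  params <- param_list(model)
  state <- adamw_init(params)
  log <- NULL
  for (step in seq_len(steps + 1L)) {
    tape <- ag_tape()
    reg <- new.env(parent = emptyenv())
    reg$leaves <- list()
    wm <- ag_wrap_module(model, tape, reg)
    terms <- c(l_vfl = 0, l_giou = 0, l_l1 = 0)
    total <- NULL
    for (k in seq_along(imgs)) {
      out <- model_run_ag(wm, ag_const(tape, imgs[[k]]))
      mt <- hungarian_match(out$boxes$val, out$scores$val,
                            tgts[[k]]$boxes, tgts[[k]]$labels,
                            cfg$match_weights)
      lt <- loss_run_ag(out$scores, out$boxes, tgts[[k]], mt, cfg$loss)
      terms <- terms + c(lt$l_vfl$val, lt$l_giou$val, lt$l_l1$val)
      total <- if (is.null(total)) lt$total else ag_add(total, lt$total)
    }
    total <- ag_cmul(total, 1 / length(imgs))
    if (!is.finite(total$val))
      stop("non-finite training loss at step ", step - 1L,
           " (terms: ", paste(signif(terms, 4), collapse = ", "), ")")
    log <- rbind(log, data.frame(step = step - 1L,
                                 l_vfl = terms[[1]] / length(imgs),
                                 l_giou = terms[[2]] / length(imgs),
                                 l_l1 = terms[[3]] / length(imgs),
                                 total = total$val))
    if (verbose && (step - 1L) %% 25L == 0L)
      message(sprintf("step %4d  loss %.5f", step - 1L, total$val))
    if (step > steps) break
    grads_by_id <- ag_backward(total)
    grads <- lapply(reg$leaves, function(l) grads_by_id[[l$id]])
    upd <- adamw_step(params, grads, state, lr_at(step), weight_decay)
    params <- upd$params
    state <- upd$state
    model <- set_param_list(model, params)
  }
  rownames(log) <- NULL
  list(model = model, log = log)
}
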