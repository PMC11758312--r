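# Layer constructors and parameter bookkeeping.
#
# A module is a list with class "nn_module": $params holds named numeric
# arrays (trainable), $buffers holds fixed statistics, and any other list
# element may be a sub-module. Initialization draws from the current R RNG
# stream, so builders are deterministic under set.seed().

nn_module <- function(type, params = list(), buffers = list(), ...) {
  structure(c(list(type = type, params = params, buffers = buffers),
              list(...)),
            class = c(paste0("nn_", type), "nn_module"))
}

kaiming_uniform <- function(dims, fan_in) {
  s <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

#' 2-D convolution layer
#' @noRd
nn_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                      bias = TRUE) {
  if (cin <= 0 || cout <= 0) stop("channel counts must be positive")
  k <- rep(as.integer(k), length.out = 2)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  fan_in <- cin * prod(k)
  p <- list(weight = kaiming_uniform(c(cout, cin, k[1], k[2]), fan_in))
  if (bias) p$bias <- stats::runif(cout, -1, 1) / sqrt(fan_in)
  nn_module("conv2d", params = p, stride = as.integer(stride),
            pad = as.integer(pad), cin = cin, cout = cout, k = k)
}

#' Frozen-statistics batch normalization (DETR-family convention): the
#' per-channel affine parameters train, the statistics stay fixed.
#' @noRd
nn_bn2d <- function(c, eps = 1e-5) {
  nn_module("bn2d",
            params = list(weight = rep(1, c), bias = rep(0, c)),
            buffers = list(mean = rep(0, c), var = rep(1, c)),
            eps = eps, c = c)
}

nn_linear <- function(cin, cout) {
  nn_module("linear",
            params = list(weight = kaiming_uniform(c(cin, cout), cin),
                          bias = stats::runif(cout, -1, 1) / sqrt(cin)),
            cin = cin, cout = cout)
}

nn_layernorm <- function(d) {
  nn_module("layernorm", params = list(gamma = rep(1, d), beta = rep(0, d)))
}

nn_embedding <- function(n, d) {
  # unit-variance init keeps the object queries distinct from one another
  nn_module("embedding",
            params = list(weight = matrix(stats::rnorm(n * d), n, d)))
}

# conv -> frozen BN -> activation, the Bconv of the attention/fusion blocks
nn_bconv <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                     act = c("silu", "relu", "none")) {
  act <- match.arg(act)
  nn_module("bconv",
            conv = nn_conv2d(cin, cout, k, stride, pad, bias = FALSE),
            bn = nn_bn2d(cout), act = act)
}

# ---- forwards (modules must be tape-wrapped via ag_wrap_module) --------

# per-channel affine y[c,.,.] = x[c,.,.] * w[c] + b[c]
ag_channel_affine <- function(x, w, b) {
  d <- dim(x$val); C <- d[1]; HW <- d[2] * d[3]
  wv <- w$val; bv <- b$val
  y <- x$val * wv + bv  # recycling: channel index is fastest
  xv <- x$val
  new_op(x$tape, y, list(x, w, b), function(g) {
    list(g * wv,
         rowSums(matrix(g * xv, C, HW)),
         rowSums(matrix(g, C, HW)))
  })
}

fwd_conv2d <- function(m, x) {
  ag_conv2d(x, m$params$weight, m$params$bias, m$stride, m$pad)
}

fwd_bn2d <- function(m, x) {
  inv <- 1 / sqrt(m$buffers$var + m$eps)
  w <- ag_cmul(m$params$weight, inv)
  b <- ag_sub(m$params$bias, ag_cmul(w, m$buffers$mean))
  ag_channel_affine(x, w, b)
}

fwd_act <- function(act, x) {
  switch(act, silu = ag_silu(x), relu = ag_relu(x), none = x)
}

fwd_bconv <- function(m, x) {
  fwd_act(m$act, fwd_bn2d(m$bn, fwd_conv2d(m$conv, x)))
}

fwd_linear <- function(m, x) {
  ag_add_rowvec(ag_matmul(x, m$params$weight), m$params$bias)
}

fwd_layernorm <- function(m, x) {
  ag_layernorm(x, m$params$gamma, m$params$beta)
}

# ---- parameter bookkeeping ---------------------------------------------

is_module_tree <- function(x) {
  inherits(x, "nn_module") ||
    (is.list(x) && !is_ag(x) && length(x) > 0 &&
       any(vapply(x, is_module_tree, logical(1))))
}

#' Count trainable parameters
#'
#' Exact number of trainable scalar values in a module tree: the sum over
#' every parameter array of its element count. Fixed buffers (e.g. frozen
#' batch-norm statistics) are excluded.
#'
#' @param model a module or any nested list of modules.
#' @return integer-valued numeric count.
#' @examples
#' set.seed(1)
#' m <- list(a = camtrapdetr:::nn_conv2d(8, 16, k = 1, bias = FALSE))
#' count_parameters(m)  # 8 * 16
#' @export
count_parameters <- function(model) {
  n <- 0
  walk <- function(m) {
    if (inherits(m, "nn_module")) {
      for (p in m$params) n <<- n + length(if (is_ag(p)) p$val else p)
      for (nm in names(m)) {
        if (nm %in% c("params", "buffers")) next
        if (is_module_tree(m[[nm]])) walk(m[[nm]])
      }
    } else if (is.list(m)) {
      for (el in m) if (is_module_tree(el)) walk(el)
    }
  }
  walk(model)
  n
}

# element labels for traversal: names where present, indices otherwise
tree_labels <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  ifelse(nm == "", as.character(seq_along(x)), nm)
}

# flat named list of parameter arrays, depth-first, stable order
param_list <- function(model, path = "m") {
  out <- list()
  if (inherits(model, "nn_module")) {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      out[[paste0(path, ".", nm)]] <- if (is_ag(p)) p$val else p
    }
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (lb[k] %in% c("params", "buffers")) next
      if (is_module_tree(model[[k]]))
        out <- c(out, param_list(model[[k]], paste0(path, ".", lb[k])))
    }
  } else if (is.list(model)) {
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (is_module_tree(model[[k]]))
        out <- c(out, param_list(model[[k]], paste0(path, ".", lb[k])))
    }
  }
  out
}

# write a flat named list of arrays back into the module tree
set_param_list <- function(model, flat, path = "m") {
  if (inherits(model, "nn_module")) {
    for (nm in names(model$params)) {
      key <- paste0(path, ".", nm)
      if (!is.null(flat[[key]])) model$params[[nm]] <- flat[[key]]
    }
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (lb[k] %in% c("params", "buffers")) next
      if (is_module_tree(model[[k]]))
        model[[k]] <- set_param_list(model[[k]], flat,
                                     paste0(path, ".", lb[k]))
    }
  } else if (is.list(model)) {
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (is_module_tree(model[[k]]))
        model[[k]] <- set_param_list(model[[k]], flat,
                                     paste0(path, ".", lb[k]))
    }
  }
  model
}

# replace every parameter array by a tape leaf; records leaves in `reg`
# (an environment with $leaves) keyed by the same paths as param_list()
ag_wrap_module <- function(model, tape, reg = NULL, path = "m") {
  if (inherits(model, "nn_module")) {
    for (nm in names(model$params)) {
      leaf <- new_leaf(tape, model$params[[nm]])
      if (!is.null(reg)) reg$leaves[[paste0(path, ".", nm)]] <- leaf
      model$params[[nm]] <- leaf
    }
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (lb[k] %in% c("params", "buffers")) next
      if (is_module_tree(model[[k]]))
        model[[k]] <- ag_wrap_module(model[[k]], tape, reg,
                                     paste0(path, ".", lb[k]))
    }
  } else if (is.list(model)) {
    lb <- tree_labels(model)
    for (k in seq_along(model)) {
      if (is_module_tree(model[[k]]))
        model[[k]] <- ag_wrap_module(model[[k]], tape, reg,
                                     paste0(path, ".", lb[k]))
    }
  }
  model
}

# convenience: wrap with a NULL tape for plain (no-gradient) evaluation
eval_wrap <- function(model) ag_wrap_module(model, NULL)

# 2-D sinusoidal positional encoding for an H x W token grid, dim d
sincos_position_2d <- function(H, W, d, temperature = 10000) {
  stopifnot(d %% 4 == 0)
  pd <- d %/% 4
  omega <- 1 / temperature^((seq_len(pd) - 1) / pd)
  xs <- rep(seq_len(W) - 1, each = H)   # tokens ordered column-major [H,W]
  ys <- rep(seq_len(H) - 1, times = W)
  outx <- outer(xs, omega)
  outy <- outer(ys, omega)
  cbind(sin(outx), cos(outx), sin(outy), cos(outy))
}
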