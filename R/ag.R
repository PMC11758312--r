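# Minimal reverse-mode automatic differentiation over plain R arrays.
#
# Feature maps are numeric arrays [C, H, W] (channel-first, single image);
# token matrices are [T, d]. A "tape" records operations so that gradients of
# a scalar loss can be propagated back to every parameter. Passing tape = NULL
# evaluates the same code without recording, which is how inference runs.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$parents <- vector("list", 256L)
  e$bwd <- vector("list", 256L)
  class(e) <- "ag_tape"
  e
}

is_ag <- function(x) inherits(x, "ag")

#' @noRd
new_leaf <- function(tape, val) {
  if (is.null(tape)) {
    return(structure(list(tape = NULL, id = NA_integer_, val = val),
                     class = "ag"))
  }
  id <- tape$n + 1L
  if (id > length(tape$parents)) {
    length(tape$parents) <- 2L * id
    length(tape$bwd) <- 2L * id
  }
  tape$n <- id
  tape$parents[[id]] <- integer()
  structure(list(tape = tape, id = id, val = val), class = "ag")
}

# Record an op node. `parents` are ag handles; `bwd(g)` returns a list of
# gradients aligned with `parents` (NULL entries allowed). Arguments are
# forced before the node id is reserved so that every parent expression
# (lazily evaluated in R) registers its nodes first — backpropagation
# relies on ids increasing from parents to consumers.
new_op <- function(tape, val, parents, bwd) {
  force(parents); force(val); force(bwd)
  if (is.null(tape)) {
    return(structure(list(tape = NULL, id = NA_integer_, val = val),
                     class = "ag"))
  }
  id <- tape$n + 1L
  if (id > length(tape$parents)) {
    length(tape$parents) <- 2L * id
    length(tape$bwd) <- 2L * id
  }
  tape$n <- id
  tape$parents[[id]] <- vapply(parents, function(p) p$id, integer(1))
  tape$bwd[[id]] <- bwd
  structure(list(tape = tape, id = id, val = val), class = "ag")
}

ag_const <- function(tape, x) new_leaf(tape, x)

ag_value <- function(x) if (is_ag(x)) x$val else x

# Backpropagate from a scalar loss; returns list of gradients indexed by
# node id (NULL where no gradient flowed).
ag_backward <- function(loss) {
  tape <- loss$tape
  if (is.null(tape)) stop("cannot backpropagate without a recording tape")
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    fn <- tape$bwd[[id]]
    if (is.null(fn)) next
    pg <- fn(g)
    ps <- tape$parents[[id]]
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
    grads[id] <- list(NULL)  # free memory without shifting indices
  }
  grads
}

# ---- elementwise ops ---------------------------------------------------

ag_add <- function(a, b) {
  new_op(a$tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  new_op(a$tape, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  new_op(a$tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(a, b) {
  av <- a$val; bv <- b$val
  new_op(a$tape, av / bv, list(a, b),
         function(g) list(g / bv, -g * av / (bv * bv)))
}

# constant (untracked) second operand; k may be scalar or same-shape array
ag_cadd <- function(a, k) new_op(a$tape, a$val + k, list(a), function(g) list(g))
ag_cmul <- function(a, k) new_op(a$tape, a$val * k, list(a), function(g) list(g * k))
ag_crsub <- function(k, a) new_op(a$tape, k - a$val, list(a), function(g) list(-g))

ag_neg <- function(a) ag_cmul(a, -1)

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  new_op(a$tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(a) {
  x <- a$val
  s <- 1 / (1 + exp(-x))
  new_op(a$tape, x * s, list(a), function(g) list(g * (s + x * s * (1 - s))))
}

ag_relu <- function(a) {
  x <- a$val
  m <- x > 0
  new_op(a$tape, x * m, list(a), function(g) list(g * m))
}

ag_exp <- function(a) {
  v <- exp(a$val)
  new_op(a$tape, v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  x <- a$val
  new_op(a$tape, log(x), list(a), function(g) list(g / x))
}

ag_abs <- function(a) {
  x <- a$val
  new_op(a$tape, abs(x), list(a), function(g) list(g * sign(x)))
}

ag_pow_const <- function(a, p) {
  x <- a$val
  new_op(a$tape, x^p, list(a), function(g) list(g * p * x^(p - 1)))
}

# clamp to [lo, hi]; gradient is passed through inside the interval only
ag_clamp <- function(a, lo, hi) {
  x <- a$val
  m <- (x >= lo) & (x <= hi)
  new_op(a$tape, pmin(pmax(x, lo), hi), list(a), function(g) list(g * m))
}

ag_pmax2 <- function(a, b) {
  av <- a$val; bv <- b$val
  m <- av >= bv
  new_op(a$tape, pmax(av, bv), list(a, b),
         function(g) list(g * m, g * !m))
}

ag_pmin2 <- function(a, b) {
  av <- a$val; bv <- b$val
  m <- av <= bv
  new_op(a$tape, pmin(av, bv), list(a, b),
         function(g) list(g * m, g * !m))
}

ag_cpmax <- function(a, k) {
  m <- a$val >= k
  new_op(a$tape, pmax(a$val, k), list(a), function(g) list(g * m))
}

ag_cpmin <- function(a, k) {
  m <- a$val <= k
  new_op(a$tape, pmin(a$val, k), list(a), function(g) list(g * m))
}

# ---- reductions --------------------------------------------------------

ag_sum <- function(a) {
  d <- dim(a$val); n <- length(a$val)
  new_op(a$tape, sum(a$val), list(a), function(g) {
    out <- rep(as.numeric(g), n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

ag_mean <- function(a) {
  d <- dim(a$val); n <- length(a$val)
  new_op(a$tape, mean(a$val), list(a), function(g) {
    out <- rep(as.numeric(g) / n, n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

# directional pools over a [C,H,W] map (the three 1-D encodings)
ag_pool_w <- function(a) {
  d <- dim(a$val); C <- d[1]; H <- d[2]; W <- d[3]
  m <- rowMeans(matrix(a$val, C * H, W))
  new_op(a$tape, array(m, c(C, H, 1)), list(a), function(g) {
    list(array(rep(c(g) / W, W), c(C, H, W)))
  })
}

ag_pool_h <- function(a) {
  d <- dim(a$val); C <- d[1]; H <- d[2]; W <- d[3]
  m <- rowMeans(matrix(aperm(a$val, c(1, 3, 2)), C * W, H))
  new_op(a$tape, array(m, c(C, 1, W)), list(a), function(g) {
    list(aperm(array(rep(c(g) / H, H), c(C, W, H)), c(1, 3, 2)))
  })
}

ag_pool_sum_hw <- function(a) {
  d <- dim(a$val); C <- d[1]; H <- d[2]; W <- d[3]
  s <- rowSums(matrix(a$val, C, H * W))
  new_op(a$tape, array(s, c(C, 1, 1)), list(a), function(g) {
    list(array(rep(c(g), H * W), c(C, H, W)))
  })
}

ag_pool_mean_hw <- function(a) {
  d <- dim(a$val); C <- d[1]; H <- d[2]; W <- d[3]
  s <- rowMeans(matrix(a$val, C, H * W))
  new_op(a$tape, array(s, c(C, 1, 1)), list(a), function(g) {
    list(array(rep(c(g) / (H * W), H * W), c(C, H, W)))
  })
}

# ---- shape ops ---------------------------------------------------------

ag_reshape <- function(a, dm) {
  d0 <- dim(a$val)
  v <- a$val; dim(v) <- dm
  new_op(a$tape, v, list(a), function(g) {
    dim(g) <- d0
    list(g)
  })
}

# broadcast an array whose dims are 1 along some axes up to `to_dim`
ag_expand <- function(a, to_dim) {
  from <- dim(a$val)
  stopifnot(length(from) == length(to_dim))
  if (all(from == to_dim)) return(a)
  ai <- arrayInd(seq_len(prod(to_dim)), to_dim)
  for (j in seq_along(from)) if (from[j] == 1L) ai[, j] <- 1L
  stride <- cumprod(c(1, from[-length(from)]))
  idx <- 1L + as.integer((ai - 1L) %*% stride)
  v <- a$val[idx]
  dim(v) <- to_dim
  n_from <- prod(from)
  new_op(a$tape, v, list(a), function(g) {
    gg <- rowsum(c(g), idx)
    out <- numeric(n_from)
    out[as.integer(rownames(gg))] <- gg
    dim(out) <- from
    list(out)
  })
}

# gather: out[i] = a[idx[i]] (linear indices); used by nearest upsampling
ag_gather <- function(a, idx, out_dim) {
  v <- a$val[idx]
  dim(v) <- out_dim
  d0 <- dim(a$val); n0 <- length(a$val)
  new_op(a$tape, v, list(a), function(g) {
    gg <- rowsum(c(g), idx)
    out <- numeric(n0)
    out[as.integer(rownames(gg))] <- gg
    if (!is.null(d0)) dim(out) <- d0
    list(out)
  })
}

# nearest-neighbour 2x spatial upsampling of [C,H,W]
ag_upsample2 <- function(a) {
  d <- dim(a$val); C <- d[1]; H <- d[2]; W <- d[3]
  ii <- (seq_len(2 * H) + 1L) %/% 2L
  jj <- (seq_len(2 * W) + 1L) %/% 2L
  inner <- as.vector(outer(ii - 1L, (jj - 1L) * H, `+`))
  idx <- rep(inner * C, each = C) + seq_len(C)
  ag_gather(a, idx, c(C, 2L * H, 2L * W))
}

# concatenate [C_i,H,W] maps along channels
ag_concat_c <- function(parts) {
  dims <- lapply(parts, function(p) dim(p$val))
  H <- dims[[1]][2]; W <- dims[[1]][3]
  cs <- vapply(dims, `[`, numeric(1), 1)
  Cout <- sum(cs)
  v <- array(0, c(Cout, H, W))
  off <- 0L
  for (k in seq_along(parts)) {
    v[off + seq_len(cs[k]), , ] <- parts[[k]]$val
    off <- off + cs[k]
  }
  offs <- cumsum(c(0, cs))
  new_op(parts[[1]]$tape, v, parts, function(g) {
    lapply(seq_along(parts), function(k) {
      g[offs[k] + seq_len(cs[k]), , , drop = FALSE]
    })
  })
}

# slice a [C,H,W] map along one dimension (1 = channel, 2 = height, 3 = width)
ag_narrow <- function(a, dm, start, len) {
  d <- dim(a$val)
  idx <- seq.int(start, length.out = len)
  v <- switch(dm,
    a$val[idx, , , drop = FALSE],
    a$val[, idx, , drop = FALSE],
    a$val[, , idx, drop = FALSE])
  new_op(a$tape, v, list(a), function(g) {
    out <- array(0, d)
    if (dm == 1) out[idx, , ] <- g else if (dm == 2) out[, idx, ] <- g
    else out[, , idx] <- g
    list(out)
  })
}

# transpose [C,H,1] <-> [C,1,W] (swap the two spatial axes)
ag_swap_hw <- function(a) {
  v <- aperm(a$val, c(1, 3, 2))
  new_op(a$tape, v, list(a), function(g) list(aperm(g, c(1, 3, 2))))
}

# ---- matrix ops (token sequences) -------------------------------------

ag_matmul <- function(a, b) {
  av <- a$val; bv <- b$val
  new_op(a$tape, av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ag_t <- function(a) {
  new_op(a$tape, t(a$val), list(a), function(g) list(t(g)))
}

ag_index_cols <- function(a, cols) {
  d <- dim(a$val)
  v <- a$val[, cols, drop = FALSE]
  new_op(a$tape, v, list(a), function(g) {
    out <- matrix(0, d[1], d[2])
    out[, cols] <- g
    list(out)
  })
}

ag_index_rows <- function(a, rows) {
  d <- dim(a$val)
  v <- a$val[rows, , drop = FALSE]
  new_op(a$tape, v, list(a), function(g) {
    out <- matrix(0, d[1], d[2])
    out[rows, ] <- g
    list(out)
  })
}

ag_cbind2 <- function(parts) {
  ncols <- vapply(parts, function(p) ncol(p$val), numeric(1))
  offs <- cumsum(c(0, ncols))
  v <- do.call(cbind, lapply(parts, ag_value))
  new_op(parts[[1]]$tape, v, parts, function(g) {
    lapply(seq_along(parts), function(k) {
      g[, offs[k] + seq_len(ncols[k]), drop = FALSE]
    })
  })
}

# add a row vector (bias) to every row of a matrix
ag_add_rowvec <- function(a, b) {
  av <- a$val; bv <- b$val
  n <- nrow(av)
  v <- av + matrix(bv, n, length(bv), byrow = TRUE)
  new_op(a$tape, v, list(a, b), function(g) {
    list(g, colSums(g))
  })
}

# multiply every row of a matrix by a row vector (elementwise)
ag_mul_rowvec <- function(a, b) {
  av <- a$val; bv <- b$val
  n <- nrow(av)
  bm <- matrix(bv, n, length(bv), byrow = TRUE)
  new_op(a$tape, av * bm, list(a, b), function(g) {
    list(g * bm, colSums(g * av))
  })
}

ag_softmax_rows <- function(a) {
  x <- a$val
  m <- apply(x, 1, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  new_op(a$tape, s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  gv <- gamma$val
  n <- nrow(x)
  y <- xhat * matrix(gv, n, length(gv), byrow = TRUE) +
    matrix(beta$val, n, length(gv), byrow = TRUE)
  new_op(a$tape, y, list(a, gamma, beta), function(g) {
    dxhat <- g * matrix(gv, n, length(gv), byrow = TRUE)
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# ---- convolution -------------------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

conv2d_index <- function(Cin, H, W, kh, kw, stride, ph, pw) {
  key <- paste(Cin, H, W, kh, kw, stride, ph, pw, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  H2 <- (Hp - kh) %/% stride + 1L
  W2 <- (Wp - kw) %/% stride + 1L
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  ci <- rep(seq_len(Cin), times = kh * kw)
  ki <- rep(rep(seq_len(kh), each = Cin), times = kw)
  kj <- rep(seq_len(kw), each = Cin * kh)
  row_pad <- outer(ki, (i2 - 1L) * stride, `+`)
  col_pad <- outer(kj, (j2 - 1L) * stride, `+`)
  idx <- ci + Cin * ((row_pad - 1L) + Hp * (col_pad - 1L))
  out <- list(idx = idx, H2 = H2, W2 = W2, Hp = Hp, Wp = Wp)
  .conv_cache[[key]] <- out
  out
}

# 2-D convolution on a single [Cin,H,W] map.
# w: ag holding array [Cout,Cin,kh,kw]; b: ag holding length-Cout vector or
# NULL. `pad` may be one value or c(pad_h, pad_w).
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x$val); Cin <- d[1]; H <- d[2]; W <- d[3]
  wd <- dim(w$val); Cout <- wd[1]; kh <- wd[3]; kw <- wd[4]
  stopifnot(wd[2] == Cin)
  pad <- rep(as.integer(pad), length.out = 2)
  ph <- pad[1]; pw <- pad[2]
  ix <- conv2d_index(Cin, H, W, kh, kw, as.integer(stride), ph, pw)
  if (ph > 0 || pw > 0) {
    xp <- array(0, c(Cin, ix$Hp, ix$Wp))
    xp[, ph + seq_len(H), pw + seq_len(W)] <- x$val
  } else xp <- x$val
  cols <- xp[ix$idx]
  dim(cols) <- dim(ix$idx)
  wm <- matrix(w$val, Cout, Cin * kh * kw)
  y <- wm %*% cols
  bv <- if (!is.null(b)) b$val else NULL
  if (!is.null(bv)) y <- y + bv  # recycles down columns (Cout fastest)
  dim(y) <- c(Cout, ix$H2, ix$W2)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_op(x$tape, y, parents, function(g) {
    gm <- matrix(g, Cout, ix$H2 * ix$W2)
    dW <- gm %*% t(cols)
    dim(dW) <- wd
    dcols <- crossprod(wm, gm)
    rs <- rowsum(c(dcols), c(ix$idx))
    dxp <- numeric(Cin * ix$Hp * ix$Wp)
    dxp[as.integer(rownames(rs))] <- rs
    dim(dxp) <- c(Cin, ix$Hp, ix$Wp)
    dx <- if (ph > 0 || pw > 0)
      dxp[, ph + seq_len(H), pw + seq_len(W), drop = FALSE] else dxp
    if (is.null(b)) list(dx, dW) else list(dx, dW, rowSums(gm))
  })
}

# max pooling over k x k windows of a [C,H,W] map
ag_maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x$val); C <- d[1]; H <- d[2]; W <- d[3]
  ix <- conv2d_index(C, H, W, k, k, as.integer(stride),
                     as.integer(pad), as.integer(pad))
  xp <- array(-Inf, c(C, ix$Hp, ix$Wp))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x$val
  vals <- xp[ix$idx]
  kk <- k * k
  Q <- ix$H2 * ix$W2
  dim(vals) <- c(C, kk, Q)
  m <- vals[, 1, ]
  am <- matrix(1L, C, Q)
  if (kk > 1) for (j in 2:kk) {
    vj <- vals[, j, ]
    upd <- vj > m
    m[upd] <- vj[upd]
    am[upd] <- j
  }
  y <- m
  dim(y) <- c(C, ix$H2, ix$W2)
  idxarr <- ix$idx
  dim(idxarr) <- c(C, kk, Q)
  new_op(x$tape, y, list(x), function(g) {
    ci <- rep(seq_len(C), times = Q)
    qi <- rep(seq_len(Q), each = C)
    sel <- idxarr[cbind(ci, c(am), qi)]
    rs <- rowsum(c(g), sel)
    dxp <- numeric(C * ix$Hp * ix$Wp)
    dxp[as.integer(rownames(rs))] <- rs
    dim(dxp) <- c(C, ix$Hp, ix$Wp)
    list(dxp[, pad + seq_len(H), pad + seq_len(W), drop = FALSE])
  })
}

# concatenate [C,H_i,W] maps along the height (2nd) axis
ag_concat_h <- function(parts) {
  dims <- lapply(parts, function(p) dim(p$val))
  C <- dims[[1]][1]; W <- dims[[1]][3]
  hs <- vapply(dims, `[`, numeric(1), 2)
  v <- array(0, c(C, sum(hs), W))
  off <- 0L
  for (k in seq_along(parts)) {
    v[, off + seq_len(hs[k]), ] <- parts[[k]]$val
    off <- off + hs[k]
  }
  offs <- cumsum(c(0, hs))
  new_op(parts[[1]]$tape, v, parts, function(g) {
    lapply(seq_along(parts), function(k) {
      g[, offs[k] + seq_len(hs[k]), , drop = FALSE]
    })
  })
}
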