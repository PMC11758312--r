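# Aggregation path: Fuse scale contracts, RepC3 structure,
# re-parameterization equivalence, and full-path composition.

test_that("fuse enforces the 2x/0.5x scale contract and outputs at the middle scale", {
  fm <- build_fuse(8, 8, 8, 8)
  set.seed(1)
  inp <- list(f_up = array(rnorm(8 * 16 * 16), c(8, 16, 16)),
              f_middle = array(rnorm(8 * 8 * 8), c(8, 8, 8)),
              f_down = array(rnorm(8 * 4 * 4), c(8, 4, 4)))
  out <- fuse(inp, fm)
  expect_equal(dim(out), c(8, 8, 8))
  bad <- inp; bad$f_up <- array(0, c(8, 12, 12))
  expect_error(fuse(bad, fm), "f_up")
  bad <- inp; bad$f_down <- array(0, c(8, 3, 3))
  expect_error(fuse(bad, fm), "f_down")
})

test_that("with zeroed shallow/deep inputs the fused output depends only on the middle map", {
  fm <- build_fuse(4, 4, 4, 4)
  set.seed(2)
  mid <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  zero_up <- array(0, c(4, 16, 16)); zero_dn <- array(0, c(4, 4, 4))
  o1 <- fuse(list(f_up = zero_up, f_middle = mid, f_down = zero_dn), fm)
  # a different middle map changes the output; different (zero) extremes do not
  o2 <- fuse(list(f_up = zero_up, f_middle = mid + 1, f_down = zero_dn), fm)
  expect_gt(max(abs(o1 - o2)), 0)
})

test_that("fuse matches the straight-line transcription within 1e-6 (both concatenation variants)", {
  set.seed(3)
  for (literal in c(FALSE, TRUE)) {
    fm <- build_fuse(6, 6, 6, 6, literal_eq8 = literal)
    fm <- randomize_bn_stats(fm, seed = 4 + literal)
    inp <- list(f_up = array(rnorm(6 * 8 * 8), c(6, 8, 8)),
                f_middle = array(rnorm(6 * 4 * 4), c(6, 4, 4)),
                f_down = array(rnorm(6 * 2 * 2), c(6, 2, 2)))
    expect_equal(fuse(inp, fm),
                 ref_fuse(fm, inp$f_up, inp$f_middle, inp$f_down),
                 tolerance = 1e-6)
  }
})

test_that("RepC3 preserves spatial dims for any N and rejects N < 1", {
  expect_error(build_repc3(8, 8, n = 0), ">= 1")
  set.seed(4)
  x <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  for (n in c(1, 3)) {
    rc <- build_repc3(8, 8, n = n)
    expect_equal(dim(repc3_forward(x, rc)), c(8, 6, 6))
  }
  expect_error(repc3_forward(array(0, c(4, 6, 6)), build_repc3(8, 8)),
               "channel")
})

test_that("RepConv fusion reproduces the multi-branch output and drops parameters", {
  set.seed(5)
  for (rep in 1:3) {
    unit <- camtrapdetr:::nn_repconv(6, 6)
    unit <- randomize_bn_stats(unit, seed = 50 + rep)
    fused <- repconv_reparameterize(unit)
    expect_lt(count_parameters(fused), count_parameters(unit))
    wu <- camtrapdetr:::eval_wrap(unit)
    wf <- camtrapdetr:::eval_wrap(fused)
    maxdiff <- 0
    for (k in 1:20) {
      x <- camtrapdetr:::new_leaf(NULL, array(rnorm(6 * 5 * 5), c(6, 5, 5)))
      y1 <- camtrapdetr:::fwd_repconv(wu, x)$val
      y2 <- camtrapdetr:::fwd_repconv_any(wf, x)$val
      maxdiff <- max(maxdiff, max(abs(y1 - y2)))
    }
    expect_lt(maxdiff, 1e-4)
  }
})

test_that("zero-initialized side branches leave only the 3x3 kernel after fusion", {
  unit <- camtrapdetr:::nn_repconv(4, 4, identity = FALSE)
  unit$conv1$params$weight[] <- 0
  fused <- repconv_reparameterize(unit)
  # fresh BN statistics are the identity up to the numerical eps
  expect_equal(fused$conv$params$weight, unit$conv3$params$weight,
               tolerance = 1e-5)
})

test_that("re-parameterizing a whole RepC3 changes eval outputs by < 1e-4", {
  set.seed(6)
  rc <- randomize_bn_stats(build_repc3(8, 8, n = 2), seed = 7)
  fused <- reparameterize_module(rc)
  x <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  expect_lt(max(abs(repc3_forward(x, rc) - repc3_forward(x, fused))), 1e-4)
})

test_that("the full aggregation path keeps the three scales and mixes information across them", {
  dm <- build_dfam(dfam_config(channels = 8, in_channels = c(4, 8, 8),
                               n_repconvs = 1), seed = 8)
  set.seed(8)
  s4 <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  s5 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  s7 <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  out <- dfam_forward(s4, s5, s7, dm)
  expect_equal(dim(out$s4), c(8, 16, 16))
  expect_equal(dim(out$s5), c(8, 8, 8))
  expect_equal(dim(out$s7), c(8, 4, 4))
  # perturbing any single input scale changes all three outputs
  for (lvl in 1:3) {
    s4b <- s4; s5b <- s5; s7b <- s7
    if (lvl == 1) s4b[1, 1, 1] <- s4b[1, 1, 1] + 0.5
    if (lvl == 2) s5b[1, 1, 1] <- s5b[1, 1, 1] + 0.5
    if (lvl == 3) s7b[1, 1, 1] <- s7b[1, 1, 1] + 0.5
    outb <- dfam_forward(s4b, s5b, s7b, dm)
    for (nm in names(out))
      expect_gt(max(abs(out[[nm]] - outb[[nm]])), 0)
  }
})

test_that("the bypass wiring reduces the path to its input projections", {
  dm <- build_dfam(dfam_config(channels = 8, in_channels = c(4, 8, 8),
                               n_repconvs = 1, bypass = TRUE), seed = 9)
  set.seed(9)
  s4 <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  s5 <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  s7 <- array(rnorm(8 * 2 * 2), c(8, 2, 2))
  out <- dfam_forward(s4, s5, s7, dm)
  wp <- camtrapdetr:::eval_wrap(dm)
  expect_equal(out$s4,
               camtrapdetr:::fwd_bconv(wp$proj4,
                                       camtrapdetr:::new_leaf(NULL, s4))$val)
})

test_that("the full path equals a hand-wired composition of fuse/repc3 calls within 1e-5", {
  dm <- build_dfam(dfam_config(channels = 8, in_channels = c(4, 8, 8),
                               n_repconvs = 1), seed = 10)
  set.seed(10)
  s4 <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  s5 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  s7 <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  out <- dfam_forward(s4, s5, s7, dm)
  # hand-wired composition through the exported per-block functions
  wp <- camtrapdetr:::eval_wrap(dm)
  bconv <- function(mod, x)
    camtrapdetr:::fwd_bconv(mod, camtrapdetr:::new_leaf(NULL, x))$val
  p4 <- bconv(wp$proj4, s4); p5 <- bconv(wp$proj5, s5)
  p7 <- bconv(wp$proj7, s7)
  t5 <- repc3_forward(fuse(list(f_up = p4, f_middle = p5, f_down = p7),
                           dm$fuse_td), dm$repc3_td5)
  up <- function(x) x[, rep(seq_len(dim(x)[2]), each = 2),
                      rep(seq_len(dim(x)[3]), each = 2), drop = FALSE]
  cat_c <- function(a, b) {
    o <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
    o[seq_len(dim(a)[1]), , ] <- a
    o[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    o
  }
  t4 <- repc3_forward(bconv(wp$agg_td4, cat_c(p4, up(t5))), dm$repc3_td4)
  b5 <- repc3_forward(fuse(list(f_up = t4, f_middle = t5, f_down = p7),
                           dm$fuse_bu), dm$repc3_bu5)
  b7 <- repc3_forward(bconv(wp$agg_bu7, cat_c(p7, bconv(wp$down_bu7, b5))),
                      dm$repc3_bu7)
  expect_equal(out$s4, t4, tolerance = 1e-5)
  expect_equal(out$s5, b5, tolerance = 1e-5)
  expect_equal(out$s7, b7, tolerance = 1e-5)
})
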