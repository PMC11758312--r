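# Loss oracles: closed-form VariFocal values, GIoU against a
# rasterization oracle, L1, and the composite objective.

test_that("VariFocal matches direct evaluation of both branches", {
  expect_equal(varifocal_loss(1e-9, 0), 0, tolerance = 1e-6)
  expect_equal(varifocal_loss(0.5, 0, alpha = 0.75, gamma = 2),
               0.75 * 0.25 * (-log(0.5)), tolerance = 1e-9)
  expect_equal(varifocal_loss(0.5, 0.8),
               -0.8 * (0.8 * log(0.5) + 0.2 * log(0.5)), tolerance = 1e-9)
  expect_error(varifocal_loss(0.5, 0, alpha = -1), ">= 0")
})

test_that("VariFocal is non-negative and increasing in the negative branch", {
  set.seed(1)
  p <- runif(200); q <- ifelse(runif(200) < 0.5, 0, runif(200))
  for (i in seq_along(p))
    expect_gte(varifocal_loss(p[i], q[i]), 0)
  neg <- sort(runif(50))
  vals <- vapply(neg, function(x) varifocal_loss(x, 0), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("GIoU matches a fine-grid rasterization oracle", {
  expect_equal(giou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  o <- ref_iou_raster(c(0, 0, 2, 2), c(1, 1, 3, 3))
  expect_equal(giou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)), o$giou_loss,
               tolerance = 1e-3)
  expect_equal(giou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               1 - 1 / 7 + 2 / 9, tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    a <- c(sort(runif(2, 0, 3))[1], sort(runif(2, 0, 3))[1], 0, 0)
    a <- c(runif(1, 0, 2), runif(1, 0, 2), 0, 0)
    a[3] <- a[1] + runif(1, 0.5, 2); a[4] <- a[2] + runif(1, 0.5, 2)
    b <- c(runif(1, 0, 2), runif(1, 0, 2), 0, 0)
    b[3] <- b[1] + runif(1, 0.5, 2); b[4] <- b[2] + runif(1, 0.5, 2)
    expect_equal(giou_loss(a, b), ref_iou_raster(a, b, 0.005)$giou_loss,
                 tolerance = 0.02)
  }
  expect_error(giou_loss(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("GIoU is bounded, jointly translation/scale invariant, and approaches 2 when far apart", {
  set.seed(3)
  for (rep in 1:50) {
    a <- runif(2); a <- c(a, a + runif(2, 0.2, 1.5))
    b <- runif(2); b <- c(b, b + runif(2, 0.2, 1.5))
    l <- giou_loss(a, b)
    expect_gte(l, 0); expect_lte(l, 2)
    s <- runif(1, 0.5, 4); t <- runif(2, -3, 3)
    expect_equal(l, giou_loss(s * a + c(t, t), s * b + c(t, t)),
                 tolerance = 1e-9)
  }
  far <- giou_loss(c(0, 0, 1, 1), c(1000, 0, 1001, 1))
  expect_gt(far, 1.99)
})

test_that("L1 box loss is a mean absolute error with homogeneity", {
  p <- matrix(c(0, 0, 1, 1), 1, 4)
  expect_equal(l1_box_loss(p, p), 0)
  expect_equal(l1_box_loss(p, matrix(c(.1, .1, .9, .9), 1, 4)), 0.1,
               tolerance = 1e-12)
  set.seed(4)
  a <- matrix(runif(20), 5, 4); b <- matrix(runif(20), 5, 4)
  expect_equal(l1_box_loss(a, a + 3 * (b - a)), 3 * l1_box_loss(a, b),
               tolerance = 1e-12)
  expect_error(l1_box_loss(a, b[1:3, ]), "mismatch")
})

test_that("the composite loss hits its global minimum on perfect predictions", {
  tb <- matrix(c(.4, .4, .2, .2, .7, .6, .2, .3), 2, 4, byrow = TRUE)
  truths <- list(labels = c(2L, 5L), boxes = tb)
  scores <- matrix(0, 4, 6)
  scores[1, 2] <- 1; scores[3, 5] <- 1
  preds <- list(scores = scores, boxes = rbind(tb[1, ], c(.1, .1, .1, .1),
                                               tb[2, ], c(.9, .9, .1, .1)))
  mt <- hungarian_match(preds$boxes, preds$scores, tb, truths$labels)
  lt <- total_loss(preds, truths, mt)
  expect_equal(lt$total, 0, tolerance = 1e-6)
  expect_equal(lt$l_vfl + lt$l_giou + lt$l_l1, lt$total, tolerance = 1e-12)
})

test_that("an empty image with zero scores has zero loss", {
  preds <- list(scores = matrix(0, 5, 6),
                boxes = matrix(runif(20, 0.2, 0.8), 5, 4))
  truths <- list(labels = integer(), boxes = NULL)
  mt <- hungarian_match(preds$boxes, preds$scores, NULL, integer())
  lt <- total_loss(preds, truths, mt)
  expect_equal(lt$total, 0)
  expect_equal(lt$l_giou, 0)
  expect_equal(lt$l_l1, 0)
})

test_that("the composite loss equals the sum of independently computed terms", {
  set.seed(5)
  for (rep in 1:5) {
    K <- 6
    preds <- list(scores = matrix(runif(K * 6), K, 6),
                  boxes = matrix(runif(K * 4, 0.2, 0.6), K, 4))
    tb <- matrix(runif(8, 0.3, 0.6), 2, 4)
    truths <- list(labels = sample(6, 2), boxes = tb)
    mt <- hungarian_match(preds$boxes, preds$scores, tb, truths$labels)
    lt <- total_loss(preds, truths, mt)
    # straight-line recomputation from the three exported primitives
    pi <- mt$pairs[, "pred"]; ti <- mt$pairs[, "truth"]
    np <- length(pi)
    target <- matrix(0, K, 6)
    for (k in seq_len(np)) {
      pxy <- box_cxcywh_to_xyxy(preds$boxes[pi[k], , drop = FALSE])
      txy <- box_cxcywh_to_xyxy(tb[ti[k], , drop = FALSE])
      target[pi[k], truths$labels[ti[k]]] <- iou(pxy[1, ], txy[1, ])
    }
    vfl <- varifocal_loss(preds$scores, target)
    gio <- mean(vapply(seq_len(np), function(k)
      giou_loss(box_cxcywh_to_xyxy(preds$boxes[pi[k], , drop = FALSE])[1, ],
                box_cxcywh_to_xyxy(tb[ti[k], , drop = FALSE])[1, ]),
      numeric(1)))
    l1 <- l1_box_loss(preds$boxes[pi, , drop = FALSE],
                      tb[ti, , drop = FALSE])
    expect_equal(lt$l_vfl, vfl, tolerance = 1e-9)
    expect_equal(lt$l_giou, gio, tolerance = 1e-9)
    expect_equal(lt$l_l1, l1, tolerance = 1e-9)
    expect_equal(lt$total, vfl + gio + l1, tolerance = 1e-9)
  }
})

test_that("the loss gradient moves a matched box toward its truth", {
  tb <- matrix(c(.6, .6, .3, .3), 1, 4)
  truths <- list(labels = 1L, boxes = tb)
  pb <- matrix(c(.4, .45, .25, .3), 1, 4)
  ps <- matrix(0.5, 1, 2)
  mt <- hungarian_match(pb, ps, tb, 1L)
  tape <- camtrapdetr:::ag_tape()
  lb <- camtrapdetr:::new_leaf(tape, pb)
  ls <- camtrapdetr:::new_leaf(tape, ps)
  lt <- camtrapdetr:::loss_run_ag(ls, lb, truths, mt, loss_config())
  g <- camtrapdetr:::ag_backward(lt$total)[[lb$id]]
  # gradient descent step decreases the center-coordinate error
  expect_lt(g[1, 1], 0)  # cx must increase toward 0.6
  expect_lt(g[1, 2], 0)  # cy must increase toward 0.6
})
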