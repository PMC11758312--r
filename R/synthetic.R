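# Deterministic generator of camera-trap-like scenes with COCO-style
# annotations. Scenes emulate the challenge regimes of wildlife trap-camera
# imagery: partial occlusion by foreground vegetation, motion/defocus blur,
# and low-light night captures. Six synthetic "species" differ in shape,
# texture and color. Images are [H,W,3] arrays in [0,1].

SPECIES <- data.frame(
  id = 1:6,
  name = c("badger", "bear", "leopard_cat", "fox", "weasel", "boar"),
  aspect = c(1.6, 1.2, 1.8, 2.0, 2.6, 1.5),
  r = c(0.45, 0.20, 0.75, 0.80, 0.85, 0.35),
  g = c(0.42, 0.15, 0.60, 0.45, 0.65, 0.30),
  b = c(0.40, 0.12, 0.40, 0.30, 0.45, 0.28),
  tex_freq = c(0.9, 0.15, 1.8, 0.4, 0.5, 0.7),
  stringsAsFactors = FALSE)

#' Specify a synthetic scene
#'
#' @param image_size `c(H, W)` pixels.
#' @param n_objects number of animals to place.
#' @param classes class ids to draw from (subset of 1:6).
#' @param occlusion_frac fraction of each animal's pixels covered by
#'   foreground occluders, in `[0,1]`.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = sharp).
#' @param night apply the low-light model (strong gamma darkening plus
#'   additive Gaussian sensor noise, sd 10/255).
#' @param seed RNG seed; the same spec and seed give byte-identical output.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(128L, 128L), n_objects = 2L,
                       classes = 1:6, occlusion_frac = 0,
                       blur_sigma = 0, night = FALSE, seed = 1L) {
  stopifnot(n_objects >= 0, occlusion_frac >= 0, occlusion_frac <= 1,
            blur_sigma >= 0, all(classes %in% 1:6))
  structure(list(image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 classes = as.integer(classes),
                 occlusion_frac = occlusion_frac,
                 blur_sigma = blur_sigma,
                 night = isTRUE(night),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth procedural background: coarse noise, bilinearly upsampled
scene_background <- function(H, W) {
  gh <- max(2L, H %/% 16L); gw <- max(2L, W %/% 16L)
  base <- c(0.30, 0.40, 0.22)
  img <- array(0, c(H, W, 3))
  ys <- seq(1, gh, length.out = H)
  xs <- seq(1, gw, length.out = W)
  y0 <- pmin(floor(ys), gh - 1L); x0 <- pmin(floor(xs), gw - 1L)
  fy <- ys - y0; fx <- xs - x0
  for (ch in 1:3) {
    g <- matrix(stats::runif(gh * gw, -0.12, 0.12), gh, gw)
    v <- g[cbind(rep(y0, W), rep(x0, each = H))] *
      outer(1 - fy, 1 - fx) +
      g[cbind(rep(y0 + 1L, W), rep(x0, each = H))] * outer(fy, 1 - fx) +
      g[cbind(rep(y0, W), rep(x0 + 1L, each = H))] * outer(1 - fy, fx) +
      g[cbind(rep(y0 + 1L, W), rep(x0 + 1L, each = H))] * outer(fy, fx)
    img[, , ch] <- pmin(pmax(base[ch] + v, 0), 1)
  }
  img
}

# separable Gaussian blur
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- dim(img)[1]; W <- dim(img)[2]
  blur1 <- function(m) {
    # replicate-padded 1-D convolution down the rows
    mp <- rbind(m[rep(1, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (t in -r:r) out <- out + k[t + r + 1] *
        mp[(1 + r + t):(nrow(m) + r + t), , drop = FALSE]
    out
  }
  for (ch in 1:3) {
    img[, , ch] <- t(blur1(t(blur1(img[, , ch]))))
  }
  img
}

#' Generate a synthetic camera-trap scene
#'
#' Textured elliptical animals on a procedural vegetation background.
#' Bounding boxes tightly enclose each animal's pre-occlusion pixels
#' (0-based pixel corners, half-open). Occluders are vegetation-colored
#' strips covering `occlusion_frac` of each animal's pixels; blur and the
#' night model are applied to the finished composite.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`[H,W,3]` array in `[0,1]`) and `truths`
#'   (data.frame `x1,y1,x2,y2,class_id`).
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  img <- scene_background(H, W)
  truths <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                       y2 = numeric(), class_id = integer())
  masks <- list()
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (obj in seq_len(spec$n_objects)) {
    placed <- FALSE
    for (try in 1:50) {
      cl <- sample(spec$classes, 1)
      sp <- SPECIES[cl, ]
      b <- stats::runif(1, 0.10, 0.22) * min(H, W)   # semi-minor axis
      a <- b * sp$aspect                              # semi-major axis
      cx <- stats::runif(1, 1, W)
      cy <- stats::runif(1, 1, H)
      th <- stats::runif(1, -0.5, 0.5)
      u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
      v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
      mask <- (u / a)^2 + (v / b)^2 <= 1
      if (sum(mask) < 16) next                        # (nearly) out of frame
      placed <- TRUE
      tex <- 0.5 + 0.5 * sin(sp$tex_freq * u) * cos(sp$tex_freq * v)
      shade <- 0.75 + 0.5 * tex[mask]
      img[, , 1][mask] <- pmin(sp$r * shade, 1)
      img[, , 2][mask] <- pmin(sp$g * shade, 1)
      img[, , 3][mask] <- pmin(sp$b * shade, 1)
      cols <- which(colSums(mask) > 0)
      rows <- which(rowSums(mask) > 0)
      truths <- rbind(truths,
                      data.frame(x1 = min(cols) - 1, y1 = min(rows) - 1,
                                 x2 = max(cols), y2 = max(rows),
                                 class_id = cl))
      masks[[length(masks) + 1]] <- mask
      break
    }
    if (!placed)
      stop("could not place an object inside the frame after 50 tries")
  }
  if (spec$occlusion_frac > 0 && length(masks) > 0) {
    occ_col <- c(0.16, 0.34, 0.12)
    for (mask in masks) {
      tot <- sum(mask)
      csum <- cumsum(colSums(mask))
      ncov <- which(csum >= spec$occlusion_frac * tot)[1]
      if (is.na(ncov) || ncov < 1) next
      cover <- mask & (col(mask) <= ncov)
      ripple <- 0.8 + 0.4 * sin(0.7 * yy[cover])
      img[, , 1][cover] <- pmin(occ_col[1] * ripple, 1)
      img[, , 2][cover] <- pmin(occ_col[2] * ripple, 1)
      img[, , 3][cover] <- pmin(occ_col[3] * ripple, 1)
    }
  }
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$night) {
    img <- img^(1 / 0.3)
    img <- img + array(stats::rnorm(length(img), 0, 10 / 255), dim(img))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, truths = truths)
}

# nearest-neighbour image resize
resize_nearest <- function(img, H2, W2) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ri <- pmin(pmax(round((seq_len(H2) - 0.5) * H / H2 + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(W2) - 0.5) * W / W2 + 0.5), 1), W)
  img[ri, ci, , drop = FALSE]
}

#' Mosaic augmentation
#'
#' With probability `p`, tiles four scenes around a random center of the
#' output canvas, rescaling each scene to its quadrant and clipping boxes
#' to the tiles (boxes with post-clip area below 1 px^2 are dropped). With
#' probability `1 - p` the first scene is returned unchanged.
#'
#' @param scenes list of exactly 4 `list(image, truths)` scenes.
#' @param out_size `c(H, W)` of the mosaic canvas.
#' @param p application probability (the conventional default is 0.5).
#' @param seed RNG seed.
#' @return a `list(image, truths)` scene.
#' @export
mosaic <- function(scenes, out_size = NULL, p = 0.5, seed = 1L) {
  stopifnot(length(scenes) == 4)
  set.seed(seed)
  if (stats::runif(1) >= p) return(scenes[[1]])
  if (is.null(out_size)) out_size <- dim(scenes[[1]]$image)[1:2]
  H <- out_size[1]; W <- out_size[2]
  cyx <- c(round(stats::runif(1, 0.25, 0.75) * H),
           round(stats::runif(1, 0.25, 0.75) * W))
  canvas <- array(0, c(H, W, 3))
  truths <- NULL
  tiles <- list(c(1, cyx[1], 1, cyx[2]),
                c(1, cyx[1], cyx[2] + 1, W),
                c(cyx[1] + 1, H, 1, cyx[2]),
                c(cyx[1] + 1, H, cyx[2] + 1, W))
  for (k in 1:4) {
    t <- tiles[[k]]
    th <- t[2] - t[1] + 1; tw <- t[4] - t[3] + 1
    if (th < 1 || tw < 1) next
    sc <- scenes[[k]]
    sh <- dim(sc$image)[1]; sw <- dim(sc$image)[2]
    canvas[t[1]:t[2], t[3]:t[4], ] <- resize_nearest(sc$image, th, tw)
    if (nrow(sc$truths) > 0) {
      b <- sc$truths
      sy <- th / sh; sx <- tw / sw
      nb <- data.frame(x1 = pmax(b$x1 * sx + t[3] - 1, t[3] - 1),
                       y1 = pmax(b$y1 * sy + t[1] - 1, t[1] - 1),
                       x2 = pmin(b$x2 * sx + t[3] - 1, t[4]),
                       y2 = pmin(b$y2 * sy + t[1] - 1, t[2]),
                       class_id = b$class_id)
      keep <- (nb$x2 - nb$x1) * (nb$y2 - nb$y1) >= 1
      truths <- rbind(truths, nb[keep, , drop = FALSE])
    }
  }
  if (is.null(truths))
    truths <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                         y2 = numeric(), class_id = integer())
  rownames(truths) <- NULL
  list(image = canvas, truths = truths)
}

#' Split an annotation set into train/validation/test
#'
#' Image-level disjoint partition with counts fixed by largest-remainder
#' rounding of the ratios, stratified by each image's class-presence
#' signature (images with the same set of classes are spread
#' proportionally across the splits).
#'
#' @param annset an annotation set (see [read_coco()]).
#' @param ratios positive split weights, default `c(7, 2, 1)`.
#' @param seed RNG seed for the within-stratum shuffle.
#' @return named list of three annotation sets (`train`, `val`, `test`).
#' @export
split_dataset <- function(annset, ratios = c(7, 2, 1), seed = 1L) {
  stopifnot(all(ratios > 0))
  n <- nrow(annset$images)
  if (n < length(ratios)) stop("fewer images than splits")
  set.seed(seed)
  # largest-remainder target counts
  exact <- n * ratios / sum(ratios)
  cnt <- floor(exact)
  rem <- n - sum(cnt)
  if (rem > 0) {
    give <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[give] <- cnt[give] + 1
  }
  sig <- vapply(annset$images$id, function(iid) {
    cls <- sort(unique(annset$annotations$class_id[
      annset$annotations$image_id == iid]))
    paste(cls, collapse = ",")
  }, character(1))
  ord <- unlist(lapply(split(seq_len(n), sig),
                       function(ix) ix[sample.int(length(ix))]),
                use.names = FALSE)
  # greedy quota assignment along the stratified order: each image goes to
  # the split with the largest remaining share, so every stratum is spread
  # close to the ratios while the global counts stay exact
  assign <- integer(n)
  left <- cnt
  for (i in seq_len(n)) {
    k <- which.max(left / ratios)
    assign[ord[i]] <- k
    left[k] <- left[k] - 1
  }
  out <- lapply(seq_along(ratios), function(k) {
    ids <- annset$images$id[assign == k]
    subset_annset(annset, ids)
  })
  names(out) <- c("train", "val", "test")[seq_along(ratios)]
  out
}

subset_annset <- function(annset, image_ids) {
  list(images = annset$images[annset$images$id %in% image_ids, ,
                              drop = FALSE],
       annotations = annset$annotations[
         annset$annotations$image_id %in% image_ids, , drop = FALSE],
       categories = annset$categories)
}

#' Write / read COCO JSON annotations
#'
#' Boxes are stored COCO-style (`[x, y, width, height]`, 0-based) and
#' converted to/from the internal half-open corner form. Category ids are
#' contiguous from 1. Reading validates box geometry and image bounds and
#' reports every offending annotation.
#'
#' @param annset list with `images` (data.frame `id,file_name,height,width`),
#'   `annotations` (data.frame `image_id,class_id,x1,y1,x2,y2`), and
#'   `categories` (data.frame `id,name`).
#' @param path JSON file path.
#' @return `write_coco` returns `path` invisibly; `read_coco` returns an
#'   annotation set.
#' @export
write_coco <- function(annset, path) {
  ann <- annset$annotations
  coco <- list(
    images = lapply(seq_len(nrow(annset$images)), function(i) {
      r <- annset$images[i, ]
      list(id = r$id, file_name = r$file_name, height = r$height,
           width = r$width)
    }),
    annotations = lapply(seq_len(nrow(ann)), function(i) {
      r <- ann[i, ]
      list(id = i, image_id = r$image_id, category_id = r$class_id,
           bbox = c(r$x1, r$y1, r$x2 - r$x1, r$y2 - r$y1),
           area = (r$x2 - r$x1) * (r$y2 - r$y1), iscrowd = 0)
    }),
    categories = lapply(seq_len(nrow(annset$categories)), function(i) {
      r <- annset$categories[i, ]
      list(id = r$id, name = r$name)
    }))
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  coco <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  images <- as.data.frame(coco$images)
  categories <- as.data.frame(coco$categories)
  if (nrow(categories) > 0 &&
      !identical(sort(categories$id), seq_len(nrow(categories))))
    stop("category ids must be contiguous from 1")
  if (length(coco$annotations) == 0 || is.null(coco$annotations) ||
      (is.data.frame(coco$annotations) && nrow(coco$annotations) == 0)) {
    ann <- data.frame(image_id = integer(), class_id = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric())
  } else {
    a <- coco$annotations
    bb <- do.call(rbind, a$bbox)
    ann <- data.frame(image_id = a$image_id, class_id = a$category_id,
                      x1 = bb[, 1], y1 = bb[, 2],
                      x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4])
    bad <- character()
    for (i in seq_len(nrow(ann))) {
      im <- images[images$id == ann$image_id[i], ]
      if (nrow(im) == 0) { bad <- c(bad, sprintf("ann %d: unknown image", i)); next }
      if (ann$x2[i] <= ann$x1[i] || ann$y2[i] <= ann$y1[i])
        bad <- c(bad, sprintf("ann %d: non-positive box", i))
      else if (ann$x1[i] < 0 || ann$y1[i] < 0 ||
               ann$x2[i] > im$width || ann$y2[i] > im$height)
        bad <- c(bad, sprintf("ann %d: box outside image bounds", i))
    }
    if (length(bad) > 0)
      stop("invalid annotations: ", paste(bad, collapse = "; "))
  }
  list(images = images, annotations = ann, categories = categories)
}

#' Export annotations in the YOLO text dialect
#'
#' One `.txt` per image with lines `class cx cy w h` (0-based class ids,
#' coordinates normalized to the image size).
#'
#' @param annset an annotation set.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_yolo <- function(annset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(annset$images))) {
    im <- annset$images[i, ]
    a <- annset$annotations[annset$annotations$image_id == im$id, ,
                            drop = FALSE]
    lines <- character()
    if (nrow(a) > 0) {
      c4 <- box_xyxy_to_cxcywh(as.matrix(a[, c("x1", "y1", "x2", "y2")]))
      lines <- sprintf("%d %.6f %.6f %.6f %.6f", a$class_id - 1L,
                       c4[, 1] / im$width, c4[, 2] / im$height,
                       c4[, 3] / im$width, c4[, 4] / im$height)
    }
    writeLines(lines, file.path(dir, sub("\\.png$", ".txt", im$file_name)))
  }
  invisible(dir)
}
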