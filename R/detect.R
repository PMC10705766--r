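# Anchor-grid detection: decoding raw head outputs into boxes, greedy
# per-class non-maximum suppression, the training loss (complete-IoU box
# term plus binary cross-entropy objectness), target assignment, and the
# SGD training loop.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration
#'
#' Defaults follow the reference training recipe: initial learning rate
#' 0.01, batch size 4, 300 epochs, SGD (momentum 0.937), no pretraining.
#'
#' @param lr Initial learning rate.
#' @param batch_size Images per SGD step.
#' @param epochs Training epochs.
#' @param momentum SGD momentum.
#' @param pretrained Must be `FALSE` (training is always from scratch).
#' @param box_gain,obj_gain,cls_gain Loss-term weights.
#' @param seed Integer seed covering weight init and data order.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.01, batch_size = 4L, epochs = 300L,
                         momentum = 0.937, pretrained = FALSE,
                         box_gain = 0.5, obj_gain = 1, cls_gain = 0.5,
                         seed = 0L) {
  if (isTRUE(pretrained))
    stop("train_config: no pretrained weights exist; training is from scratch")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 pretrained = FALSE, box_gain = box_gain,
                 obj_gain = obj_gain, cls_gain = cls_gain,
                 seed = as.integer(seed)),
            class = "train_config")
}

# reshape one raw head array (gh, gw, 3*(5+nc)) to (gh, gw, 5+nc, 3)
head_split <- function(h, nc) {
  nf <- 5L + nc
  dim(h) <- c(dim(h)[1], dim(h)[2], nf, 3L)
  h
}

#' Decode raw prediction grids into a detection set
#'
#' Per cell and anchor, the box centre is `(2 * sigmoid(t) - 0.5 + cell) *
#' stride` and the extent `(2 * sigmoid(t))^2 * anchor`; the detection score
#' is `sigmoid(objectness) * sigmoid(class score)`.  Entries scoring below
#' `conf_threshold` are removed (order preserving).
#'
#' @param heads List of raw head arrays (`gh x gw x (3*(5+nc))`), one per
#'   scale.
#' @param anchors List of 3x2 anchor matrices (pixels), one per scale.
#' @param strides Integer strides per scale (e.g. 8/16/32).
#' @param input_size Network input resolution (pixels).
#' @param conf_threshold Detection score threshold.
#' @param num_classes Class count.
#' @return A `detection_set` data frame: `class`, `cx`, `cy`, `bw`, `bh`
#'   (normalised), `conf`.
#' @export
decode_predictions <- function(heads, anchors, strides, input_size,
                               conf_threshold = 0.25, num_classes = 1L) {
  out <- NULL
  for (s in seq_along(heads)) {
    h <- heads[[s]]
    nf <- 5L + num_classes
    if (dim(h)[3] != 3L * nf)
      stop("decode_predictions: head ", s, " has ", dim(h)[3],
           " channels; expected ", 3L * nf)
    a <- head_split(h, num_classes)
    gh <- dim(a)[1]; gw <- dim(a)[2]
    ci <- matrix(rep(0:(gh - 1), times = gw), gh, gw)  # row index (y)
    cj <- matrix(rep(0:(gw - 1), each = gh), gh, gw)   # col index (x)
    for (an in 1:3) {
      sx <- sigmoid(a[, , 1, an]); sy <- sigmoid(a[, , 2, an])
      sw <- sigmoid(a[, , 3, an]); sh <- sigmoid(a[, , 4, an])
      obj <- sigmoid(a[, , 5, an])
      cls <- array(sigmoid(a[, , 5 + seq_len(num_classes), an]),
                   dim = c(gh, gw, num_classes))
      best_c <- apply(cls, c(1, 2), which.max)
      best_s <- apply(cls, c(1, 2), max)
      score <- obj * best_s
      keep <- which(score >= conf_threshold)
      if (length(keep) == 0) next
      cxp <- (2 * sx - 0.5 + cj) * strides[s]
      cyp <- (2 * sy - 0.5 + ci) * strides[s]
      bwp <- (2 * sw)^2 * anchors[[s]][an, 1]
      bhp <- (2 * sh)^2 * anchors[[s]][an, 2]
      out <- rbind(out, data.frame(
        class = as.integer(best_c[keep] - 1L),
        cx = cxp[keep] / input_size, cy = cyp[keep] / input_size,
        bw = bwp[keep] / input_size, bh = bhp[keep] / input_size,
        conf = score[keep]))
    }
  }
  if (is.null(out))
    out <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      bw = numeric(0), bh = numeric(0), conf = numeric(0))
  class(out) <- c("detection_set", "data.frame")
  out
}

#' Greedy per-class non-maximum suppression
#'
#' Detections are visited per class in order of descending confidence
#' (stable for ties); each kept detection suppresses all later same-class
#' detections overlapping it at IoU >= `iou_threshold`.
#'
#' @param dets A `detection_set` data frame.
#' @param iou_threshold Suppression threshold in (0, 1).
#' @return The surviving `detection_set`, ordered by descending confidence
#'   within class.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  if (nrow(dets) <= 1) return(dets)
  keep_rows <- integer(0)
  for (cl in sort(unique(dets$class))) {
    rows <- which(dets$class == cl)
    ord <- rows[order(-dets$conf[rows])]
    m <- cbind(dets$cx[ord] - dets$bw[ord] / 2,
               dets$cy[ord] - dets$bh[ord] / 2,
               dets$cx[ord] + dets$bw[ord] / 2,
               dets$cy[ord] + dets$bh[ord] / 2)
    alive <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      keep_rows <- c(keep_rows, ord[i])
      later <- which(alive & seq_along(ord) > i)
      if (length(later) == 0) next
      ious <- iou_one_many(m[i, ], m[later, , drop = FALSE])
      alive[later[ious >= iou_threshold]] <- FALSE
    }
  }
  out <- dets[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- complete-IoU with analytic gradient ----------------------------------
# boxes are c(cx, cy, w, h) in pixels; returns the CIoU value and its
# gradient with respect to the predicted box (alpha treated as constant,
# as usual)
ciou_with_grad <- function(p, g, eps = 1e-9) {
  px1 <- p[1] - p[3] / 2; px2 <- p[1] + p[3] / 2
  py1 <- p[2] - p[4] / 2; py2 <- p[2] + p[4] / 2
  gx1 <- g[1] - g[3] / 2; gx2 <- g[1] + g[3] / 2
  gy1 <- g[2] - g[4] / 2; gy2 <- g[2] + g[4] / 2
  iw <- min(px2, gx2) - max(px1, gx1)
  ih <- min(py2, gy2) - max(py1, gy1)
  inter <- max(0, iw) * max(0, ih)
  union <- p[3] * p[4] + g[3] * g[4] - inter
  iou_v <- inter / (union + eps)
  # d(inter)/d(p): indicator-based piecewise derivatives
  if (iw > 0 && ih > 0) {
    diw_dx <- (px2 < gx2) - (px1 > gx1)
    diw_dw <- 0.5 * ((px2 < gx2) + (px1 > gx1))
    dih_dy <- (py2 < gy2) - (py1 > gy1)
    dih_dh <- 0.5 * ((py2 < gy2) + (py1 > gy1))
    dI <- c(ih * diw_dx, iw * dih_dy, ih * diw_dw, iw * dih_dh)
  } else dI <- c(0, 0, 0, 0)
  dU <- c(-dI[1], -dI[2], p[4] - dI[3], p[3] - dI[4])
  dIoU <- (dI * union - inter * dU) / (union + eps)^2
  # centre-distance penalty rho^2 / c^2 over the enclosing box diagonal
  cw <- max(px2, gx2) - min(px1, gx1)
  chh <- max(py2, gy2) - min(py1, gy1)
  c2 <- cw^2 + chh^2 + eps
  rho2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  dcw <- c((px2 > gx2) - (px1 < gx1), 0,
           0.5 * ((px2 > gx2) + (px1 < gx1)), 0)
  dch <- c(0, (py2 > gy2) - (py1 < gy1), 0,
           0.5 * ((py2 > gy2) + (py1 < gy1)))
  dc2 <- 2 * cw * dcw + 2 * chh * dch
  drho2 <- c(2 * (p[1] - g[1]), 2 * (p[2] - g[2]), 0, 0)
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  # aspect-ratio consistency term
  k <- 4 / pi^2
  delta <- atan(g[3] / g[4]) - atan(p[3] / p[4])
  v <- k * delta^2
  denom <- p[3]^2 + p[4]^2 + eps
  dv <- c(0, 0, 2 * k * delta * (-p[4] / denom),
          2 * k * delta * (p[3] / denom))
  alpha <- v / (1 - iou_v + v + eps)
  list(value = iou_v - rho2 / c2 - alpha * v,
       grad = dIoU - dpen - alpha * dv,
       parts = c(iou = iou_v, pen = rho2 / c2, v = v, alpha = alpha))
}

# ---- target assignment and loss -------------------------------------------

# anchors pass when the box/anchor extent ratio is below 4 in both axes;
# boxes no anchor accepts anywhere fall back to the best-ratio anchor.
# besides the centre cell, the two laterally nearest cells are assigned as
# well (the decode offset spans -0.5..1.5 cells, so they can represent the
# same centre), which triples the positive examples
build_targets <- function(boxes, anchors, strides, input_size,
                          ratio_thresh = 4) {
  if (nrow(boxes) == 0) return(NULL)
  tgts <- NULL
  best <- NULL
  for (b in seq_len(nrow(boxes))) {
    wpx <- boxes$bw[b] * input_size; hpx <- boxes$bh[b] * input_size
    cxp <- boxes$cx[b] * input_size; cyp <- boxes$cy[b] * input_size
    any_hit <- FALSE
    best_r <- Inf
    for (s in seq_along(strides)) {
      gw <- input_size %/% strides[s]
      gx <- cxp / strides[s]; gy <- cyp / strides[s]
      cj <- min(max(floor(gx), 0), gw - 1)
      ci <- min(max(floor(gy), 0), gw - 1)
      cj2 <- cj + if (gx - cj < 0.5) -1L else 1L
      ci2 <- ci + if (gy - ci < 0.5) -1L else 1L
      cells <- data.frame(ci = c(ci, ci, ci2), cj = c(cj, cj2, cj))
      cells <- cells[cells$ci >= 0 & cells$ci < gw &
                       cells$cj >= 0 & cells$cj < gw, ]
      for (an in 1:3) {
        r <- max(wpx / anchors[[s]][an, 1], anchors[[s]][an, 1] / wpx,
                 hpx / anchors[[s]][an, 2], anchors[[s]][an, 2] / hpx)
        rows <- data.frame(scale = s, anchor = an, ci = cells$ci,
                           cj = cells$cj, box = b)
        if (r < ratio_thresh) {
          tgts <- rbind(tgts, rows)
          any_hit <- TRUE
        }
        if (r < best_r) { best_r <- r; best <- rows[1, ] }
      }
    }
    if (!any_hit) tgts <- rbind(tgts, best)
  }
  tgts
}

# loss + head gradients for one image; boxes normalised cxcywh + class
compute_loss <- function(heads, boxes, anchors, strides, input_size,
                         num_classes = 1L, box_gain = 0.5, obj_gain = 1,
                         cls_gain = 0.5, balance = c(4, 1, 0.4)) {
  nf <- 5L + num_classes
  grads <- lapply(heads, function(h) array(0, dim = dim(h)))
  tgts <- build_targets(boxes, anchors, strides, input_size)
  lbox <- 0; lcls <- 0; lobj <- 0
  npos <- if (is.null(tgts)) 0L else nrow(tgts)
  tobj <- lapply(heads, function(h)
    array(0, dim = c(dim(h)[1], dim(h)[2], 3)))
  if (npos > 0) {
    for (t in seq_len(npos)) {
      s <- tgts$scale[t]; an <- tgts$anchor[t]
      i <- tgts$ci[t] + 1L; j <- tgts$cj[t] + 1L
      b <- boxes[tgts$box[t], ]
      ch0 <- (an - 1L) * nf
      logit <- heads[[s]][i, j, ch0 + 1:4]
      sg <- sigmoid(logit)
      pred <- c((2 * sg[1] - 0.5 + (j - 1L)) * strides[s],
                (2 * sg[2] - 0.5 + (i - 1L)) * strides[s],
                (2 * sg[3])^2 * anchors[[s]][an, 1],
                (2 * sg[4])^2 * anchors[[s]][an, 2])
      gt <- c(b$cx, b$cy, b$bw, b$bh) * input_size
      ci_res <- ciou_with_grad(pred, gt)
      lbox <- lbox + (1 - ci_res$value)
      # chain rule through the decode: d pred / d logit
      dpd <- c(2 * sg[1] * (1 - sg[1]) * strides[s],
               2 * sg[2] * (1 - sg[2]) * strides[s],
               8 * sg[3] * (1 - sg[3]) * sg[3] * anchors[[s]][an, 1],
               8 * sg[4] * (1 - sg[4]) * sg[4] * anchors[[s]][an, 2])
      grads[[s]][i, j, ch0 + 1:4] <- grads[[s]][i, j, ch0 + 1:4] -
        ci_res$grad * dpd
      tobj[[s]][i, j, an] <- 1   # hard objectness target
      if (num_classes >= 1L) {
        clogit <- heads[[s]][i, j, ch0 + 5L + seq_len(num_classes)]
        cs <- sigmoid(clogit)
        tcls <- as.numeric(seq_len(num_classes) == (b$class + 1L))
        lcls <- lcls + sum(bce(cs, tcls)) / num_classes
        grads[[s]][i, j, ch0 + 5L + seq_len(num_classes)] <-
          grads[[s]][i, j, ch0 + 5L + seq_len(num_classes)] +
          cls_gain * (cs - tcls) / (num_classes * max(1L, npos))
      }
    }
    for (s in seq_along(grads))
      grads[[s]] <- grads[[s]] * (box_gain / max(1L, npos))
  }
  # objectness: balanced binary cross-entropy -- positives and negatives
  # are each averaged within their own group, so the handful of assigned
  # cells is not drowned out by the thousands of empty ones
  for (s in seq_along(heads)) {
    for (an in 1:3) {
      ch0 <- (an - 1L) * nf
      so <- sigmoid(heads[[s]][, , ch0 + 5L])
      tg <- tobj[[s]][, , an]
      pos <- tg > 0
      n_pos <- sum(pos); n_neg <- length(tg) - n_pos
      e <- bce(so, tg)
      wgt <- array(1 / max(1L, n_neg), dim = dim(tg))
      if (n_pos > 0) wgt[pos] <- 1 / n_pos
      lobj <- lobj + balance[s] * sum(e * wgt)
      grads[[s]][, , ch0 + 5L] <- grads[[s]][, , ch0 + 5L] +
        obj_gain * balance[s] * (so - tg) * wgt
    }
  }
  loss <- box_gain * lbox / max(1L, npos) + obj_gain * lobj +
    cls_gain * lcls / max(1L, npos)
  list(loss = loss, box = lbox / max(1L, npos), obj = lobj,
       cls = lcls / max(1L, npos), grads = grads, n_assigned = npos)
}

bce <- function(p, t, eps = 1e-9) {
  -(t * log(p + eps) + (1 - t) * log(1 - p + eps))
}

#' Train the detector
#'
#' Standard single-stage training: complete-IoU box loss and binary
#' cross-entropy objectness (class loss only for multi-class heads),
#' multi-anchor assignment, SGD with momentum, fully seeded.
#'
#' @param images Training images: a list of [annotated_image()] objects or
#'   a `dataset_index` (its train split is loaded).
#' @param net A compiled `gd_network` whose input size matches the images.
#' @param cfg A [train_config()].
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return The trained network, with a `log` data frame (epoch, loss and
#'   its box/objectness components) attached as `net$log`.
#' @export
train_detector <- function(images, net, cfg = train_config(),
                           verbose = 0L) {
  if (inherits(images, "dataset_index"))
    images <- load_dataset(images$dir, "train")
  stopifnot(length(images) > 0)
  if (length(images) == 0) stop("train_detector: empty training split")
  spec <- net$spec
  S <- spec$input_size
  xs <- lapply(images, function(im) {
    d <- dim(im$pixels)
    if (d[1] != S || d[2] != S)
      stop("train_detector: image is ", d[1], "x", d[2],
           " but the network input is ", S, "x", S)
    im$pixels / 255
  })
  bxs <- lapply(images, function(im) im$boxes)
  set.seed(cfg$seed)
  n <- length(xs)
  log <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_box <- 0; ep_obj <- 0
    bstart <- seq(1, n, by = cfg$batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1, n)]
      net_zero_grads(net)
      for (ii in idx) {
        heads <- network_forward(net, xs[[ii]])
        l <- compute_loss(heads, bxs[[ii]], spec$anchors, spec$strides, S,
                          spec$num_classes, box_gain = cfg$box_gain,
                          obj_gain = cfg$obj_gain, cls_gain = cfg$cls_gain)
        network_backward(net, lapply(l$grads, function(g) g / length(idx)))
        ep_loss <- ep_loss + l$loss; ep_box <- ep_box + l$box
        ep_obj <- ep_obj + l$obj
      }
      net_sgd_step(net, cfg$lr, cfg$momentum)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 box = ep_box / n, obj = ep_obj / n))
    if (verbose > 0 && ep %% verbose == 0)
      cat(sprintf("epoch %4d  loss %.4f  box %.4f  obj %.4f\n", ep,
                  ep_loss / n, ep_box / n, ep_obj / n))
  }
  net$log <- log
  invisible(net)
}

#' Run detection on one image
#'
#' @param net A trained `gd_network`.
#' @param img An [annotated_image()] matching the network input size.
#' @param conf Confidence threshold (default 0.25).
#' @param iou NMS IoU threshold (default 0.45).
#' @return A `detection_set` data frame.
#' @export
detect_objects <- function(net, img, conf = 0.25, iou = 0.45) {
  spec <- net$spec
  heads <- network_forward(net, img$pixels / 255)
  dets <- decode_predictions(heads, spec$anchors, spec$strides,
                             spec$input_size, conf_threshold = conf,
                             num_classes = spec$num_classes)
  nms(dets, iou)
}

#' Evaluate a detector on a set of annotated images
#'
#' @param net A trained `gd_network`.
#' @param images List of [annotated_image()] objects.
#' @param conf,iou Inference thresholds (see [detect_objects()]).
#' @param iou_match Matching threshold for metrics (default 0.5).
#' @return A `metrics_report` (see [metrics()]).
#' @export
evaluate_detector <- function(net, images, conf = 0.25, iou = 0.45,
                              iou_match = 0.5) {
  ms <- lapply(images, function(im)
    match_detections(detect_objects(net, im, conf, iou), im$boxes,
                     iou_match))
  metrics(ms)
}
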