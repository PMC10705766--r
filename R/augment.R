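# Annotation-preserving augmentation: synthetic fog, rain and snow overlays,
# mirroring, rotation-scaling, and a dataset-level driver that augments a
# seeded random fraction of the images.

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fog parameters
#'
#' @param L Fog brightness, intensity units 0-255.
#' @param theta0 Fog concentration; must be `<= 0` for a fogging effect
#'   (positive values are clamped to 0 with a warning).
#' @return A `fog_params` list.
#' @export
fog_params <- function(L = 200, theta0 = -0.05) {
  if (L < 0 || L > 255) stop("fog_params: L must be in [0, 255]")
  if (theta0 > 0) {
    warning("fog_params: theta0 > 0 gives no fogging effect; clamping to 0")
    theta0 <- 0
  }
  structure(list(L = L, theta0 = theta0), class = "fog_params")
}

#' Add synthetic fog to an image
#'
#' For each pixel at (0-based) row `i`, column `j` of an `h x w` image with
#' `size = max(h, w)`, the fog thickness is
#' `d = -0.04 * sqrt((i - h/2)^2 + (j - w/2)^2) + size` and the transmission
#' `t_d = exp(theta0 * d)`; the pixel becomes the convex combination
#' `pixel * t_d + L * (1 - t_d)` (strongest fog at the image centre, where
#' `d` is largest).  Boxes are unchanged; the result is rounded half-up to
#' integer intensities and clipped to `[0, 255]`.
#'
#' @param img An [annotated_image()].
#' @param params A [fog_params()].
#' @return The fogged `annotated_image`.
#' @examples
#' img <- annotated_image(array(100, dim = c(4, 4, 3)))
#' foggy <- add_fog(img, fog_params(L = 200, theta0 = -0.25))
#' foggy$pixels[3, 3, 1]  # 163: e^-1 * 100 + (1 - e^-1) * 200, rounded
#' @export
add_fog <- function(img, params = fog_params()) {
  stopifnot(inherits(img, "annotated_image"), inherits(params, "fog_params"))
  d <- dim(img$pixels)
  h <- d[1]; w <- d[2]
  size <- max(h, w)
  iv <- (seq_len(h) - 1) - h / 2
  jv <- (seq_len(w) - 1) - w / 2
  dist <- sqrt(outer(iv^2, jv^2, "+"))
  td <- exp(params$theta0 * (-0.04 * dist + size))
  px <- img$pixels * as.vector(td) + params$L * as.vector(1 - td)
  img$pixels <- clip255(round_half_up(px))
  img
}

#' Rain / snow parameters
#'
#' The paper-specified pipeline (random noise, affine stretch, Gaussian
#' blur, rotation, additive overlay) with configurable free parameters.
#' Presets: rain is sparse thin streaks at a steep angle
#' (density 300 particles/megapixel, stretch 8, angle -75 deg, sigma 0.7);
#' snow is rounder and slower (density 200, stretch 2, angle -5 deg,
#' sigma 1.5).
#'
#' @param kind `"rain"` or `"snow"`.
#' @param density Particles per megapixel.
#' @param length Affine stretch factor applied to the noise (dimensionless).
#' @param angle Rotation of the noise layer, degrees.
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @param intensity Particle brightness, 0-255.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return A `precip_params` list.
#' @export
precip_params <- function(kind = c("rain", "snow"), density = NULL,
                          length = NULL, angle = NULL, blur_sigma = NULL,
                          intensity = 200, seed = 0L) {
  kind <- match.arg(kind)
  def <- if (kind == "rain")
    list(density = 300, length = 8, angle = -75, blur_sigma = 0.7)
  else
    list(density = 200, length = 2, angle = -5, blur_sigma = 1.5)
  p <- list(kind = kind,
            density = if (is.null(density)) def$density else density,
            length = if (is.null(length)) def$length else length,
            angle = if (is.null(angle)) def$angle else angle,
            blur_sigma = if (is.null(blur_sigma)) def$blur_sigma
                         else blur_sigma,
            intensity = intensity, seed = as.integer(seed))
  if (p$density < 0 || p$blur_sigma < 0)
    stop("precip_params: density and blur_sigma must be >= 0")
  structure(p, class = "precip_params")
}

#' Overlay synthetic rain or snow
#'
#' Sparse random noise is sampled at the configured density (seeded), shaped
#' into streaks/flakes by an affine stretch and a Gaussian blur, rotated to
#' the fall angle, and additively overlaid onto the image (clipped to
#' `[0, 255]`).  Boxes are unchanged.
#'
#' @param img An [annotated_image()].
#' @param params A [precip_params()].
#' @return The augmented `annotated_image`.
#' @export
add_precipitation <- function(img, params = precip_params("rain")) {
  stopifnot(inherits(img, "annotated_image"),
            inherits(params, "precip_params"))
  d <- dim(img$pixels)
  h <- d[1]; w <- d[2]
  n <- ceiling(params$density * h * w / 1e6)   # >= 1 particle if density > 0
  if (n <= 0) return(img)
  layer <- with_seed(params$seed, {
    lay <- matrix(0, h, w)
    pos <- sample.int(h * w, min(n, h * w))
    lay[pos] <- params$intensity
    lay
  })
  if (params$length > 1) layer <- streak_rows(layer, params$length)
  if (params$blur_sigma > 0) layer <- gauss_blur_mat(layer,
                                                     params$blur_sigma)
  if (params$angle != 0) layer <- rotate_mat(layer, params$angle, fill = 0)
  img$pixels <- clip255(img$pixels + as.vector(layer))
  img
}

# affine elongation of each particle along the vertical axis: the layer is
# dilated by a 1 x `length` structuring line (shifted maximum), turning
# point noise into streaks `length` pixels long
streak_rows <- function(mat, len) {
  h <- nrow(mat)
  len <- max(1L, as.integer(round(len)))
  off <- seq_len(len) - 1L - (len - 1L) %/% 2L
  out <- mat
  for (t in off) {
    if (t == 0L) next
    shifted <- matrix(0, h, ncol(mat))
    src <- seq_len(h) - t
    ok <- src >= 1L & src <= h
    shifted[ok, ] <- mat[src[ok], , drop = FALSE]
    out <- pmax(out, shifted)
  }
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with zero padding
gauss_blur_mat <- function(mat, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(mat); w <- ncol(mat)
  pad <- matrix(0, h + 2L * r, w)
  pad[r + seq_len(h), ] <- mat
  out <- matrix(0, h, w)
  for (t in seq_along(k)) out <- out + k[t] * pad[(t - 1L) + seq_len(h), ]
  pad2 <- matrix(0, h, w + 2L * r)
  pad2[, r + seq_len(w)] <- out
  out2 <- matrix(0, h, w)
  for (t in seq_along(k)) out2 <- out2 + k[t] * pad2[, (t - 1L) + seq_len(w)]
  out2
}

#' Standalone Gaussian blur augmentation
#'
#' @param img An [annotated_image()].
#' @param sigma Blur standard deviation, pixels.
#' @return The blurred `annotated_image` (boxes unchanged).
#' @export
gaussian_blur <- function(img, sigma = 1.5) {
  stopifnot(inherits(img, "annotated_image"))
  for (ch in 1:3)
    img$pixels[, , ch] <- gauss_blur_mat(img$pixels[, , ch], sigma)
  img$pixels <- clip255(img$pixels)
  img
}

# ---- geometric transforms --------------------------------------------------

# forward point map in normalised coordinates: rotate by `angle` degrees
# about the centre (a +90 rotation sends (x, y) to (y, 1 - x)), then scale
map_points <- function(xy, angle, scale) {
  th <- angle * pi / 180
  dx <- xy[, 1] - 0.5; dy <- xy[, 2] - 0.5
  cbind(0.5 + scale * (cos(th) * dx + sin(th) * dy),
        0.5 + scale * (-sin(th) * dx + cos(th) * dy))
}

# nearest-neighbour inverse-mapped rotation+scale of one matrix
rotate_mat <- function(mat, angle, scale = 1, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  th <- angle * pi / 180
  jj <- rep(seq_len(w), each = h)
  ii <- rep(seq_len(h), times = w)
  # output pixel centres in normalised coords
  x <- (jj - 0.5) / w; y <- (ii - 0.5) / h
  dx <- (x - 0.5) / scale; dy <- (y - 0.5) / scale
  # inverse rotation
  sx <- 0.5 + cos(th) * dx - sin(th) * dy
  sy <- 0.5 + sin(th) * dx + cos(th) * dy
  sj <- round_half_up(sx * w + 0.5)
  si <- round_half_up(sy * h + 0.5)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- rep(fill, h * w)
  out[ok] <- mat[cbind(si[ok], sj[ok])]
  matrix(out, h, w)
}

#' Mirror an image and its boxes
#'
#' @param img An [annotated_image()].
#' @param mode `"horizontal"` (left-right, `cx <- 1 - cx`), `"vertical"`
#'   (top-bottom, `cy <- 1 - cy`) or `"diagonal"` (both).
#' @return The mirrored `annotated_image`.  Applying the same mirror twice
#'   restores the original exactly.
#' @export
mirror <- function(img, mode = c("horizontal", "vertical", "diagonal")) {
  stopifnot(inherits(img, "annotated_image"))
  mode <- match.arg(mode)
  d <- dim(img$pixels)
  if (mode %in% c("horizontal", "diagonal")) {
    img$pixels <- img$pixels[, d[2]:1, , drop = FALSE]
    img$boxes$cx <- 1 - img$boxes$cx
  }
  if (mode %in% c("vertical", "diagonal")) {
    img$pixels <- img$pixels[d[1]:1, , , drop = FALSE]
    img$boxes$cy <- 1 - img$boxes$cy
  }
  img
}

#' Rotate and scale an image with box co-transformation
#'
#' The image is rotated about its centre by `angle` degrees and scaled by
#' `scale` (nearest-neighbour resampling, out-of-frame pixels filled with
#' neutral grey).  Each box is mapped as the axis-aligned envelope of its
#' four transformed corners, clipped to the frame; boxes retaining less
#' than 10% of their transformed area after clipping are dropped.
#'
#' @param img An [annotated_image()].
#' @param angle Rotation angle, degrees (positive sends (x,y) to (y,1-x)
#'   at 90).
#' @param scale Scale factor (> 0).
#' @param fill Fill intensity for out-of-frame pixels.
#' @return The transformed `annotated_image`.
#' @export
rotate_scale <- function(img, angle, scale = 1, fill = 114) {
  stopifnot(inherits(img, "annotated_image"))
  if (scale <= 0) stop("rotate_scale: scale must be > 0")
  if (angle == 0 && scale == 1) return(img)
  for (ch in 1:3)
    img$pixels[, , ch] <- rotate_mat(img$pixels[, , ch], angle, scale, fill)
  img$boxes <- transform_boxes(img$boxes, angle, scale)
  img
}

transform_boxes <- function(boxes, angle, scale, min_keep = 0.1) {
  if (nrow(boxes) == 0) return(boxes)
  out <- boxes[0, ]
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    corners <- cbind(b$cx + c(-1, 1, 1, -1) * b$bw / 2,
                     b$cy + c(-1, -1, 1, 1) * b$bh / 2)
    tc <- map_points(corners, angle, scale)
    x1 <- min(tc[, 1]); x2 <- max(tc[, 1])
    y1 <- min(tc[, 2]); y2 <- max(tc[, 2])
    full_area <- (x2 - x1) * (y2 - y1)
    cx1 <- clip01(x1); cx2 <- clip01(x2)
    cy1 <- clip01(y1); cy2 <- clip01(y2)
    clip_area <- max(0, cx2 - cx1) * max(0, cy2 - cy1)
    if (full_area <= 0 || clip_area < min_keep * full_area) next
    out <- rbind(out, data.frame(class = b$class, cx = (cx1 + cx2) / 2,
                                 cy = (cy1 + cy2) / 2, bw = cx2 - cx1,
                                 bh = cy2 - cy1))
  }
  out
}

#' Augment a seeded random fraction of a dataset
#'
#' A seeded random subset of `floor(fraction * N)` images each receives one
#' uniformly chosen augmentation from the menu (three mirrorings,
#' rotation-scaling, fog, rain, snow).  Originals are replaced by default
#' (dataset size preserved) or kept alongside.
#'
#' @param dataset List of [annotated_image()] objects.
#' @param fraction Proportion of images to augment, in `[0, 1]`
#'   (default 0.5).
#' @param seed Integer seed; the same seed reproduces the augmented set
#'   exactly.
#' @param keep_originals If `TRUE`, augmented copies are appended instead of
#'   replacing the originals.
#' @return The augmented list of images.
#' @export
augment_dataset <- function(dataset, fraction = 0.5, seed = 0L,
                            keep_originals = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_aug <- floor(fraction * length(dataset))
  if (n_aug == 0) return(dataset)
  ops <- c("mirror_h", "mirror_v", "mirror_d", "rotate_scale", "fog",
           "rain", "snow")
  plan <- with_seed(seed, {
    idx <- sample.int(length(dataset), n_aug)
    list(idx = idx,
         op = sample(ops, n_aug, replace = TRUE),
         angle = stats::runif(n_aug, -30, 30),
         zoom = stats::runif(n_aug, 0.8, 1.2),
         fogL = stats::runif(n_aug, 180, 230),
         fogth = stats::runif(n_aug, -0.08, -0.03),
         pseed = sample.int(1e6, n_aug))
  })
  aug <- vector("list", n_aug)
  for (t in seq_len(n_aug)) {
    im <- dataset[[plan$idx[t]]]
    aug[[t]] <- switch(plan$op[t],
      mirror_h = mirror(im, "horizontal"),
      mirror_v = mirror(im, "vertical"),
      mirror_d = mirror(im, "diagonal"),
      rotate_scale = rotate_scale(im, plan$angle[t], plan$zoom[t]),
      fog = add_fog(im, fog_params(plan$fogL[t], plan$fogth[t])),
      rain = add_precipitation(im, precip_params("rain",
                                                 seed = plan$pseed[t])),
      snow = add_precipitation(im, precip_params("snow",
                                                 seed = plan$pseed[t])))
  }
  if (keep_originals) {
    c(dataset, aug)
  } else {
    dataset[plan$idx] <- aug
    dataset
  }
}
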