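# Seeded synthetic barn scenes: textured pen floor, ellipse-bodied sheep
# with head blobs, and "aggression" events rendered as two sheep whose head
# blobs collide along a shared axis; each event is annotated with one box
# of the single class "aggression" covering the contact pair.

#' Scene generation parameters
#'
#' @param image_size Square image side, pixels (>= 64).
#' @param n_sheep Number of sheep in the pen.
#' @param n_aggression Number of head-contact pairs (each consumes two
#'   sheep; `2 * n_aggression <= n_sheep`).
#' @param clutter Background texture level in `[0, 1]`.
#' @param lighting `"day"` or `"dim"` (dim scenes are darkened and
#'   desaturated, mimicking non-daytime recordings).
#' @param seed Integer seed; identical parameters and seed give an
#'   identical scene.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = 320L, n_sheep = 8L, n_aggression = 1L,
                         clutter = 0.3, lighting = c("day", "dim"),
                         seed = 0L) {
  lighting <- match.arg(lighting)
  image_size <- as.integer(image_size)
  n_sheep <- as.integer(n_sheep); n_aggression <- as.integer(n_aggression)
  if (image_size < 64L) stop("scene_params: image_size must be >= 64")
  if (2L * n_aggression > n_sheep)
    stop("scene_params: need 2 * n_aggression <= n_sheep")
  if (clutter < 0 || clutter > 1) stop("scene_params: clutter in [0, 1]")
  structure(list(image_size = image_size, n_sheep = n_sheep,
                 n_aggression = n_aggression, clutter = clutter,
                 lighting = lighting, seed = as.integer(seed)),
            class = "scene_params")
}

#' Generate one synthetic barn scene
#'
#' Renders a textured pen background and `n_sheep` sheep (light ellipse
#' body plus darker head blob at the body tip).  `n_aggression` pairs are
#' placed head-to-head along a shared axis so the head blobs collide; each
#' pair produces one ground-truth box (class 0, "aggression") spanning the
#' two animals.  Remaining sheep are placed with non-overlapping poses.
#'
#' @param params A [scene_params()].
#' @return An [annotated_image()].
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, render_scene(params))
}

render_scene <- function(params) {
  S <- params$image_size
  px <- scene_background(S, params$clutter)
  a0 <- S * 0.055                      # nominal body semi-major axis
  boxes <- NULL
  centers <- matrix(0, 0, 2)
  place_ok <- function(cx, cy, margin) {
    if (cx < margin || cx > S - margin || cy < margin || cy > S - margin)
      return(FALSE)
    nrow(centers) == 0 ||
      all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) > 2.2 * a0)
  }
  # aggression pairs first (they need the most room)
  for (p in seq_len(params$n_aggression)) {
    placed <- FALSE
    for (try in 1:200) {
      phi <- stats::runif(1, 0, 2 * pi)
      a <- a0 * stats::runif(1, 0.9, 1.1)
      hr <- 0.5 * 0.6 * a              # head radius
      off <- a + 0.2 * hr              # body centre to head centre
      gap <- off + 0.8 * hr            # body centre to contact point
      mx <- stats::runif(1, 2.5 * a0, S - 2.5 * a0)
      my <- stats::runif(1, 2.5 * a0, S - 2.5 * a0)
      u <- c(cos(phi), sin(phi))
      c1 <- c(mx, my) - gap * u
      c2 <- c(mx, my) + gap * u
      if (place_ok(c1[1], c1[2], 1.3 * a0) &&
          place_ok(c2[1], c2[2], 1.3 * a0)) {
        px <- draw_sheep(px, c1[1], c1[2], phi, a)
        px <- draw_sheep(px, c2[1], c2[2], phi + pi, a)
        centers <- rbind(centers, c1, c2)
        ext <- a + 0.6 * a             # body + head reach
        x1 <- min(c1[1], c2[1]) - ext; x2 <- max(c1[1], c2[1]) + ext
        y1 <- min(c1[2], c2[2]) - ext; y2 <- max(c1[2], c2[2]) + ext
        x1 <- max(x1, 0); y1 <- max(y1, 0)
        x2 <- min(x2, S); y2 <- min(y2, S)
        boxes <- rbind(boxes,
                       data.frame(class = 0L, cx = (x1 + x2) / 2 / S,
                                  cy = (y1 + y2) / 2 / S,
                                  bw = (x2 - x1) / S, bh = (y2 - y1) / S))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("generate_scene: could not place aggression pair after 200 tries")
  }
  # bystander sheep
  for (k in seq_len(params$n_sheep - 2L * params$n_aggression)) {
    for (try in 1:200) {
      cx <- stats::runif(1, 1.5 * a0, S - 1.5 * a0)
      cy <- stats::runif(1, 1.5 * a0, S - 1.5 * a0)
      if (place_ok(cx, cy, 1.3 * a0)) {
        phi <- stats::runif(1, 0, 2 * pi)
        px <- draw_sheep(px, cx, cy, phi, a0 * stats::runif(1, 0.9, 1.1))
        centers <- rbind(centers, c(cx, cy))
        break
      }
      if (try == 200)
        stop("generate_scene: could not place sheep after 200 tries")
    }
  }
  if (params$lighting == "dim") {
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    for (ch in 1:3) px[, , ch] <- 0.45 * (0.5 * px[, , ch] + 0.5 * gray)
  }
  annotated_image(clip255(round_half_up(px)), boxes)
}

scene_background <- function(S, clutter) {
  base <- c(128, 117, 100)             # trodden straw / packed earth
  coarse_n <- max(4L, S %/% 16L)
  coarse <- matrix(stats::rnorm(coarse_n^2), coarse_n, coarse_n)
  rep_f <- ceiling(S / coarse_n)
  coarse_up <- kronecker(coarse, matrix(1, rep_f, rep_f))[1:S, 1:S]
  fine <- matrix(stats::rnorm(S * S), S, S)
  tex <- clutter * (30 * coarse_up + 8 * fine)
  px <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) px[, , ch] <- base[ch] + tex
  px
}

# body: ellipse with semi-axes (a, 0.6a) at orientation phi;
# head: darker disc of radius 0.3a just beyond the body tip
draw_sheep <- function(px, cx, cy, phi, a) {
  S <- dim(px)[1]
  b <- 0.6 * a
  hr <- 0.5 * b
  hx <- cx + (a + 0.2 * hr) * cos(phi)
  hy <- cy + (a + 0.2 * hr) * sin(phi)
  reach <- ceiling(a + 2 * hr + 2)
  i1 <- max(1, floor(min(cy, hy) - reach)); i2 <- min(S, ceiling(max(cy, hy) + reach))
  j1 <- max(1, floor(min(cx, hx) - reach)); j2 <- min(S, ceiling(max(cx, hx) + reach))
  ii <- i1:i2; jj <- j1:j2
  X <- matrix(rep(jj, each = length(ii)), length(ii))
  Y <- matrix(rep(ii, times = length(jj)), length(ii))
  dx <- X - cx; dy <- Y - cy
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  body <- (xr / a)^2 + (yr / b)^2 <= 1
  head <- (X - hx)^2 + (Y - hy)^2 <= hr^2
  fleece <- 215 + 12 * stats::rnorm(1)
  wool_tex <- matrix(stats::rnorm(length(ii) * length(jj), sd = 6),
                     length(ii))
  for (ch in 1:3) {
    tone <- fleece * c(1, 0.98, 0.94)[ch]
    sub <- px[ii, jj, ch]
    sub[body] <- tone + wool_tex[body]
    sub[head] <- 85 * c(1, 0.95, 0.9)[ch]
    px[ii, jj, ch] <- sub
  }
  px
}

#' Largest-remainder split of n items by ratio
#'
#' Floor shares are assigned first; leftover items go to the splits with the
#' largest fractional remainders, ties broken in split order.
#'
#' @param n Total item count.
#' @param ratios Positive split weights (e.g. `c(6, 2, 2)`).
#' @return Integer vector of split sizes summing to `n`.
#' @examples
#' split_counts(3218, c(6, 2, 2))  # 1931 644 643
#' @export
split_counts <- function(n, ratios = c(6, 2, 2)) {
  stopifnot(all(ratios > 0))
  exact <- n * ratios / sum(ratios)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic detection dataset on disk
#'
#' Writes `images/{train,val,test}/*.png` and co-named
#' `labels/{split}/*.txt` YOLO label files plus a `manifest.yaml`.  The
#' split follows a seeded shuffle and a contiguous largest-remainder
#' partition at the given ratios; a fraction of scenes (default 5%) uses
#' dim lighting.
#'
#' @param n_images Number of scenes.
#' @param dir Output directory.
#' @param ratios Train/val/test weights (default 6:2:2).
#' @param image_size Scene size in pixels.
#' @param n_sheep_range,n_aggression_range Inclusive integer ranges sampled
#'   per scene.
#' @param clutter_range Range of background texture levels.
#' @param dim_fraction Probability a scene is rendered in dim lighting.
#' @param seed Integer seed for the whole dataset.
#' @return A `dataset_index`: per-split file tables, the manifest, and the
#'   output directory.
#' @export
generate_dataset <- function(n_images, dir, ratios = c(6, 2, 2),
                             image_size = 320L,
                             n_sheep_range = c(4L, 10L),
                             n_aggression_range = c(0L, 2L),
                             clutter_range = c(0.1, 0.5),
                             dim_fraction = 0.05, seed = 0L) {
  splits <- c("train", "val", "test")
  for (s in splits) {
    dir.create(file.path(dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  sizes <- split_counts(n_images, ratios)
  assign_split <- rep(splits, times = sizes)
  plan <- with_seed(seed, {
    ord <- sample.int(n_images)
    list(ord = ord,
         n_sheep = sample(n_sheep_range[1]:n_sheep_range[2], n_images,
                          replace = TRUE),
         dim = stats::runif(n_images) < dim_fraction,
         clutter = stats::runif(n_images, clutter_range[1],
                                clutter_range[2]),
         n_agg = sample(n_aggression_range[1]:n_aggression_range[2],
                        n_images, replace = TRUE),
         seeds = sample.int(.Machine$integer.max - 1L, n_images))
  })
  split_of <- character(n_images)
  split_of[plan$ord] <- assign_split
  index <- list(train = NULL, val = NULL, test = NULL)
  n_boxes <- 0; box_areas <- numeric(0); checksum <- 0
  for (i in seq_len(n_images)) {
    n_agg <- min(plan$n_agg[i], plan$n_sheep[i] %/% 2L)
    sp <- scene_params(image_size = image_size, n_sheep = plan$n_sheep[i],
                       n_aggression = n_agg, clutter = plan$clutter[i],
                       lighting = if (plan$dim[i]) "dim" else "day",
                       seed = plan$seeds[i])
    img <- generate_scene(sp)
    s <- split_of[i]
    stem <- sprintf("img_%05d", i)
    ipath <- file.path(dir, "images", s, paste0(stem, ".png"))
    lpath <- file.path(dir, "labels", s, paste0(stem, ".txt"))
    write_image(img, ipath, lpath)
    index[[s]] <- rbind(index[[s]],
                        data.frame(image = ipath, label = lpath,
                                   n_boxes = nrow(img$boxes)))
    n_boxes <- n_boxes + nrow(img$boxes)
    box_areas <- c(box_areas, img$boxes$bw * img$boxes$bh)
    checksum <- (checksum + sum(img$pixels)) %% 2^31
  }
  manifest <- list(n_images = n_images, seed = seed, ratios = ratios,
                   split_sizes = stats::setNames(as.list(sizes), splits),
                   image_size = image_size, classes = list("aggression"),
                   n_boxes = n_boxes,
                   box_area_mean = if (n_boxes > 0) mean(box_areas) else 0,
                   box_area_range = if (n_boxes > 0) range(box_areas)
                                    else c(0, 0),
                   dim_fraction = dim_fraction,
                   checksum = checksum)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  structure(list(dir = dir, splits = index, manifest = manifest),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %s: train=%d val=%d test=%d (%d boxes)\n",
              x$dir, nrow(x$splits$train), nrow(x$splits$val),
              nrow(x$splits$test), x$manifest$n_boxes))
  invisible(x)
}

#' Load a dataset split into memory
#'
#' @param dir Dataset directory as written by [generate_dataset()].
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List of [annotated_image()] objects.
#' @export
load_dataset <- function(dir, split = "train") {
  ipaths <- sort(list.files(file.path(dir, "images", split),
                            pattern = "\\.png$", full.names = TRUE))
  lapply(ipaths, function(p) {
    lp <- file.path(dir, "labels", split,
                    sub("\\.png$", ".txt", basename(p)))
    read_image(p, lp)
  })
}
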