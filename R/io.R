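# Image and annotation I/O: 8-bit RGB rasters as H x W x 3 arrays with
# values in 0..255, YOLO-format label files ("class cx cy w h" per line,
# normalised coordinates), and PNG read/write.

#' An image with normalised bounding-box annotations
#'
#' @param pixels Numeric array `H x W x 3`, intensities 0-255.
#' @param boxes Data frame with columns `class` (0-based integer), `cx`,
#'   `cy`, `bw`, `bh`, all normalised to `[0, 1]`.  `NULL` means no boxes.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, boxes = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (is.null(boxes))
    boxes <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                        bw = numeric(0), bh = numeric(0))
  boxes <- as.data.frame(boxes)
  stopifnot(all(c("class", "cx", "cy", "bw", "bh") %in% names(boxes)))
  if (nrow(boxes) > 0) {
    ok <- boxes$cx >= 0 & boxes$cx <= 1 & boxes$cy >= 0 & boxes$cy <= 1 &
      boxes$bw > 0 & boxes$bw <= 1 & boxes$bh > 0 & boxes$bh <= 1
    if (!all(ok)) stop("annotated_image: boxes must be normalised to [0,1] ",
                       "with positive extents")
  }
  structure(list(pixels = pixels, boxes = boxes), class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image> %dx%d px, %d box(es)\n", d[2], d[1],
              nrow(x$boxes)))
  invisible(x)
}

#' Display an annotated image with its boxes
#'
#' @param x An `annotated_image`.
#' @param box_col Box outline colour.
#' @param ... Ignored.
#' @export
plot.annotated_image <- function(x, box_col = "red", ...) {
  d <- dim(x$pixels)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = d[1] / d[2])
  graphics::rasterImage(x$pixels / 255, 0, 0, 1, 1)
  if (nrow(x$boxes) > 0) {
    for (i in seq_len(nrow(x$boxes))) {
      b <- x$boxes[i, ]
      graphics::rect(b$cx - b$bw / 2, 1 - (b$cy + b$bh / 2),
                     b$cx + b$bw / 2, 1 - (b$cy - b$bh / 2),
                     border = box_col, lwd = 2)
    }
  }
  invisible(x)
}

#' Read an image file into an annotated_image
#'
#' @param path PNG file path.
#' @param label_path Optional YOLO label file; defaults to the co-located
#'   `.txt` of the same stem, read if it exists.
#' @return An `annotated_image`.
#' @export
read_image <- function(path, label_path = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (is.null(label_path))
    label_path <- sub("\\.png$", ".txt", path, ignore.case = TRUE)
  boxes <- if (file.exists(label_path)) read_yolo_labels(label_path) else NULL
  annotated_image(round(px * 255), boxes)
}

#' Write an annotated_image to PNG (+ YOLO label file)
#'
#' @param img An `annotated_image`.
#' @param path Output PNG path.
#' @param label_path Output label path (`NULL`: co-located `.txt`;
#'   `NA`: skip).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, label_path = NULL) {
  stopifnot(inherits(img, "annotated_image"))
  png::writePNG(pmin(pmax(img$pixels, 0), 255) / 255, path)
  if (is.null(label_path))
    label_path <- sub("\\.png$", ".txt", path, ignore.case = TRUE)
  if (!is.na(label_path)) write_yolo_labels(img$boxes, label_path)
  invisible(path)
}

#' Read a YOLO-format label file
#'
#' One line per box: `class cx cy w h`, whitespace separated, normalised
#' coordinates, 0-based integer class.
#'
#' @param path Label file path.
#' @return Data frame with columns `class`, `cx`, `cy`, `bw`, `bh` (and
#'   `conf` if the file carries a sixth column).
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      bw = numeric(0), bh = numeric(0)))
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                                  as.numeric))
  out <- data.frame(class = as.integer(fields[, 1]), cx = fields[, 2],
                    cy = fields[, 3], bw = fields[, 4], bh = fields[, 5])
  if (ncol(fields) >= 6) out$conf <- fields[, 6]
  out
}

#' Write boxes to a YOLO-format label file
#'
#' @param boxes Data frame with `class`, `cx`, `cy`, `bw`, `bh` and
#'   optionally `conf`.
#' @param path Output path; an empty file is written for zero boxes.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (nrow(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fmt <- function(v) formatC(v, format = "fg", digits = 8)
  lines <- sprintf("%d %s %s %s %s", as.integer(boxes$class), fmt(boxes$cx),
                   fmt(boxes$cy), fmt(boxes$bw), fmt(boxes$bh))
  if (!is.null(boxes$conf))
    lines <- paste(lines, fmt(boxes$conf))
  writeLines(lines, path)
  invisible(path)
}

clip01 <- function(v) pmin(pmax(v, 0), 1)
clip255 <- function(v) pmin(pmax(v, 0), 255)

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(v) floor(v + 0.5)
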