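# Shared fixtures and independent oracles for the test suite.

rand_map <- function(c, h, w = h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(c * h * w), dim = c(h, w, c))
}

flat_image <- function(value = 100, size = 4) {
  annotated_image(array(value, dim = c(size, size, 3)))
}

# independent finite-difference gradient
num_grad <- function(f, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    x2 <- x
    x2[i] <- x2[i] + h
    (f(x2) - f(x)) / h
  }, numeric(1))
}

# independent output-size oracle (standard convolution arithmetic)
expect_conv_size <- function(len, k, stride, pad) {
  floor((len + 2 * pad - k) / stride) + 1
}

# reshape/transpose channel-shuffle oracle, independent of the package's
# permutation construction
shuffle_oracle <- function(channels, groups) {
  m <- matrix(channels, ncol = groups)   # columns = groups (row-major fill)
  as.vector(t(m))
}

# corner-transform oracle for mirroring: reflect both corners, re-derive
# the box from the corner envelope
mirror_box_oracle <- function(b, mode) {
  x1 <- b$cx - b$bw / 2; x2 <- b$cx + b$bw / 2
  y1 <- b$cy - b$bh / 2; y2 <- b$cy + b$bh / 2
  if (mode %in% c("horizontal", "diagonal")) {
    xs <- 1 - c(x1, x2); x1 <- min(xs); x2 <- max(xs)
  }
  if (mode %in% c("vertical", "diagonal")) {
    ys <- 1 - c(y1, y2); y1 <- min(ys); y2 <- max(ys)
  }
  data.frame(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
             bw = x2 - x1, bh = y2 - y1)
}

# brute-force all-points average precision: evaluate precision/recall at
# every distinct confidence threshold and integrate the running-maximum
# precision over the recall steps
ap_brute_force <- function(conf, tp, n_truth) {
  if (n_truth == 0 || length(conf) == 0) return(0)
  thresholds <- sort(unique(conf), decreasing = TRUE)
  pr <- t(vapply(thresholds, function(th) {
    sel <- conf >= th
    c(r = sum(tp[sel]) / n_truth,
      p = sum(tp[sel]) / sum(sel))
  }, c(r = 0, p = 0)))
  ap <- 0
  prev_r <- 0
  for (i in seq_len(nrow(pr))) {
    # precision envelope at this recall: best precision at recall >= r
    p_env <- max(pr[pr[, "r"] >= pr[i, "r"], "p"])
    ap <- ap + (pr[i, "r"] - prev_r) * p_env
    prev_r <- pr[i, "r"]
  }
  unname(ap)
}

# random small detection problem for metric tests
random_detections <- function(seed, n_truth_max = 8, n_pred_max = 12) {
  set.seed(seed)
  nt <- sample.int(n_truth_max, 1)
  truths <- data.frame(class = sample(0:1, nt, replace = TRUE),
                       cx = runif(nt, 0.2, 0.8), cy = runif(nt, 0.2, 0.8),
                       bw = runif(nt, 0.05, 0.2), bh = runif(nt, 0.05, 0.2))
  np <- sample.int(n_pred_max, 1)
  base <- truths[sample.int(nt, np, replace = TRUE), ]
  preds <- data.frame(class = base$class,
                      cx = pmin(pmax(base$cx + rnorm(np, 0, 0.05), 0.05), 0.95),
                      cy = pmin(pmax(base$cy + rnorm(np, 0, 0.05), 0.05), 0.95),
                      bw = base$bw * runif(np, 0.7, 1.3),
                      bh = base$bh * runif(np, 0.7, 1.3),
                      conf = runif(np))
  list(preds = preds, truths = truths)
}
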