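test_that("the default network places blocks per the structural rules", {
  ns <- ghost_network_spec(input_size = 160, width_multiple = 0.25)
  expect_true(validate_network_spec(ns))
  for (ly in ns$layers) {
    if (ly$kind == "inverted_ghost_bottleneck")
      expect_equal(ly$section, "backbone")
    if (ly$section == "neck" &&
        grepl("ghost_conv", ly$kind))
      expect_equal(ly$kind, "cs_ghost_conv")
  }
  expect_length(ns$head_ids, 3)
  expect_true(all(vapply(ns$anchors, nrow, 0L) == 3L))
  # a hand-built violation is rejected
  bad <- ns
  i <- which(vapply(bad$layers, function(l) l$section == "neck" &&
                      l$kind == "cs_ghost_conv", logical(1)))[1]
  bad$layers[[i]]$kind <- "inverted_ghost_bottleneck"
  expect_error(validate_network_spec(bad), "backbone")
})

test_that("ablation variants build and the plain-ghost baseline has no shuffles", {
  for (v in c("ghost_ghost", "pw_pw", "cs_cs", "cs_pw", "pw_cs"))
    expect_s3_class(ghost_network_spec(input_size = 160,
                                       width_multiple = 0.25, variant = v),
                    "network_spec")
  base <- ghost_network_spec(input_size = 160, width_multiple = 0.25,
                             variant = "ghost_ghost")
  backbone <- Filter(function(l) l$section == "backbone", base$layers)
  expect_false(any(vapply(backbone, function(l)
    grepl("cs_|inverted", l$kind), logical(1))))
})

test_that("forward pass yields three grids at strides 8/16/32", {
  for (S in c(160, 320)) {
    net <- compile_network(ghost_network_spec(input_size = S,
                                              width_multiple = 0.25),
                           seed = 1)
    x <- array(runif(S * S * 3), dim = c(S, S, 3))
    heads <- network_forward(net, x)
    expect_length(heads, 3)
    for (k in 1:3)
      expect_equal(dim(heads[[k]]), c(S / c(8, 16, 32)[k],
                                      S / c(8, 16, 32)[k], 18))
  }
})

test_that("the ghost backbone undercuts the reference backbone parameter count", {
  improved <- backbone_params(ghost_network_spec(input_size = 640))
  reference <- backbone_params(cspdarknet_small_spec())
  expect_lt(improved, reference)
})

test_that("a single crafted logit peak decodes into its own cell", {
  ns <- ghost_network_spec(input_size = 160, width_multiple = 0.25)
  heads <- list(array(-10, dim = c(20, 20, 18)),
                array(-10, dim = c(10, 10, 18)),
                array(-10, dim = c(5, 5, 18)))
  heads[[1]][5, 7, 1:6] <- c(0, 0, 0, 0, 8, 8)   # cell ci=4, cj=6, anchor 1
  dets <- decode_predictions(heads, ns$anchors, ns$strides, 160, 0.25)
  expect_equal(nrow(dets), 1)
  # zero offset logits decode to the cell centre
  expect_equal(dets$cx, (0.5 + 6) * 8 / 160)
  expect_equal(dets$cy, (0.5 + 4) * 8 / 160)
  # zero size logits decode to the anchor prior
  expect_equal(dets$bw, ns$anchors[[1]][1, 1] / 160)
  expect_gt(dets$conf, 0.99)
  # an impossible threshold empties the set
  none <- decode_predictions(heads, ns$anchors, ns$strides, 160, 1.0 + 1e-9)
  expect_equal(nrow(none), 0)
  # thresholding removes exactly the below-threshold entries
  all_dets <- decode_predictions(heads, ns$anchors, ns$strides, 160, 0)
  expect_equal(nrow(all_dets), 20 * 20 * 3 + 10 * 10 * 3 + 5 * 5 * 3)
  expect_true(all(all_dets$conf[all_dets$conf >= 0.25] %in% dets$conf))
  expect_error(decode_predictions(list(heads[[1]][, , 1:6]), ns$anchors,
                                  ns$strides, 160), "channels")
})

test_that("NMS keeps the strongest box and respects the IoU threshold", {
  one <- data.frame(class = 0L, cx = 0.5, cy = 0.5, bw = 0.2, bh = 0.2,
                    conf = 0.9)
  expect_equal(nms(one, 0.45), one)
  dup <- rbind(one, transform(one, conf = 0.8))
  kept <- nms(dup, 0.45)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)
  # IoU 1/3 under threshold 0.45: both survive
  pair <- rbind(one, data.frame(class = 0L, cx = 0.6, cy = 0.5, bw = 0.2,
                                bh = 0.2, conf = 0.8))
  expect_equal(iou(as.numeric(pair[1, 2:5]), as.numeric(pair[2, 2:5])),
               1 / 3)
  expect_equal(nrow(nms(pair, 0.45)), 2)
  # different classes never suppress each other
  cross <- rbind(one, transform(one, class = 1L, conf = 0.8))
  expect_equal(nrow(nms(cross, 0.45)), 2)
  expect_error(nms(one, 1.5), "iou_threshold")
})

test_that("NMS output is stable for equal-confidence disjoint boxes", {
  boxes <- data.frame(class = 0L,
                      cx = c(0.2, 0.5, 0.8), cy = 0.5,
                      bw = 0.1, bh = 0.1, conf = 0.7)
  a <- nms(boxes, 0.45)
  b <- nms(boxes[3:1, ], 0.45)
  expect_equal(nrow(a), 3)
  expect_equal(sort(a$cx), sort(b$cx))
})

test_that("complete-IoU value and gradient are consistent", {
  set.seed(55)
  expect_equal(ciou_with_grad(c(50, 50, 20, 10), c(50, 50, 20, 10))$value,
               1, tolerance = 1e-6)
  for (rep in 1:40) {
    p <- c(runif(2, 20, 80), runif(2, 5, 50))
    g <- c(runif(2, 20, 80), runif(2, 5, 50))
    res <- ciou_with_grad(p, g)
    expect_lte(res$value, 1)
    expect_gte(res$value, -1)
    # finite differences with alpha frozen at its analytic value
    a0 <- res$parts["alpha"]
    f <- function(q) {
      r <- ciou_with_grad(q, g)
      unname(r$parts["iou"] - r$parts["pen"] - a0 * r$parts["v"])
    }
    nm <- vapply(1:4, function(i) {
      h <- 1e-6
      q <- p; q[i] <- q[i] + h
      (f(q) - f(p)) / h
    }, numeric(1))
    expect_equal(res$grad, nm, tolerance = 1e-3)
  }
})

test_that("target assignment respects anchor ratios with a best-anchor fallback", {
  ns <- ghost_network_spec(input_size = 160, width_multiple = 0.25)
  boxes <- data.frame(class = 0L, cx = 0.5, cy = 0.5, bw = 0.25, bh = 0.25)
  tg <- ghostdet:::build_targets(boxes, ns$anchors, ns$strides, 160)
  expect_true(nrow(tg) >= 1)
  # every assigned anchor passes the ratio-4 test (or is the single fallback)
  for (r in seq_len(nrow(tg))) {
    an <- ns$anchors[[tg$scale[r]]][tg$anchor[r], ]
    ratio <- max(40 / an[1], an[1] / 40, 40 / an[2], an[2] / 40)
    if (nrow(tg) > 1) expect_lt(ratio, 4)
  }
  # a tiny box no anchor accepts still gets one assignment
  tiny <- data.frame(class = 0L, cx = 0.5, cy = 0.5, bw = 0.004, bh = 0.004)
  tg2 <- ghostdet:::build_targets(tiny, ns$anchors, ns$strides, 160)
  expect_equal(nrow(tg2), 1)
})

test_that("training config defaults follow the reference recipe", {
  cfg <- train_config()
  expect_equal(cfg$lr, 0.01)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$epochs, 300L)
  expect_false(cfg$pretrained)
  expect_error(train_config(pretrained = TRUE), "scratch")
})

test_that("training is deterministic and reduces the loss on a tiny set", {
  imgs <- lapply(1:2, function(i)
    generate_scene(scene_params(image_size = 96, n_sheep = 3,
                                n_aggression = 1, seed = 400 + i)))
  run <- function() {
    net <- compile_network(ghost_network_spec(input_size = 96,
                                              width_multiple = 0.25),
                           seed = 3)
    train_detector(imgs, net, train_config(epochs = 20, batch_size = 2L,
                                           seed = 3))
    net
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$log$loss[1], n2$log$loss[1])
  expect_identical(n1$log, n2$log)
  expect_lt(n1$log$loss[20], 0.5 * n1$log$loss[1])
  # the empty-split contract
  expect_error(train_detector(list(), n1), "length")
})

test_that("block and network specs round-trip through YAML configs", {
  bs <- block_spec("ghost_conv", conv_spec(16, 32, k = 3, d = 3, s = 2,
                                           stride = 2))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_spec_config(bs, p)
  back <- read_spec_config(p)
  expect_equal(back, bs)
  ns <- ghost_network_spec(input_size = 320, width_multiple = 0.5,
                           variant = "pw_cs")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_spec_config(ns, p2)
  ns2 <- read_spec_config(p2)
  expect_equal(count_costs(ns2)$macs, count_costs(ns)$macs)
  expect_equal(ns2$variant, ns$variant)
  expect_equal(ns2$anchors, ns$anchors)
})
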