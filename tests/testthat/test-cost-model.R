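test_that("ordinary convolution worked example is exact", {
  rep <- count_costs(block_spec("conv", conv_spec(3, 16, k = 3, d = 1,
                                                  s = 1, stride = 2)),
                     feature_map_spec(3, 640, 640))
  expect_equal(rep$params, 432)
  expect_equal(rep$macs, 432 * 320 * 320)
})

test_that("ghost convolution cost decomposition matches brute-force counting", {
  fm <- feature_map_spec(64, 32, 32)
  ghost <- count_costs(block_spec("ghost_conv",
                                  conv_spec(64, 128, k = 3, d = 3, s = 2)),
                       fm)
  ordinary <- count_costs(block_spec("conv",
                                     conv_spec(64, 128, k = 3, d = 1, s = 1)),
                          fm)
  expect_equal(ghost$macs, 64 * 64 * 9 * 1024 + 64 * 9 * 1024)  # 38,338,560
  expect_equal(ordinary$macs, 75497472)
  expect_equal(ordinary$macs / ghost$macs, 128 / 65)
})

test_that("closed-form ratios equal exhaustive counting over the spec grid", {
  n_checked <- 0
  for (c in c(4, 8, 16, 64)) for (n in c(4, 8, 16, 64))
    for (k in c(1, 3, 5)) for (d in c(1, 3, 5)) for (s in c(1, 2, 4)) {
      if (n %% s != 0) next
      fm <- feature_map_spec(c, 8, 8)
      ghost <- count_costs(block_spec("ghost_conv",
                                      conv_spec(c, n, k = k, d = d, s = s)),
                           fm)
      ordinary <- count_costs(block_spec("conv",
                                         conv_spec(c, n, k = k, d = 1,
                                                   s = 1)),
                              fm)
      expect_identical(speedup_ratio(c, n, k, d, s),
                       ordinary$macs / ghost$macs)
      expect_identical(compression_ratio(c, n, k, d, s),
                       ordinary$params / ghost$params)
      n_checked <- n_checked + 1
    }
  expect_gte(n_checked, 100)
})

test_that("speedup and compression ratios: identity, worked value, large-c limit", {
  expect_identical(speedup_ratio(64, 128, 3, 3, 1), 1)
  expect_identical(compression_ratio(64, 128, 3, 3, 1), 1)
  expect_equal(speedup_ratio(64, 128, 3, 3, 2), 2 * 64 / 65)
  expect_equal(compression_ratio(64, 128, 3, 3, 2), 128 / 65)
  # k = d, wide layer: both ratios approach s = 2 ("save half")
  expect_equal(speedup_ratio(4096, 4096, 3, 3, 2), 2, tolerance = 1e-3)
  expect_equal(compression_ratio(4096, 4096, 3, 3, 2), 2, tolerance = 1e-3)
  expect_error(speedup_ratio(8, 15, 3, 3, 2), "divide")
})

test_that("instrumented forward pass and enumeration agree with count_costs", {
  specs <- list(
    list("conv", conv_spec(3, 8, k = 3, d = 1, s = 1, stride = 2), 3),
    list("conv", conv_spec(8, 8, k = 1, d = 1, s = 1), 8),
    list("conv", conv_spec(4, 6, k = 5, d = 1, s = 1), 4),
    list("dw_conv", conv_spec(8, 8, k = 3, d = 3, s = 1), 8),
    list("dw_conv", conv_spec(4, 4, k = 5, d = 5, s = 1, stride = 2), 4),
    list("dw_conv", conv_spec(16, 16, k = 3, d = 3, s = 1), 16),
    list("ghost_conv", conv_spec(8, 16, k = 3, d = 3, s = 2), 8),
    list("ghost_conv", conv_spec(16, 32, k = 1, d = 3, s = 2), 16),
    list("ghost_conv", conv_spec(8, 16, k = 3, d = 5, s = 4, stride = 2), 8),
    list("pw_ghost_conv", conv_spec(8, 16, k = 3, d = 3, s = 2), 8),
    list("pw_ghost_conv", conv_spec(16, 16, k = 3, d = 3, s = 2), 16),
    list("pw_ghost_conv", conv_spec(8, 32, k = 3, d = 3, s = 2, stride = 2), 8),
    list("cs_ghost_conv", conv_spec(8, 16, k = 3, d = 3, s = 2), 8),
    list("cs_ghost_conv", conv_spec(16, 32, k = 3, d = 3, s = 2), 16),
    list("cs_ghost_conv", conv_spec(8, 16, k = 1, d = 3, s = 2), 8))
  for (sp in specs) {
    bs <- block_spec(sp[[1]], sp[[2]])
    fm <- feature_map_spec(sp[[3]], 8, 8)
    closed <- count_costs(bs, fm)$macs
    expect_identical(count_macs_enum(bs, fm), closed)
    mod <- switch(sp[[1]],
      conv = conv_block(sp[[2]]$c, sp[[2]]$n, sp[[2]]$k, sp[[2]]$stride),
      dw_conv = dw_conv_block(sp[[2]]$c, sp[[2]]$k, sp[[2]]$stride),
      ghost_conv = ghost_conv(sp[[2]], variant = "plain"),
      pw_ghost_conv = ghost_conv(sp[[2]], variant = "pw"),
      cs_ghost_conv = ghost_conv(sp[[2]], variant = "cs"))
    expect_identical(count_macs_forward(mod, fm), closed)
  }
})

test_that("bottleneck costs agree across all three counters", {
  for (style in c("ghost", "cs_ghost", "inverted")) {
    kind <- switch(style, ghost = "ghost_bottleneck",
                   cs_ghost = "cs_ghost_bottleneck",
                   inverted = "inverted_ghost_bottleneck")
    for (cfg in list(c(8, 8, 1), c(8, 16, 2), c(16, 16, 1))) {
      bs <- block_spec(kind, conv_spec(cfg[1], cfg[2], k = 1, d = 3, s = 2,
                                       stride = cfg[3]))
      fm <- feature_map_spec(cfg[1], 8, 8)
      closed <- count_costs(bs, fm)$macs
      expect_identical(count_macs_enum(bs, fm), closed)
      mod <- ghost_bottleneck(cfg[1], cfg[2], cfg[3], style = style)
      expect_identical(count_macs_forward(mod, fm), closed)
    }
  }
})

test_that("channel shuffle and the cs variant add exactly zero cost", {
  fm <- feature_map_spec(16, 8, 8)
  shuf <- count_costs(block_spec("channel_shuffle",
                                 conv_spec(16, 16, k = 1, d = 1, s = 1)),
                      fm)
  expect_identical(shuf$macs, 0)
  expect_identical(shuf$params, 0)
  for (cfg in list(c(8, 16), c(16, 32), c(32, 32))) {
    sp <- conv_spec(cfg[1], cfg[2], k = 3, d = 3, s = 2)
    fm <- feature_map_spec(cfg[1], 8, 8)
    a <- count_costs(block_spec("ghost_conv", sp), fm)
    b <- count_costs(block_spec("cs_ghost_conv", sp), fm)
    expect_identical(a$macs, b$macs)
    expect_identical(a$params, b$params)
  }
})

test_that("compress-first bottleneck cost is unchanged by the shuffle but inverted is wider", {
  fm <- feature_map_spec(64, 32, 32)
  g <- count_costs(block_spec("ghost_bottleneck",
                              conv_spec(64, 64, k = 1, d = 3, s = 2)), fm)
  cs <- count_costs(block_spec("cs_ghost_bottleneck",
                               conv_spec(64, 64, k = 1, d = 3, s = 2)), fm)
  inv <- count_costs(block_spec("inverted_ghost_bottleneck",
                                conv_spec(64, 64, k = 1, d = 3, s = 2)), fm)
  expect_identical(g$macs, cs$macs)
  expect_identical(g$params, cs$params)
  # 2c vs c/2 mid-width: the inverted block must cost strictly more
  expect_gt(inv$macs, g$macs)
  expect_gt(inv$params, g$params)
})

test_that("network cost reports are additive and audit totals match", {
  ns <- ghost_network_spec(input_size = 160, width_multiple = 0.25)
  rep <- count_costs(ns)
  expect_equal(rep$macs, sum(rep$breakdown$macs))
  expect_equal(rep$params, sum(rep$breakdown$params))
  out <- capture.output(bd <- cost_audit(ns))
  expect_equal(attr(bd, "totals")$macs, rep$macs)
  expect_true(any(grepl("TOTAL", out)))
  # FLOPs convention doubles MACs
  expect_equal(count_costs(ns, flops = TRUE)$macs, 2 * rep$macs)
})

test_that("swapping every ghost conv for its shuffle variant leaves network cost unchanged", {
  a <- count_costs(ghost_network_spec(input_size = 160,
                                      width_multiple = 0.25,
                                      variant = "ghost_ghost"))
  b <- count_costs(ghost_network_spec(input_size = 160,
                                      width_multiple = 0.25,
                                      variant = "cs_cs"))
  expect_identical(a$macs, b$macs)
  expect_identical(a$params, b$params)
})

test_that("ghost cost is below ordinary-conv cost for s > 1, equal at s = 1", {
  for (c in c(4, 8, 16)) for (k in c(1, 3)) for (s in c(1, 2, 4)) {
    n <- 16
    fm <- feature_map_spec(c, 8, 8)
    ghost <- count_costs(block_spec("ghost_conv",
                                    conv_spec(c, n, k = k, d = k, s = s)),
                         fm)$macs
    ordinary <- count_costs(block_spec("conv",
                                       conv_spec(c, n, k = k, d = 1, s = 1)),
                            fm)$macs
    if (s == 1) expect_identical(ghost, ordinary)
    else expect_lt(ghost, ordinary)
  }
})
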