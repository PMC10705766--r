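test_that("conv_spec validates its invariants", {
  expect_s3_class(conv_spec(16, 32, k = 3, d = 3, s = 2), "conv_spec")
  expect_error(conv_spec(16, 30, s = 4), "must divide")
  expect_error(conv_spec(0, 8), ">= 1")
  expect_error(feature_map_spec(0, 4), ">= 1")
})

test_that("block output shapes follow stride/padding arithmetic on a grid", {
  for (c in c(2, 4, 8)) for (hw in c(4, 8)) for (stride in c(1, 2)) {
    x <- rand_map(c, hw, seed = c * 100 + hw + stride)
    n <- 2 * c
    for (variant in c("plain", "pw", "cs")) {
      m <- ghost_conv(conv_spec(c, n, k = 3, d = 3, s = 2, stride = stride),
                      variant = variant)
      y <- block_forward(m, x)
      expect_equal(dim(y), c(expect_conv_size(hw, 3, stride, 1),
                             expect_conv_size(hw, 3, stride, 1), n))
    }
    for (style in c("ghost", "cs_ghost", "inverted")) {
      b <- ghost_bottleneck(c, n, stride, style = style)
      yb <- mod_forward(b, x)
      ho <- expect_conv_size(hw, 3, stride, 1)
      expect_equal(dim(yb), c(ho, ho, n))
    }
    d <- dw_conv_block(c, k = 3, stride = stride)
    expect_equal(dim(mod_forward(d, x))[3], c)
  }
})

test_that("ghost convolution with s = 1 degenerates to an ordinary conv", {
  sp <- conv_spec(8, 16, k = 3, d = 3, s = 1, stride = 1)
  m <- ghost_conv(sp, act = FALSE, norm = "identity")
  x <- rand_map(8, 6, seed = 42)
  ref <- prim_conv(8, 16, 3, 1)
  ref$W <- m$primary$W
  expect_equal(block_forward(m, x), prim_forward(ref, x))
})

test_that("channel shuffle is the deterministic group interleave", {
  x <- array(seq_len(4), dim = c(1, 1, 4))
  expect_equal(as.vector(channel_shuffle(x, 2)),
               shuffle_oracle(1:4, 2))
  expect_equal(as.vector(channel_shuffle(x, 2)), c(1, 3, 2, 4))
  expect_identical(channel_shuffle(x, 1), x)
  expect_error(channel_shuffle(x, 3), "divide")
})

test_that("channel shuffle is a channel bijection preserving pixel values", {
  for (c in c(4, 8, 12)) for (g in c(2, 4)) {
    x <- rand_map(c, 5, seed = c + g)
    y <- channel_shuffle(x, g)
    # multiset of channel planes is preserved
    sx <- apply(x, 3, sum); sy <- apply(y, 3, sum)
    expect_equal(sort(sx), sort(sy))
    # applying the inverse permutation restores the input exactly
    perm <- as.vector(t(matrix(seq_len(c), ncol = g)))
    expect_identical(y[, , order(perm), drop = FALSE], x)
  }
})

test_that("channel-shuffle ghost output is a permutation of ghost output", {
  sp <- conv_spec(8, 16, k = 3, d = 3, s = 2)
  m_plain <- ghost_conv(sp, variant = "plain")
  m_cs <- ghost_conv(sp, variant = "cs")
  # share all weights
  m_cs$primary$W <- m_plain$primary$W
  m_cs$cheap$W <- m_plain$cheap$W
  m_cs$bn$gamma <- m_plain$bn$gamma; m_cs$bn$beta <- m_plain$bn$beta
  x <- rand_map(8, 6, seed = 9)
  y_plain <- block_forward(m_plain, x)
  y_cs <- block_forward(m_cs, x)
  expect_equal(y_cs, y_plain[, , m_cs$shuffle$perm])
  # same multiset of channel planes
  expect_equal(sort(apply(y_cs, 3, sum)), sort(apply(y_plain, 3, sum)))
})

test_that("pointwise variant composes ghost then 1x1 conv", {
  sp <- conv_spec(8, 16, k = 3, d = 3, s = 2)
  m <- ghost_conv(sp, variant = "pw")
  x <- rand_map(8, 6, seed = 11)
  expect_equal(dim(block_forward(m, x)), c(6, 6, 16))
  expect_equal(m$pw$k, 1L)   # kernel footprint is exactly 1x1
  d <- describe(m, feature_map_spec(8, 6, 6))
  d0 <- describe(ghost_conv(sp, variant = "plain"), feature_map_spec(8, 6, 6))
  expect_equal(d$cost$macs - d0$cost$macs, 16^2 * 6 * 6)
  expect_equal(d$cost$params - d0$cost$params, 16^2)
})

test_that("depthwise and pointwise parameter counts are c*k^2 and c*n", {
  dw <- count_costs(block_spec("dw_conv", conv_spec(64, 64, k = 3, d = 3,
                                                    s = 1)),
                    feature_map_spec(64, 8, 8))
  expect_equal(dw$params, 64 * 9)
  pw <- count_costs(block_spec("pointwise_conv",
                               conv_spec(32, 32, k = 1, d = 1, s = 1)),
                    feature_map_spec(32, 16, 16))
  expect_equal(pw$params, 32 * 32)
})

test_that("bottlenecks with zero weights and bypassed norm are identities", {
  for (style in c("ghost", "cs_ghost", "inverted")) {
    b <- ghost_bottleneck(8, 8, 1, style = style, norm = "identity")
    zero_weights(b)
    x <- rand_map(8, 6, seed = 5)
    expect_identical(mod_forward(b, x), x)
  }
})

test_that("bottleneck mid-widths: halved for compress-first, doubled for inverted", {
  expect_equal(ghost_bottleneck(64, 64, 1, style = "ghost")$mid, 32)
  expect_equal(ghost_bottleneck(64, 64, 1, style = "cs_ghost")$mid, 32)
  expect_equal(ghost_bottleneck(64, 64, 1, style = "inverted")$mid, 128)
  # odd widths stay total functions
  expect_equal(ghost_bottleneck(3, 4, 1, style = "ghost")$mid, 1)
  expect_s3_class(block_spec("inverted_ghost_bottleneck"), "block_spec")
  expect_equal(block_spec("inverted_ghost_bottleneck")$expansion_factor, 2.0)
  expect_equal(block_spec("ghost_bottleneck")$expansion_factor, 0.5)
})

test_that("stride-2 bottlenecks halve the spatial size", {
  b <- ghost_bottleneck(8, 8, 2, style = "ghost")
  x <- rand_map(8, 8, seed = 6)
  expect_equal(dim(mod_forward(b, x)), c(4, 4, 8))
})

test_that("backward passes agree with finite differences", {
  set.seed(31)
  cases <- list(
    conv_block(3, 5, k = 3, stride = 2),
    dw_conv_block(4, k = 3, stride = 1),
    ghost_conv(conv_spec(4, 8, k = 3, d = 3, s = 2), variant = "cs"),
    ghost_conv(conv_spec(4, 8, k = 3, d = 3, s = 2), variant = "pw"),
    ghost_bottleneck(4, 6, 2, style = "inverted")
  )
  cins <- c(3, 4, 4, 4, 4)
  for (i in seq_along(cases)) {
    m <- cases[[i]]
    x <- rand_map(cins[i], 6, seed = 60 + i)
    y <- mod_forward(m, x)
    r <- array(rnorm(length(y)), dim = dim(y))
    g <- mod_backward(m, r)
    f <- function(xx) sum(mod_forward(m, xx) * r)
    idx <- seq_len(min(8, length(x)))
    expect_equal(g[idx], num_grad(f, x, idx, h = 1e-5), tolerance = 1e-3)
  }
})

test_that("block mismatch and misconfiguration raise contract errors", {
  m <- ghost_conv(conv_spec(8, 16))
  expect_error(block_forward(m, rand_map(4, 6)))       # channel mismatch
  expect_error(conv_spec(8, 15, s = 2), "divide")      # non-integral n/s
})
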