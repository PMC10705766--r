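#' Hyperparameters of one ghost-style convolutional transform
#'
#' A `conv_spec` gathers the quantities that determine both the forward
#' semantics and the exact cost of a ghost-module convolution: `c` input
#' channels, `n` output channels, a `k x k` primary kernel, a `d x d`
#' per-channel cheap (linear-transform) kernel, and the partition ratio `s`
#' that says what fraction of the output is produced by the primary
#' convolution (`n/s` channels) versus the cheap transforms (`n(s-1)/s`
#' channels).
#'
#' @param c Input channel count (>= 1).
#' @param n Output channel count (>= 1); `s` must divide `n`.
#' @param k Primary convolution kernel size in pixels.
#' @param d Cheap-transform kernel size in pixels (depthwise).
#' @param s Partition ratio between primary and cheap output channels
#'   (`s = 1` degenerates to an ordinary convolution; default 2).
#' @param stride Spatial stride.
#' @param pad Zero padding; defaults to "same" padding `(k - 1) %/% 2`.
#' @return An object of class `conv_spec`.
#' @examples
#' conv_spec(c = 64, n = 128, k = 3, d = 3, s = 2)
#' @export
conv_spec <- function(c, n, k = 3L, d = 3L, s = 2L, stride = 1L,
                      pad = (k - 1L) %/% 2L) {
  c <- as.integer(c); n <- as.integer(n); k <- as.integer(k)
  d <- as.integer(d); s <- as.integer(s); stride <- as.integer(stride)
  pad <- as.integer(pad)
  if (c < 1L || n < 1L || k < 1L || d < 1L || stride < 1L || s < 1L)
    stop("conv_spec: c, n, k, d, s and stride must all be >= 1")
  if (n %% s != 0L)
    stop("conv_spec: partition ratio s = ", s, " must divide n = ", n,
         " (n/s primary channels must be integral)")
  structure(list(c = c, n = n, k = k, d = d, s = s, stride = stride,
                 pad = pad),
            class = "conv_spec")
}

#' @export
print.conv_spec <- function(x, ...) {
  cat(sprintf("<conv_spec> c=%d -> n=%d  k=%d d=%d s=%d stride=%d pad=%d\n",
              x$c, x$n, x$k, x$d, x$s, x$stride, x$pad))
  invisible(x)
}

#' Shape of a feature map
#'
#' @param channels,height,width Positive integer dimensions.
#' @return An object of class `feature_map_spec`.
#' @export
feature_map_spec <- function(channels, height, width = height) {
  channels <- as.integer(channels); height <- as.integer(height)
  width <- as.integer(width)
  if (channels < 1L || height < 1L || width < 1L)
    stop("feature_map_spec: all dimensions must be >= 1")
  structure(list(channels = channels, height = height, width = width),
            class = "feature_map_spec")
}

BLOCK_KINDS <- c("conv", "ghost_conv", "pw_ghost_conv", "cs_ghost_conv",
                 "dw_conv", "pointwise_conv", "channel_shuffle",
                 "ghost_bottleneck", "cs_ghost_bottleneck",
                 "inverted_ghost_bottleneck",
                 # cost-model-only kinds used by reference networks
                 "c3", "sppf", "head", "concat", "upsample")

#' Declarative description of one network block
#'
#' @param kind Block kind, one of the ghost toolkit kinds (`"conv"`,
#'   `"ghost_conv"`, `"pw_ghost_conv"`, `"cs_ghost_conv"`, `"dw_conv"`,
#'   `"pointwise_conv"`, `"channel_shuffle"`, `"ghost_bottleneck"`,
#'   `"cs_ghost_bottleneck"`, `"inverted_ghost_bottleneck"`) or a
#'   cost-model-only kind (`"c3"`, `"sppf"`, `"head"`, `"concat"`,
#'   `"upsample"`).
#' @param conv_spec A [conv_spec()] where applicable.
#' @param shuffle_groups Channel-shuffle group count (default 2, aligning the
#'   interleave with the primary/cheap split).
#' @param ... Additional kind-specific fields (e.g. `n_repeat` for `c3`).
#' @return An object of class `block_spec`. The expansion factor is fixed by
#'   the kind: 0.5 for compress-first bottlenecks, 2.0 for the inverted
#'   bottleneck.
#' @export
block_spec <- function(kind, conv_spec = NULL, shuffle_groups = 2L, ...) {
  kind <- match.arg(kind, BLOCK_KINDS)
  expansion <- switch(kind,
                      ghost_bottleneck = 0.5,
                      cs_ghost_bottleneck = 0.5,
                      inverted_ghost_bottleneck = 2.0,
                      NA_real_)
  structure(list(kind = kind, conv_spec = conv_spec,
                 expansion_factor = expansion,
                 shuffle_groups = as.integer(shuffle_groups), ...),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat("<block_spec>", x$kind)
  if (!is.null(x$conv_spec))
    cat(sprintf("  c=%d n=%d k=%d d=%d s=%d stride=%d",
                x$conv_spec$c, x$conv_spec$n, x$conv_spec$k, x$conv_spec$d,
                x$conv_spec$s, x$conv_spec$stride))
  if (!is.na(x$expansion_factor))
    cat("  expansion=", x$expansion_factor, sep = "")
  cat("\n")
  invisible(x)
}

# ---- module constructors ---------------------------------------------------
#
# Modules are environments with $prims (list of primitives, for the
# optimiser), $spec (block_spec) and class-dispatched mod_forward /
# mod_backward.  `norm = "identity"` bypasses normalisation in every
# constituent, which together with zero_weights() realises the pure-shortcut
# identity contracts.

new_module <- function(cls, spec) {
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$prims <- list()
  class(e) <- c(cls, "gd_module")
  e
}

add_prim <- function(m, p) {
  m$prims <- c(m$prims, list(p))
  p
}

mod_forward <- function(m, x) UseMethod("mod_forward")
mod_backward <- function(m, g) UseMethod("mod_backward")

#' Ordinary convolution block (conv + norm + SiLU)
#'
#' @param cin,cout Channel counts.
#' @param k Kernel size; `stride` spatial stride.
#' @param stride Stride.
#' @param act Apply the SiLU nonlinearity (`FALSE` for linear blocks).
#' @param norm `"bn"` (default) or `"identity"` to bypass normalisation.
#' @return A module usable with [block_forward()].
#' @export
conv_block <- function(cin, cout, k = 3L, stride = 1L, act = TRUE,
                       norm = "bn") {
  sp <- block_spec("conv", conv_spec(cin, cout, k = k, d = 1L, s = 1L,
                                     stride = stride))
  m <- new_module("gd_convblock", sp)
  m$conv <- add_prim(m, prim_conv(cin, cout, k, stride))
  m$bn <- add_prim(m, prim_bn(cout, mode = norm))
  m$act <- if (act) add_prim(m, prim_silu()) else NULL
  m
}

#' @export
mod_forward.gd_convblock <- function(m, x) {
  y <- prim_forward(m$conv, x)
  y <- prim_forward(m$bn, y)
  if (!is.null(m$act)) y <- prim_forward(m$act, y)
  y
}

#' @export
mod_backward.gd_convblock <- function(m, g) {
  if (!is.null(m$act)) g <- prim_backward(m$act, g)
  g <- prim_backward(m$bn, g)
  prim_backward(m$conv, g)
}

#' Ghost convolution block and its information-exchange variants
#'
#' A ghost convolution produces `n/s` "primary" channels with an ordinary
#' `k x k` convolution and the remaining `n(s-1)/s` channels by cheap
#' per-channel (depthwise) `d x d` transforms of the primary channels; the two
#' groups are concatenated, normalised and activated.  The `variant` argument
#' selects the plain module, the pointwise variant (a 1x1 convolution mixes
#' all channels after the ghost module) or the channel-shuffle variant (a
#' parameter-free group interleave mixes primary and cheap channels).
#'
#' @param spec A [conv_spec()].
#' @param variant `"plain"`, `"pw"` or `"cs"`.
#' @param act Apply SiLU after the block.
#' @param norm `"bn"` or `"identity"`.
#' @param shuffle_groups Interleave groups for the `"cs"` variant.
#' @return A module; its forward output has `spec$n` channels and spatial
#'   size given by standard stride/padding arithmetic.
#' @export
ghost_conv <- function(spec, variant = c("plain", "pw", "cs"), act = TRUE,
                       norm = "bn", shuffle_groups = 2L) {
  variant <- match.arg(variant)
  kind <- switch(variant, plain = "ghost_conv", pw = "pw_ghost_conv",
                 cs = "cs_ghost_conv")
  m <- new_module("gd_ghost", block_spec(kind, spec,
                                         shuffle_groups = shuffle_groups))
  np <- ghost_primary_channels(spec)
  ncheap <- spec$n - np
  m$np <- np; m$ncheap <- ncheap
  m$primary <- add_prim(m, prim_conv(spec$c, np, spec$k, spec$stride,
                                     spec$pad))
  if (ncheap > 0L) {
    mult <- as.integer(ceiling(ncheap / np))
    m$cheap <- add_prim(m, prim_dwconv(np, spec$d, 1L,
                                       (spec$d - 1L) %/% 2L, mult))
    m$cheap_keep <- seq_len(ncheap)
  }
  m$bn <- add_prim(m, prim_bn(spec$n, mode = norm))
  m$act <- if (act) add_prim(m, prim_silu()) else NULL
  if (variant == "pw") {
    m$pw <- add_prim(m, prim_conv(spec$n, spec$n, 1L, 1L, 0L))
    m$pw_bn <- add_prim(m, prim_bn(spec$n, mode = norm))
    m$pw_act <- if (act) add_prim(m, prim_silu()) else NULL
  } else if (variant == "cs") {
    # degenerate widths not divisible by the group count fall back to the
    # identity permutation (groups = 1)
    g <- if (spec$n %% shuffle_groups == 0L) shuffle_groups else 1L
    m$shuffle <- add_prim(m, prim_shuffle(spec$n, g))
  }
  m
}

# n/s primary maps; ceiling keeps the block total on odd widths arising from
# bottleneck halving (exact n/s whenever s | n).
ghost_primary_channels <- function(spec) {
  as.integer(ceiling(spec$n / spec$s))
}

#' @export
mod_forward.gd_ghost <- function(m, x) {
  p <- prim_forward(m$primary, x)
  if (m$ncheap > 0L) {
    ch <- prim_forward(m$cheap, p)
    d <- dim(p)
    y <- array(0, dim = c(d[1], d[2], m$spec$conv_spec$n))
    y[, , seq_len(m$np)] <- p
    y[, , m$np + m$cheap_keep] <- ch[, , m$cheap_keep, drop = FALSE]
    m$cheap_dim <- dim(ch)
  } else {
    y <- p
  }
  y <- prim_forward(m$bn, y)
  if (!is.null(m$act)) y <- prim_forward(m$act, y)
  if (!is.null(m$pw)) {
    y <- prim_forward(m$pw, y)
    y <- prim_forward(m$pw_bn, y)
    if (!is.null(m$pw_act)) y <- prim_forward(m$pw_act, y)
  }
  if (!is.null(m$shuffle)) y <- prim_forward(m$shuffle, y)
  y
}

#' @export
mod_backward.gd_ghost <- function(m, g) {
  if (!is.null(m$shuffle)) g <- prim_backward(m$shuffle, g)
  if (!is.null(m$pw)) {
    if (!is.null(m$pw_act)) g <- prim_backward(m$pw_act, g)
    g <- prim_backward(m$pw_bn, g)
    g <- prim_backward(m$pw, g)
  }
  if (!is.null(m$act)) g <- prim_backward(m$act, g)
  g <- prim_backward(m$bn, g)
  if (m$ncheap > 0L) {
    gp <- g[, , seq_len(m$np), drop = FALSE]
    gch <- array(0, dim = m$cheap_dim)
    gch[, , m$cheap_keep] <- g[, , m$np + m$cheap_keep, drop = FALSE]
    gp <- gp + prim_backward(m$cheap, gch)
  } else {
    gp <- g
  }
  prim_backward(m$primary, gp)
}

#' Depthwise convolution block
#'
#' Per-channel spatial convolution (no cross-channel mixing), followed by
#' normalisation; channel count is unchanged.
#'
#' @inheritParams conv_block
#' @export
dw_conv_block <- function(cin, k = 3L, stride = 1L, act = FALSE,
                          norm = "bn") {
  sp <- block_spec("dw_conv", conv_spec(cin, cin, k = k, d = k, s = 1L,
                                        stride = stride))
  m <- new_module("gd_dwblock", sp)
  m$dw <- add_prim(m, prim_dwconv(cin, k, stride))
  m$bn <- add_prim(m, prim_bn(cin, mode = norm))
  m$act <- if (act) add_prim(m, prim_silu()) else NULL
  m
}

#' @export
mod_forward.gd_dwblock <- function(m, x) {
  y <- prim_forward(m$dw, x)
  y <- prim_forward(m$bn, y)
  if (!is.null(m$act)) y <- prim_forward(m$act, y)
  y
}

#' @export
mod_backward.gd_dwblock <- function(m, g) {
  if (!is.null(m$act)) g <- prim_backward(m$act, g)
  g <- prim_backward(m$bn, g)
  prim_backward(m$dw, g)
}

#' Ghost bottlenecks: compress-first, channel-shuffle, and inverted
#'
#' The compress-first bottleneck (`style = "ghost"`) halves the channel count
#' with a ghost convolution, extracts features with a depthwise convolution
#' (the stride is applied here), and restores the channel count with a second,
#' linear ghost convolution; a shortcut connects input to output.  The
#' `"cs_ghost"` style replaces both internal ghost convolutions with their
#' channel-shuffle variants at identical cost.  The `"inverted"` style
#' expands to twice the input channels first and compresses last, preserving
#' more feature information at higher intermediate width; it likewise uses
#' channel-shuffle ghost convolutions internally.
#'
#' When `stride = 1` and `cout = cin` the shortcut is the identity; otherwise
#' it is a depthwise 3x3 (stride-matched) plus pointwise 1x1 projection.
#'
#' @param cin,cout Channel counts.
#' @param stride Stride applied in the depthwise stage.
#' @param style `"ghost"`, `"cs_ghost"` or `"inverted"`.
#' @param inner Variant of the two internal ghost convolutions:
#'   `"auto"` (plain for `"ghost"`, channel-shuffle otherwise), `"plain"`,
#'   `"pw"` or `"cs"`.  Non-auto values support the ablation variants that
#'   swap only the bottleneck-internal modules.
#' @param norm `"bn"` or `"identity"`.
#' @return A module.
#' @export
ghost_bottleneck <- function(cin, cout, stride = 1L,
                             style = c("ghost", "cs_ghost", "inverted"),
                             inner = c("auto", "plain", "pw", "cs"),
                             norm = "bn") {
  style <- match.arg(style)
  inner <- match.arg(inner)
  kind <- switch(style, ghost = "ghost_bottleneck",
                 cs_ghost = "cs_ghost_bottleneck",
                 inverted = "inverted_ghost_bottleneck")
  cin <- as.integer(cin); cout <- as.integer(cout)
  stride <- as.integer(stride)
  mid <- if (style == "inverted") 2L * cin else max(1L, cin %/% 2L)
  m <- new_module("gd_bottleneck",
                  block_spec(kind, conv_spec(cin, cout, k = 1L, d = 3L,
                                             s = 2L, stride = stride),
                             inner = inner))
  m$cin <- cin; m$cout <- cout; m$stride <- stride; m$mid <- mid
  if (inner == "auto")
    inner <- if (style == "ghost") "plain" else "cs"
  g1_spec <- conv_spec(cin, mid, k = 1L, d = 3L,
                       s = if (mid %% 2L == 0L) 2L else 1L)
  g2_spec <- conv_spec(mid, cout, k = 1L, d = 3L,
                       s = if (cout %% 2L == 0L) 2L else 1L)
  m$g1 <- add_prim_module(m, ghost_conv(g1_spec, variant = inner, act = TRUE,
                                        norm = norm))
  m$dw <- add_prim_module(m, dw_conv_block(mid, k = 3L, stride = stride,
                                           act = FALSE, norm = norm))
  m$g2 <- add_prim_module(m, ghost_conv(g2_spec, variant = inner,
                                        act = FALSE, norm = norm))
  m$identity_shortcut <- (stride == 1L && cin == cout)
  if (!m$identity_shortcut) {
    m$sc_dw <- add_prim_module(m, dw_conv_block(cin, k = 3L, stride = stride,
                                                act = FALSE, norm = norm))
    m$sc_pw <- add_prim_module(m, conv_block(cin, cout, k = 1L, stride = 1L,
                                             act = FALSE, norm = norm))
  }
  m
}

add_prim_module <- function(parent, child) {
  parent$prims <- c(parent$prims, child$prims)
  child
}

#' @export
mod_forward.gd_bottleneck <- function(m, x) {
  y <- mod_forward(m$g1, x)
  y <- mod_forward(m$dw, y)
  y <- mod_forward(m$g2, y)
  sc <- if (m$identity_shortcut) x else
    mod_forward(m$sc_pw, mod_forward(m$sc_dw, x))
  y + sc
}

#' @export
mod_backward.gd_bottleneck <- function(m, g) {
  gx <- mod_backward(m$g1, mod_backward(m$dw, mod_backward(m$g2, g)))
  if (m$identity_shortcut) {
    gx + g
  } else {
    gx + mod_backward(m$sc_dw, mod_backward(m$sc_pw, g))
  }
}

# ---- user-facing forward helpers ------------------------------------------

#' Run a block forward
#'
#' @param m A module created by [conv_block()], [ghost_conv()],
#'   [dw_conv_block()] or [ghost_bottleneck()].
#' @param x Numeric array with dim `c(H, W, C)`.
#' @return Numeric array `c(H', W', C')`.
#' @export
block_forward <- function(m, x) {
  stopifnot(inherits(m, "gd_module"), is.array(x), length(dim(x)) == 3L)
  mod_forward(m, x)
}

#' Channel shuffle
#'
#' Applies the deterministic group-interleave permutation to the channels of
#' a feature map: channels are reshaped to `groups x (C/groups)`, transposed
#' and flattened.  Pixel values are unchanged and the operation costs zero
#' multiply-accumulates and zero parameters.
#'
#' @param x Numeric array `c(H, W, C)`.
#' @param groups Group count; must divide `C`.
#' @return The permuted array, same dim as `x`.
#' @examples
#' x <- array(seq_len(4), dim = c(1, 1, 4))
#' channel_shuffle(x, 2)[1, 1, ]  # 1 3 2 4
#' @export
channel_shuffle <- function(x, groups) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x[, , shuffle_perm(dim(x)[3], as.integer(groups)), drop = FALSE]
}

#' Zero every learnable weight of a module (normalisation scale stays 1)
#'
#' Together with `norm = "identity"` this makes every bottleneck with an
#' identity shortcut reproduce its input exactly.
#'
#' @param m A module.
#' @return The module, invisibly (mutated in place).
#' @export
zero_weights <- function(m) {
  stopifnot(inherits(m, "gd_module"))
  lapply(m$prims, prim_zero_weights)
  invisible(m)
}

#' Describe a block: its spec and exact cost
#'
#' @param m A module.
#' @param input_shape A [feature_map_spec()] giving the input the costs are
#'   evaluated at.
#' @return List with elements `spec` (the [block_spec()]) and `cost`
#'   (a `cost_report`, see [count_costs()]).
#' @export
describe <- function(m, input_shape) {
  stopifnot(inherits(m, "gd_module"))
  list(spec = m$spec, cost = count_costs(m$spec, input_shape))
}
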