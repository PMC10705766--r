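# Network assembly: an ordered layer graph (blocks + concat/upsample routing)
# describing the improved ghost backbone, a feature-pyramid neck built from
# channel-shuffle ghost convolutions, and a 3-scale anchor head.  The spec is
# declarative (consumed by the cost model and the validator); compile_network
# instantiates the trainable modules.

# Anchor priors (pixels at the reference 640 input), three per scale.
DEFAULT_ANCHORS <- list(
  p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
  p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
  p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))

net_layer <- function(name, kind, from, section, spec = NULL) {
  list(name = name, kind = kind, from = as.integer(from), section = section,
       spec = spec)
}

scale_width <- function(ch, wm) {
  max(4L, as.integer(round(ch * wm / 2) * 2))
}

#' Build the layer graph of the ghost detection network
#'
#' The backbone alternates standalone downsampling ghost convolutions with
#' bottleneck stacks; the neck is the usual top-down/bottom-up feature
#' pyramid with channel-shuffle ghost convolutions in place of every
#' convolution block; the head predicts three anchors at each of three
#' scales (strides 8/16/32).  `variant` selects which ghost flavours are
#' placed where:
#'
#' * `"improved"` - pointwise-ghost standalone downsamplers and inverted
#'   ghost bottlenecks (backbone only), the default network;
#' * `"ghost_ghost"`, `"pw_pw"`, `"cs_cs"`, `"cs_pw"`, `"pw_cs"` - the
#'   ablation variants pairing a standalone flavour with a bottleneck-internal
#'   flavour, all with compress-first bottlenecks (`"ghost_ghost"` is the
#'   plain ghost baseline).
#'
#' @param input_size Input resolution (square, pixels).
#' @param num_classes Number of object classes (1: "aggression").
#' @param width_multiple Channel width multiplier applied to the default
#'   16-24-40-80-112-160 stage widths.
#' @param variant Network variant (see above).
#' @param anchors List of three 3x2 matrices of anchor priors (pixels).
#' @return A `network_spec`.
#' @export
ghost_network_spec <- function(input_size = 640L, num_classes = 1L,
                               width_multiple = 1,
                               variant = c("improved", "ghost_ghost",
                                           "pw_pw", "cs_cs", "cs_pw",
                                           "pw_cs"),
                               anchors = DEFAULT_ANCHORS) {
  variant <- match.arg(variant)
  vdef <- switch(variant,
    improved    = list(standalone = "pw", bstyle = "inverted", inner = "auto"),
    ghost_ghost = list(standalone = "plain", bstyle = "ghost", inner = "plain"),
    pw_pw       = list(standalone = "pw", bstyle = "ghost", inner = "pw"),
    cs_cs       = list(standalone = "cs", bstyle = "cs_ghost", inner = "cs"),
    cs_pw       = list(standalone = "cs", bstyle = "ghost", inner = "pw"),
    pw_cs       = list(standalone = "pw", bstyle = "cs_ghost", inner = "cs"))
  w <- vapply(c(16, 24, 40, 80, 112, 160), scale_width, 0L,
              wm = width_multiple)
  nf <- 3L * (5L + num_classes)
  sa_kind <- switch(vdef$standalone, plain = "ghost_conv",
                    pw = "pw_ghost_conv", cs = "cs_ghost_conv")
  b_kind <- switch(vdef$bstyle, ghost = "ghost_bottleneck",
                   cs_ghost = "cs_ghost_bottleneck",
                   inverted = "inverted_ghost_bottleneck")
  sa <- function(name, cin, cout, stride)
    net_layer(name, sa_kind, -1L, "backbone",
              block_spec(sa_kind, conv_spec(cin, cout, k = 3L, d = 3L,
                                            s = 2L, stride = stride)))
  bt <- function(name, cin, cout)
    net_layer(name, b_kind, -1L, "backbone",
              block_spec(b_kind, conv_spec(cin, cout, k = 1L, d = 3L,
                                           s = 2L, stride = 1L),
                         inner = vdef$inner))
  cs_neck <- function(name, cin, cout, k, stride, from = -1L)
    net_layer(name, "cs_ghost_conv", from, "neck",
              block_spec("cs_ghost_conv",
                         conv_spec(cin, cout, k = k, d = 3L, s = 2L,
                                   stride = stride)))
  layers <- list(
    net_layer("stem", "conv", -1L, "backbone",                        # 1
              block_spec("conv", conv_spec(3L, w[1], k = 3L, d = 1L,
                                           s = 1L, stride = 2L))),
    sa("down2", w[1], w[2], 2L),                                      # 2
    bt("b2.1", w[2], w[2]),                                           # 3
    sa("down3", w[2], w[3], 2L),                                      # 4
    bt("b3.1", w[3], w[3]),                                           # 5
    bt("b3.2", w[3], w[3]),                                           # 6  P3
    sa("down4", w[3], w[4], 2L),                                      # 7
    bt("b4.1", w[4], w[4]),                                           # 8
    bt("b4.2", w[4], w[4]),                                           # 9  P4
    sa("down5", w[4], w[5], 2L),                                      # 10
    bt("b5.1", w[5], w[5]),                                           # 11
    cs_neck("p5.out", w[5], w[6], 1L, 1L),                            # 12 P5
    cs_neck("fpn5.lat", w[6], w[4], 1L, 1L, from = 12L),              # 13
    net_layer("fpn5.up", "upsample", 13L, "neck",
              block_spec("upsample")),                                # 14
    net_layer("fpn4.cat", "concat", c(14L, 9L), "neck"),              # 15
    cs_neck("fpn4.fuse", 2L * w[4], w[4], 3L, 1L, from = 15L),        # 16
    cs_neck("fpn4.lat", w[4], w[3], 1L, 1L, from = 16L),              # 17
    net_layer("fpn4.up", "upsample", 17L, "neck",
              block_spec("upsample")),                                # 18
    net_layer("fpn3.cat", "concat", c(18L, 6L), "neck"),              # 19
    cs_neck("fpn3.fuse", 2L * w[3], w[3], 3L, 1L, from = 19L),        # 20 N3
    cs_neck("pan3.down", w[3], w[3], 3L, 2L, from = 20L),             # 21
    net_layer("pan4.cat", "concat", c(21L, 17L), "neck"),             # 22
    cs_neck("pan4.fuse", 2L * w[3], w[4], 3L, 1L, from = 22L),        # 23 N4
    cs_neck("pan4.down", w[4], w[4], 3L, 2L, from = 23L),             # 24
    net_layer("pan5.cat", c("concat"), c(24L, 13L), "neck"),          # 25
    cs_neck("pan5.fuse", 2L * w[4], w[5], 3L, 1L, from = 25L),        # 26 N5
    net_layer("head.p3", "head", 20L, "head",
              block_spec("head", conv_spec(w[3], nf, k = 1L, d = 1L,
                                           s = 1L))),                 # 27
    net_layer("head.p4", "head", 23L, "head",
              block_spec("head", conv_spec(w[4], nf, k = 1L, d = 1L,
                                           s = 1L))),                 # 28
    net_layer("head.p5", "head", 26L, "head",
              block_spec("head", conv_spec(w[5], nf, k = 1L, d = 1L,
                                           s = 1L))))                 # 29
  spec <- structure(list(layers = layers, anchors = anchors,
                         strides = c(8L, 16L, 32L),
                         num_classes = as.integer(num_classes),
                         input_size = as.integer(input_size),
                         head_ids = c(27L, 28L, 29L),
                         variant = variant,
                         width_multiple = width_multiple),
                    class = "network_spec")
  validate_network_spec(spec)
  spec
}

#' Validate the structural invariants of a network spec
#'
#' Inverted ghost bottlenecks may appear only in the backbone; the neck must
#' use channel-shuffle ghost convolutions (never plain ghost convolutions);
#' there must be exactly three detection scales with three anchors each.
#'
#' @param spec A `network_spec`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_network_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  for (ly in spec$layers) {
    if (ly$kind == "inverted_ghost_bottleneck" && ly$section != "backbone")
      stop("network_spec: inverted ghost bottlenecks are restricted to the ",
           "backbone (found '", ly$name, "' in section '", ly$section, "')")
    if (ly$section == "neck" && ly$kind == "ghost_conv")
      stop("network_spec: the neck must use cs_ghost_conv, not plain ",
           "ghost_conv (layer '", ly$name, "')")
  }
  if (length(spec$head_ids) != 3L)
    stop("network_spec: exactly 3 detection scales are required")
  if (length(spec$anchors) != 3L ||
      !all(vapply(spec$anchors, nrow, 0L) == 3L))
    stop("network_spec: 3 anchor priors per scale are required")
  invisible(TRUE)
}

#' Reference backbone: cross-stage-partial DarkNet (small), cost model only
#'
#' The comparison baseline the lightweight backbone is measured against.
#'
#' @param width_multiple,depth_multiple The usual small-model scalings
#'   (0.5 / 0.33).
#' @return A `network_spec` restricted to backbone layers (no head).
#' @export
cspdarknet_small_spec <- function(width_multiple = 0.5,
                                  depth_multiple = 0.33) {
  wch <- function(ch) max(8L, as.integer(ceiling(ch * width_multiple / 8) * 8))
  dn <- function(n) max(1L, as.integer(round(n * depth_multiple)))
  cv <- function(name, cin, cout, k, stride)
    net_layer(name, "conv", -1L, "backbone",
              block_spec("conv", conv_spec(cin, cout, k = k, d = 1L, s = 1L,
                                           stride = stride)))
  c3 <- function(name, cin, cout, n)
    net_layer(name, "c3", -1L, "backbone",
              block_spec("c3", conv_spec(cin, cout, k = 1L, d = 1L, s = 1L),
                         n_repeat = dn(n)))
  layers <- list(
    cv("stem", 3L, wch(64), 6L, 2L),
    cv("down2", wch(64), wch(128), 3L, 2L),
    c3("c3.2", wch(128), wch(128), 3L),
    cv("down3", wch(128), wch(256), 3L, 2L),
    c3("c3.3", wch(256), wch(256), 6L),
    cv("down4", wch(256), wch(512), 3L, 2L),
    c3("c3.4", wch(512), wch(512), 9L),
    cv("down5", wch(512), wch(1024), 3L, 2L),
    c3("c3.5", wch(1024), wch(1024), 3L),
    net_layer("sppf", "sppf", -1L, "backbone",
              block_spec("sppf", conv_spec(wch(1024), wch(1024), k = 1L,
                                           d = 1L, s = 1L))))
  structure(list(layers = layers, anchors = DEFAULT_ANCHORS,
                 strides = c(8L, 16L, 32L), num_classes = 1L,
                 input_size = 640L, head_ids = integer(0),
                 variant = "cspdarknet_small",
                 width_multiple = width_multiple),
            class = "network_spec")
}

#' Parameter count of the backbone section of a network spec
#'
#' @param spec A `network_spec`.
#' @return Numeric parameter count of the backbone layers.
#' @export
backbone_params <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  keep <- vapply(spec$layers, function(l) l$section == "backbone",
                 logical(1))
  sub <- spec
  sub$layers <- spec$layers[keep]
  count_costs.network_spec(sub)$params
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> variant=%s  input=%d  classes=%d  layers=%d\n",
              x$variant, x$input_size, x$num_classes, length(x$layers)))
  invisible(x)
}

# ---- compilation into trainable modules ------------------------------------

#' Instantiate a trainable network from its spec
#'
#' @param spec A `network_spec` from [ghost_network_spec()].
#' @param seed Integer seed for weight initialisation.
#' @param norm `"bn"` or `"identity"`.
#' @return A `gd_network` object (mutable; holds all weights).
#' @export
compile_network <- function(spec, seed = 0L, norm = "bn") {
  validate_network_spec(spec)
  set.seed(seed)
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  net$nodes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    mod <- switch(ly$kind,
      conv = {
        cs <- ly$spec$conv_spec
        conv_block(cs$c, cs$n, cs$k, cs$stride, norm = norm)
      },
      ghost_conv = ,
      pw_ghost_conv = ,
      cs_ghost_conv = {
        variant <- switch(ly$kind, ghost_conv = "plain",
                          pw_ghost_conv = "pw", cs_ghost_conv = "cs")
        ghost_conv(ly$spec$conv_spec, variant = variant, norm = norm)
      },
      ghost_bottleneck = ,
      cs_ghost_bottleneck = ,
      inverted_ghost_bottleneck = {
        cs <- ly$spec$conv_spec
        style <- switch(ly$kind, ghost_bottleneck = "ghost",
                        cs_ghost_bottleneck = "cs_ghost",
                        inverted_ghost_bottleneck = "inverted")
        inner <- if (is.null(ly$spec$inner)) "auto" else ly$spec$inner
        ghost_bottleneck(cs$c, cs$n, cs$stride, style = style,
                         inner = inner, norm = norm)
      },
      upsample = prim_upsample(),
      concat = NULL,
      head = {
        cs <- ly$spec$conv_spec
        h <- prim_conv(cs$c, cs$n, 1L, 1L, 0L, bias = TRUE)
        # start with low objectness probability so early training is stable
        nf <- 5L + spec$num_classes
        obj_idx <- seq.int(5L, cs$n, by = nf)
        h$b[obj_idx] <- stats::qlogis(0.01)
        h
      },
      stop("compile_network: unknown kind ", ly$kind))
    net$nodes[[i]] <- list(layer = ly, mod = mod,
                           from = resolve_from(ly$from, i))
  }
  class(net) <- "gd_network"
  net
}

net_prims <- function(net) {
  out <- list()
  for (nd in net$nodes) {
    m <- nd$mod
    if (is.null(m)) next
    if (inherits(m, "gd_module")) out <- c(out, m$prims)
    else if (inherits(m, "gd_prim")) out <- c(out, list(m))
  }
  out
}

#' Forward pass of a compiled network
#'
#' @param net A `gd_network`.
#' @param x Input array `c(H, W, 3)`, values in `[0, 1]`.
#' @return List of three raw head arrays (`gh x gw x (3 * (5 + nc))`), one
#'   per scale (strides 8/16/32).
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "gd_network"))
  outs <- vector("list", length(net$nodes))
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    y <- if (nd$layer$kind == "concat") {
      ins <- lapply(nd$from, function(j) outs[[j]])
      net$nodes[[i]]$splits <- vapply(ins, function(a) dim(a)[3], 0L)
      do.call(cat_channels, ins)
    } else {
      xin <- if (nd$from[1] == 0L) x else outs[[nd$from[1]]]
      if (inherits(nd$mod, "gd_module")) mod_forward(nd$mod, xin)
      else prim_forward(nd$mod, xin)
    }
    outs[[i]] <- y
  }
  net$outs <- outs
  outs[net$spec$head_ids]
}

cat_channels <- function(...) {
  ins <- list(...)
  d1 <- dim(ins[[1]])
  ctot <- sum(vapply(ins, function(a) dim(a)[3], 0L))
  y <- array(0, dim = c(d1[1], d1[2], ctot))
  at <- 0L
  for (a in ins) {
    ca <- dim(a)[3]
    y[, , at + seq_len(ca)] <- a
    at <- at + ca
  }
  y
}

#' Backward pass of a compiled network
#'
#' @param net A `gd_network` whose forward pass has just been run.
#' @param head_grads List of three gradient arrays matching the head outputs.
#' @return Invisibly `NULL`; parameter gradients accumulate inside the net.
#' @export
network_backward <- function(net, head_grads) {
  n <- length(net$nodes)
  gbuf <- vector("list", n)
  for (k in seq_len(3L)) gbuf[[net$spec$head_ids[k]]] <- head_grads[[k]]
  for (i in rev(seq_len(n))) {
    g <- gbuf[[i]]
    if (is.null(g)) next
    nd <- net$nodes[[i]]
    if (nd$layer$kind == "concat") {
      at <- 0L
      for (idx in seq_along(nd$from)) {
        ca <- nd$splits[idx]
        gpart <- g[, , at + seq_len(ca), drop = FALSE]
        j <- nd$from[idx]
        gbuf[[j]] <- if (is.null(gbuf[[j]])) gpart else gbuf[[j]] + gpart
        at <- at + ca
      }
    } else {
      gin <- if (inherits(nd$mod, "gd_module")) mod_backward(nd$mod, g)
             else prim_backward(nd$mod, g)
      j <- nd$from[1]
      if (j > 0L)
        gbuf[[j]] <- if (is.null(gbuf[[j]])) gin else gbuf[[j]] + gin
    }
    gbuf[i] <- list(NULL)   # free; plain [[<- NULL would drop the slot
  }
  invisible(NULL)
}

net_zero_grads <- function(net) {
  lapply(net_prims(net), prim_zero_grads)
  invisible(NULL)
}

net_sgd_step <- function(net, lr, momentum) {
  lapply(net_prims(net), prim_sgd_step, lr = lr, momentum = momentum)
  invisible(NULL)
}

#' @export
print.gd_network <- function(x, ...) {
  np <- sum(vapply(net_prims(x), prim_n_params, 0))
  cat(sprintf("<gd_network> %s  input=%d  %d nodes, %s parameters\n",
              x$spec$variant, x$spec$input_size, length(x$nodes),
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- config serialisation --------------------------------------------------

#' Serialise a block spec or network configuration to YAML
#'
#' Block specs round-trip through a nested key-value representation;
#' network configurations store the constructor arguments
#' (input size, class count, width multiplier, variant, anchors).
#'
#' @param x A [block_spec()] or `network_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spec_config <- function(x, path) {
  if (inherits(x, "block_spec")) {
    lst <- list(type = "block_spec", kind = x$kind,
                shuffle_groups = x$shuffle_groups)
    if (!is.null(x$conv_spec))
      lst$conv_spec <- unclass(x$conv_spec)
    if (!is.null(x$inner)) lst$inner <- x$inner
    if (!is.null(x$n_repeat)) lst$n_repeat <- x$n_repeat
  } else if (inherits(x, "network_spec")) {
    lst <- list(type = "network_spec", input_size = x$input_size,
                num_classes = x$num_classes,
                width_multiple = x$width_multiple, variant = x$variant,
                anchors = lapply(x$anchors,
                                 function(m) as.vector(t(m))))
  } else stop("write_spec_config: unsupported object")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a block spec or network configuration from YAML
#'
#' @param path File written by [write_spec_config()].
#' @return A [block_spec()] or `network_spec`.
#' @export
read_spec_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (identical(lst$type, "block_spec")) {
    cs <- if (!is.null(lst$conv_spec))
      do.call(conv_spec, lst$conv_spec)
    extra <- list()
    if (!is.null(lst$inner)) extra$inner <- lst$inner
    if (!is.null(lst$n_repeat)) extra$n_repeat <- lst$n_repeat
    do.call(block_spec, c(list(kind = lst$kind, conv_spec = cs,
                               shuffle_groups = lst$shuffle_groups),
                          extra))
  } else if (identical(lst$type, "network_spec")) {
    anchors <- lapply(lst$anchors,
                      function(v) matrix(v, ncol = 2, byrow = TRUE))
    names(anchors) <- names(lst$anchors)
    ghost_network_spec(input_size = lst$input_size,
                       num_classes = lst$num_classes,
                       width_multiple = lst$width_multiple,
                       variant = lst$variant, anchors = anchors)
  } else stop("read_spec_config: unrecognised config file")
}
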