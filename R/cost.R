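# Exact analytical cost accounting (multiply-accumulates and parameters),
# plus two independent empirical counters used as oracles: an exhaustive
# per-output-element enumeration and an instrumented forward pass.
#
# Counting conventions: multiply-accumulate operations (MACs) are reported;
# FLOPs, when requested, are 2x MACs.  Normalisation, activation, channel
# shuffle, concatenation and upsampling contribute zero MACs and zero
# parameters (normalisation scale/shift is foldable into the preceding
# convolution at inference, so block-level parameter counts are kernel
# counts, keeping the closed-form compression ratio an exact identity).

cost_entry <- function(name, kind, macs, params, out) {
  data.frame(name = name, kind = kind,
             out_c = out[1], out_h = out[2], out_w = out[3],
             params = params, macs = macs, stringsAsFactors = FALSE)
}

new_cost_report <- function(breakdown) {
  structure(list(macs = sum(breakdown$macs), params = sum(breakdown$params),
                 breakdown = breakdown),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> params = %s, MACs = %s (%.3f GFLOPs)\n",
              format(x$params, big.mark = ","),
              format(x$macs, big.mark = ","), 2 * x$macs / 1e9))
  invisible(x)
}

# ---- per-kind exact costs --------------------------------------------------
# Every helper returns list(macs, params, out = c(C, H, W), breakdown).

cost_conv <- function(cin, cout, k, stride, pad, h, w, bias = FALSE,
                      name = "conv") {
  ho <- conv_out_len(h, k, stride, pad)
  wo <- conv_out_len(w, k, stride, pad)
  macs <- as.numeric(k)^2 * cin * cout * ho * wo
  params <- as.numeric(k)^2 * cin * cout + if (bias) cout else 0
  list(macs = macs, params = params, out = c(cout, ho, wo),
       breakdown = cost_entry(name, "conv", macs, params, c(cout, ho, wo)))
}

cost_dw <- function(cn, k, stride, pad, h, w, mult = 1, name = "dw_conv") {
  ho <- conv_out_len(h, k, stride, pad)
  wo <- conv_out_len(w, k, stride, pad)
  macs <- as.numeric(k)^2 * cn * mult * ho * wo
  params <- as.numeric(k)^2 * cn * mult
  list(macs = macs, params = params, out = c(cn * mult, ho, wo),
       breakdown = cost_entry(name, "dw_conv", macs, params,
                              c(cn * mult, ho, wo)))
}

cost_ghost <- function(sp, h, w, variant = "plain", name = "ghost_conv") {
  np <- ghost_primary_channels(sp)
  ncheap <- sp$n - np
  pr <- cost_conv(sp$c, np, sp$k, sp$stride, sp$pad, h, w,
                  name = paste0(name, ".primary"))
  bd <- pr$breakdown
  macs <- pr$macs; params <- pr$params
  ho <- pr$out[2]; wo <- pr$out[3]
  if (ncheap > 0) {
    cheap_macs <- as.numeric(sp$d)^2 * ncheap * ho * wo
    cheap_params <- as.numeric(sp$d)^2 * ncheap
    bd <- rbind(bd, cost_entry(paste0(name, ".cheap"), "dw_conv",
                               cheap_macs, cheap_params, c(ncheap, ho, wo)))
    macs <- macs + cheap_macs; params <- params + cheap_params
  }
  if (variant == "pw") {
    pw <- cost_conv(sp$n, sp$n, 1L, 1L, 0L, ho, wo,
                    name = paste0(name, ".pw"))
    bd <- rbind(bd, pw$breakdown)
    macs <- macs + pw$macs; params <- params + pw$params
  }
  # the channel-shuffle variant adds exactly zero MACs and zero parameters
  list(macs = macs, params = params, out = c(sp$n, ho, wo), breakdown = bd)
}

cost_bottleneck <- function(cin, cout, stride, style, inner, h, w,
                            name = "bottleneck") {
  mid <- if (style == "inverted") 2L * cin else max(1L, cin %/% 2L)
  if (inner == "auto") inner <- if (style == "ghost") "plain" else "cs"
  g1 <- cost_ghost(conv_spec(cin, mid, k = 1L, d = 3L,
                             s = if (mid %% 2L == 0L) 2L else 1L),
                   h, w, variant = inner, name = paste0(name, ".g1"))
  dw <- cost_dw(mid, 3L, stride, 1L, g1$out[2], g1$out[3],
                name = paste0(name, ".dw"))
  g2 <- cost_ghost(conv_spec(mid, cout, k = 1L, d = 3L,
                             s = if (cout %% 2L == 0L) 2L else 1L),
                   dw$out[2], dw$out[3], variant = inner,
                   name = paste0(name, ".g2"))
  bd <- rbind(g1$breakdown, dw$breakdown, g2$breakdown)
  macs <- g1$macs + dw$macs + g2$macs
  params <- g1$params + dw$params + g2$params
  if (!(stride == 1L && cin == cout)) {
    sdw <- cost_dw(cin, 3L, stride, 1L, h, w, name = paste0(name, ".sc_dw"))
    spw <- cost_conv(cin, cout, 1L, 1L, 0L, sdw$out[2], sdw$out[3],
                     name = paste0(name, ".sc_pw"))
    bd <- rbind(bd, sdw$breakdown, spw$breakdown)
    macs <- macs + sdw$macs + spw$macs
    params <- params + sdw$params + spw$params
  }
  list(macs = macs, params = params, out = g2$out, breakdown = bd)
}

# YOLO-style C3 cross-stage block and SPPF, used only for the reference
# backbone the comparison claims are made against.
cost_c3 <- function(cin, cout, n_repeat, h, w, name = "c3") {
  c2 <- cout %/% 2L
  parts <- list(cost_conv(cin, c2, 1L, 1L, 0L, h, w, name = paste0(name, ".cv1")),
                cost_conv(cin, c2, 1L, 1L, 0L, h, w, name = paste0(name, ".cv2")))
  for (i in seq_len(n_repeat)) {
    parts <- c(parts,
               list(cost_conv(c2, c2, 1L, 1L, 0L, h, w,
                              name = sprintf("%s.m%d.cv1", name, i)),
                    cost_conv(c2, c2, 3L, 1L, 1L, h, w,
                              name = sprintf("%s.m%d.cv2", name, i))))
  }
  parts <- c(parts, list(cost_conv(2L * c2, cout, 1L, 1L, 0L, h, w,
                                   name = paste0(name, ".cv3"))))
  bd <- do.call(rbind, lapply(parts, `[[`, "breakdown"))
  list(macs = sum(vapply(parts, `[[`, 0, "macs")),
       params = sum(vapply(parts, `[[`, 0, "params")),
       out = c(cout, h, w), breakdown = bd)
}

cost_sppf <- function(cin, cout, h, w, name = "sppf") {
  ch <- cin %/% 2L
  p1 <- cost_conv(cin, ch, 1L, 1L, 0L, h, w, name = paste0(name, ".cv1"))
  p2 <- cost_conv(4L * ch, cout, 1L, 1L, 0L, h, w, name = paste0(name, ".cv2"))
  list(macs = p1$macs + p2$macs, params = p1$params + p2$params,
       out = c(cout, h, w), breakdown = rbind(p1$breakdown, p2$breakdown))
}

block_spec_cost <- function(sp, in_shape, name = sp$kind) {
  h <- in_shape[2]; w <- in_shape[3]
  switch(sp$kind,
    conv = {
      cs <- sp$conv_spec
      cost_conv(cs$c, cs$n, cs$k, cs$stride, cs$pad, h, w, name = name)
    },
    pointwise_conv = {
      cs <- sp$conv_spec
      cost_conv(cs$c, cs$n, 1L, 1L, 0L, h, w, name = name)
    },
    dw_conv = {
      cs <- sp$conv_spec
      cost_dw(cs$c, cs$k, cs$stride, cs$pad, h, w, name = name)
    },
    ghost_conv = cost_ghost(sp$conv_spec, h, w, "plain", name),
    pw_ghost_conv = cost_ghost(sp$conv_spec, h, w, "pw", name),
    cs_ghost_conv = cost_ghost(sp$conv_spec, h, w, "cs", name),
    channel_shuffle = list(macs = 0, params = 0, out = in_shape,
                           breakdown = cost_entry(name, sp$kind, 0, 0,
                                                  in_shape)),
    upsample = list(macs = 0, params = 0,
                    out = c(in_shape[1], 2 * h, 2 * w),
                    breakdown = cost_entry(name, sp$kind, 0, 0,
                                           c(in_shape[1], 2 * h, 2 * w))),
    ghost_bottleneck = ,
    cs_ghost_bottleneck = ,
    inverted_ghost_bottleneck = {
      cs <- sp$conv_spec
      style <- switch(sp$kind, ghost_bottleneck = "ghost",
                      cs_ghost_bottleneck = "cs_ghost",
                      inverted_ghost_bottleneck = "inverted")
      inner <- if (is.null(sp$inner)) "auto" else sp$inner
      cost_bottleneck(cs$c, cs$n, cs$stride, style, inner, h, w, name)
    },
    head = {
      cs <- sp$conv_spec
      cost_conv(cs$c, cs$n, 1L, 1L, 0L, h, w, bias = TRUE, name = name)
    },
    c3 = cost_c3(sp$conv_spec$c, sp$conv_spec$n, sp$n_repeat, h, w, name),
    sppf = cost_sppf(sp$conv_spec$c, sp$conv_spec$n, h, w, name),
    stop("count_costs: unsupported block kind ", sp$kind)
  )
}

#' Exact MAC and parameter counts for a block or a whole network
#'
#' @param x A [block_spec()] or a `network_spec` (see
#'   [ghost_network_spec()]).
#' @param input_shape A [feature_map_spec()]; for a network, its channel
#'   count and spatial size must match the network input.
#' @param flops If `TRUE`, report FLOPs (2 x MACs) in the totals.
#' @return A `cost_report`: `macs`, `params` and a per-layer `breakdown`
#'   data frame whose totals equal the reported totals (additivity).
#' @examples
#' sp <- block_spec("ghost_conv", conv_spec(64, 128, k = 3, d = 3, s = 2))
#' count_costs(sp, feature_map_spec(64, 32, 32))
#' @export
count_costs <- function(x, input_shape, flops = FALSE) {
  UseMethod("count_costs")
}

#' @export
count_costs.block_spec <- function(x, input_shape, flops = FALSE) {
  stopifnot(inherits(input_shape, "feature_map_spec"))
  res <- block_spec_cost(x, c(input_shape$channels, input_shape$height,
                              input_shape$width))
  rep <- new_cost_report(res$breakdown)
  if (flops) rep$macs <- 2 * rep$macs
  rep
}

#' @export
count_costs.network_spec <- function(x, input_shape = NULL, flops = FALSE) {
  if (is.null(input_shape))
    input_shape <- feature_map_spec(3L, x$input_size, x$input_size)
  shapes <- list(c(input_shape$channels, input_shape$height,
                   input_shape$width))
  bds <- list()
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    from <- resolve_from(ly$from, i)
    if (ly$kind == "concat") {
      ins <- lapply(from, function(j) shapes[[j + 1L]])
      out <- c(sum(vapply(ins, `[`, 0, 1)), ins[[1]][2], ins[[1]][3])
      bds[[i]] <- cost_entry(ly$name, "concat", 0, 0, out)
      shapes[[i + 1L]] <- out
    } else {
      res <- block_spec_cost(ly$spec, shapes[[from[1] + 1L]], name = ly$name)
      bds[[i]] <- res$breakdown
      shapes[[i + 1L]] <- res$out
    }
  }
  rep <- new_cost_report(do.call(rbind, bds))
  if (flops) rep$macs <- 2 * rep$macs
  rep
}

resolve_from <- function(from, i) {
  ifelse(from < 0L, i + from, from)
}

# ---- closed-form ratios ----------------------------------------------------

#' Computational speedup ratio of a ghost convolution over an ordinary one
#'
#' Ratio of multiply-accumulates of an ordinary `k x k` convolution
#' (`n * c * k^2 * h' * w'`) to those of the ghost module producing the same
#' output (`(n/s) * c * k^2 * h' * w'` primary plus
#' `(n(s-1)/s) * d^2 * h' * w'` cheap depthwise), which simplifies to
#' `s * c * k^2 / (c * k^2 + (s - 1) * d^2)` -- independent of the output
#' resolution and approaching `s` for wide layers with `k = d`.
#'
#' @param c,n Input and output channel counts (`s` must divide `n`).
#' @param k,d Primary and cheap kernel sizes.
#' @param s Partition ratio.
#' @return The dimensionless speedup ratio.
#' @examples
#' speedup_ratio(c = 64, n = 128, k = 3, d = 3, s = 2)  # 128/65
#' @export
speedup_ratio <- function(c, n, k, d, s) {
  check_ratio_args(c, n, k, d, s)
  (s * c * k^2) / (c * k^2 + (s - 1) * d^2)
}

#' Model compression ratio of a ghost convolution
#'
#' Ratio of learnable parameters of an ordinary convolution (`n * c * k^2`)
#' to those of the ghost module (`(n/s) * c * k^2 + (n(s-1)/s) * d^2`).
#' With `k = d` this is approximately `s * c / (s + c - 1)`, approaching `s`
#' for wide layers.
#'
#' @inheritParams speedup_ratio
#' @return The dimensionless compression ratio.
#' @export
compression_ratio <- function(c, n, k, d, s) {
  check_ratio_args(c, n, k, d, s)
  ordinary <- n * c * k^2
  ghost <- (n / s) * c * k^2 + (n * (s - 1) / s) * d^2
  ordinary / ghost
}

check_ratio_args <- function(c, n, k, d, s) {
  if (any(c(c, n, k, d, s) < 1))
    stop("ratio arguments must all be positive")
  if (n %% s != 0)
    stop("partition ratio s = ", s, " must divide n = ", n)
  invisible(NULL)
}

# ---- empirical oracles -----------------------------------------------------

#' Count MACs by exhaustive enumeration over output elements
#'
#' Independent of the closed-form accounting: for every output element of
#' every convolution stage the kernel taps are enumerated and summed.
#'
#' @param x A [block_spec()].
#' @param input_shape A [feature_map_spec()].
#' @return MAC count (numeric scalar).
#' @export
count_macs_enum <- function(x, input_shape) {
  stopifnot(inherits(x, "block_spec"), inherits(input_shape,
                                                "feature_map_spec"))
  enum_block(x, c(input_shape$channels, input_shape$height,
                  input_shape$width))$macs
}

# one MAC per (output position, output channel, kernel row, kernel col,
# contributing input channel); positions and taps are enumerated, not
# computed from the closed form
enum_conv <- function(cin, cout, k, stride, pad, h, w) {
  oi <- seq.int(1L, h + 2L * pad - k + 1L, by = stride)
  oj <- seq.int(1L, w + 2L * pad - k + 1L, by = stride)
  taps <- nrow(expand.grid(ki = seq_len(k), kj = seq_len(k),
                           ci = seq_len(cin)))
  n_out <- length(oi) * length(oj) * cout
  list(macs = sum(rep(as.numeric(taps), n_out)),
       out = c(cout, length(oi), length(oj)))
}

enum_dw <- function(cn, k, stride, pad, h, w, mult = 1L) {
  oi <- seq.int(1L, h + 2L * pad - k + 1L, by = stride)
  oj <- seq.int(1L, w + 2L * pad - k + 1L, by = stride)
  taps <- nrow(expand.grid(ki = seq_len(k), kj = seq_len(k)))
  n_out <- length(oi) * length(oj) * cn * mult
  list(macs = sum(rep(as.numeric(taps), n_out)),
       out = c(cn * mult, length(oi), length(oj)))
}

enum_ghost <- function(sp, h, w, variant = "plain") {
  np <- ghost_primary_channels(sp)
  ncheap <- sp$n - np
  pr <- enum_conv(sp$c, np, sp$k, sp$stride, sp$pad, h, w)
  macs <- pr$macs
  if (ncheap > 0L)
    macs <- macs + enum_dw(ncheap, sp$d, 1L, (sp$d - 1L) %/% 2L,
                           pr$out[2], pr$out[3])$macs
  if (variant == "pw")
    macs <- macs + enum_conv(sp$n, sp$n, 1L, 1L, 0L, pr$out[2], pr$out[3])$macs
  list(macs = macs, out = c(sp$n, pr$out[2], pr$out[3]))
}

enum_block <- function(sp, in_shape) {
  h <- in_shape[2]; w <- in_shape[3]
  cs <- sp$conv_spec
  switch(sp$kind,
    conv = enum_conv(cs$c, cs$n, cs$k, cs$stride, cs$pad, h, w),
    pointwise_conv = enum_conv(cs$c, cs$n, 1L, 1L, 0L, h, w),
    head = enum_conv(cs$c, cs$n, 1L, 1L, 0L, h, w),
    dw_conv = enum_dw(cs$c, cs$k, cs$stride, cs$pad, h, w),
    ghost_conv = enum_ghost(cs, h, w, "plain"),
    pw_ghost_conv = enum_ghost(cs, h, w, "pw"),
    cs_ghost_conv = enum_ghost(cs, h, w, "cs"),
    channel_shuffle = list(macs = 0, out = in_shape),
    upsample = list(macs = 0, out = c(in_shape[1], 2L * h, 2L * w)),
    ghost_bottleneck = ,
    cs_ghost_bottleneck = ,
    inverted_ghost_bottleneck = {
      style <- switch(sp$kind, ghost_bottleneck = "ghost",
                      cs_ghost_bottleneck = "cs_ghost",
                      inverted_ghost_bottleneck = "inverted")
      inner <- if (is.null(sp$inner) || sp$inner == "auto") {
        if (style == "ghost") "plain" else "cs"
      } else sp$inner
      mid <- if (style == "inverted") 2L * cs$c else max(1L, cs$c %/% 2L)
      g1 <- enum_ghost(conv_spec(cs$c, mid, k = 1L, d = 3L,
                                 s = if (mid %% 2L == 0L) 2L else 1L),
                       h, w, inner)
      dw <- enum_dw(mid, 3L, cs$stride, 1L, g1$out[2], g1$out[3])
      g2 <- enum_ghost(conv_spec(mid, cs$n, k = 1L, d = 3L,
                                 s = if (cs$n %% 2L == 0L) 2L else 1L),
                       dw$out[2], dw$out[3], inner)
      macs <- g1$macs + dw$macs + g2$macs
      if (!(cs$stride == 1L && cs$c == cs$n)) {
        sdw <- enum_dw(cs$c, 3L, cs$stride, 1L, h, w)
        macs <- macs + sdw$macs +
          enum_conv(cs$c, cs$n, 1L, 1L, 0L, sdw$out[2], sdw$out[3])$macs
      }
      list(macs = macs, out = g2$out)
    },
    stop("count_macs_enum: unsupported kind ", sp$kind)
  )
}

#' Count MACs with an instrumented forward pass
#'
#' Instantiates the module, runs a real forward pass on random input and
#' counts every multiply issued by the runtime kernels.
#'
#' @param m A module (e.g. from [ghost_conv()]), or a compiled network.
#' @param input_shape A [feature_map_spec()] (ignored for networks, which
#'   know their input size).
#' @return MAC count (numeric scalar).
#' @export
count_macs_forward <- function(m, input_shape = NULL) {
  if (inherits(m, "gd_network")) {
    x <- array(stats::rnorm(3 * m$spec$input_size^2),
               dim = c(m$spec$input_size, m$spec$input_size, 3))
    mac_counter_start()
    network_forward(m, x)
    return(mac_counter_stop())
  }
  stopifnot(inherits(m, "gd_module"), inherits(input_shape,
                                               "feature_map_spec"))
  x <- array(stats::rnorm(input_shape$channels * input_shape$height *
                            input_shape$width),
             dim = c(input_shape$height, input_shape$width,
                     input_shape$channels))
  mac_counter_start()
  mod_forward(m, x)
  mac_counter_stop()
}

#' Per-layer cost audit of a network
#'
#' @param spec A `network_spec`.
#' @param input_size Optional input resolution override (pixels, square).
#' @param flops Report FLOPs (2 x MACs) instead of MACs.
#' @return Invisibly, the audit data frame (name, kind, output shape,
#'   params, MACs) with a `"totals"` attribute; printed as an aligned table.
#' @export
cost_audit <- function(spec, input_size = NULL, flops = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(input_size)) spec$input_size <- as.integer(input_size)
  rep <- count_costs(spec, flops = FALSE)
  bd <- rep$breakdown
  if (flops) bd$macs <- 2 * bd$macs
  unit <- if (flops) "FLOPs" else "MACs"
  cat(sprintf("%-28s %-10s %12s %14s %16s\n", "layer", "kind", "out CxHxW",
              "params", unit))
  for (r in seq_len(nrow(bd))) {
    cat(sprintf("%-28s %-10s %12s %14s %16s\n",
                substr(bd$name[r], 1, 28), bd$kind[r],
                sprintf("%dx%dx%d", bd$out_c[r], bd$out_h[r], bd$out_w[r]),
                format(bd$params[r], big.mark = ","),
                format(bd$macs[r], big.mark = ",")))
  }
  cat(sprintf("TOTAL  params = %s   %s = %s\n",
              format(rep$params, big.mark = ","), unit,
              format(sum(bd$macs), big.mark = ",")))
  attr(bd, "totals") <- list(params = rep$params, macs = rep$macs)
  invisible(bd)
}
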