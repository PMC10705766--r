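# Internal tensor engine.
#
# Feature maps are plain numeric arrays with dim c(H, W, C) (row, column,
# channel).  Every primitive is a mutable environment holding its weights,
# gradient buffers and forward caches; prim_forward()/prim_backward() dispatch
# on class.  Dense convolutions are evaluated as k^2 shifted GEMMs against the
# padded input, which keeps everything inside BLAS and gives an exact
# multiply count for the instrumented MAC counter.

.mac_env <- new.env(parent = emptyenv())
.mac_env$on <- FALSE
.mac_env$macs <- 0

mac_counter_start <- function() {
  .mac_env$on <- TRUE
  .mac_env$macs <- 0
  invisible(NULL)
}

mac_counter_stop <- function() {
  .mac_env$on <- FALSE
  .mac_env$macs
}

mac_tick <- function(n) {
  if (.mac_env$on) .mac_env$macs <- .mac_env$macs + n
  invisible(NULL)
}

# Standard output-size arithmetic shared by every convolution primitive.
conv_out_len <- function(len, k, stride, pad) {
  (len + 2L * pad - k) %/% stride + 1L
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

unpad_hw <- function(xp, pad, H, W) {
  if (pad == 0L) return(xp)
  xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

new_prim <- function(kind, cls) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  class(e) <- c(cls, "gd_prim")
  e
}

# Dense (fully-connected across channels) 2-D convolution, no bias unless
# followed by nothing (detection heads carry a bias).
prim_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE) {
  e <- new_prim("conv", "gd_conv")
  e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$k <- as.integer(k); e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  sd <- sqrt(2 / (k * k * cin))
  e$W <- array(stats::rnorm(k * k * cin * cout, sd = sd),
               dim = c(k, k, cin, cout))
  e$gW <- array(0, dim = dim(e$W))
  if (bias) {
    e$b <- numeric(cout)
    e$gb <- numeric(cout)
  }
  e
}

prim_forward <- function(e, x) UseMethod("prim_forward")
prim_backward <- function(e, g) UseMethod("prim_backward")

#' @export
prim_forward.gd_conv <- function(e, x) {
  d <- dim(x)
  stopifnot(d[3] == e$cin)
  H <- d[1]; W <- d[2]
  k <- e$k; s <- e$stride; p <- e$pad
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(W, k, s, p)
  xp <- pad_hw(x, p)
  oi <- seq.int(1L, by = s, length.out = Ho)
  oj <- seq.int(1L, by = s, length.out = Wo)
  out <- matrix(0, Ho * Wo, e$cout)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    xs <- xp[oi + (ki - 1L), oj + (kj - 1L), , drop = FALSE]
    dim(xs) <- c(Ho * Wo, e$cin)
    out <- out + xs %*% matrix(e$W[ki, kj, , ], e$cin, e$cout)
    mac_tick(Ho * Wo * e$cin * e$cout)
  }
  if (!is.null(e$b)) out <- sweep(out, 2L, e$b, "+")
  e$cache <- list(xp = xp, oi = oi, oj = oj, H = H, W = W, Ho = Ho, Wo = Wo)
  dim(out) <- c(Ho, Wo, e$cout)
  out
}

#' @export
prim_backward.gd_conv <- function(e, g) {
  cc <- e$cache
  k <- e$k; p <- e$pad
  gm <- g
  dim(gm) <- c(cc$Ho * cc$Wo, e$cout)
  gxp <- array(0, dim = dim(cc$xp))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    ii <- cc$oi + (ki - 1L); jj <- cc$oj + (kj - 1L)
    xs <- cc$xp[ii, jj, , drop = FALSE]
    dim(xs) <- c(cc$Ho * cc$Wo, e$cin)
    e$gW[ki, kj, , ] <- e$gW[ki, kj, , ] + crossprod(xs, gm)
    gx <- gm %*% t(matrix(e$W[ki, kj, , ], e$cin, e$cout))
    dim(gx) <- c(cc$Ho, cc$Wo, e$cin)
    gxp[ii, jj, ] <- gxp[ii, jj, ] + gx
  }
  if (!is.null(e$b)) e$gb <- e$gb + colSums(gm)
  unpad_hw(gxp, p, cc$H, cc$W)
}

# Depthwise convolution with channel multiplier `mult`: output channel
# (m-1)*C + c is the m-th filtered copy of input channel c.
prim_dwconv <- function(cin, k, stride = 1L, pad = (k - 1L) %/% 2L,
                        mult = 1L) {
  e <- new_prim("dwconv", "gd_dwconv")
  e$cin <- as.integer(cin); e$k <- as.integer(k)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$mult <- as.integer(mult)
  sd <- sqrt(2 / (k * k))
  e$W <- array(stats::rnorm(k * k * cin * mult, sd = sd),
               dim = c(k, k, cin, mult))
  e$gW <- array(0, dim = dim(e$W))
  e
}

#' @export
prim_forward.gd_dwconv <- function(e, x) {
  d <- dim(x)
  stopifnot(d[3] == e$cin)
  H <- d[1]; W <- d[2]; C <- e$cin
  k <- e$k; s <- e$stride; p <- e$pad
  Ho <- conv_out_len(H, k, s, p); Wo <- conv_out_len(W, k, s, p)
  xp <- pad_hw(x, p)
  out <- dw_conv_fwd_cpp(xp, dim(xp), e$W, dim(e$W), s, Ho, Wo)
  mac_tick(as.numeric(k)^2 * Ho * Wo * C * e$mult)
  e$cache <- list(xp = xp, H = H, W = W, Ho = Ho, Wo = Wo)
  dim(out) <- c(Ho, Wo, C * e$mult)
  out
}

#' @export
prim_backward.gd_dwconv <- function(e, g) {
  cc <- e$cache
  res <- dw_conv_bwd_cpp(cc$xp, dim(cc$xp), e$W, dim(e$W), g, e$stride,
                         cc$Ho, cc$Wo)
  gw <- res$gW
  dim(gw) <- dim(e$W)
  e$gW <- e$gW + gw
  gxp <- res$gxp
  dim(gxp) <- dim(cc$xp)
  unpad_hw(gxp, e$pad, cc$H, cc$W)
}

# Per-channel normalisation over the spatial extent of the current map, with
# learnable scale/shift.  mode = "identity" bypasses it entirely (used by the
# zero-weight shortcut identities and their tests).
prim_bn <- function(cn, mode = "bn", eps = 1e-5) {
  e <- new_prim("bn", "gd_bn")
  e$cn <- as.integer(cn)
  e$mode <- mode
  e$eps <- eps
  e$gamma <- rep(1, cn); e$beta <- rep(0, cn)
  e$ggamma <- numeric(cn); e$gbeta <- numeric(cn)
  e
}

#' @export
prim_forward.gd_bn <- function(e, x) {
  if (e$mode == "identity") return(x)
  d <- dim(x)
  N <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(N, d[3])
  mu <- .colMeans(xm, N, d[3])
  xc <- xm - rep(mu, each = N)
  va <- .colMeans(xc * xc, N, d[3])
  istd <- 1 / sqrt(va + e$eps)
  xhat <- xc * rep(istd, each = N)
  y <- xhat * rep(e$gamma, each = N) + rep(e$beta, each = N)
  e$cache <- list(xhat = xhat, istd = istd, N = N, d = d)
  dim(y) <- d
  y
}

#' @export
prim_backward.gd_bn <- function(e, g) {
  if (e$mode == "identity") return(g)
  cc <- e$cache
  N <- cc$N
  gm <- g
  dim(gm) <- c(N, cc$d[3])
  e$ggamma <- e$ggamma + .colSums(gm * cc$xhat, N, cc$d[3])
  e$gbeta <- e$gbeta + .colSums(gm, N, cc$d[3])
  dxhat <- gm * rep(e$gamma, each = N)
  s1 <- .colSums(dxhat, N, cc$d[3])
  s2 <- .colSums(dxhat * cc$xhat, N, cc$d[3])
  dx <- (dxhat - rep(s1 / N, each = N) -
           cc$xhat * rep(s2 / N, each = N)) * rep(cc$istd, each = N)
  dim(dx) <- cc$d
  dx
}

prim_silu <- function() new_prim("silu", "gd_silu")

#' @export
prim_forward.gd_silu <- function(e, x) {
  s <- 1 / (1 + exp(-x))
  e$cache <- list(x = x, s = s)
  x * s
}

#' @export
prim_backward.gd_silu <- function(e, g) {
  cc <- e$cache
  g * (cc$s * (1 + cc$x * (1 - cc$s)))
}

# Deterministic group-interleave channel permutation (reshape to
# groups x (c/groups), transpose, flatten).
shuffle_perm <- function(cn, groups) {
  if (cn %% groups != 0L)
    stop("channel_shuffle: `groups` (", groups,
         ") must divide the channel count (", cn, ")")
  # row-major reshape to groups x (c/groups), transpose, row-major flatten;
  # in column-major R that collapses to reading a (c/groups)-column matrix
  # row by row
  as.vector(t(matrix(seq_len(cn), ncol = groups)))
}

prim_shuffle <- function(cn, groups) {
  e <- new_prim("shuffle", "gd_shuffle")
  e$cn <- as.integer(cn)
  e$groups <- as.integer(groups)
  e$perm <- shuffle_perm(cn, groups)
  e$inv <- order(e$perm)
  e
}

#' @export
prim_forward.gd_shuffle <- function(e, x) x[, , e$perm, drop = FALSE]

#' @export
prim_backward.gd_shuffle <- function(e, g) g[, , e$inv, drop = FALSE]

prim_upsample <- function() new_prim("upsample", "gd_upsample")

#' @export
prim_forward.gd_upsample <- function(e, x) {
  d <- dim(x)
  e$cache <- d
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

#' @export
prim_backward.gd_upsample <- function(e, g) {
  d <- e$cache
  i1 <- seq.int(1L, 2L * d[1], by = 2L)
  j1 <- seq.int(1L, 2L * d[2], by = 2L)
  g[i1, j1, , drop = FALSE] + g[i1 + 1L, j1, , drop = FALSE] +
    g[i1, j1 + 1L, , drop = FALSE] + g[i1 + 1L, j1 + 1L, , drop = FALSE]
}

# ---- parameter bookkeeping ------------------------------------------------

prim_param_fields <- function(e) {
  switch(e$kind,
         conv = , dwconv = if (is.null(e$b)) c("W") else c("W", "b"),
         bn = c("gamma", "beta"),
         character(0))
}

prim_zero_grads <- function(e) {
  for (f in prim_param_fields(e)) {
    gf <- paste0("g", f)
    e[[gf]][] <- 0
  }
  invisible(NULL)
}

prim_zero_weights <- function(e) {
  for (f in prim_param_fields(e)) {
    if (f == "gamma") next  # scale stays 1; shift and kernels go to zero
    e[[f]][] <- 0
  }
  invisible(NULL)
}

prim_sgd_step <- function(e, lr, momentum) {
  for (f in prim_param_fields(e)) {
    gf <- paste0("g", f); vf <- paste0("v", f)
    if (is.null(e[[vf]])) e[[vf]] <- e[[gf]] * 0
    e[[vf]] <- momentum * e[[vf]] - lr * e[[gf]]
    e[[f]] <- e[[f]] + e[[vf]]
  }
  invisible(NULL)
}

prim_n_params <- function(e) {
  sum(vapply(prim_param_fields(e), function(f) length(e[[f]]), numeric(1)))
}
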