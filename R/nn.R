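# Compact neural-network engine backing the virtual-staining GAN.
#
# Tensors are column-major H x W x C x N arrays. Convolutions run through the
# C++ im2col/GEMM kernels; everything else (activations, pooling, nearest
# upsampling, channel concatenation, Adam) is plain vectorized R. Gradients
# are hand-derived per layer; there is no general autograd and none is
# needed for the two fixed architectures below.

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) return(structure(as.numeric(x), dim = c(d, 1L, 1L)))
  if (length(d) == 3L) return(structure(as.numeric(x), dim = c(d, 1L)))
  x
}

conv_layer <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = NULL, gain = 2) {
  pad <- pad %||% (k %/% 2L)
  fan_in <- k * k * in_ch
  list(w = matrix(rnorm(fan_in * out_ch, 0, sqrt(gain / fan_in)), fan_in, out_ch),
       b = numeric(out_ch), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

conv_fwd <- function(x, ly) .conv2d_fwd(x, ly$w, ly$b, ly$k, ly$k, ly$pad, ly$stride)

conv_bwd <- function(x, ly, dy, need_dx = TRUE)
  .conv2d_bwd(x, ly$w, dy, ly$k, ly$k, ly$pad, ly$stride, need_dx)

LRELU_SLOPE <- 0.1
lrelu <- function(x) .lrelu_fwd(x, LRELU_SLOPE)
lrelu_bwd <- function(dy, pre) .lrelu_bwd(dy, pre, LRELU_SLOPE)
pool2 <- function(x) .pool2_cpp(x)
pool2_bwd <- function(dy) .pool2_bwd_cpp(dy)
up2 <- function(x) .up2_cpp(x)
up2_bwd <- function(dy) .up2_bwd_cpp(dy)
cat_ch <- function(a, b) .cat_ch_cpp(a, b)
split_ch <- function(x, ca) .split_ch_cpp(x, ca)

# ---- U-Net generator --------------------------------------------------------

gen_init <- function(cfg) {
  L <- cfg$unet_levels; w0 <- cfg$base_width
  ch <- w0 * 2^(seq_len(L) - 1L)
  enc <- vector("list", L)
  inc <- cfg$in_channels
  for (l in seq_len(L)) {
    enc[[l]] <- conv_layer(inc, ch[l], 3L)
    inc <- ch[l]
  }
  dec <- vector("list", L - 1L)
  for (l in seq_len(L - 1L))
    dec[[l]] <- conv_layer(ch[l + 1L] + ch[l], ch[l], 3L)
  out <- conv_layer(ch[1L], cfg$out_channels, 1L, gain = 1)
  # start from a plausible bright field: bias at the blank-slide
  # transmittance level so early training fits structure, not global offset
  out$b[] <- 0.8
  list(enc = enc, dec = dec, out = out, levels = L)
}

gen_forward <- function(P, x) {
  L <- P$levels
  cache <- list(x = x, enc_in = vector("list", L), enc_pre = vector("list", L),
                skips = vector("list", L - 1L),
                dec_in = vector("list", L - 1L), dec_pre = vector("list", L - 1L))
  h <- x
  for (l in seq_len(L - 1L)) {
    cache$enc_in[[l]] <- h
    pre <- conv_fwd(h, P$enc[[l]])
    cache$enc_pre[[l]] <- pre
    a <- lrelu(pre)
    cache$skips[[l]] <- a
    h <- pool2(a)
  }
  cache$enc_in[[L]] <- h
  pre <- conv_fwd(h, P$enc[[L]])
  cache$enc_pre[[L]] <- pre
  h <- lrelu(pre)
  for (l in rev(seq_len(L - 1L))) {
    z <- cat_ch(up2(h), cache$skips[[l]])
    cache$dec_in[[l]] <- z
    pre <- conv_fwd(z, P$dec[[l]])
    cache$dec_pre[[l]] <- pre
    h <- lrelu(pre)
  }
  cache$out_in <- h
  y <- conv_fwd(h, P$out)
  list(y = y, cache = cache)
}

gen_backward <- function(P, cache, dy) {
  L <- P$levels
  g <- list(enc = vector("list", L), dec = vector("list", L - 1L), out = NULL)
  bw <- conv_bwd(cache$out_in, P$out, dy)
  g$out <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  dskip <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dpre <- lrelu_bwd(dh, cache$dec_pre[[l]])
    bw <- conv_bwd(cache$dec_in[[l]], P$dec[[l]], dpre)
    g$dec[[l]] <- list(w = bw$dw, b = bw$db)
    sp <- split_ch(bw$dx, dim(bw$dx)[3L] - dim(cache$skips[[l]])[3L])
    dskip[[l]] <- sp$b
    dh <- up2_bwd(sp$a)
  }
  dpre <- lrelu_bwd(dh, cache$enc_pre[[L]])
  bw <- conv_bwd(cache$enc_in[[L]], P$enc[[L]], dpre)
  g$enc[[L]] <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  for (l in rev(seq_len(L - 1L))) {
    da <- pool2_bwd(dh) + dskip[[l]]
    dpre <- lrelu_bwd(da, cache$enc_pre[[l]])
    bw <- conv_bwd(cache$enc_in[[l]], P$enc[[l]], dpre, need_dx = l > 1L)
    g$enc[[l]] <- list(w = bw$dw, b = bw$db)
    if (l > 1L) dh <- bw$dx
  }
  g
}

# ---- discriminator ----------------------------------------------------------

disc_init <- function(cfg) {
  w0 <- cfg$disc_width %||% cfg$base_width
  ch_in <- cfg$out_channels
  layers <- vector("list", 5L)
  for (l in 1:5) {
    ch_out <- w0 * 2^(min(l, 4L) - 1L)
    layers[[l]] <- conv_layer(ch_in, ch_out, 3L, stride = 2L)
    ch_in <- ch_out
  }
  head <- conv_layer(ch_in, 1L, 1L, gain = 1)
  list(layers = layers, head = head)
}

disc_forward <- function(D, x) {
  cache <- list(ins = vector("list", 5L), pres = vector("list", 5L))
  h <- x
  for (l in 1:5) {
    cache$ins[[l]] <- h
    pre <- conv_fwd(h, D$layers[[l]])
    cache$pres[[l]] <- pre
    h <- lrelu(pre)
  }
  cache$head_in <- h
  z <- conv_fwd(h, D$head)
  d <- dim(z)
  zm <- apply(z, 4L, mean)
  s <- 1 / (1 + exp(-zm))
  cache$z_dim <- d; cache$s <- s
  list(s = s, cache = cache)
}

disc_backward <- function(D, cache, ds, need_dx = FALSE) {
  d <- cache$z_dim; s <- cache$s
  per <- ds * s * (1 - s) / (d[1L] * d[2L])
  dz <- array(rep(per, each = d[1L] * d[2L] * d[3L]), dim = d)
  g <- list(layers = vector("list", 5L), head = NULL)
  bw <- conv_bwd(cache$head_in, D$head, dz)
  g$head <- list(w = bw$dw, b = bw$db)
  dh <- bw$dx
  for (l in 5:1) {
    dpre <- lrelu_bwd(dh, cache$pres[[l]])
    bw <- conv_bwd(cache$ins[[l]], D$layers[[l]], dpre, need_dx = need_dx || l > 1L)
    g$layers[[l]] <- list(w = bw$dw, b = bw$db)
    if (l > 1L || need_dx) dh <- bw$dx
  }
  list(grads = g, dx = if (need_dx) dh else NULL)
}

# ---- parameter-tree utilities and Adam --------------------------------------

# Flatten parameter tree into a named list of arrays (layers only).
tree_leaves <- function(tree, path = "") {
  if (is.list(tree) && !is.null(tree$w) && is.numeric(tree$w))
    return(stats::setNames(list(tree$w, tree$b), paste0(path, c(".w", ".b"))))
  if (is.list(tree)) {
    out <- list()
    idx <- names(tree) %||% as.character(seq_along(tree))
    for (i in seq_along(tree)) {
      if (!is.list(tree[[i]])) next
      out <- c(out, tree_leaves(tree[[i]], paste0(path, "/", idx[i])))
    }
    return(out)
  }
  list()
}

adam_init <- function(params) {
  leaves <- tree_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  pl <- tree_leaves(params)
  gl <- tree_leaves(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in seq_along(pl)) {
    g <- gl[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    pl[[k]] <- pl[[k]] - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = tree_rebuild(params, pl), state = state)
}

tree_rebuild <- function(tree, leaves) {
  env <- new.env(); env$i <- 0L
  rebuild <- function(t) {
    if (is.list(t) && !is.null(t$w) && is.numeric(t$w)) {
      env$i <- env$i + 1L; t$w <- leaves[[env$i]]
      env$i <- env$i + 1L; t$b <- leaves[[env$i]]
      return(t)
    }
    if (is.list(t)) {
      for (i in seq_along(t)) if (is.list(t[[i]])) t[[i]] <- rebuild(t[[i]])
      return(t)
    }
    t
  }
  rebuild(tree)
}
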