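#' @useDynLib vistain, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm fft mvfft median optim quantile rnorm runif sd var
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < min || x > max)
    stop_field(field, sprintf("must be in [%s, %s]", format(min), format(max)))
  invisible(x)
}

check_image <- function(x, field = "image", channels = NULL) {
  if (!is.numeric(x) || !(length(dim(x)) %in% c(2L, 3L)))
    stop_field(field, "must be a numeric matrix or H x W x C array")
  if (any(!is.finite(x)))
    stop_field(field, "contains non-finite pixels")
  if (!is.null(channels)) {
    nc <- if (length(dim(x)) == 3L) dim(x)[3L] else 1L
    if (nc != channels)
      stop_field(field, sprintf("must have %d channel(s), has %d", channels, nc))
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)", what,
                 paste(dim(a) %||% length(a), collapse = "x"),
                 paste(dim(b) %||% length(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Luminance of an RGB image
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`. Grayscale input is returned
#' unchanged.
#' @param img numeric matrix or H x W x 3 array in any intensity scale.
#' @return numeric matrix.
#' @export
luminance <- function(img) {
  if (length(dim(img)) == 2L || is.null(dim(img))) return(as.matrix(img))
  check_image(img, "img", channels = 3L)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

each_channel <- function(img, f) {
  if (length(dim(img)) == 2L) return(f(img))
  out <- img
  for (c in seq_len(dim(img)[3L])) out[, , c] <- f(img[, , c])
  out
}

nchannels <- function(img) if (length(dim(img)) == 3L) dim(img)[3L] else 1L

channel_medians <- function(img) {
  if (length(dim(img)) == 2L) return(median(img))
  apply(img, 3L, median)
}

# Exact Gaussian smoothing along one axis of a matrix using the symmetric
# (mirror) extension: circular FFT convolution on the doubled signal equals
# convolution of the infinite mirror extension, for any sigma.
gauss_blur_axis <- function(X, sigma) {
  n <- nrow(X)
  if (n == 1L) return(X)
  m <- 2L * n
  d <- c(0:(n - 1L), -(n:1L))
  k <- dnorm(d, sd = sigma)
  k <- k / sum(k)
  K <- fft(k)
  X2 <- rbind(X, X[n:1L, , drop = FALSE])
  Y2 <- Re(mvfft(mvfft(X2) * K, inverse = TRUE)) / m
  Y2[seq_len(n), , drop = FALSE]
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian filter with symmetric (mirror) boundary handling,
#' computed exactly for arbitrary kernel widths via FFT on the mirror-extended
#' signal. Multi-channel images are filtered per channel.
#'
#' @param img numeric matrix or H x W x C array.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return smoothed image, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  check_number(sigma, "sigma")
  if (sigma <= 0) stop_field("sigma", "must be > 0")
  check_image(img, "img")
  each_channel(img, function(ch) {
    ch <- gauss_blur_axis(ch, sigma)
    t(gauss_blur_axis(t(ch), sigma))
  })
}

# 2x2 average downsample (dims must be even-truncated).
downsample2 <- function(img) {
  f <- function(ch) {
    H <- 2L * (nrow(ch) %/% 2L); W <- 2L * (ncol(ch) %/% 2L)
    ch <- ch[seq_len(H), seq_len(W), drop = FALSE]
    oi <- seq(1L, H, by = 2L); oj <- seq(1L, W, by = 2L)
    (ch[oi, oj, drop = FALSE] + ch[oi + 1L, oj, drop = FALSE] +
       ch[oi, oj + 1L, drop = FALSE] + ch[oi + 1L, oj + 1L, drop = FALSE]) / 4
  }
  each_channel2 <- function(img, f) {
    if (length(dim(img)) == 2L) return(f(img))
    slices <- lapply(seq_len(dim(img)[3L]), function(c) f(img[, , c]))
    array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
  }
  each_channel2(img, f)
}

decimate <- function(img, factor) {
  if (factor <= 1L) return(img)
  n <- as.integer(round(log2(factor)))
  for (i in seq_len(n)) img <- downsample2(img)
  img
}

# Bilinear resize of a matrix to (H, W) treating pixels as cell centers.
resize_bilinear <- function(ch, H, W) {
  h0 <- nrow(ch); w0 <- ncol(ch)
  if (h0 == H && w0 == W) return(ch)
  si <- if (H == 1L) rep((h0 - 1) / 2, 1L) else (seq_len(H) - 1) * (h0 - 1) / (H - 1)
  sj <- if (W == 1L) rep((w0 - 1) / 2, 1L) else (seq_len(W) - 1) * (w0 - 1) / (W - 1)
  i0 <- pmin(floor(si), h0 - 2); i0[i0 < 0] <- 0
  j0 <- pmin(floor(sj), w0 - 2); j0[j0 < 0] <- 0
  if (h0 == 1L) i0 <- rep(0, H)
  if (w0 == 1L) j0 <- rep(0, W)
  a <- si - i0; b <- sj - j0
  i1 <- pmin(i0 + 1, h0 - 1); j1 <- pmin(j0 + 1, w0 - 1)
  A00 <- ch[cbind(rep(i0 + 1, W), rep(j0 + 1, each = H))]
  A10 <- ch[cbind(rep(i1 + 1, W), rep(j0 + 1, each = H))]
  A01 <- ch[cbind(rep(i0 + 1, W), rep(j1 + 1, each = H))]
  A11 <- ch[cbind(rep(i1 + 1, W), rep(j1 + 1, each = H))]
  wa <- rep(a, W); wb <- rep(b, each = H)
  matrix((1 - wa) * (1 - wb) * A00 + wa * (1 - wb) * A10 +
           (1 - wa) * wb * A01 + wa * wb * A11, H, W)
}
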