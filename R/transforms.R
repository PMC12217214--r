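#' Geometric transforms between image grids
#'
#' Three transform classes describe the geometric relationship between a
#' *fixed* image grid and a *moving* image:
#'
#' * `rigid_transform(rotation, shift)` — a rotation (degrees, about the image
#'   center) followed by a translation `(drow, dcol)` in pixels, describing the
#'   *content motion* that carries the fixed image onto the moving image.
#' * `affine_transform(matrix)` — a 2 x 3 matrix mapping fixed-frame pixel
#'   coordinates `(row, col)` (0-based, pixel-centered) to moving-frame sample
#'   coordinates: `q = M %*% c(p, 1)`.
#' * `displacement_field(u, v)` — a dense pull-back field:
#'   `output(p) = input(p + d(p))` with `d = (u, v)` in pixels.
#'
#' [warp()] applies a transform; `warp(moving, register_*(fixed, moving))`
#' aligns the moving image onto the fixed grid for affine and displacement
#' fields, while rigid transforms describe the forward motion and are aligned
#' with `warp(moving, invert_transform(tf))`.
#'
#' @param rotation rotation angle in degrees (counter-clockwise about the
#'   image center in (row, col) axes).
#' @param shift numeric length-2 translation `(drow, dcol)` in pixels.
#' @param correlation_score optional normalized correlation at the optimum.
#' @return an object of class `rigid_transform`, `affine_transform` or
#'   `displacement_field`.
#' @name transforms
NULL

#' @rdname transforms
#' @export
rigid_transform <- function(rotation = 0, shift = c(0, 0), correlation_score = NA_real_) {
  check_number(rotation, "rotation")
  if (length(shift) != 2L || any(!is.finite(shift)))
    stop_field("shift", "must be two finite numbers (drow, dcol)")
  structure(list(rotation = rotation, shift = as.numeric(shift),
                 correlation_score = correlation_score),
            class = "rigid_transform")
}

#' @rdname transforms
#' @param matrix 2 x 3 numeric matrix `[M | t]`.
#' @export
affine_transform <- function(matrix = cbind(diag(2), c(0, 0))) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(2L, 3L)) || any(!is.finite(matrix)))
    stop_field("matrix", "must be a finite 2 x 3 matrix")
  if (abs(det(matrix[, 1:2])) <= 1e-6)
    stop_field("matrix", "linear part is singular (|det| <= 1e-6)")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @rdname transforms
#' @param u,v numeric matrices of per-pixel row/col displacements.
#' @param block_grid optional coarse grid the field was estimated on.
#' @param confidence optional per-block correlation peak values.
#' @export
displacement_field <- function(u, v, block_grid = NULL, confidence = NULL) {
  check_same_shape(u, v, "u and v")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop_field("u/v", "field contains non-finite displacements")
  structure(list(u = u, v = v, block_grid = block_grid, confidence = confidence),
            class = "displacement_field")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# Pull-back affine map equivalent to applying the content motion of `tf`
# on an H x W grid: out(p) = img(R(-theta) (p - c - s) + c).
rigid_pullback_matrix <- function(tf, dims) {
  ctr <- (dims[1:2] - 1) / 2
  R <- rot2(-tf$rotation)
  t0 <- ctr - R %*% (ctr + tf$shift)
  cbind(R, t0)
}

#' Invert a geometric transform
#'
#' Rigid and affine transforms are inverted in closed form; displacement
#' fields numerically by fixed-point iteration on
#' `e(p) = -d(p + e(p))`.
#' @param tf a transform object.
#' @param iterations fixed-point iterations for displacement fields.
#' @return transform of the same class.
#' @export
invert_transform <- function(tf, iterations = 20L) {
  if (inherits(tf, "rigid_transform")) {
    R <- rot2(-tf$rotation)
    return(rigid_transform(-tf$rotation, as.numeric(-R %*% tf$shift)))
  }
  if (inherits(tf, "affine_transform")) {
    M <- tf$matrix[, 1:2]; t0 <- tf$matrix[, 3L]
    Mi <- solve(M)
    return(affine_transform(cbind(Mi, -Mi %*% t0)))
  }
  if (inherits(tf, "displacement_field")) {
    u <- tf$u * 0; v <- tf$v * 0
    for (k in seq_len(iterations)) {
      du <- sample_field(tf$u, u, v)
      dv <- sample_field(tf$v, u, v)
      u <- -du; v <- -dv
    }
    return(displacement_field(u, v))
  }
  stop("not a transform object", call. = FALSE)
}

# Sample matrix `m` at (i + u, j + v), clamped bilinear.
sample_field <- function(m, u, v) {
  out <- .warp_field_cpp(structure(as.numeric(m), dim = c(dim(m), 1L)),
                         u, v, fill = 0)
  # clamp instead of fill: re-sample out-of-range at border
  H <- nrow(m); W <- ncol(m)
  ii <- row(m) - 1 + u; jj <- col(m) - 1 + v
  bad <- ii < 0 | ii > H - 1 | jj < 0 | jj > W - 1
  if (any(bad)) {
    ic <- pmin(pmax(ii, 0), H - 1); jc <- pmin(pmax(jj, 0), W - 1)
    outm <- matrix(out, H, W)
    outm[bad] <- m[cbind(floor(ic[bad]) + 1, floor(jc[bad]) + 1)]
    return(outm)
  }
  matrix(out, H, W)
}

#' Compose two transforms
#'
#' Returns the transform whose single application equals
#' `warp(warp(img, a), b)` (for pull-back affine maps this is the matrix
#' product `a(b(p))`; for displacement fields,
#' `d(p) = d_b(p) + d_a(p + d_b(p))`).
#' @param a,b affine transforms or displacement fields (same class).
#' @return composed transform.
#' @export
compose_transforms <- function(a, b) {
  if (inherits(a, "affine_transform") && inherits(b, "affine_transform")) {
    Ma <- a$matrix[, 1:2]; ta <- a$matrix[, 3L]
    Mb <- b$matrix[, 1:2]; tb <- b$matrix[, 3L]
    return(affine_transform(cbind(Ma %*% Mb, Ma %*% tb + ta)))
  }
  if (inherits(a, "displacement_field") && inherits(b, "displacement_field")) {
    u <- b$u + sample_field(a$u, b$u, b$v)
    v <- b$v + sample_field(a$v, b$u, b$v)
    return(displacement_field(u, v))
  }
  stop("compose_transforms() requires two transforms of the same class",
       call. = FALSE)
}

#' Resample an image under a geometric transform
#'
#' Bilinear interpolation; samples falling outside the canvas are filled with
#' the per-channel median (a proxy for blank slide/glass) unless `fill` is
#' given. Rigid transforms are applied as content motion (rotate about center,
#' then translate); affine transforms and displacement fields are applied in
#' the pull-back convention (`out(p) = img(M p + t)` and
#' `out(p) = img(p + d(p))`).
#'
#' @param img numeric matrix or H x W x C array.
#' @param tf a transform from [transforms].
#' @param fill per-channel fill value(s); default: per-channel median.
#' @return warped image, same shape.
#' @export
warp <- function(img, tf, fill = NULL) {
  check_image(img, "img")
  fill <- fill %||% channel_medians(img)
  dims <- dim(img) %||% c(length(img), 1L)
  H <- dims[1L]; W <- dims[2L]
  if (inherits(tf, "rigid_transform")) {
    if (tf$rotation == 0 && all(tf$shift == round(tf$shift))) {
      return(shift_integer(img, tf$shift, fill))
    }
    M <- rigid_pullback_matrix(tf, dims)
  } else if (inherits(tf, "affine_transform")) {
    M <- tf$matrix
  } else if (inherits(tf, "displacement_field")) {
    if (any(!is.finite(tf$u)) || any(!is.finite(tf$v)))
      stop("displacement field contains non-finite values", call. = FALSE)
    check_same_shape(tf$u, if (length(dims) == 3L) img[, , 1L] else img,
                     "field and image")
    x <- if (length(dims) == 2L) structure(as.numeric(img), dim = c(H, W, 1L)) else img
    out <- .warp_field_cpp(x, tf$u, tf$v, as.numeric(fill))
    if (length(dims) == 2L) out <- matrix(out, H, W)
    return(out)
  } else stop("`tf` is not a transform object", call. = FALSE)
  p <- cbind(rep(seq_len(H) - 1, W), rep(seq_len(W) - 1, each = H))
  q <- p %*% t(M[, 1:2]) + rep(1, H * W) %*% t(M[, 3L])
  u <- matrix(q[, 1L] - p[, 1L], H, W)
  v <- matrix(q[, 2L] - p[, 2L], H, W)
  x <- if (length(dims) == 2L) structure(as.numeric(img), dim = c(H, W, 1L)) else img
  out <- .warp_field_cpp(x, u, v, as.numeric(fill))
  if (length(dims) == 2L) out <- matrix(out, H, W)
  out
}

# Exact integer-shift translation (no interpolation): content moves by `shift`.
shift_integer <- function(img, shift, fill) {
  f <- function(ch, fl) {
    H <- nrow(ch); W <- ncol(ch)
    out <- matrix(fl, H, W)
    dr <- shift[1L]; dc <- shift[2L]
    ri <- seq_len(H); ci <- seq_len(W)
    rdst <- ri + dr; cdst <- ci + dc
    ok_r <- rdst >= 1 & rdst <= H; ok_c <- cdst >= 1 & cdst <= W
    out[rdst[ok_r], cdst[ok_c]] <- ch[ri[ok_r], ci[ok_c]]
    out
  }
  if (length(dim(img)) == 2L) return(f(img, fill[1L]))
  out <- img
  for (c in seq_len(dim(img)[3L])) out[, , c] <- f(img[, , c], fill[(c - 1L) %% length(fill) + 1L])
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation %.3f deg, shift (%.3f, %.3f), corr %.4f\n",
              x$rotation, x$shift[1L], x$shift[2L], x$correlation_score))
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n"); print(round(x$matrix, 6)); invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<displacement_field> %d x %d, |d| median %.3f px, max %.3f px\n",
              nrow(x$u), ncol(x$u), median(mag), max(mag)))
  invisible(x)
}
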