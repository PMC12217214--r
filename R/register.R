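#' Convert a bright-field image to a registration proxy
#'
#' Registration correlates the two modalities through `1 - luminance` of the
#' stained bright-field image: dark, absorbing tissue becomes bright, matching
#' autofluorescent tissue on a dark background.
#' @param bf H x W x 3 RGB image in `[0, 1]`, or a grayscale matrix.
#' @return single-channel matrix in `[0, 1]`.
#' @export
bf_to_proxy <- function(bf) {
  check_image(bf, "bf")
  1 - luminance(bf)
}

# Cross-correlation of two same-size matrices with zero padding (no circular
# wrap). Returns the integer shift d maximizing sum_p f(p) m(p + d) within
# |d| <= max_shift, plus the normalized correlation there.
xcorr_peak <- function(f, m, max_shift) {
  H <- nrow(f); W <- ncol(f)
  f0 <- f - mean(f); m0 <- m - mean(m)
  nf <- sqrt(sum(f0^2)); nm <- sqrt(sum(m0^2))
  if (nf < 1e-12 || nm < 1e-12) return(NULL)
  P <- 2L * H; Q <- 2L * W
  fp <- matrix(0, P, Q); fp[seq_len(H), seq_len(W)] <- f0
  mp <- matrix(0, P, Q); mp[seq_len(H), seq_len(W)] <- m0
  cc <- Re(fft(Conj(fft(fp)) * fft(mp), inverse = TRUE)) / (P * Q)
  dr <- seq(-max_shift[1L], max_shift[1L])
  dc <- seq(-max_shift[2L], max_shift[2L])
  sub <- cc[(dr %% P) + 1L, (dc %% Q) + 1L, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)
  # deterministic tie-break: smallest |shift|, then row-major order
  if (nrow(best) > 1L) {
    mag <- abs(dr[best[, 1L]]) + abs(dc[best[, 2L]])
    best <- best[order(mag, best[, 1L], best[, 2L])[1L], , drop = FALSE]
  }
  list(shift = c(dr[best[1L, 1L]], dc[best[1L, 2L]]),
       score = max(sub) / (nf * nm),
       sub = sub, dr = dr, dc = dc, i = best[1L, 1L], j = best[1L, 2L])
}

#' Rigid WSI registration by exhaustive rotation search
#'
#' For every angle on `angle_grid` the fixed image is rotated by that angle
#' and correlated against the moving image in the frequency domain
#' (mean-subtracted, zero-padded); the `(angle, shift)` pair with the highest
#' normalized cross-correlation wins. Ties break to the smallest `|angle|`,
#' then the smallest `|shift|`. The returned transform describes the content
#' motion from the fixed to the moving frame, so
#' `warp(moving, invert_transform(tf))` aligns the moving image.
#'
#' @param fixed_proxy,moving_proxy same-size single-channel images (use
#'   [bf_to_proxy()] for the stained side).
#' @param angle_grid candidate rotations in degrees.
#' @param max_shift largest shift searched, px (default 25% of the smaller
#'   image side).
#' @return a [rigid_transform()] with its `correlation_score`.
#' @export
register_rigid <- function(fixed_proxy, moving_proxy,
                           angle_grid = seq(-10, 10, by = 0.5),
                           max_shift = NULL) {
  check_image(fixed_proxy, "fixed_proxy"); check_image(moving_proxy, "moving_proxy")
  check_same_shape(fixed_proxy, moving_proxy)
  if (length(angle_grid) < 1L) stop_field("angle_grid", "must be non-empty")
  if (sd(fixed_proxy) < 1e-12 || sd(moving_proxy) < 1e-12)
    stop("no texture: constant image cannot be registered", call. = FALSE)
  ms <- max_shift %||% floor(min(dim(fixed_proxy)) / 4)
  ms <- rep(as.integer(ms), length.out = 2L)
  # search smallest |angle| first so strict ">" implements the tie-break
  grid <- angle_grid[order(abs(angle_grid), angle_grid)]
  best <- NULL
  for (ang in grid) {
    rot_fixed <- if (ang == 0) fixed_proxy else
      warp(fixed_proxy, rigid_transform(ang, c(0, 0)))
    pk <- xcorr_peak(rot_fixed, moving_proxy, ms)
    if (is.null(pk)) next
    if (is.null(best) || pk$score > best$score + 1e-12)
      best <- list(angle = ang, shift = pk$shift, score = pk$score)
  }
  if (is.null(best)) stop("no texture: correlation undefined", call. = FALSE)
  rigid_transform(best$angle, best$shift, correlation_score = best$score)
}

# --- mutual information ------------------------------------------------------

# Joint histogram with bilinear (partial-volume style) bin interpolation.
mutual_information <- function(a, b, bins = 64L, ra = range(a), rb = range(b)) {
  ba <- (as.vector(a) - ra[1L]) / max(ra[2L] - ra[1L], 1e-12) * (bins - 1L)
  bb <- (as.vector(b) - rb[1L]) / max(rb[2L] - rb[1L], 1e-12) * (bins - 1L)
  ba <- pmin(pmax(ba, 0), bins - 1L); bb <- pmin(pmax(bb, 0), bins - 1L)
  i0 <- pmin(floor(ba), bins - 2L); j0 <- pmin(floor(bb), bins - 2L)
  fa <- ba - i0; fb <- bb - j0
  h <- numeric(bins * bins)
  acc <- function(ii, jj, w) {
    idx <- ii + bins * jj + 1L
    s <- rowsum(w, idx)
    h[as.integer(rownames(s))] <<- h[as.integer(rownames(s))] + s[, 1L]
  }
  acc(i0, j0, (1 - fa) * (1 - fb))
  acc(i0 + 1L, j0, fa * (1 - fb))
  acc(i0, j0 + 1L, (1 - fa) * fb)
  acc(i0 + 1L, j0 + 1L, fa * fb)
  p <- h / sum(h)
  P <- matrix(p, bins, bins)
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (px[row(P)[nz]] * py[col(P)[nz]])))
}

affine_from_params <- function(par, dims) {
  ctr <- (dims[1:2] - 1) / 2
  L <- rot2(par[1L]) %*% diag(exp(par[2:3])) %*% matrix(c(1, 0, par[4L], 1), 2L, 2L)
  affine_transform(cbind(L, ctr + par[5:6] - L %*% ctr))
}

#' Multimodal affine registration by mutual-information maximization
#'
#' Optimizes 6 affine parameters (rotation, log-scales, shear, shifts; all
#' anchored at the image center) with a derivative-free simplex search in a
#' multi-resolution cascade (4x, 2x, 1x). The similarity is the mutual
#' information of a 64-bin joint histogram with bilinear bin interpolation,
#' which needs no intensity relationship between the modalities. If the
#' optimum does not improve on the identity, the identity transform is
#' returned with attribute `warning = "no improvement"`.
#'
#' @param fixed_fov,moving_fov same-shape single-channel images with non-zero
#'   variance.
#' @param cfg list of optional settings: `bins` (64), `scales` (`c(4,2,1)`),
#'   `maxit` per scale (300), `restarts` at the finest scale (1).
#' @return an [affine_transform()] mapping fixed-frame to moving-frame
#'   coordinates, with attributes `mi` (final value) and `mi_identity`.
#' @export
register_affine <- function(fixed_fov, moving_fov, cfg = list()) {
  check_image(fixed_fov, "fixed_fov"); check_image(moving_fov, "moving_fov")
  check_same_shape(fixed_fov, moving_fov)
  if (sd(fixed_fov) < 1e-12 || sd(moving_fov) < 1e-12)
    stop("zero-variance image cannot be registered", call. = FALSE)
  bins <- cfg$bins %||% 64L
  scales <- cfg$scales %||% c(4L, 2L, 1L)
  maxit <- cfg$maxit %||% 300L
  fillm <- median(moving_fov)
  par <- rep(0, 6L)
  first <- TRUE
  for (s in scales) {
    fs <- decimate(fixed_fov, s); msc <- decimate(moving_fov, s)
    rb <- range(msc)
    obj <- function(p) {
      tf <- affine_from_params(p, dim(fs))
      w <- warp(msc, tf, fill = fillm)
      -mutual_information(fs, w, bins = bins, rb = rb)
    }
    p0 <- par; p0[5:6] <- p0[5:6] / s
    starts <- list(p0)
    if (first) {
      # translation pre-alignment by cross-correlation guards the simplex
      # against starting in the wrong basin for larger shifts; both proxies
      # show tissue bright on a dark background, so the peak is informative
      # even across modalities
      pk <- xcorr_peak(fs, msc, rep(ceiling(nrow(fs) / 4), 2L))
      if (!is.null(pk)) {
        p1 <- p0; p1[5:6] <- pk$shift
        starts <- c(starts, list(p1))
      }
      first <- FALSE
    }
    res <- NULL
    for (st in starts) {
      cand <- optim(st, obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-8,
                                   parscale = c(0.5, 0.01, 0.01, 0.01, 1, 1)))
      if (is.null(res) || cand$value < res$value) res <- cand
    }
    if (s == min(scales)) {
      for (r in seq_len(cfg$restarts %||% 1L)) {
        res2 <- optim(res$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9,
                                     parscale = c(0.1, 0.003, 0.003, 0.003, 0.3, 0.3)))
        if (res2$value < res$value) res <- res2
      }
    }
    par <- res$par; par[5:6] <- par[5:6] * s
  }
  tf <- affine_from_params(par, dim(fixed_fov))
  rb <- range(moving_fov)
  mi_id <- mutual_information(fixed_fov, moving_fov, bins = bins, rb = rb)
  mi_fin <- mutual_information(fixed_fov, warp(moving_fov, tf, fill = fillm),
                               bins = bins, rb = rb)
  if (mi_fin < mi_id) {
    tf <- affine_transform()
    attr(tf, "warning") <- "no improvement over identity"
    mi_fin <- mi_id
  }
  attr(tf, "mi") <- mi_fin
  attr(tf, "mi_identity") <- mi_id
  tf
}

# --- elastic pyramid block matching -----------------------------------------

# Per-block shift with subpixel parabolic refinement.
block_shift <- function(fb, mb, max_shift) {
  pk <- xcorr_peak(fb, mb, c(max_shift, max_shift))
  if (is.null(pk)) return(NULL)
  refine <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < 1e-12) return(0)
    d <- 0.5 * (cm1 - cp1) / den
    max(min(d, 0.5), -0.5)
  }
  i <- pk$i; j <- pk$j
  ddr <- if (i > 1L && i < nrow(pk$sub))
    refine(pk$sub[i - 1L, j], pk$sub[i, j], pk$sub[i + 1L, j]) else 0
  ddc <- if (j > 1L && j < ncol(pk$sub))
    refine(pk$sub[i, j - 1L], pk$sub[i, j], pk$sub[i, j + 1L]) else 0
  list(shift = pk$shift + c(ddr, ddc), conf = pk$score)
}

#' Elastic registration by pyramid block cross-correlation
#'
#' Coarse-to-fine dense registration of two same-modality images: at each
#' level the images are tiled into overlapping blocks, each block's shift is
#' estimated from the normalized cross-correlation peak with subpixel
#' parabolic refinement, low-confidence blocks (peak below
#' `conf_threshold`) are infilled from accepted neighbors, the block-grid
#' shifts are interpolated to a dense smooth field, and the field is composed
#' with the coarser levels' result. The moving image is always re-warped from
#' the original with the composed field, so interpolation error does not
#' accumulate.
#'
#' @param fixed,moving same-shape single-channel images in the same
#'   (bright-field proxy) modality.
#' @param levels number of pyramid levels used from `block_sizes`.
#' @param block_sizes block side per level, px, coarse to fine.
#' @param overlap fractional block overlap in `[0, 0.75]`.
#' @param conf_threshold minimum normalized correlation peak to accept a
#'   block.
#' @param amplitude_cap largest admissible displacement magnitude, px.
#' @param iters_per_level estimate/warp/re-estimate passes per level (block
#'   matching recovers an attenuated estimate of any displacement that varies
#'   within a block, so each pass corrects a fraction of the residual;
#'   iteration converges geometrically). A pass that changes the field by
#'   less than 0.1 px (median) ends the level early.
#' @return a [displacement_field()] `d` such that `warp(moving, d)` aligns
#'   the moving image onto the fixed grid; per-block confidences of the
#'   finest level are attached.
#' @export
register_elastic <- function(fixed, moving, levels = 4L,
                             block_sizes = c(256L, 128L, 64L, 32L), overlap = 0.5,
                             conf_threshold = 0.3, amplitude_cap = 10,
                             iters_per_level = 3L) {
  check_image(fixed, "fixed"); check_image(moving, "moving")
  check_same_shape(fixed, moving)
  check_number(overlap, "overlap", min = 0, max = 0.75)
  H <- nrow(fixed); W <- ncol(fixed)
  sizes <- head(block_sizes, levels)
  sizes <- pmin(sizes, min(H, W))
  total <- displacement_field(matrix(0, H, W), matrix(0, H, W))
  any_ok <- FALSE
  confs <- NULL
  grid <- NULL
  for (bs in sizes) {
    stride <- max(1L, as.integer(round(bs * (1 - overlap))))
    r0 <- unique(pmin(seq(1L, max(1L, H - bs + 1L), by = stride), H - bs + 1L))
    c0 <- unique(pmin(seq(1L, max(1L, W - bs + 1L), by = stride), W - bs + 1L))
    max_shift <- max(2L, min(bs %/% 4L, ceiling(amplitude_cap)))
    for (it in seq_len(iters_per_level)) {
      warped <- warp(moving, total)
      gu <- matrix(NA_real_, length(r0), length(c0))
      gv <- gu; gc <- gu
      for (a in seq_along(r0)) for (b in seq_along(c0)) {
        fb <- fixed[r0[a] + seq_len(bs) - 1L, c0[b] + seq_len(bs) - 1L]
        mb <- warped[r0[a] + seq_len(bs) - 1L, c0[b] + seq_len(bs) - 1L]
        est <- block_shift(fb, mb, max_shift)
        if (is.null(est) || est$conf < conf_threshold) { gc[a, b] <- est$conf %||% 0; next }
        # correlation found fixed-block content displaced by `shift` in the
        # moving block: the pull-back correction samples moving at p + shift
        gu[a, b] <- est$shift[1L]; gv[a, b] <- est$shift[2L]
        gc[a, b] <- est$conf
        any_ok <- TRUE
      }
      if (all(is.na(gu))) {
        if (!any_ok && bs == sizes[length(sizes)])
          stop("untextured pair: all blocks below confidence threshold", call. = FALSE)
        break
      }
      gu <- infill_grid(gu); gv <- infill_grid(gv)
      # anchor the grid estimates at the block centers (0-based coordinates)
      inc_u <- interp_grid(gu, r0 - 1 + (bs - 1) / 2, c0 - 1 + (bs - 1) / 2, H, W)
      inc_v <- interp_grid(gv, r0 - 1 + (bs - 1) / 2, c0 - 1 + (bs - 1) / 2, H, W)
      sm <- max(1, bs / 8)
      inc_u <- gaussian_blur(inc_u, sm); inc_v <- gaussian_blur(inc_v, sm)
      # an increment this small is sub-pixel estimation noise, not signal:
      # composing it would only accumulate drift (e.g. on identical inputs)
      if (median(sqrt(inc_u^2 + inc_v^2)) < 0.1) break
      total <- compose_transforms(total, displacement_field(inc_u, inc_v))
      mag <- sqrt(total$u^2 + total$v^2)
      over <- mag > amplitude_cap
      if (any(over)) {
        scl <- amplitude_cap / mag[over]
        total$u[over] <- total$u[over] * scl
        total$v[over] <- total$v[over] * scl
      }
      confs <- gc
      grid <- list(rows = r0, cols = c0)
    }
  }
  displacement_field(total$u, total$v, block_grid = grid, confidence = confs)
}

# Bilinear interpolation of values `g` anchored at coordinates
# (anchors_r, anchors_c) onto a dense H x W grid (0-based pixel coords);
# constant extrapolation beyond the outermost anchors. Separable:
# F = Ar %*% g %*% t(Ac) with per-axis bilinear weight matrices.
interp_grid <- function(g, anchors_r, anchors_c, H, W) {
  axis_weights <- function(n, anchors) {
    m <- length(anchors)
    A <- matrix(0, n, m)
    x <- seq_len(n) - 1
    if (m == 1L) { A[, 1L] <- 1; return(A) }
    k <- findInterval(x, anchors, all.inside = TRUE)
    t <- (x - anchors[k]) / (anchors[k + 1L] - anchors[k])
    t <- pmin(pmax(t, 0), 1)   # constant extrapolation outside the anchors
    A[cbind(seq_len(n), k)] <- 1 - t
    A[cbind(seq_len(n), k + 1L)] <- A[cbind(seq_len(n), k + 1L)] + t
    A
  }
  axis_weights(H, anchors_r) %*% g %*% t(axis_weights(W, anchors_c))
}

# Replace NA entries of a coarse grid by the mean of available neighbors
# (iterative dilation; falls back to the global mean).
infill_grid <- function(g) {
  if (!anyNA(g)) return(g)
  glob <- mean(g, na.rm = TRUE)
  for (it in 1:20) {
    if (!anyNA(g)) break
    na <- which(is.na(g), arr.ind = TRUE)
    filled <- g
    for (k in seq_len(nrow(na))) {
      i <- na[k, 1L]; j <- na[k, 2L]
      nb <- g[max(1, i - 1):min(nrow(g), i + 1), max(1, j - 1):min(ncol(g), j + 1)]
      if (any(!is.na(nb))) filled[i, j] <- mean(nb, na.rm = TRUE)
    }
    g <- filled
  }
  g[is.na(g)] <- glob
  g
}

registration_report <- function(residual_rms, median_disp, cycles, converged) {
  structure(list(residual_rms = residual_rms, median_displacement = median_disp,
                 cycles = cycles, converged = converged),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> %d cycle(s), converged: %s\n",
              x$cycles, x$converged))
  for (k in seq_len(x$cycles))
    cat(sprintf("  cycle %d: median |d| %.3f px, residual RMS %.4f\n",
                k, x$median_displacement[k], x$residual_rms[k]))
  invisible(x)
}

#' Iterative training-registration refinement of training pairs
#'
#' Alternates between (a) fitting a rough virtual stainer on the current
#' pairs, (b) rendering a rough stained image for every autofluorescence
#' patch, (c) elastically registering each histochemical target onto its
#' rough rendering (both in the bright-field domain), and (d) warping the
#' targets by the recovered field. Iteration stops when the median residual
#' displacement magnitude drops below `stop_threshold` (default 1 px) or
#' after `max_cycles` cycles; per-cycle residuals are recorded in a
#' [registration_report].
#'
#' @param pairs list of `list(af =, bf =)` coarsely registered pairs.
#' @param rough_trainer function taking `pairs` and returning a renderer
#'   `function(af) -> bright-field image`; e.g. [make_gan_trainer()] with a
#'   reduced budget.
#' @param max_cycles maximum cycles (3 to 5).
#' @param stop_threshold median displacement stopping criterion, px.
#' @param elastic_args list of extra arguments for [register_elastic()].
#' @return `list(pairs =, report =)`; `report$converged` is `FALSE` when the
#'   rough trainer diverged (non-finite rendering) or the budget ran out.
#' @export
training_registration_cycle <- function(pairs, rough_trainer, max_cycles = 5L,
                                        stop_threshold = 1,
                                        elastic_args = list()) {
  if (max_cycles < 3L || max_cycles > 5L)
    stop_field("max_cycles", "must be between 3 and 5")
  if (length(pairs) < 1L) stop_field("pairs", "must be non-empty")
  med_hist <- rms_hist <- numeric(0)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    render <- rough_trainer(pairs)
    disp <- rms <- numeric(length(pairs))
    fields <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      rough <- render(pairs[[i]]$af)
      if (any(!is.finite(rough))) {
        report <- registration_report(rms_hist, med_hist, cycle - 1L, FALSE)
        attr(report, "diverged") <- TRUE
        return(list(pairs = pairs, report = report))
      }
      fx <- bf_to_proxy(rough); mv <- bf_to_proxy(pairs[[i]]$bf)
      fld <- do.call(register_elastic, c(list(fixed = fx, moving = mv), elastic_args))
      fields[[i]] <- fld
      disp[i] <- median(sqrt(fld$u^2 + fld$v^2))
      rms[i] <- sqrt(mean((fx - mv)^2))
    }
    med <- median(disp)
    med_hist <- c(med_hist, med)
    rms_hist <- c(rms_hist, median(rms))
    if (med < stop_threshold) { converged <- TRUE
      # still apply the (sub-threshold) correction of this final cycle
      for (i in seq_along(pairs))
        pairs[[i]]$bf <- warp(pairs[[i]]$bf, fields[[i]])
      break
    }
    for (i in seq_along(pairs))
      pairs[[i]]$bf <- warp(pairs[[i]]$bf, fields[[i]])
  }
  list(pairs = pairs,
       report = registration_report(rms_hist, med_hist, length(med_hist), converged))
}
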