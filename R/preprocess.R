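#' Preprocessing configuration
#'
#' Parameters for the WSI-to-patch preparation pipeline: per-channel
#' intensity flattening by a wide Gaussian background estimate, tiling into
#' fields of view (FOVs), center-cropping to remove registration edge
#' artifacts, and extraction of network-ready patches.
#'
#' @param background_sigma Gaussian background kernel standard deviation in
#'   px (default 300, matched to WSI-scale illumination gradients).
#' @param fov_size FOV tile side in px (default 3248).
#' @param crop_size center-crop side in px (default 2048).
#' @param patch_size training patch side in px (default 256).
#' @param background_epsilon positive guard for the background division; if
#'   `NULL`, `1e-3` of the channel median is used at call time.
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(background_sigma = 300, fov_size = 3248L,
                              crop_size = 2048L, patch_size = 256L,
                              background_epsilon = NULL) {
  check_number(background_sigma, "background_sigma")
  if (background_sigma <= 0) stop_field("background_sigma", "must be > 0")
  check_number(fov_size, "fov_size", min = 1)
  check_number(crop_size, "crop_size", min = 1)
  check_number(patch_size, "patch_size", min = 1)
  if (crop_size > fov_size) stop_field("crop_size", "must be <= fov_size")
  if (!is.null(background_epsilon)) {
    check_number(background_epsilon, "background_epsilon")
    if (background_epsilon <= 0) stop_field("background_epsilon", "must be > 0")
  }
  if (crop_size %% patch_size != 0)
    warning("patch_size does not divide crop_size; patch tiling will truncate")
  structure(list(background_sigma = background_sigma,
                 fov_size = as.integer(fov_size),
                 crop_size = as.integer(crop_size),
                 patch_size = as.integer(patch_size),
                 background_epsilon = background_epsilon),
            class = "preprocess_config")
}

#' Estimate the smooth background of one autofluorescence channel
#'
#' A wide Gaussian filter (mirror boundary, so edges are not darkened)
#' estimates the slowly varying illumination/background field; the result is
#' clamped from below so the subsequent division is always defined.
#'
#' @param channel_image single-channel numeric matrix.
#' @param sigma Gaussian standard deviation in px.
#' @param epsilon positive lower clamp; default `1e-3` of the channel median
#'   (floored at 1e-9 for all-dark channels).
#' @return background image, same shape, strictly positive.
#' @export
estimate_background <- function(channel_image, sigma = 300, epsilon = NULL) {
  if (length(dim(channel_image)) == 3L)
    stop_field("channel_image", "must be single-channel")
  check_image(channel_image, "channel_image")
  bg <- gaussian_blur(as.matrix(channel_image), sigma)
  eps <- epsilon %||% max(1e-3 * median(channel_image), 1e-9)
  pmax(bg, eps)
}

#' Flatten a channel by its background estimate
#'
#' Pixel-wise division of the raw channel by its smooth background; cancels
#' global intensity scale and slow illumination gradients
#' (`normalize(k * image) == normalize(image)` for `k > 0`).
#'
#' @param channel_image,background_image same-shape numeric matrices;
#'   background strictly positive.
#' @return normalized image.
#' @export
normalize_channel <- function(channel_image, background_image) {
  check_same_shape(channel_image, background_image)
  if (any(background_image <= 0))
    stop_field("background_image", "must be strictly positive")
  out <- channel_image / background_image
  if (any(!is.finite(out))) stop("normalization produced non-finite pixels", call. = FALSE)
  out
}

tile_index <- function(fov_origin, crop_origin, patient_id = NA_character_,
                       stain = NA_character_, channel = NA_character_) {
  structure(list(fov_origin = as.integer(fov_origin),
                 crop_origin = as.integer(crop_origin),
                 patient_id = patient_id, stain = stain, channel = channel),
            class = "tile_index")
}

#' Tile a WSI into non-overlapping fields of view
#'
#' Cuts the WSI into a regular grid of `fov_size` tiles anchored at the
#' origin; edge remainders that do not fill a whole FOV are dropped (their
#' pixel count is attached as the `dropped_px` attribute). Origins are
#' 0-based `(row, col)` with half-open windows, so tile/crop coordinate
#' arithmetic is exactly invertible.
#'
#' @param wsi numeric matrix or H x W x C array.
#' @param cfg a [preprocess_config()].
#' @return list of `list(index = tile_index, image =)` entries.
#' @export
tile_wsi <- function(wsi, cfg = preprocess_config()) {
  check_image(wsi, "wsi")
  H <- dim(wsi)[1L]; W <- dim(wsi)[2L]; fov <- cfg$fov_size
  nr <- H %/% fov; nc <- W %/% fov
  if (nr < 1L || nc < 1L) {
    warning(sprintf("WSI (%d x %d) smaller than one FOV (%d); no tiles", H, W, fov))
    out <- list()
    attr(out, "dropped_px") <- H * W
    return(out)
  }
  off <- (fov - cfg$crop_size) %/% 2L
  out <- vector("list", nr * nc)
  k <- 1L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1L) * fov; c0 <- (j - 1L) * fov
    img <- if (length(dim(wsi)) == 2L) wsi[r0 + seq_len(fov), c0 + seq_len(fov)]
    else wsi[r0 + seq_len(fov), c0 + seq_len(fov), , drop = FALSE]
    out[[k]] <- list(index = tile_index(c(r0, c0), c(r0 + off, c0 + off)),
                     image = img)
    k <- k + 1L
  }
  attr(out, "dropped_px") <- H * W - nr * nc * fov * fov
  out
}

#' Center-crop an image
#'
#' Offset is `floor((size - crop) / 2)` on each axis.
#' @param fov_image numeric matrix or H x W x C array.
#' @param crop_size window side in px (must not exceed either image side).
#' @return cropped image; the 0-based crop offset is attached as attribute
#'   `offset`.
#' @export
center_crop <- function(fov_image, crop_size) {
  check_image(fov_image, "fov_image")
  H <- dim(fov_image)[1L]; W <- dim(fov_image)[2L]
  if (crop_size > H || crop_size > W)
    stop_field("crop_size", sprintf("(%d) exceeds image size (%d x %d)", crop_size, H, W))
  crop_size <- as.integer(crop_size)
  or <- (H - crop_size) %/% 2L; oc <- (W - crop_size) %/% 2L
  out <- if (length(dim(fov_image)) == 2L)
    fov_image[or + seq_len(crop_size), oc + seq_len(crop_size)]
  else fov_image[or + seq_len(crop_size), oc + seq_len(crop_size), , drop = FALSE]
  attr(out, "offset") <- c(or, oc)
  out
}

#' Standardize a patch to zero mean and unit variance
#'
#' Statistics are computed per channel over the patch, with the population
#' variance (denominator n), so a standardized channel has mean 0 and
#' variance exactly 1. A constant channel is mapped to all zeros (declared
#' degenerate rule).
#' @param patch numeric matrix or H x W x C array.
#' @return standardized patch, same shape.
#' @export
standardize_patch <- function(patch) {
  check_image(patch, "patch")
  each_channel(patch, function(ch) {
    mu <- mean(ch)
    s <- sqrt(mean((ch - mu)^2))
    if (s < 1e-12) return(ch * 0)
    (ch - mu) / s
  })
}

rot90_ccw <- function(img) {
  f <- function(ch) t(ch)[ncol(ch):1, , drop = FALSE]
  each_channel3 <- function(img) {
    if (length(dim(img)) == 2L) return(f(img))
    slices <- lapply(seq_len(dim(img)[3L]), function(c) f(img[, , c]))
    array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices)))
  }
  each_channel3(img)
}

flip_rows <- function(img) {
  if (length(dim(img)) == 2L) return(img[nrow(img):1, , drop = FALSE])
  img[dim(img)[1L]:1, , , drop = FALSE]
}

#' Jointly augment a registered patch pair
#'
#' Draws one transform uniformly from the 8 compositions of
#' {0, 90, 180, 270 degree rotation} x {row flip, no flip} and applies it
#' identically to both patches, preserving their pixel-wise correspondence.
#' Rotations are restricted to multiples of 90 degrees so augmentation never
#' interpolates.
#'
#' @param af_patch,bf_patch same-spatial-shape patches.
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return `list(af =, bf =, rotation =, flip =)`.
#' @export
augment_pair <- function(af_patch, bf_patch, seed = NULL) {
  if (!identical(dim(af_patch)[1:2], dim(bf_patch)[1:2]))
    stop("af_patch and bf_patch must share spatial dimensions", call. = FALSE)
  draw <- function() list(k = sample.int(4L, 1L) - 1L, flip = runif(1) < 0.5)
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tfm <- function(img) {
    if (d$flip) img <- flip_rows(img)
    if (d$k > 0) for (i in seq_len(d$k)) img <- rot90_ccw(img)
    img
  }
  list(af = tfm(af_patch), bf = tfm(bf_patch), rotation = 90L * d$k, flip = d$flip)
}

#' Cut a registered image into non-overlapping patches
#'
#' Helper used when preparing training sets: splits an image into
#' `patch_size` tiles (edge remainders dropped).
#' @param img numeric matrix or H x W x C array.
#' @param patch_size patch side in px.
#' @return list of patches with 0-based `origin` attributes.
#' @export
extract_patches <- function(img, patch_size = 256L) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  nr <- H %/% patch_size; nc <- W %/% patch_size
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1L) * patch_size; c0 <- (j - 1L) * patch_size
    p <- if (length(dim(img)) == 2L) img[r0 + seq_len(patch_size), c0 + seq_len(patch_size)]
    else img[r0 + seq_len(patch_size), c0 + seq_len(patch_size), , drop = FALSE]
    attr(p, "origin") <- c(r0, c0)
    out[[length(out) + 1L]] <- p
  }
  out
}
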