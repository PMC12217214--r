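#' Plan a tiled, feather-blended traversal of a WSI canvas
#'
#' Tiles of side `tile` are laid on a regular grid with `overlap` px of
#' overlap; the final row/column is clamped so the canvas is fully covered.
#' Blend weights are separable linear feather ramps of width `overlap`,
#' normalized per axis so the contributing weights sum to exactly 1 at every
#' output pixel (`overlap = 0` gives 0/1 indicator weights on a grid-aligned
#' canvas). A tile larger than the canvas degenerates to a single-tile plan.
#'
#' @param wsi_shape integer `(height, width)` of the canvas.
#' @param tile tile side, px.
#' @param overlap overlap between neighboring tiles, px (`0 <= overlap < tile`).
#' @return a `stitch_plan` with 0-based `origins_r`/`origins_c`, per-tile
#'   normalized row/col weight profiles, and the effective tile size.
#' @export
make_stitch_plan <- function(wsi_shape, tile = 1024L, overlap = 128L) {
  H <- as.integer(wsi_shape[1L]); W <- as.integer(wsi_shape[2L])
  check_number(tile, "tile", min = 1); check_number(overlap, "overlap", min = 0)
  if (overlap >= tile) stop_field("overlap", "must be smaller than tile")
  tile <- as.integer(min(tile, H, W))
  overlap <- as.integer(min(overlap, tile - 1L))
  axis_origins <- function(n) {
    if (tile >= n) return(0L)
    o <- seq(0L, n - tile, by = tile - overlap)
    if (tail(o, 1L) != n - tile) o <- c(o, n - tile)
    as.integer(unique(o))
  }
  or <- axis_origins(H); oc <- axis_origins(W)
  profile <- function() {
    k <- seq_len(tile) - 0.5
    if (overlap == 0L) rep(1, tile)
    else pmin(1, k / overlap, (tile - k) / overlap)
  }
  normalize_axis <- function(origins, n) {
    raw <- lapply(origins, function(o) profile())
    tot <- numeric(n)
    for (i in seq_along(origins)) {
      idx <- origins[i] + seq_len(tile)
      tot[idx] <- tot[idx] + raw[[i]]
    }
    lapply(seq_along(origins), function(i) {
      idx <- origins[i] + seq_len(tile)
      raw[[i]] / tot[idx]
    })
  }
  structure(list(shape = c(H, W), tile = tile, overlap = overlap,
                 origins_r = or, origins_c = oc,
                 w_r = normalize_axis(or, H), w_c = normalize_axis(oc, W)),
            class = "stitch_plan")
}

#' @export
print.stitch_plan <- function(x, ...) {
  cat(sprintf("<stitch_plan> canvas %d x %d, tile %d, overlap %d, %d x %d tiles\n",
              x$shape[1L], x$shape[2L], x$tile, x$overlap,
              length(x$origins_r), length(x$origins_c)))
  invisible(x)
}

#' Stable digest of a stitch plan
#'
#' Two WSI renderings are pixel-registered by construction when their plans
#' share a digest.
#' @param plan a [make_stitch_plan()] result.
#' @return character scalar.
#' @export
stitch_plan_digest <- function(plan) {
  paste(c(plan$shape, plan$tile, plan$overlap, plan$origins_r, plan$origins_c),
        collapse = "-")
}

#' Per-pixel sum of blend weights
#'
#' Diagnostic: returns the H x W field of summed contributing weights, which
#' is 1 everywhere (within float tolerance) for any valid plan.
#' @param plan a `stitch_plan`.
#' @return numeric matrix.
#' @export
stitch_weight_sum <- function(plan) {
  H <- plan$shape[1L]; W <- plan$shape[2L]
  out <- matrix(0, H, W)
  for (i in seq_along(plan$origins_r)) for (j in seq_along(plan$origins_c)) {
    ri <- plan$origins_r[i] + seq_len(plan$tile)
    ci <- plan$origins_c[j] + seq_len(plan$tile)
    out[ri, ci] <- out[ri, ci] + outer(plan$w_r[[i]], plan$w_c[[j]])
  }
  out
}

#' Blend per-tile images into one canvas
#'
#' @param tiles list (row-major over the plan grid) of tile images
#'   (tile x tile x C).
#' @param plan the `stitch_plan` the tiles were produced with.
#' @return blended H x W x C image.
#' @export
blend_tiles <- function(tiles, plan) {
  C <- nchannels(tiles[[1L]])
  H <- plan$shape[1L]; W <- plan$shape[2L]
  out <- array(0, c(H, W, C))
  k <- 1L
  for (i in seq_along(plan$origins_r)) for (j in seq_along(plan$origins_c)) {
    ri <- plan$origins_r[i] + seq_len(plan$tile)
    ci <- plan$origins_c[j] + seq_len(plan$tile)
    wgt <- outer(plan$w_r[[i]], plan$w_c[[j]])
    tl <- tiles[[k]]
    if (length(dim(tl)) == 2L) tl <- array(tl, c(dim(tl), 1L))
    for (c in seq_len(C)) out[ri, ci, c] <- out[ri, ci, c] + wgt * tl[, , c]
    k <- k + 1L
  }
  if (C == 1L) out <- out[, , 1L]
  out
}

crop_tile <- function(img, r0, c0, tile) {
  if (length(dim(img)) == 2L) img[r0 + seq_len(tile), c0 + seq_len(tile)]
  else img[r0 + seq_len(tile), c0 + seq_len(tile), , drop = FALSE]
}

resolve_model <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "vs_generator")) return(function(af) predict_stain(model, af))
  if (is.list(model) && !is.null(model$generator))
    return(function(af) predict_stain(model$generator, af))
  stop("model must be a function, a vs_generator, or a checkpoint", call. = FALSE)
}

#' Virtually stain a whole-slide autofluorescence image
#'
#' Runs tiled inference for one or more stain models over a (normalized)
#' autofluorescence stack and blends the per-tile renderings with feathered
#' weights. Every stain is rendered through the *same* stitch plan on the
#' same input grid, so the multi-stain outputs are identical in size and
#' pixel-registered with each other by construction.
#'
#' @param af_wsi H x W x 4 autofluorescence stack (already
#'   background-normalized, see [normalize_channel()]).
#' @param models named list (one per stain) of trained generators,
#'   checkpoints, or plain functions `af_tile -> rgb_tile`.
#' @param tile,overlap stitch geometry in px (defaults 1024 / 128).
#' @return named list of H x W x 3 `bf_image` renderings in `[0, 1]`, each
#'   carrying the shared plan digest as attribute `plan_digest`.
#' @export
virtually_stain_wsi <- function(af_wsi, models, tile = 1024L, overlap = 128L) {
  check_image(af_wsi, "af_wsi")
  if (length(dim(af_wsi)) != 3L)
    stop_field("af_wsi", "must be an H x W x C array")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop_field("models", "must be a named list (one entry per stain)")
  plan <- make_stitch_plan(dim(af_wsi)[1:2], tile, overlap)
  digest <- stitch_plan_digest(plan)
  fns <- lapply(models, resolve_model)
  out <- vector("list", length(models))
  names(out) <- names(models)
  for (s in names(models)) {
    tiles <- list(); k <- 1L
    for (r0 in plan$origins_r) for (c0 in plan$origins_c) {
      af_tile <- crop_tile(af_wsi, r0, c0, plan$tile)
      rgb <- fns[[s]](af_tile)
      if (!identical(dim(rgb)[1:2], dim(af_tile)[1:2]))
        stop(sprintf("model '%s' changed tile geometry", s), call. = FALSE)
      tiles[[k]] <- clip01(rgb); k <- k + 1L
    }
    img <- clip01(blend_tiles(tiles, plan))
    img <- bf_image(img, stain = s)
    attr(img, "plan_digest") <- digest
    out[[s]] <- img
  }
  out
}

#' Export a rendered WSI as a pyramidal TIFF
#'
#' Writes a lossless multi-page TIFF (32-bit float, uncompressed): page 1 is
#' the full-resolution image, subsequent pages a 2x downsampling pyramid.
#' Pixel-size and stain metadata travel in a YAML companion file
#' (`<path>.yaml`), so a write/read round trip is bit-identical and keeps its
#' physical calibration.
#'
#' @param image H x W (x C) numeric image in `[0, 1]`.
#' @param path output file path (`.tif`).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param min_level smallest pyramid level side, px.
#' @return invisibly, the path written.
#' @export
export_wsi <- function(image, path, pixel_size_um = 0.325, min_level = 64L) {
  check_image(image, "image")
  if (min(image) < 0 || max(image) > 1)
    stop_field("image", "values must lie in [0, 1]")
  pages <- list(if (length(dim(image)) == 2L) image else unclass(image))
  lvl <- image
  while (min(dim(lvl)[1:2]) >= 2L * min_level) {
    lvl <- downsample2(lvl)
    pages[[length(pages) + 1L]] <- if (length(dim(lvl)) == 2L) lvl else unclass(lvl)
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none"),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write '%s': %s", path, attr(ok, "condition")$message),
         call. = FALSE)
  yaml::write_yaml(list(pixel_size_um = pixel_size_um,
                        height = dim(image)[1L], width = dim(image)[2L],
                        channels = nchannels(image),
                        stain = attr(image, "stain") %||% NA,
                        levels = length(pages)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname export_wsi
#' @param level pyramid level to read (1 = full resolution).
#' @return `read_wsi`: the image array with metadata attributes
#'   (`pixel_size_um`, `stain`).
#' @export
read_wsi <- function(path, level = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- pages[[level]]
  meta_path <- paste0(path, ".yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(img, "pixel_size_um") <- meta$pixel_size_um
    if (!is.null(meta$stain) && !is.na(meta$stain)) attr(img, "stain") <- meta$stain
  }
  img
}
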