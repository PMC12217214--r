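#' Specification of a synthetic tissue phantom
#'
#' A phantom is built from K = 5 non-negative component maps — nuclei,
#' cytoplasm, collagen, elastic fibers, and background — the minimal set that
#' distinguishes the H&E, Masson's Trichrome (MT) and elastic Verhoeff-Van
#' Gieson (EVG) stain targets. Autofluorescence is a linear mixture of the
#' components (plus Gaussian noise, clipped at zero) in the four standard
#' filter channels (DAPI, TxRed, FITC, Cy5); bright-field stains follow a
#' Beer-Lambert forward model, `transmittance = exp(-OD %*% components)` per
#' RGB channel. The same component geometry feeds every stain, so all
#' bright-field renderings of one phantom are pixel-registered by
#' construction.
#'
#' @param width,height image size in pixels (>= 64).
#' @param nucleus_density expected nuclei per 100 x 100 px.
#' @param nucleus_radius_range min/max nucleus semi-axis in px.
#' @param cytoplasm_fraction,collagen_fraction,elastic_fiber_fraction target
#'   area fractions in `[0, 1]`.
#' @param af_mixing_matrix 4 x 5 non-negative matrix mapping components to the
#'   DAPI/TxRed/FITC/Cy5 channels.
#' @param stain_od_matrix named list of 3 x 5 non-negative optical-density
#'   matrices (RGB x component), one per stain.
#' @param noise_sd standard deviation of additive autofluorescence noise
#'   (relative intensity units).
#' @param seed integer seed; the same spec and seed reproduce the phantom
#'   bit for bit.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(width = 256L, height = 256L,
                         nucleus_density = 6,
                         nucleus_radius_range = c(3, 7),
                         cytoplasm_fraction = 0.5,
                         collagen_fraction = 0.25,
                         elastic_fiber_fraction = 0.1,
                         af_mixing_matrix = default_af_mixing(),
                         stain_od_matrix = default_stain_od(),
                         noise_sd = 0.01,
                         seed = 1L) {
  check_number(width, "width", min = 64); check_number(height, "height", min = 64)
  check_number(nucleus_density, "nucleus_density", min = 0)
  if (length(nucleus_radius_range) != 2L || any(nucleus_radius_range <= 0) ||
      diff(nucleus_radius_range) < 0)
    stop_field("nucleus_radius_range", "must be increasing positive (min, max)")
  for (f in c("cytoplasm_fraction", "collagen_fraction", "elastic_fiber_fraction"))
    check_number(get(f), f, min = 0, max = 1)
  if (!is.matrix(af_mixing_matrix) || nrow(af_mixing_matrix) != 4L ||
      ncol(af_mixing_matrix) != 5L || any(!is.finite(af_mixing_matrix)) ||
      any(af_mixing_matrix < 0))
    stop_field("af_mixing_matrix", "must be a finite non-negative 4 x 5 matrix")
  if (!is.list(stain_od_matrix) || is.null(names(stain_od_matrix)))
    stop_field("stain_od_matrix", "must be a named list of 3 x 5 matrices")
  for (s in names(stain_od_matrix)) {
    m <- stain_od_matrix[[s]]
    if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 5L || any(!is.finite(m)) || any(m < 0))
      stop_field(paste0("stain_od_matrix$", s), "must be a finite non-negative 3 x 5 matrix")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed")
  structure(list(width = as.integer(width), height = as.integer(height),
                 nucleus_density = nucleus_density,
                 nucleus_radius_range = nucleus_radius_range,
                 cytoplasm_fraction = cytoplasm_fraction,
                 collagen_fraction = collagen_fraction,
                 elastic_fiber_fraction = elastic_fiber_fraction,
                 af_mixing_matrix = af_mixing_matrix,
                 stain_od_matrix = stain_od_matrix,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

COMPONENTS <- c("nuclei", "cytoplasm", "collagen", "elastic", "background")
AF_CHANNELS <- c("DAPI", "TxRed", "FITC", "Cy5")

#' @rdname phantom_spec
#' @export
default_af_mixing <- function() {
  m <- rbind(DAPI  = c(1.00, 0.05, 0.02, 0.02, 0.01),
             TxRed = c(0.10, 0.80, 0.15, 0.10, 0.01),
             FITC  = c(0.10, 0.50, 0.60, 0.20, 0.01),
             Cy5   = c(0.05, 0.10, 0.10, 0.90, 0.01))
  colnames(m) <- COMPONENTS
  m
}

#' @rdname phantom_spec
#' @export
default_stain_od <- function() {
  od <- function(...) {
    m <- cbind(...)
    rownames(m) <- c("R", "G", "B"); colnames(m) <- COMPONENTS
    m
  }
  list(
    HE = od(nuclei = c(0.65, 0.70, 0.29) * 1.6,
            cytoplasm = c(0.07, 0.99, 0.11) * 0.7,
            collagen = c(0.07, 0.99, 0.11) * 0.35,
            elastic = c(0.07, 0.99, 0.11) * 0.45,
            background = c(0, 0, 0)),
    MT = od(nuclei = c(0.60, 0.75, 0.40) * 1.3,
            cytoplasm = c(0.10, 0.85, 0.50) * 0.55,
            collagen = c(0.75, 0.50, 0.10) * 1.0,
            elastic = c(0.20, 0.40, 0.30) * 0.35,
            background = c(0, 0, 0)),
    EVG = od(nuclei = c(0.60, 0.60, 0.60) * 0.6,
             cytoplasm = c(0.10, 0.25, 0.70) * 0.35,
             collagen = c(0.10, 0.80, 0.55) * 0.8,
             elastic = c(0.85, 0.85, 0.85) * 1.5,
             background = c(0, 0, 0)))
}

af_stack <- function(a) {
  stopifnot(length(dim(a)) == 3L, dim(a)[3L] == 4L)
  dimnames(a) <- list(NULL, NULL, AF_CHANNELS)
  structure(a, class = c("af_stack", class(a)))
}

bf_image <- function(a, stain, style = "native") {
  stopifnot(length(dim(a)) == 3L, dim(a)[3L] == 3L)
  structure(a, stain = stain, style = style, class = c("bf_image", class(a)))
}

# --- component map textures (all draws in documented order) -----------------

draw_nuclei <- function(H, W, density, rrange) {
  map <- matrix(0, H, W)
  n <- round(density * H * W / 1e4)
  if (n < 1) return(map)
  cy <- runif(n, 1, H); cx <- runif(n, 1, W)
  rr <- runif(n, rrange[1L], rrange[2L])
  asp <- runif(n, 0.6, 1); phi <- runif(n, 0, pi)
  for (k in seq_len(n)) {
    a <- rr[k]; b <- rr[k] * asp[k]
    r <- ceiling(a) + 1L
    ri <- max(1L, floor(cy[k] - r)):min(H, ceiling(cy[k] + r))
    ci <- max(1L, floor(cx[k] - r)):min(W, ceiling(cx[k] + r))
    dy <- outer(ri - cy[k], rep(1, length(ci)))
    dx <- outer(rep(1, length(ri)), ci - cx[k])
    u <- (dy * cos(phi[k]) + dx * sin(phi[k])) / a
    v <- (-dy * sin(phi[k]) + dx * cos(phi[k])) / b
    d2 <- u^2 + v^2
    map[ri, ci] <- pmax(map[ri, ci], pmin(1, pmax(0, 1.15 - d2) / 0.3))
  }
  pmin(map, 1)
}

threshold_to_fraction <- function(tex, fraction) {
  if (fraction <= 0) return(tex * 0)
  thr <- quantile(tex, 1 - fraction, names = FALSE)
  soft <- (tex - thr) / max(1e-9, sd(tex) * 0.5)
  pmin(1, pmax(0, soft))
}

draw_cytoplasm <- function(H, W, fraction) {
  tex <- gaussian_blur(matrix(runif(H * W), H, W), 8)
  threshold_to_fraction(tex, fraction) * 0.9
}

draw_fibers <- function(H, W, fraction, n_curves, thickness, wiggle) {
  map <- matrix(0, H, W)
  if (fraction <= 0 || n_curves < 1) return(map)
  for (k in seq_len(n_curves)) {
    y <- runif(1, 1, H); x <- runif(1, 1, W)
    th <- runif(1, 0, 2 * pi)
    steps <- round(1.2 * max(H, W))
    dth <- rnorm(steps, 0, wiggle)
    for (s in seq_len(steps)) {
      th <- th + dth[s]
      y <- y + sin(th); x <- x + cos(th)
      if (y < 1 || y > H || x < 1 || x > W) break
      map[round(y), round(x)] <- 1
    }
  }
  map <- gaussian_blur(map, thickness)
  m <- max(map)
  if (m > 0) map <- map / m
  # rescale so occupied area roughly matches `fraction`
  threshold_to_fraction(map, min(1, fraction * 1.2)) * pmin(map * 3, 1)
}

#' Generate a synthetic tissue phantom
#'
#' Draws seeded component maps (elliptical nuclei, smooth cytoplasm blobs,
#' fibrous collagen and thin elastic fibers), mixes them into a 4-channel
#' autofluorescence stack and renders one bright-field image per configured
#' stain via the Beer-Lambert transmittance model. Identical `(spec)` —
#' including its `seed` — always yields a bit-identical phantom; the random
#' draws happen in a fixed order (nuclei, cytoplasm, collagen, elastic
#' fibers, then per-channel noise DAPI..Cy5).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom` list with `component_maps` (H x W x 5), `af`
#'   (H x W x 4 `af_stack`), `bf` (named list of H x W x 3 `bf_image`), and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    nuc <- draw_nuclei(H, W, spec$nucleus_density, spec$nucleus_radius_range)
    cyt <- draw_cytoplasm(H, W, spec$cytoplasm_fraction)
    col <- draw_fibers(H, W, spec$collagen_fraction,
                       n_curves = round(spec$collagen_fraction * 40),
                       thickness = 2.0, wiggle = 0.10)
    ela <- draw_fibers(H, W, spec$elastic_fiber_fraction,
                       n_curves = round(spec$elastic_fiber_fraction * 60),
                       thickness = 0.9, wiggle = 0.25)
    bg <- pmax(0, 1 - nuc - cyt - col - ela) * 0.5
    comps <- array(c(nuc, cyt, col, ela, bg), dim = c(H, W, 5L),
                   dimnames = list(NULL, NULL, COMPONENTS))
    cm <- matrix(comps, H * W, 5L)
    af <- cm %*% t(spec$af_mixing_matrix)
    if (spec$noise_sd > 0)
      af <- af + matrix(rnorm(length(af), 0, spec$noise_sd), nrow(af), ncol(af))
    af <- pmax(af, 0)
    af <- af_stack(array(af, dim = c(H, W, 4L)))
    bf <- lapply(names(spec$stain_od_matrix), function(s) {
      tr <- exp(-cm %*% t(spec$stain_od_matrix[[s]]))
      bf_image(array(tr, dim = c(H, W, 3L)), stain = s)
    })
    names(bf) <- names(spec$stain_od_matrix)
    structure(list(component_maps = comps, af = af, bf = bf, spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, stains: %s, noise_sd %.3g, seed %d\n",
              x$spec$height, x$spec$width, paste(names(x$bf), collapse = ", "),
              x$spec$noise_sd, x$spec$seed))
  invisible(x)
}

#' Apply a known geometric misalignment
#'
#' Warps an image by a rigid, affine or elastic motion and returns both the
#' warped image and the exact ground-truth transform, for building
#' registration test cases. Parameter bounds: shifts at most 25% of the image
#' size, rotations at most 15 degrees, elastic amplitude at most 10 px with a
#' smoothness scale of at least 32 px. Out-of-canvas samples are filled with
#' the per-channel median.
#'
#' @param image numeric matrix or H x W x C array.
#' @param kind `"rigid"`, `"affine"` or `"elastic"`.
#' @param params a list; rigid: `shift`, `rotation`; affine: `scale`
#'   (scalar or length 2), `rotation`, `shear`, `shift`; elastic: either
#'   `amplitude` + `smoothness` (random smooth field) or `amplitude` +
#'   `wavelength` (sinusoidal field).
#' @param seed integer seed for random elastic fields.
#' @return `list(image =, transform =)`; for rigid/affine the transform maps
#'   the original (fixed) frame to the warped (moving) frame; for elastic it
#'   is the pull-back [displacement_field()] used to create the warp.
#' @export
apply_misalignment <- function(image, kind = c("rigid", "affine", "elastic"),
                               params = list(), seed = 1L) {
  kind <- match.arg(kind)
  check_image(image, "image")
  dims <- dim(image)
  maxshift <- 0.25 * min(dims[1:2])
  p <- params
  if (kind == "rigid") {
    shift <- p$shift %||% c(0, 0); rotation <- p$rotation %||% 0
    if (any(abs(shift) > maxshift)) stop_field("shift", "exceeds 25% of image size")
    if (abs(rotation) > 15) stop_field("rotation", "must be within +/- 15 degrees")
    tf <- rigid_transform(rotation, shift)
    return(list(image = warp(image, tf), transform = tf))
  }
  if (kind == "affine") {
    scale <- p$scale %||% 1; rotation <- p$rotation %||% 0
    shear <- p$shear %||% 0; shift <- p$shift %||% c(0, 0)
    if (length(scale) == 1L) scale <- c(scale, scale)
    if (any(abs(scale - 1) > 0.2)) stop_field("scale", "must be within [0.8, 1.2]")
    if (abs(rotation) > 15) stop_field("rotation", "must be within +/- 15 degrees")
    if (abs(shear) > 0.2) stop_field("shear", "must be within +/- 0.2")
    if (any(abs(shift) > maxshift)) stop_field("shift", "exceeds 25% of image size")
    ctr <- (dims[1:2] - 1) / 2
    L <- rot2(rotation) %*% matrix(c(scale[1L], 0, shear, scale[2L]), 2L, 2L)
    # content motion g(p) = L (p - c) + c + shift; moving = fixed(g^{-1}(p))
    g <- affine_transform(cbind(L, ctr + shift - L %*% ctr))
    return(list(image = warp(image, invert_transform(g)), transform = g))
  }
  amplitude <- p$amplitude %||% 6
  if (amplitude < 0 || amplitude > 10) stop_field("amplitude", "must be in [0, 10] px")
  H <- dims[1L]; W <- dims[2L]
  if (!is.null(p$wavelength)) {
    lam <- p$wavelength
    if (lam < 32) stop_field("wavelength", "smoothness scale must be >= 32 px")
    rr <- outer(seq_len(H) - 1, rep(1, W)); cc <- outer(rep(1, H), seq_len(W) - 1)
    u <- amplitude * sin(2 * pi * cc / lam)
    v <- amplitude * cos(2 * pi * rr / lam)
  } else {
    smoothness <- p$smoothness %||% 48
    if (smoothness < 32) stop_field("smoothness", "must be >= 32 px")
    uv <- with_seed(seed, list(
      u = gaussian_blur(matrix(rnorm(H * W), H, W), smoothness / 3),
      v = gaussian_blur(matrix(rnorm(H * W), H, W), smoothness / 3)))
    u <- uv$u; v <- uv$v
    m <- max(sqrt(u^2 + v^2))
    if (m > 0) { u <- u * amplitude / m; v <- v * amplitude / m }
  }
  tf <- displacement_field(u, v)
  list(image = warp(image, tf), transform = tf)
}

# --- stain styles ------------------------------------------------------------

hue_rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  axis <- rep(1 / sqrt(3), 3L)
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Registered bright-field color styles
#'
#' A style is a global invertible color transform — hue rotation about the
#' gray axis, then per-channel gain, then per-channel gamma — emulating the
#' systematic color differences between staining laboratories. The built-in
#' registry carries an identity style and two institution-like styles.
#' @return named list of style definitions.
#' @export
default_stain_styles <- function() {
  list(identity = list(gain = c(1, 1, 1), gamma = c(1, 1, 1), hue_deg = 0),
       inst1 = list(gain = c(0.92, 1.00, 1.08), gamma = c(1.05, 1.00, 0.95), hue_deg = 6),
       inst2 = list(gain = c(1.06, 0.97, 0.90), gamma = c(0.95, 1.00, 1.06), hue_deg = -5))
}

resolve_style <- function(style_id, styles) {
  if (is.list(style_id)) return(style_id)
  if (!style_id %in% names(styles))
    stop(sprintf("unknown style_id '%s' (registered: %s)", style_id,
                 paste(names(styles), collapse = ", ")), call. = FALSE)
  styles[[style_id]]
}

#' Apply or invert a registered stain color style
#'
#' @param bf H x W x 3 bright-field image in `[0, 1]`.
#' @param style_id name of a registered style or a style definition list with
#'   `gain`, `gamma`, `hue_deg`.
#' @param styles style registry (default [default_stain_styles()]).
#' @return restyled image clipped to `[0, 1]`, with its `style` attribute set;
#'   pixels clipped at any stage are flagged in the logical `clipped`
#'   attribute (the transform is exactly invertible everywhere else).
#' @export
apply_stain_style <- function(bf, style_id, styles = default_stain_styles()) {
  check_image(bf, "bf", channels = 3L)
  st <- resolve_style(style_id, styles)
  H <- dim(bf)[1L]; W <- dim(bf)[2L]
  m <- matrix(bf, H * W, 3L)
  m <- m %*% t(hue_rotation_matrix(st$hue_deg))
  clipped <- m < 0
  m[clipped] <- 0
  m <- sweep(m, 2L, st$gain, `*`)
  pos <- m > 0
  m[pos] <- exp(sweep(log(m), 2L, st$gamma, `*`)[pos])
  clipped <- clipped | m > 1
  # inversion mixes channels through the hue rotation, so a clip in any
  # channel makes the whole pixel non-invertible: flag per pixel
  clipped <- matrix(rowSums(clipped) > 0, nrow(m), 3L)
  out <- clip01(array(m, dim = dim(bf)))
  out <- bf_image(out, stain = attr(bf, "stain") %||% "unknown",
                  style = if (is.character(style_id)) style_id else "custom")
  attr(out, "clipped") <- array(clipped, dim = dim(bf))
  out
}

#' @rdname apply_stain_style
#' @export
invert_stain_style <- function(bf, style_id, styles = default_stain_styles()) {
  check_image(bf, "bf", channels = 3L)
  st <- resolve_style(style_id, styles)
  H <- dim(bf)[1L]; W <- dim(bf)[2L]
  m <- matrix(pmax(bf, 0), H * W, 3L)
  pos <- m > 0
  m[pos] <- exp(sweep(log(m), 2L, 1 / st$gamma, `*`)[pos])
  m <- sweep(m, 2L, st$gain, `/`)
  m <- m %*% t(hue_rotation_matrix(-st$hue_deg))
  out <- clip01(array(m, dim = dim(bf)))
  bf_image(out, stain = attr(bf, "stain") %||% "unknown", style = "native")
}

#' Apply an imaging/staining artifact
#'
#' `defocus` blurs the image with a Gaussian kernel; `tear` replaces a region
#' (a random compact patch covering an exact pixel fraction, or a supplied
#' polygon) with the per-channel background fill, emulating tissue tearing.
#'
#' @param image numeric matrix or H x W x C array.
#' @param kind `"defocus"` or `"tear"`.
#' @param params defocus: `sigma` (> 0); tear: `fraction` in (0, 1] or
#'   `polygon` (n x 2 matrix of (row, col) vertices), optional `fill`.
#' @param seed seed for random tear placement.
#' @return degraded image, same shape.
#' @export
apply_artifact <- function(image, kind = c("defocus", "tear"), params = list(),
                           seed = 1L) {
  kind <- match.arg(kind)
  check_image(image, "image")
  p <- params
  if (kind == "defocus") {
    sigma <- p$sigma %||% 4
    if (!is.numeric(sigma) || sigma <= 0) stop_field("sigma", "must be > 0")
    return(gaussian_blur(image, sigma))
  }
  H <- dim(image)[1L]; W <- dim(image)[2L]
  fill <- p$fill %||% channel_medians(image)
  if (!is.null(p$polygon)) {
    poly <- p$polygon
    if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L ||
        any(poly[, 1L] < 1) || any(poly[, 1L] > H) ||
        any(poly[, 2L] < 1) || any(poly[, 2L] > W))
      stop_field("polygon", "must be an n x 2 vertex matrix inside the canvas")
    mask <- point_in_polygon(H, W, poly)
  } else {
    fraction <- p$fraction %||% 0.2
    check_number(fraction, "fraction", min = 0, max = 1)
    m <- ceiling(fraction * H * W)
    mask <- matrix(FALSE, H, W)
    if (m > 0) {
      with_seed(seed, {
        cy <- runif(1, 1, H); cx <- runif(1, 1, W)
        d2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)
        ord <- order(d2, seq_along(d2))
        mask[ord[seq_len(m)]] <- TRUE
      })
    }
  }
  out <- image
  if (length(dim(image)) == 2L) out[mask] <- fill[1L]
  else for (c in seq_len(dim(image)[3L])) {
    ch <- out[, , c]; ch[mask] <- fill[(c - 1L) %% length(fill) + 1L]
    out[, , c] <- ch
  }
  out
}

# Even-odd rule rasterization of a polygon given as (row, col) vertices.
point_in_polygon <- function(H, W, poly) {
  py <- poly[, 1L]; px <- poly[, 2L]
  n <- nrow(poly)
  mask <- matrix(FALSE, H, W)
  yy <- rep(seq_len(H), W); xx <- rep(seq_len(W), each = H)
  inside <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > yy) != (py[j] > yy)) &
      (xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i] + 1e-300) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  mask[] <- inside
  mask
}

#' Write a phantom to disk
#'
#' Autofluorescence channels are written as one 32-bit float grayscale TIFF
#' each (scaled into `[0, 1]` by a per-channel factor recorded in the
#' sidecar, since TIFF intensity outside that range is not portable),
#' bright-field stains as RGB TIFFs, and the spec/seed/scales as a YAML
#' sidecar (`phantom.yaml`).
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  af_scale <- pmax(apply(phantom$af, 3L, max), 1)
  for (k in seq_along(AF_CHANNELS)) {
    pth <- file.path(dir, sprintf("af_%s.tif", AF_CHANNELS[k]))
    tiff::writeTIFF(phantom$af[, , k] / af_scale[k], pth,
                    bits.per.sample = 32L, compression = "none")
    paths <- c(paths, pth)
  }
  for (s in names(phantom$bf)) {
    pth <- file.path(dir, sprintf("bf_%s.tif", s))
    tiff::writeTIFF(unclass(phantom$bf[[s]]), pth, bits.per.sample = 32L,
                    compression = "none")
    paths <- c(paths, pth)
  }
  meta <- phantom$spec
  meta$af_mixing_matrix <- as.numeric(meta$af_mixing_matrix)
  meta$stain_od_matrix <- lapply(meta$stain_od_matrix, as.numeric)
  meta$af_scale <- as.numeric(af_scale)
  ypth <- file.path(dir, "phantom.yaml")
  yaml::write_yaml(unclass(meta), ypth)
  invisible(c(paths, ypth))
}
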