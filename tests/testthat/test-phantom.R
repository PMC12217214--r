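test_that("phantom generation is deterministic and physically ranged", {
  spec <- phantom_spec(width = 96, height = 96, seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$component_maps, b$component_maps)
  expect_identical(unclass(a$af), unclass(b$af))
  expect_identical(unclass(a$bf$EVG), unclass(b$bf$EVG))
  expect_identical(dim(a$af), c(96L, 96L, 4L))
  expect_true(all(unclass(a$af) >= 0))
  for (s in names(a$bf)) {
    expect_gte(min(a$bf[[s]]), 0)
    expect_lte(max(a$bf[[s]]), 1)
    expect_identical(dim(a$bf[[s]])[1:2], dim(a$component_maps)[1:2])
  }
})

test_that("empty tissue gives white bright-field and noise-only autofluorescence", {
  spec <- phantom_spec(width = 64, height = 64, nucleus_density = 0,
                       cytoplasm_fraction = 0, collagen_fraction = 0,
                       elastic_fiber_fraction = 0, noise_sd = 0.02, seed = 2)
  # zero out the background channel weights so components are identically zero
  m <- spec$af_mixing_matrix; m[, "background"] <- 0
  od <- lapply(spec$stain_od_matrix, function(x) { x[, "background"] <- 0; x })
  spec <- phantom_spec(width = 64, height = 64, nucleus_density = 0,
                       cytoplasm_fraction = 0, collagen_fraction = 0,
                       elastic_fiber_fraction = 0, noise_sd = 0.02, seed = 2,
                       af_mixing_matrix = m, stain_od_matrix = od)
  ph <- generate_phantom(spec)
  expect_equal(max(abs(ph$component_maps[, , 1:4])), 0)
  for (s in names(ph$bf)) expect_equal(min(ph$bf[[s]]), 1)  # transmittance 1
  # autofluorescence is clipped Gaussian noise around zero
  expect_lte(max(ph$af), 6 * 0.02)
  expect_gte(mean(unclass(ph$af) == 0), 0.3)  # about half clipped at zero
})

test_that("total bright-field absorbance matches the Beer-Lambert closed form", {
  # single nucleus-only component map of known area
  spec <- phantom_spec(width = 64, height = 64, nucleus_density = 0,
                       cytoplasm_fraction = 0, collagen_fraction = 0,
                       elastic_fiber_fraction = 0, noise_sd = 0, seed = 3)
  ph <- generate_phantom(spec)
  comp <- ph$component_maps * 0
  comp[20:29, 30:39, "nuclei"] <- 1          # area A = 100 px at density 1
  od <- spec$stain_od_matrix$HE
  cm <- matrix(comp, 64 * 64, 5)
  bf <- array(exp(-cm %*% t(od)), c(64, 64, 3))
  total_absorbance <- -sum(log(bf))
  A <- sum(comp[, , "nuclei"])
  expect_equal(total_absorbance, A * sum(od[, "nuclei"]), tolerance = 1e-6)
})

test_that("noise-free autofluorescence is an exact linear mixture of components", {
  spec <- phantom_spec(width = 96, height = 96, noise_sd = 0, seed = 7)
  ph <- generate_phantom(spec)
  cm <- matrix(ph$component_maps, 96 * 96, 5)
  rec <- array(cm %*% t(spec$af_mixing_matrix), c(96, 96, 4))
  expect_lt(max(abs(rec - unclass(ph$af))), 1e-9)
})

test_that("all stains of one phantom share identical geometry", {
  ph <- get_phantom(4)
  d <- dim(ph$bf$HE)
  expect_identical(dim(ph$bf$MT), d)
  expect_identical(dim(ph$bf$EVG), d)
  # tissue mask (low transmittance) overlaps across stains
  m1 <- luminance(ph$bf$HE) < 0.9
  m2 <- luminance(ph$bf$MT) < 0.9
  expect_gt(mean(m1 == m2), 0.8)
})

test_that("invalid phantom specs name the offending field", {
  expect_error(phantom_spec(width = 32), "width")
  expect_error(phantom_spec(cytoplasm_fraction = 1.2), "cytoplasm_fraction")
  expect_error(phantom_spec(af_mixing_matrix = matrix(-1, 4, 5)), "af_mixing_matrix")
  expect_error(phantom_spec(noise_sd = -0.1), "noise_sd")
})

test_that("misalignment with identity parameters returns the input unchanged", {
  img <- textured_image(96)
  r <- apply_misalignment(img, "rigid", list(shift = c(0, 0), rotation = 0))
  expect_equal(r$image, img)
  expect_equal(r$transform$rotation, 0)
  a <- apply_misalignment(img, "affine", list())
  expect_lt(max(abs(a$image - img)), 1e-9)
})

test_that("integer rigid shifts translate content exactly on the overlap", {
  img <- textured_image(96)
  r <- apply_misalignment(img, "rigid", list(shift = c(12, -7)))
  # content at (i, j) moved to (i + 12, j - 7)
  expect_equal(r$image[13:96, 1:89], img[1:84, 8:96])
})

test_that("elastic misalignment round-trips through the inverted field", {
  img <- textured_image(128)
  r <- apply_misalignment(img, "elastic", list(amplitude = 6, wavelength = 128))
  inv <- invert_transform(r$transform)
  back <- warp(r$image, inv)
  interior <- 16:112
  err <- mean(abs(back[interior, interior] - img[interior, interior]))
  expect_lt(err, 0.02 * diff(range(img)))
})

test_that("misalignment parameter bounds are enforced", {
  img <- textured_image(64)
  expect_error(apply_misalignment(img, "rigid", list(shift = c(20, 0))), "shift")
  expect_error(apply_misalignment(img, "rigid", list(rotation = 20)), "rotation")
  expect_error(apply_misalignment(img, "elastic", list(amplitude = 12)), "amplitude")
  expect_error(apply_misalignment(img, "elastic", list(smoothness = 8)), "smoothness")
})

test_that("stain styles: identity, gains, and inverse composition", {
  ph <- get_phantom(6)
  bf <- ph$bf$HE
  out <- apply_stain_style(bf, "identity")
  expect_equal(as.numeric(out), as.numeric(bf), tolerance = 1e-9)
  # gains on a mid-gray image scale channel means
  gray <- array(0.5, c(32, 32, 3))
  st <- list(gain = c(0.9, 1.0, 1.1), gamma = c(1, 1, 1), hue_deg = 0)
  res <- apply_stain_style(gray, st)
  expect_equal(apply(res, 3, mean), 0.5 * c(0.9, 1.0, 1.1), tolerance = 1e-9)
  # style then inverse recovers input where unclipped
  styled <- apply_stain_style(bf, "inst1")
  back <- invert_stain_style(styled, "inst1")
  unclipped <- !attr(styled, "clipped")
  expect_gt(mean(unclipped), 0.2)  # bright background gains past 1 and clips
  expect_lt(max(abs(back[unclipped] - bf[unclipped])), 1e-6)
  expect_error(apply_stain_style(bf, "nope"), "unknown style_id")
})

test_that("defocus artifact approaches identity at small sigma and lowers TV", {
  img <- textured_image(64)
  out <- apply_artifact(img, "defocus", list(sigma = 1e-3))
  expect_lt(max(abs(out - img)), 1e-6)
  blurred <- apply_artifact(img, "defocus", list(sigma = 4))
  expect_lt(tv_loss(blurred), tv_loss(img))
  expect_error(apply_artifact(img, "defocus", list(sigma = -1)), "sigma")
})

test_that("tear artifact changes exactly the requested pixel count", {
  img <- matrix(2, 50, 40)  # distinct from its own median? fill = median = 2
  img[1:25, ] <- 5          # make fill (median) differ from torn pixels
  f <- 0.13
  out <- apply_artifact(img, "tear", list(fraction = f, fill = -1), seed = 4)
  expect_identical(sum(out == -1), as.integer(ceiling(f * length(img))))
  # polygon tear
  poly <- rbind(c(5, 5), c(5, 20), c(20, 20), c(20, 5))
  out2 <- apply_artifact(img, "tear", list(polygon = poly, fill = -1))
  expect_gt(sum(out2 == -1), 100)
  expect_error(apply_artifact(img, "tear", list(polygon = rbind(c(0, 0), c(5, 5), c(9, 1)))),
               "polygon")
})

test_that("phantoms round-trip to disk as TIFF + YAML sidecar", {
  ph <- get_phantom(8, size = 128L)
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "af_DAPI.tif")))
  expect_true(file.exists(file.path(dir, "bf_HE.tif")))
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  expect_equal(meta$seed, 8)
  af1 <- tiff::readTIFF(file.path(dir, "af_DAPI.tif")) * meta$af_scale[1L]
  expect_equal(af1, ph$af[, , 1], tolerance = 1e-6)  # 32-bit float storage
})
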