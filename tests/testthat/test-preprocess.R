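test_that("background estimation: constants, delta kernel value, conservation", {
  cst <- matrix(3.7, 40, 40)
  expect_equal(estimate_background(cst, sigma = 5), cst, tolerance = 1e-9)
  # delta image: peak equals the normalized discrete kernel center weight
  n <- 129L
  delta <- matrix(0, n, n); delta[65, 65] <- 1
  bg <- gaussian_blur(delta, sigma = 2)
  k <- dnorm(-64:64, sd = 2); k2 <- outer(k, k) / sum(k)^2
  expect_equal(bg[65, 65], k2[65, 65], tolerance = 1e-9)
  # interior-supported mass is conserved
  img <- matrix(0, 101, 101); img[40:60, 40:60] <- runif(441)
  expect_equal(sum(gaussian_blur(img, 3)), sum(img), tolerance = 1e-6)
})

test_that("normalization: constants to one, zeros to zero, pattern recovery", {
  img <- matrix(2.5, 30, 30)
  bg <- estimate_background(img, 4)
  expect_equal(normalize_channel(img, bg), matrix(1, 30, 30), tolerance = 1e-9)
  expect_equal(normalize_channel(matrix(0, 8, 8), matrix(1, 8, 8)), matrix(0, 8, 8))
  # synthesized smooth background times pattern: division recovers the pattern
  n <- 256L
  rr <- outer(seq_len(n), rep(1, n)); cc <- t(rr)
  smooth_bg <- 1 + 0.5 * sin(rr / 80) + 0.3 * cos(cc / 90)
  pattern <- 1 + 0.2 * sin(rr / 4) * cos(cc / 5)
  img2 <- smooth_bg * pattern
  est <- estimate_background(img2, sigma = 30)
  rec <- normalize_channel(img2, est)
  interior <- 40:216
  expect_lt(mean(abs(rec[interior, interior] - pattern[interior, interior])), 0.05)
  expect_error(normalize_channel(matrix(1, 4, 4), matrix(1, 5, 5)), "identical dimensions")
})

test_that("normalization is scale-equivariant", {
  img <- textured_image(96) + 0.1
  bg1 <- estimate_background(img, 10)
  bg2 <- estimate_background(7 * img, 10)
  expect_lt(max(abs(normalize_channel(7 * img, bg2) - normalize_channel(img, bg1))), 1e-9)
})

test_that("FOV tiling: counts, origins, undersized input", {
  cfg <- preprocess_config(fov_size = 32L, crop_size = 16L, patch_size = 8L)
  wsi <- matrix(runif(64 * 64), 64, 64)
  tiles <- tile_wsi(wsi, cfg)
  expect_length(tiles, 4L)
  expect_identical(tiles[[1L]]$index$fov_origin, c(0L, 0L))
  expect_identical(tiles[[4L]]$index$fov_origin, c(32L, 32L))
  expect_identical(attr(tiles, "dropped_px"), 0L)
  one <- tile_wsi(matrix(1, 32, 32), cfg)
  expect_length(one, 1L)
  expect_identical(one[[1L]]$index$fov_origin, c(0L, 0L))
  expect_warning(none <- tile_wsi(matrix(1, 31, 32), cfg), "smaller than one FOV")
  expect_length(none, 0L)
  # remainder dropped and counted
  t2 <- tile_wsi(matrix(1, 70, 64), cfg)
  expect_length(t2, 4L)
  expect_identical(attr(t2, "dropped_px"), 70L * 64L - 4L * 32L * 32L)
})

test_that("tile and crop coordinates compose invertibly", {
  cfg <- preprocess_config(fov_size = 32L, crop_size = 16L, patch_size = 8L)
  wsi <- matrix(seq_len(96 * 96), 96, 96)
  tiles <- tile_wsi(wsi, cfg)
  for (t in tiles) {
    cropped <- center_crop(t$image, cfg$crop_size)
    off <- attr(cropped, "offset")
    expect_identical(t$index$crop_origin, t$index$fov_origin + off)
    # every cropped pixel maps back to its WSI value through the index
    o <- t$index$crop_origin
    expect_identical(cropped[1L, 1L], wsi[o[1L] + 1L, o[2L] + 1L])
    expect_identical(cropped[16L, 16L], wsi[o[1L] + 16L, o[2L] + 16L])
  }
})

test_that("center crop offsets follow the floor rule", {
  expect_identical(attr(center_crop(matrix(0, 64, 64), 32), "offset"), c(16L, 16L))
  # the standard FOV -> crop geometry: (3248 - 2048) / 2 = 600
  expect_identical(attr(center_crop(matrix(0, 3248, 3248), 2048), "offset"), c(600L, 600L))
  odd <- center_crop(matrix(seq_len(25), 5, 5), 2)
  expect_identical(attr(odd, "offset"), c(1L, 1L))
  same <- center_crop(matrix(1:4, 2, 2), 2)
  expect_identical(same[, ], matrix(1:4, 2, 2)[, ])
  expect_error(center_crop(matrix(0, 4, 4), 5), "exceeds image size")
})

test_that("patch standardization: exact two-pixel case, degenerate rule, moments", {
  expect_equal(standardize_patch(matrix(c(0, 2), 1, 2))[1, ], c(-1, 1))
  expect_equal(standardize_patch(matrix(5, 4, 4)), matrix(0, 4, 4))
  p <- array(runif(16 * 16 * 3), c(16, 16, 3))
  s <- standardize_patch(p)
  for (c in 1:3) {
    expect_lt(abs(mean(s[, , c])), 1e-6)
    expect_lt(abs(mean(s[, , c]^2) - 1), 1e-6)
  }
})

test_that("augmentation transforms compose to identity and stay paired", {
  img <- matrix(runif(64), 8, 8)
  r4 <- img
  for (i in 1:4) r4 <- vistain:::rot90_ccw(r4)
  expect_identical(r4, img)
  expect_identical(vistain:::flip_rows(vistain:::flip_rows(img)), img)
  # same seed applies the same transform to both pair members (marker pixel)
  af <- array(0, c(8, 8, 4)); af[2, 3, 1] <- 1
  bf <- array(0, c(8, 8, 3)); bf[2, 3, 1] <- 1
  for (seed in 1:8) {
    out <- augment_pair(af, bf, seed = seed)
    expect_identical(which(out$af[, , 1] == 1), which(out$bf[, , 1] == 1))
  }
  expect_error(augment_pair(array(0, c(8, 8, 4)), array(0, c(9, 8, 3))),
               "spatial dimensions")
})

test_that("augmentation draw is uniform over the 8 transforms", {
  counts <- table(vapply(1:400, function(s) {
    out <- augment_pair(matrix(0, 4, 4), matrix(0, 4, 4), seed = s)
    paste(out$rotation, out$flip)
  }, ""))
  expect_length(counts, 8L)
  expect_gt(min(counts), 20)
})
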