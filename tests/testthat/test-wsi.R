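test_that("stitch plans cover the canvas with unit weight sums", {
  plan <- make_stitch_plan(c(512L, 512L), tile = 256L, overlap = 64L)
  expect_equal(plan$origins_r[1L], 0L)
  expect_equal(tail(plan$origins_r, 1L), 512L - 256L)
  ws <- stitch_weight_sum(plan)
  expect_lt(max(abs(ws - 1)), 1e-6)
  # random geometries
  set.seed(8)
  for (i in 1:6) {
    H <- sample(100:400, 1); W <- sample(100:400, 1)
    tl <- sample(40:120, 1); ov <- sample(0:(tl - 1), 1)
    p <- make_stitch_plan(c(H, W), tl, ov)
    expect_lt(max(abs(stitch_weight_sum(p) - 1)), 1e-6)
  }
})

test_that("zero overlap on a grid-aligned canvas gives indicator weights", {
  plan <- make_stitch_plan(c(128L, 128L), tile = 64L, overlap = 0L)
  for (wr in plan$w_r) expect_true(all(wr %in% c(0, 1)))
  expect_equal(length(plan$origins_r), 2L)
})

test_that("tiles larger than the canvas degenerate to a single tile", {
  plan <- make_stitch_plan(c(100L, 80L), tile = 256L, overlap = 32L)
  expect_equal(plan$tile, 80L)
  expect_equal(length(plan$origins_c), 1L)
  expect_lt(max(abs(stitch_weight_sum(plan) - 1)), 1e-6)
})

test_that("blending crops of a global image reproduces it", {
  set.seed(5)
  global <- array(runif(200 * 160 * 3), c(200, 160, 3))
  plan <- make_stitch_plan(c(200L, 160L), tile = 96L, overlap = 32L)
  tiles <- list(); k <- 1L
  for (r0 in plan$origins_r) for (c0 in plan$origins_c) {
    tiles[[k]] <- global[r0 + seq_len(plan$tile), c0 + seq_len(plan$tile), , drop = FALSE]
    k <- k + 1L
  }
  out <- blend_tiles(tiles, plan)
  expect_lt(max(abs(out - global)), 1e-6)
})

test_that("multi-stain outputs share dimensions and stitch-plan digests", {
  ph <- get_phantom(16, 128L)
  af <- unclass(ph$af)
  toy <- function(stain) {
    od <- default_stain_od()[[stain]][, 1:4]
    function(af_tile) {
      H <- dim(af_tile)[1L]; W <- dim(af_tile)[2L]
      m <- matrix(af_tile, H * W, 4L)
      array(exp(-m %*% t(od)), c(H, W, 3L))
    }
  }
  out <- virtually_stain_wsi(af, list(HE = toy("HE"), MT = toy("MT"),
                                      EVG = toy("EVG")),
                             tile = 64L, overlap = 16L)
  d <- dim(out$HE)
  expect_identical(dim(out$MT), d)
  expect_identical(dim(out$EVG), d)
  digests <- vapply(out, attr, "", "plan_digest")
  expect_length(unique(digests), 1L)
})

test_that("constant input with an identity-like model blends seamlessly", {
  af <- array(0.7, c(160, 160, 4))
  model <- function(af_tile) {
    v <- mean(af_tile)
    array(v, c(dim(af_tile)[1:2], 3L))
  }
  out <- virtually_stain_wsi(af, list(HE = model), tile = 64L, overlap = 16L)$HE
  interior <- 8:152
  expect_lt(max(out[interior, interior, ]) - min(out[interior, interior, ]), 1e-6)
})

test_that("tiled inference approximates single-pass inference", {
  ph <- get_phantom(17, 128L)
  af <- unclass(ph$af)
  set.seed(4)
  cfg <- gan_config(patch_size = 32L, unet_levels = 3L, base_width = 4L)
  G <- build_generator(cfg)
  model <- function(af_tile) predict_stain(G, af_tile, standardize = FALSE)
  whole <- clip01(predict_stain(G, af, standardize = FALSE))
  tiled <- virtually_stain_wsi(af, list(HE = model), tile = 64L, overlap = 16L)$HE
  expect_lt(mean(abs(tiled - whole)), 0.01 * diff(range(whole)))
})

test_that("WSI export round-trips losslessly with metadata", {
  dir <- withr::local_tempdir()
  img <- array(runif(160 * 128 * 3), c(160, 128, 3))
  pth <- file.path(dir, "he.tif")
  export_wsi(img, pth, pixel_size_um = 0.325)
  back <- read_wsi(pth)
  expect_equal(back, img, tolerance = 1e-6, ignore_attr = TRUE)  # float32
  expect_equal(attr(back, "pixel_size_um"), 0.325)
  # pyramid pages exist and shrink by 2x
  pages <- tiff::readTIFF(pth, all = TRUE)
  expect_gte(length(pages), 2L)
  expect_equal(dim(pages[[2L]])[1:2], dim(img)[1:2] / 2L)
  # multi-stain export: equal dimensions in all files
  for (s in c("a", "b", "c")) export_wsi(img, file.path(dir, paste0(s, ".tif")))
  dims <- sapply(c("a", "b", "c"), function(s)
    dim(tiff::readTIFF(file.path(dir, paste0(s, ".tif"))))[1:2])
  expect_true(all(dims == dims[, 1L]))
  expect_error(export_wsi(img * 2, file.path(dir, "bad.tif")), "\\[0, 1\\]")
})
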