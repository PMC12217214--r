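test_that("bf_to_proxy inverts luminance", {
  white <- array(1, c(8, 8, 3)); black <- array(0, c(8, 8, 3))
  expect_equal(bf_to_proxy(white), matrix(0, 8, 8))
  expect_equal(bf_to_proxy(black), matrix(1, 8, 8))
  gray <- array(0.5, c(8, 8, 3))
  expect_equal(bf_to_proxy(gray), matrix(0.5, 8, 8), tolerance = 1e-12)
})

test_that("rigid registration: self-match, brute-force shift equivalence", {
  fx <- textured_image(128)
  tf0 <- register_rigid(fx, fx, angle_grid = seq(-2, 2, 0.5))
  expect_equal(tf0$rotation, 0)
  expect_equal(tf0$shift, c(0, 0))
  expect_gt(tf0$correlation_score, 0.999)
  # integer shift recovered exactly, matching brute-force spatial correlation
  small <- fx[1:96, 1:96]
  mis <- apply_misalignment(small, "rigid", list(shift = c(12, -7)))
  tf <- register_rigid(small, mis$image, angle_grid = 0, max_shift = 20)
  expect_identical(tf$shift, c(12, -7))
  # brute-force spatial-domain correlation oracle over all shifts
  f0 <- small - mean(small); m0 <- mis$image - mean(mis$image)
  best <- c(NA, NA); bestv <- -Inf
  for (dr in -15:15) for (dc in -15:15) {
    rs <- max(1, 1 + dr):min(96, 96 + dr)
    cs <- max(1, 1 + dc):min(96, 96 + dc)
    v <- sum(f0[rs - dr, cs - dc] * m0[rs, cs])
    if (v > bestv) { bestv <- v; best <- c(dr, dc) }
  }
  expect_equal(best, tf$shift)
  expect_error(register_rigid(matrix(1, 32, 32), matrix(1, 32, 32)), "no texture")
})

test_that("rigid registration recovers rotation on the search grid", {
  fx <- textured_image(128)
  mis <- apply_misalignment(fx, "rigid", list(shift = c(9, 4), rotation = 2.5))
  tf <- register_rigid(fx, mis$image, angle_grid = seq(-5, 5, 0.5), max_shift = 16)
  expect_lte(abs(tf$rotation - 2.5), 0.5)
  expect_identical(tf$shift, c(9, 4))
})

test_that("affine registration recovers identity and known transforms", {
  ph <- get_phantom(3, 128L)
  fx <- rowMeans(unclass(ph$af), dims = 2)      # autofluorescence side
  mv <- bf_to_proxy(ph$bf$HE)                   # bright-field side (multimodal)
  tf0 <- register_affine(fx, mv)
  corners <- rbind(c(0, 0), c(0, 127), c(127, 0), c(127, 127))
  disp <- function(tf) {
    q <- corners %*% t(tf$matrix[, 1:2]) + rep(1, 4) %*% t(tf$matrix[, 3])
    mean(sqrt(rowSums((q - corners)^2)))
  }
  expect_lt(disp(tf0), 0.5)
  # known affine misalignment
  mis <- apply_misalignment(mv, "affine",
                            list(scale = 1.03, rotation = 1, shift = c(4, -3)))
  tf <- register_affine(fx, mis$image)
  true_m <- mis$transform$matrix
  q_true <- corners %*% t(true_m[, 1:2]) + rep(1, 4) %*% t(true_m[, 3])
  q_est <- corners %*% t(tf$matrix[, 1:2]) + rep(1, 4) %*% t(tf$matrix[, 3])
  expect_lt(mean(sqrt(rowSums((q_true - q_est)^2))), 1)
  # mutual information does not decrease at the solution
  expect_gte(attr(tf, "mi"), attr(tf, "mi_identity"))
})

test_that("elastic registration: null recovery and sinusoidal field recovery", {
  fx <- textured_image(128)
  f0 <- register_elastic(fx, fx)
  expect_lt(max(sqrt(f0$u^2 + f0$v^2)), 0.25)
  mis <- apply_misalignment(fx, "elastic", list(amplitude = 6, wavelength = 128))
  fld <- register_elastic(fx, mis$image)
  truth <- invert_transform(mis$transform)
  interior <- 17:112
  epe <- sqrt((fld$u - truth$u)^2 + (fld$v - truth$v)^2)
  expect_lt(mean(epe[interior, interior]), 1.5)
  # warping with the recovered field reduces the residual by >= 60%
  before <- sqrt(mean((fx - mis$image)^2))
  after <- sqrt(mean((fx[interior, interior] -
                        warp(mis$image, fld)[interior, interior])^2))
  expect_lt(after, 0.4 * before)
  expect_error(register_elastic(matrix(0, 64, 64), matrix(0, 64, 64)),
               "untextured")
})

test_that("returned elastic fields satisfy the smoothness bound", {
  fx <- textured_image(128)
  for (amp in c(3, 6)) {
    mis <- apply_misalignment(fx, "elastic", list(amplitude = amp, wavelength = 128))
    fld <- register_elastic(fx, mis$image)
    gu <- max(abs(diff(fld$u)), abs(t(diff(t(fld$u)))))
    gv <- max(abs(diff(fld$v)), abs(t(diff(t(fld$v)))))
    expect_lt(max(gu, gv), 0.5)
    expect_lt(max(sqrt(fld$u^2 + fld$v^2)), 10 + 1e-9)
  }
})

test_that("registration operations are deterministic", {
  fx <- textured_image(96)
  mis <- apply_misalignment(fx, "elastic", list(amplitude = 4, smoothness = 48),
                            seed = 5)
  f1 <- register_elastic(fx, mis$image)
  f2 <- register_elastic(fx, mis$image)
  expect_identical(f1$u, f2$u)
  t1 <- register_rigid(fx, mis$image, angle_grid = seq(-1, 1, 0.5))
  t2 <- register_rigid(fx, mis$image, angle_grid = seq(-1, 1, 0.5))
  expect_identical(t1$shift, t2$shift)
})

test_that("training-registration cycle: aligned pairs stop at one cycle", {
  ph <- get_phantom(11, 128L)
  pairs <- list(list(af = unclass(ph$af), bf = unclass(ph$bf$HE)))
  oracle <- function(prs) function(af) unclass(ph$bf$HE)
  res <- training_registration_cycle(pairs, oracle, max_cycles = 3L)
  expect_true(res$report$converged)
  expect_equal(res$report$cycles, 1L)
  expect_lt(res$report$median_displacement[1L], 1)
})

test_that("training-registration cycle converges with an oracle stainer", {
  ph <- get_phantom(12, 128L)
  bf_true <- unclass(ph$bf$HE)
  mis <- apply_misalignment(bf_true, "elastic",
                            list(amplitude = 4, smoothness = 48), seed = 3)
  pairs <- list(list(af = unclass(ph$af), bf = mis$image))
  oracle <- function(prs) function(af) bf_true
  res <- training_registration_cycle(pairs, oracle, max_cycles = 3L)
  expect_lte(length(res$report$median_displacement), 3L)
  final_fld <- register_elastic(bf_to_proxy(bf_true),
                                bf_to_proxy(res$pairs[[1L]]$bf))
  expect_lt(median(sqrt(final_fld$u^2 + final_fld$v^2)), 1)
  # per-cycle median displacement never increases
  md <- res$report$median_displacement
  if (length(md) > 1L) expect_true(all(diff(md) <= 1e-9))
})

test_that("training-registration cycle aborts on a divergent trainer", {
  ph <- get_phantom(13, 128L)
  pairs <- list(list(af = unclass(ph$af), bf = unclass(ph$bf$HE)))
  bad <- function(prs) function(af) matrix(NaN, nrow(af), ncol(af))
  res <- training_registration_cycle(pairs, bad, max_cycles = 3L)
  expect_false(res$report$converged)
  expect_true(isTRUE(attr(res$report, "diverged")))
  expect_error(training_registration_cycle(pairs, bad, max_cycles = 2L),
               "max_cycles")
})
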