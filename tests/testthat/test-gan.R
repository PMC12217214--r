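test_that("loss operations match independent direct-summation oracles", {
  # hand-rolled reference implementations, element loops only
  l1_ref <- function(a, b) {
    s <- 0; n <- 0
    for (i in seq_along(a)) { s <- s + abs(a[i] - b[i]); n <- n + 1 }
    s / n
  }
  tv_ref <- function(a) {
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    s <- 0
    for (c in seq_len(dim(a)[3])) for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2])) {
      if (i < dim(a)[1]) s <- s + abs(a[i + 1, j, c] - a[i, j, c])
      if (j < dim(a)[2]) s <- s + abs(a[i, j + 1, c] - a[i, j, c])
    }
    s
  }
  set.seed(17)
  for (trial in 1:30) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    a <- matrix(rnorm(h * w), h, w); b <- matrix(rnorm(h * w), h, w)
    d1 <- runif(1); d2 <- runif(1)
    expect_equal(l1_loss(a, b), l1_ref(a, b), tolerance = 1e-9)
    expect_equal(tv_loss(a), tv_ref(a), tolerance = 1e-9)
    expect_equal(generator_loss(a, b, d1),
                 l1_ref(a, b) + 0.02 * tv_ref(a) + 100 * (1 - d1)^2,
                 tolerance = 1e-9)
    expect_equal(discriminator_loss(d1, d2), d1^2 + (1 - d2)^2, tolerance = 1e-12)
  }
  # closed-form anchor cases
  expect_equal(l1_loss(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  expect_equal(l1_loss(matrix(c(0, 0, 1, 1), 2), matrix(0, 2, 2)), 0.5)
  expect_equal(tv_loss(matrix(0.3, 5, 5)), 0)
  expect_equal(tv_loss(matrix(c(0, 0, 1, 1), 2)), 2)
  a <- matrix(runif(9), 3, 3)
  expect_equal(tv_loss(3 * a), 3 * tv_loss(a))
  cst <- matrix(0.4, 4, 4)
  expect_equal(generator_loss(cst, cst, 1), 0)
  expect_equal(generator_loss(matrix(c(0, 0, 1, 1), 2), matrix(0, 2, 2), 0.5),
               0.5 + 0.02 * 2 + 100 * 0.25)
  expect_equal(generator_loss(a, a * 0, 0.123, beta = 0),
               generator_loss(a, a * 0, 0.999, beta = 0))
  expect_equal(discriminator_loss(0, 1), 0)
  expect_equal(discriminator_loss(1, 0), 2)
  expect_equal(discriminator_loss(0.5, 0.5), 0.5)
  expect_error(generator_loss(a, a, 1.2), "outside")
  expect_error(discriminator_loss(-0.1, 0.5), "outside")
  expect_error(tv_loss(matrix(1, 1, 1)), "1 x 1")
})

test_that("generator maps 4 channels to 3 at unchanged spatial size", {
  cfg <- gan_config(patch_size = 64L, base_width = 4L)
  set.seed(1)
  G <- build_generator(cfg)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  y <- predict_stain(G, x, clip = FALSE)
  expect_identical(dim(y), c(64L, 64L, 3L))
  # indivisible sizes are rejected (100 not divisible by 2^4)
  bad <- array(rnorm(100 * 100 * 4), c(100, 100, 4))
  expect_error(predict_stain(G, bad), "not divisible")
  expect_error(gan_config(patch_size = 100L), "divisible")
})

test_that("discriminator emits per-patch probabilities, deterministically", {
  cfg <- gan_config(patch_size = 64L, base_width = 4L)
  set.seed(2)
  D <- build_discriminator(cfg)
  x <- array(runif(64 * 64 * 3 * 5), c(64, 64, 3, 5))
  s1 <- vistain:::disc_forward(D, x)$s
  s2 <- vistain:::disc_forward(D, x)$s
  expect_length(s1, 5L)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, s2)
})

test_that("training keeps the 3:1 generator:discriminator schedule", {
  pairs <- make_pairs(31, size = 128L, patch = 32L)
  cfg <- gan_config(base_width = 4L, patch_size = 32L, unet_levels = 3L,
                    batch_size = 2L, val_every = 150L, seed = 5)
  st <- train_gan(pairs, cfg, g_steps = 300L)
  expect_equal(st$g_steps, 300L)
  expect_equal(st$d_steps, 100L)
  expect_equal(nrow(st$history), 300L)
  # schedule invariant holds along the whole trajectory
  d_after <- cumsum(!is.na(st$history$ld))
  expect_true(all(abs(st$history$step - 3 * d_after) <= 3))
})

test_that("training is reproducible under a fixed seed", {
  pairs <- make_pairs(32, size = 128L, patch = 32L)
  cfg <- gan_config(base_width = 4L, patch_size = 32L, unet_levels = 3L,
                    batch_size = 2L, val_every = 100L, seed = 9)
  a <- train_gan(pairs, cfg, g_steps = 10L)
  b <- train_gan(pairs, cfg, g_steps = 10L)
  expect_equal(a$history$lg, b$history$lg, tolerance = 1e-5)
  expect_equal(a$history$lg[1:10], b$history$lg[1:10], tolerance = 1e-12)
})

test_that("a short run reduces the validation generator loss", {
  pairs <- make_pairs(33:34, size = 128L, patch = 32L, noise_sd = 0)
  val <- make_pairs(35, size = 128L, patch = 32L, noise_sd = 0)
  cfg <- gan_config(base_width = 4L, patch_size = 32L, unet_levels = 3L,
                    batch_size = 4L, val_every = 10L, seed = 3)
  st <- train_gan(pairs, cfg, validation_pairs = val, g_steps = 120L)
  vls <- vapply(st$checkpoints, `[[`, 0, "val_loss")
  expect_lt(min(vls), vls[1L])
  expect_lt(tail(vls, 1L), vls[1L])
  expect_false(st$diverged)
})

test_that("model selection picks the lowest validation loss, latest on ties", {
  fake_state <- function(vls, steps) {
    structure(list(checkpoints = Map(function(v, s)
      list(step = s, val_loss = v, generator = paste0("G", s)), vls, steps)),
      class = "gan_state")
  }
  expect_equal(select_model(fake_state(c(5, 3.2, 4.1), c(100, 200, 300)))$step, 200)
  expect_equal(select_model(fake_state(7.7, 50))$step, 50)
  expect_equal(select_model(fake_state(c(3, 3), c(100, 200)))$step, 200)
  expect_error(select_model(structure(list(checkpoints = list()), class = "gan_state")),
               "no checkpoints")
})

test_that("gan_config validates its invariants", {
  expect_error(gan_config(alpha = -1), "alpha")
  expect_error(gan_config(lr_g = 0), "lr_g")
  expect_error(gan_config(batch_size = 0), "batch_size")
  cfg <- gan_config()
  expect_equal(cfg$alpha, 0.02)
  expect_equal(cfg$beta, 100)
  expect_equal(cfg$lr_g, 1e-4)
  expect_equal(cfg$lr_d, 1e-5)
  expect_equal(cfg$gd_ratio, c(3L, 1L))
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$unet_levels, 5L)
})
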