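#' Style-harmonization training configuration
#'
#' Settings for the unpaired, cycle-consistent color-style translator used to
#' standardize ground-truth stain appearance across staining laboratories
#' before GAN training. Two small residual translators (RGB to RGB; a 1 x 1
#' color mixing layer, one 3 x 3 convolution, and a 1 x 1 projection added to
#' the input) are trained against two patch discriminators with least-squares
#' adversarial losses plus cycle-consistency and identity terms. Translators
#' act purely on color: near-identity initialization plus the cycle penalty
#' keep geometry untouched.
#'
#' @param crop_size training crop side, px (default 128).
#' @param batch_size crops per step.
#' @param steps training steps.
#' @param lr Adam learning rate for all four networks.
#' @param cycle_weight weight of the cycle-reconstruction L1 terms.
#' @param identity_weight weight of the identity L1 terms.
#' @param width translator/discriminator feature width.
#' @param seed integer seed.
#' @return a `style_config` object.
#' @export
style_config <- function(crop_size = 128L, batch_size = 4L, steps = 400L,
                         lr = 2e-4, cycle_weight = 10, identity_weight = 2,
                         width = 8L, seed = 1L) {
  check_number(crop_size, "crop_size", min = 8)
  check_number(steps, "steps", min = 1)
  check_number(lr, "lr"); if (lr <= 0) stop_field("lr", "must be > 0")
  check_number(cycle_weight, "cycle_weight", min = 0)
  check_number(identity_weight, "identity_weight", min = 0)
  structure(list(crop_size = as.integer(crop_size), batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lr = lr, cycle_weight = cycle_weight,
                 identity_weight = identity_weight, width = as.integer(width),
                 seed = as.integer(seed)),
            class = "style_config")
}

style_translator_init <- function(width) {
  # near-identity start: small weights make f(x) ~ 0, so T(x) ~ x
  list(c1 = conv_layer(3L, width, 1L, gain = 0.2),
       c2 = conv_layer(width, width, 3L, gain = 0.2),
       c3 = conv_layer(width, 3L, 1L, gain = 0.05))
}

style_t_fwd <- function(P, x) {
  cache <- list(x = x)
  cache$p1 <- conv_fwd(x, P$c1); a1 <- lrelu(cache$p1)
  cache$a1 <- a1
  cache$p2 <- conv_fwd(a1, P$c2); a2 <- lrelu(cache$p2)
  cache$a2 <- a2
  r <- conv_fwd(a2, P$c3)
  list(y = x + r, cache = cache)
}

style_t_bwd <- function(P, cache, dy) {
  bw3 <- conv_bwd(cache$a2, P$c3, dy)
  d2 <- lrelu_bwd(bw3$dx, cache$p2)
  bw2 <- conv_bwd(cache$a1, P$c2, d2)
  d1 <- lrelu_bwd(bw2$dx, cache$p1)
  bw1 <- conv_bwd(cache$x, P$c1, d1)
  list(grads = list(c1 = list(w = bw1$dw, b = bw1$db),
                    c2 = list(w = bw2$dw, b = bw2$db),
                    c3 = list(w = bw3$dw, b = bw3$db)),
       dx = dy + bw1$dx)
}

style_disc_init <- function(width) {
  list(l1 = conv_layer(3L, width, 3L, stride = 2L),
       l2 = conv_layer(width, 2L * width, 3L, stride = 2L),
       l3 = conv_layer(2L * width, 4L * width, 3L, stride = 2L),
       head = conv_layer(4L * width, 1L, 1L, gain = 1))
}

# Least-squares adversarial discriminator on the *raw* mean logit (LSGAN
# convention: no sigmoid, so the gradient does not vanish when D becomes
# confident — essential for the color push to reach the translators).
style_d_fwd <- function(P, x) {
  cache <- list(x = x)
  cache$p1 <- conv_fwd(x, P$l1); a1 <- lrelu(cache$p1); cache$a1 <- a1
  cache$p2 <- conv_fwd(a1, P$l2); a2 <- lrelu(cache$p2); cache$a2 <- a2
  cache$p3 <- conv_fwd(a2, P$l3); a3 <- lrelu(cache$p3); cache$a3 <- a3
  z <- conv_fwd(a3, P$head)
  d <- dim(z)
  cache$z_dim <- d
  list(s = apply(z, 4L, mean), cache = cache)
}

style_d_bwd <- function(P, cache, ds, need_dx = FALSE) {
  d <- cache$z_dim
  per <- ds / (d[1L] * d[2L])
  dz <- array(rep(per, each = d[1L] * d[2L] * d[3L]), dim = d)
  bwh <- conv_bwd(cache$a3, P$head, dz)
  d3 <- lrelu_bwd(bwh$dx, cache$p3)
  bw3 <- conv_bwd(cache$a2, P$l3, d3)
  d2 <- lrelu_bwd(bw3$dx, cache$p2)
  bw2 <- conv_bwd(cache$a1, P$l2, d2)
  d1 <- lrelu_bwd(bw2$dx, cache$p1)
  bw1 <- conv_bwd(cache$x, P$l1, d1, need_dx = need_dx)
  list(grads = list(l1 = list(w = bw1$dw, b = bw1$db),
                    l2 = list(w = bw2$dw, b = bw2$db),
                    l3 = list(w = bw3$dw, b = bw3$db),
                    head = list(w = bwh$dw, b = bwh$db)),
       dx = if (need_dx) bw1$dx else NULL)
}

sample_crops <- function(set, n, crop) {
  out <- vector("list", n)
  for (k in seq_len(n)) {
    img <- set[[sample.int(length(set), 1L)]]
    H <- dim(img)[1L]; W <- dim(img)[2L]
    cs <- min(crop, H, W)
    r0 <- if (H > cs) sample.int(H - cs + 1L, 1L) - 1L else 0L
    c0 <- if (W > cs) sample.int(W - cs + 1L, 1L) - 1L else 0L
    out[[k]] <- img[r0 + seq_len(cs), c0 + seq_len(cs), , drop = FALSE]
  }
  d1 <- dim(out[[1L]])
  array(unlist(out), dim = c(d1, n))
}

#' Train an unpaired stain-style mapper
#'
#' Cycle-consistent adversarial training between two unpaired image sets:
#' translator A->B learns to render set-A images in set-B's color style and
#' vice versa, two discriminators judge style membership, and cycle +
#' identity L1 terms pin geometry and prevent drift. All four networks are
#' updated once per step with Adam. Training aborts (state flagged
#' `diverged`) if any loss becomes non-finite.
#'
#' @param set_a,set_b lists (>= 8 each) of H x W x 3 images in `[0, 1]`,
#'   style tags taken from the first image's `style` attribute if present.
#' @param cfg a [style_config()].
#' @return a `style_mapper` with `forward`/`backward` translator parameters,
#'   discriminators, loss `history`, and `source_style`/`target_style` tags.
#' @export
train_style_mapper <- function(set_a, set_b, cfg = style_config()) {
  if (length(set_a) < 8L || length(set_b) < 8L)
    stop_field("set_a/set_b", "need at least 8 images per style set")
  with_seed(cfg$seed, {
    Tab <- style_translator_init(cfg$width)
    Tba <- style_translator_init(cfg$width)
    Da <- style_disc_init(cfg$width)
    Db <- style_disc_init(cfg$width)
    oTab <- adam_init(Tab); oTba <- adam_init(Tba)
    oDa <- adam_init(Da); oDb <- adam_init(Db)
    lam <- cfg$cycle_weight; lid <- cfg$identity_weight
    hist <- data.frame(step = integer(0), adv = numeric(0), cycle = numeric(0),
                       identity = numeric(0), d = numeric(0))
    diverged <- FALSE
    n <- cfg$batch_size
    for (step in seq_len(cfg$steps)) {
      a <- sample_crops(set_a, n, cfg$crop_size)
      b <- sample_crops(set_b, n, cfg$crop_size)
      numel <- prod(dim(a)[1:3])
      # ---- translator update ----
      fab <- style_t_fwd(Tab, a)   # fake B
      fba <- style_t_fwd(Tba, b)   # fake A
      rec_a <- style_t_fwd(Tba, fab$y)
      rec_b <- style_t_fwd(Tab, fba$y)
      id_b <- style_t_fwd(Tab, b)
      id_a <- style_t_fwd(Tba, a)
      sb <- style_d_fwd(Db, fab$y)
      sa <- style_d_fwd(Da, fba$y)
      adv <- mean((1 - sb$s)^2) + mean((1 - sa$s)^2)
      cyc <- mean(abs(rec_a$y - a)) + mean(abs(rec_b$y - b))
      idn <- mean(abs(id_b$y - b)) + mean(abs(id_a$y - a))
      lg <- adv + lam * cyc + lid * idn
      if (!is.finite(lg)) { diverged <- TRUE; break }
      # gradients wrt fake images
      d_fab <- style_d_bwd(Db, sb$cache, -2 * (1 - sb$s) / n, need_dx = TRUE)$dx
      d_fba <- style_d_bwd(Da, sa$cache, -2 * (1 - sa$s) / n, need_dx = TRUE)$dx
      # cycle paths
      d_reca <- lam * sign(rec_a$y - a) / (numel * n)
      bw_rec_a <- style_t_bwd(Tba, rec_a$cache, d_reca)
      d_fab <- d_fab + bw_rec_a$dx
      d_recb <- lam * sign(rec_b$y - b) / (numel * n)
      bw_rec_b <- style_t_bwd(Tab, rec_b$cache, d_recb)
      d_fba <- d_fba + bw_rec_b$dx
      # identity paths
      bw_id_b <- style_t_bwd(Tab, id_b$cache, lid * sign(id_b$y - b) / (numel * n))
      bw_id_a <- style_t_bwd(Tba, id_a$cache, lid * sign(id_a$y - a) / (numel * n))
      # translator grads: Tab gets fab, rec_b, id_b paths; Tba symmetric
      bw_fab <- style_t_bwd(Tab, fab$cache, d_fab)
      bw_fba <- style_t_bwd(Tba, fba$cache, d_fba)
      gTab <- add_trees(add_trees(bw_fab$grads, bw_rec_b$grads), bw_id_b$grads)
      gTba <- add_trees(add_trees(bw_fba$grads, bw_rec_a$grads), bw_id_a$grads)
      up <- adam_step(Tab, gTab, oTab, cfg$lr); Tab <- up$params; oTab <- up$state
      up <- adam_step(Tba, gTba, oTba, cfg$lr); Tba <- up$params; oTba <- up$state
      # ---- discriminator update ----
      sbf <- style_d_fwd(Db, fab$y); sbr <- style_d_fwd(Db, b)
      saf <- style_d_fwd(Da, fba$y); sar <- style_d_fwd(Da, a)
      ld <- mean(sbf$s^2) + mean((1 - sbr$s)^2) + mean(saf$s^2) + mean((1 - sar$s)^2)
      if (!is.finite(ld)) { diverged <- TRUE; break }
      gDb <- add_trees(style_d_bwd(Db, sbf$cache, 2 * sbf$s / n)$grads,
                       style_d_bwd(Db, sbr$cache, -2 * (1 - sbr$s) / n)$grads)
      gDa <- add_trees(style_d_bwd(Da, saf$cache, 2 * saf$s / n)$grads,
                       style_d_bwd(Da, sar$cache, -2 * (1 - sar$s) / n)$grads)
      up <- adam_step(Db, gDb, oDb, cfg$lr); Db <- up$params; oDb <- up$state
      up <- adam_step(Da, gDa, oDa, cfg$lr); Da <- up$params; oDa <- up$state
      hist <- rbind(hist, data.frame(step = step, adv = adv, cycle = cyc,
                                     identity = idn, d = ld))
    }
    structure(list(forward = Tab, backward = Tba, disc_a = Da, disc_b = Db,
                   history = hist, cfg = cfg, diverged = diverged,
                   source_style = attr(set_a[[1L]], "style") %||% "A",
                   target_style = attr(set_b[[1L]], "style") %||% "B"),
              class = "style_mapper")
  })
}

#' Translate a bright-field image between stain styles
#'
#' Applies the mapper's forward translator (or the backward one with
#' `direction = "backward"`). Geometry and dimensions are preserved exactly;
#' values are clipped to `[0, 1]` and the style tag updated. Inference is
#' deterministic.
#'
#' @param bf H x W x 3 image in `[0, 1]`; if it carries a `style` attribute it
#'   must match the mapper's source (target for backward) style.
#' @param mapper a trained [train_style_mapper()] result.
#' @param direction `"forward"` (source -> target) or `"backward"`.
#' @return restyled `bf_image`.
#' @export
harmonize <- function(bf, mapper, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  check_image(bf, "bf", channels = 3L)
  from <- if (direction == "forward") mapper$source_style else mapper$target_style
  to <- if (direction == "forward") mapper$target_style else mapper$source_style
  tag <- attr(bf, "style")
  if (!is.null(tag) && !identical(tag, "native") && !identical(tag, from))
    stop(sprintf("style tag '%s' does not match mapper source '%s'", tag, from),
         call. = FALSE)
  P <- if (direction == "forward") mapper$forward else mapper$backward
  y <- style_t_fwd(P, as_batch(bf))$y
  out <- clip01(array(y, dim = dim(bf)))
  bf_image(out, stain = attr(bf, "stain") %||% "unknown", style = to)
}

#' @export
print.style_mapper <- function(x, ...) {
  cat(sprintf("<style_mapper> %s -> %s, %d step(s)%s\n", x$source_style,
              x$target_style, nrow(x$history),
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}
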