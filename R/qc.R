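#' Quality-control configuration for training-pair filtering
#'
#' Pairs whose rough virtually stained rendering and histochemical target
#' disagree — peak signal-to-noise ratio below `psnr_threshold` (16 dB) or
#' structural similarity below `ssim_threshold` (0.6), both strict — are
#' excluded from training; these are the operating thresholds that reject
#' tissue tears, folds and defocused regions.
#'
#' @param psnr_threshold exclusion threshold in dB (default 16).
#' @param ssim_threshold exclusion threshold, unitless (default 0.6).
#' @param data_range intensity dynamic range (default 1 for images in
#'   `[0, 1]`).
#' @param ssim_window Gaussian window size in px (default 11).
#' @param ssim_sigma Gaussian window standard deviation (default 1.5).
#' @return a `qc_config` object.
#' @export
qc_config <- function(psnr_threshold = 16, ssim_threshold = 0.6,
                      data_range = 1, ssim_window = 11L, ssim_sigma = 1.5) {
  check_number(psnr_threshold, "psnr_threshold")
  check_number(ssim_threshold, "ssim_threshold")
  check_number(data_range, "data_range")
  if (data_range <= 0) stop_field("data_range", "must be > 0")
  check_number(ssim_window, "ssim_window", min = 3)
  check_number(ssim_sigma, "ssim_sigma")
  structure(list(psnr_threshold = psnr_threshold, ssim_threshold = ssim_threshold,
                 data_range = data_range, ssim_window = as.integer(ssim_window),
                 ssim_sigma = ssim_sigma),
            class = "qc_config")
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`; identical images return `Inf`.
#' @param a,b same-shape numeric images.
#' @param data_range intensity dynamic range.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = 1) {
  check_image(a, "a"); check_image(b, "b"); check_same_shape(a, b)
  check_number(data_range, "data_range")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Separable Gaussian-window local mean with truncated, renormalized kernel
# (symmetric boundary via gaussian kernel on the valid support).
ssim_filter <- function(m, win, sigma) {
  half <- win %/% 2L
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_sym <- function(x) {
    n <- nrow(x)
    rbind(x[half:1, , drop = FALSE], x, x[n:(n - half + 1L), , drop = FALSE])
  }
  conv_rows <- function(x) {
    xp <- pad_sym(x)
    out <- matrix(0, nrow(x), ncol(x))
    for (t in seq_len(win)) out <- out + k[t] * xp[(t - 1L) + seq_len(nrow(x)), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5) and the
#' conventional stabilization constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`
#' with `K1 = 0.01`, `K2 = 0.03` and `L = data_range`. RGB inputs are
#' converted to luminance first. Symmetric in its arguments.
#'
#' @param a,b same-shape images (matrices or RGB arrays).
#' @param cfg a [qc_config()].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, cfg = qc_config()) {
  check_image(a, "a"); check_image(b, "b"); check_same_shape(a, b)
  a <- luminance(a); b <- luminance(b)
  win <- cfg$ssim_window; sg <- cfg$ssim_sigma
  if (nrow(a) < win || ncol(a) < win)
    stop(sprintf("image (%d x %d) smaller than SSIM window (%d)",
                 nrow(a), ncol(a), win), call. = FALSE)
  L <- cfg$data_range
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- ssim_filter(a, win, sg); mu_b <- ssim_filter(b, win, sg)
  s_aa <- ssim_filter(a * a, win, sg) - mu_a^2
  s_bb <- ssim_filter(b * b, win, sg) - mu_b^2
  s_ab <- ssim_filter(a * b, win, sg) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

#' Filter training pairs by rough-stain similarity
#'
#' Applies the exclusion rule: a pair is excluded iff `psnr < psnr_threshold`
#' OR `ssim < ssim_threshold` (strict inequalities), where both metrics
#' compare the pair's rough virtually stained rendering with its
#' histochemical target in the same bright-field domain. The kept/excluded
#' partition is exhaustive and disjoint; pairs lacking a rendering raise an
#' error count but do not silently pass.
#'
#' @param pairs list of `list(rendering =, target =)` (both same-shape
#'   bright-field images in `[0, data_range]`).
#' @param cfg a [qc_config()].
#' @return `list(kept =, excluded =, metrics =)`; `metrics` is a data frame
#'   with one row per pair (`psnr`, `ssim`, `decision`, `reason`).
#' @export
filter_pairs <- function(pairs, cfg = qc_config()) {
  n <- length(pairs)
  met <- data.frame(pair = seq_len(n), psnr = NA_real_, ssim = NA_real_,
                    decision = NA_character_, reason = "")
  kept <- excluded <- integer(0)
  n_missing <- 0L
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    if (is.null(p$rendering) || is.null(p$target)) {
      n_missing <- n_missing + 1L
      met$decision[i] <- "error"; met$reason[i] <- "missing rendering"
      next
    }
    ps <- psnr(p$rendering, p$target, cfg$data_range)
    ss <- ssim(p$rendering, p$target, cfg)
    met$psnr[i] <- ps; met$ssim[i] <- ss
    if (ps < cfg$psnr_threshold || ss < cfg$ssim_threshold) {
      excluded <- c(excluded, i)
      met$decision[i] <- "excluded"
      met$reason[i] <- paste(c(
        if (ps < cfg$psnr_threshold) sprintf("psnr %.2f < %.2f", ps, cfg$psnr_threshold),
        if (ss < cfg$ssim_threshold) sprintf("ssim %.3f < %.3f", ss, cfg$ssim_threshold)),
        collapse = "; ")
    } else {
      kept <- c(kept, i)
      met$decision[i] <- "kept"
    }
  }
  structure(list(kept = pairs[kept], excluded = pairs[excluded], metrics = met,
                 n_missing = n_missing),
            class = "pair_filter_result")
}

#' @export
print.pair_filter_result <- function(x, ...) {
  cat(sprintf("<pair_filter_result> kept %d, excluded %d, missing %d\n",
              length(x$kept), length(x$excluded), x$n_missing))
  invisible(x)
}
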