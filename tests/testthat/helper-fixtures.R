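# Shared fixtures: all test inputs are generated in code at run time.

# Small phantom cached per seed to keep the suite fast.
phantom_cache <- new.env(parent = emptyenv())
get_phantom <- function(seed = 1L, size = 128L, noise_sd = 0.01) {
  key <- paste(seed, size, noise_sd, sep = "_")
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- generate_phantom(
      phantom_spec(width = size, height = size, noise_sd = noise_sd, seed = seed))
  phantom_cache[[key]]
}

# Paired 64 x 64 autofluorescence / bright-field patches cut from phantoms.
make_pairs <- function(seeds, stain = "HE", size = 128L, patch = 64L,
                       noise_sd = 0.01) {
  pairs <- list()
  for (s in seeds) {
    ph <- get_phantom(s, size, noise_sd)
    afp <- extract_patches(unclass(ph$af), patch)
    bfp <- extract_patches(unclass(ph$bf[[stain]]), patch)
    for (k in seq_along(afp))
      pairs[[length(pairs) + 1L]] <- list(af = afp[[k]], bf = bfp[[k]])
  }
  pairs
}

# Crop the most tissue-covered window from a bright-field image, emulating
# the pipeline's selection of tissue-bearing training patches.
dense_tissue_crop <- function(bf, size = 64L) {
  lum <- luminance(bf)
  cov <- gaussian_blur(1 * (lum < 0.85), size / 2)
  half <- size %/% 2L
  interior <- half:(nrow(lum) - half)
  sub <- cov[interior, interior]
  ctr <- which(sub == max(sub), arr.ind = TRUE)[1, ] + half - 1L
  r0 <- min(max(1L, ctr[1L] - half), nrow(lum) - size + 1L)
  c0 <- min(max(1L, ctr[2L] - half), ncol(lum) - size + 1L)
  bf[r0 + 0:(size - 1L), c0 + 0:(size - 1L), , drop = FALSE]
}

# Textured single-channel test image (deterministic).
textured_image <- function(n = 128L, seed = 1L) {
  ph <- get_phantom(seed, max(n, 128L))
  bf_to_proxy(ph$bf$HE)[seq_len(n), seq_len(n)]
}
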