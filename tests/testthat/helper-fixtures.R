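# Shared fixtures, all generated in code under fixed seeds.

# Uniform-color image
solid_image <- function(r, g, b, h = 4L, w = 4L) {
  rgb_image(array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3)))
}

random_image <- function(h, w, seed = 1L) {
  withr::with_seed(seed,
    rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))))
}

random_mask <- function(h, w, p = 0.5, seed = 1L) {
  withr::with_seed(seed,
    binary_mask(matrix(255L * stats::rbinom(h * w, 1, p), h, w)))
}

# Two well-separated color clusters -> linearly separable pixel dataset.
# Foreground around bright green, background around dark brown.
separable_dataset <- function(n_per_class = 300L, seed = 0L,
                              channels = c("rgb.R", "rgb.G")) {
  withr::with_seed(seed, {
    fg <- cbind(stats::runif(n_per_class, 30, 70),
                stats::runif(n_per_class, 170, 230),
                stats::runif(n_per_class, 30, 70))
    bg <- cbind(stats::runif(n_per_class, 90, 130),
                stats::runif(n_per_class, 40, 80),
                stats::runif(n_per_class, 20, 60))
  })
  feats <- pixels_to_features(rbind(fg, bg))[, channels, drop = FALSE]
  pixel_dataset(feats, c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

# The default quiet test configuration for scenes
quiet_cfg <- function(...) scene_config(height = 96L, width = 96L, ...)
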