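#' Canonical channel names of the 24-channel color feature stack
#'
#' Eight color spaces derived from 8-bit sRGB, three channels each, in the
#' fixed order that defines the per-pixel feature-vector layout used
#' throughout the package.
#'
#' @return Character vector of length 24.
#' @export
channel_names <- function() {
  c("rgb.R", "rgb.G", "rgb.B",
    "hsv.H", "hsv.S", "hsv.V",
    "ycbcr.Y", "ycbcr.Cb", "ycbcr.Cr",
    "lab.L", "lab.a", "lab.b",
    "yuv.Y", "yuv.U", "yuv.V",
    "luv.L", "luv.u", "luv.v",
    "hls.h", "hls.l", "hls.s",
    "xyz.X", "xyz.Y", "xyz.Z")
}

#' Construct an 8-bit RGB image
#'
#' @param x Numeric array `h x w x 3` with values in `[0, 255]`.
#' @return An `rgb_image` object (integer-valued array with class attribute).
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("rgb_image requires an h x w x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("rgb_image dimensions must be at least 1 x 1", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("rgb_image channel values must lie in [0, 255]", call. = FALSE)
  x <- round(x)
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, 8-bit>\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

assert_rgb_image <- function(x) {
  if (!is_rgb_image(x)) stop("expected an rgb_image", call. = FALSE)
  invisible(x)
}

# ---- low-level conversion kernels (vectorized over an N x 3 matrix) --------

srgb_to_linear <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

# sRGB D65 matrix; rows X, Y, Z
.xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.white_d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' Per-pixel 24-channel color features from raw RGB triplets
#'
#' The workhorse behind [to_feature_stack()] and dataset assembly: converts a
#' flat matrix of 8-bit RGB triplets into the 24 normalized channels. All
#' channels are rescaled to `[0, 1]`: hue channels map the full circle to
#' `[0, 1]`; Lab and Luv use the D65 white point with `L/100` and fixed affine
#' maps covering the sRGB gamut for `a`, `b`, `u*`, `v*`; YCbCr follows the
#' ITU-R BT.601 full-range convention; XYZ is divided by the D65 white point.
#'
#' @param rgbmat Numeric matrix `N x 3` of values in `[0, 255]`.
#' @return Numeric matrix `N x 24` with `channel_names()` as column names.
#' @export
pixels_to_features <- function(rgbmat) {
  if (!is.matrix(rgbmat) || ncol(rgbmat) != 3L)
    stop("pixels_to_features requires an N x 3 matrix", call. = FALSE)
  r <- rgbmat[, 1] / 255; g <- rgbmat[, 2] / 255; b <- rgbmat[, 3] / 255
  n <- length(r)
  out <- matrix(0, nrow = n, ncol = 24L, dimnames = list(NULL, channel_names()))

  out[, "rgb.R"] <- r; out[, "rgb.G"] <- g; out[, "rgb.B"] <- b

  hsv <- grDevices::rgb2hsv(t(rgbmat), maxColorValue = 255)
  out[, "hsv.H"] <- hsv[1, ]; out[, "hsv.S"] <- hsv[2, ]; out[, "hsv.V"] <- hsv[3, ]

  # YCbCr, BT.601 full range (JPEG convention); exact [0, 1]
  y601 <- 0.299 * r + 0.587 * g + 0.114 * b
  out[, "ycbcr.Y"]  <- y601
  out[, "ycbcr.Cb"] <- 0.5 - 0.168736 * r - 0.331264 * g + 0.5 * b
  out[, "ycbcr.Cr"] <- 0.5 + 0.5 * r - 0.418688 * g - 0.081312 * b

  # CIE Lab / Luv via linear sRGB -> XYZ (D65)
  lin <- cbind(srgb_to_linear(r), srgb_to_linear(g), srgb_to_linear(b))
  xyz <- lin %*% t(.xyz_mat)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  fx <- lab_f(X / .white_d65["X"]); fy <- lab_f(Y / .white_d65["Y"]); fz <- lab_f(Z / .white_d65["Z"])
  L <- 116 * fy - 16
  out[, "lab.L"] <- clip01(L / 100)
  out[, "lab.a"] <- clip01((500 * (fx - fy) + 128) / 255)
  out[, "lab.b"] <- clip01((200 * (fy - fz) + 128) / 255)

  # YUV, BT.601 analog; U in [-0.436, 0.436], V in [-0.615, 0.615]
  out[, "yuv.Y"] <- y601
  out[, "yuv.U"] <- clip01(0.492 * (b - y601) / 0.872 + 0.5)
  out[, "yuv.V"] <- clip01(0.877 * (r - y601) / 1.230 + 0.5)

  # CIE Luv (D65); affine maps cover the sRGB gamut (u* in [-84, 176], v* in [-135, 108])
  denom <- X + 15 * Y + 3 * Z
  up <- ifelse(denom > 0, 4 * X / denom, 4 * .white_d65["X"] / sum(.white_d65 * c(1, 15, 3)))
  vp <- ifelse(denom > 0, 9 * Y / denom, 9 * .white_d65["Y"] / sum(.white_d65 * c(1, 15, 3)))
  un <- 4 * .white_d65["X"] / sum(.white_d65 * c(1, 15, 3))
  vn <- 9 * .white_d65["Y"] / sum(.white_d65 * c(1, 15, 3))
  u_star <- 13 * L * (up - un)
  v_star <- 13 * L * (vp - vn)
  out[, "luv.L"] <- clip01(L / 100)
  out[, "luv.u"] <- clip01((u_star + 84) / 260)
  out[, "luv.v"] <- clip01((v_star + 135) / 243)

  # HLS (hue as in HSV; lightness / saturation per the standard bicone)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  s_hls <- ifelse(mx == mn, 0,
                  ifelse(l <= 0.5, (mx - mn) / (mx + mn), (mx - mn) / (2 - mx - mn)))
  out[, "hls.h"] <- hsv[1, ]
  out[, "hls.l"] <- l
  out[, "hls.s"] <- clip01(s_hls)

  out[, "xyz.X"] <- clip01(X / .white_d65["X"])
  out[, "xyz.Y"] <- clip01(Y)
  out[, "xyz.Z"] <- clip01(Z / .white_d65["Z"])

  out
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Build the 24-channel per-pixel feature stack of an image
#'
#' @param image An [rgb_image()].
#' @return A `feature_stack`: list with `values` (array `h x w x 24`),
#'   `channel_names`, `height`, `width`. All values lie in `[0, 1]`.
#' @export
to_feature_stack <- function(image) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgbmat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                  as.vector(image[, , 3]))
  feats <- pixels_to_features(rgbmat)
  vals <- array(feats, dim = c(h, w, 24L),
                dimnames = list(NULL, NULL, channel_names()))
  structure(list(values = vals, channel_names = channel_names(),
                 height = h, width = w),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack %d x %d, %d channels>\n",
              x$height, x$width, length(x$channel_names)))
  invisible(x)
}

#' Flatten a feature stack to a pixel matrix
#'
#' @param stack A `feature_stack`.
#' @return Numeric matrix `(h*w) x C`, column-major pixel order.
#' @export
stack_to_matrix <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  m <- matrix(stack$values, nrow = stack$height * stack$width,
              ncol = length(stack$channel_names))
  colnames(m) <- stack$channel_names
  m
}

# ---- color-checker reference ----------------------------------------------

#' Color-checker reference card
#'
#' A 24-patch reference: nominal sRGB values per patch, the indices of the
#' neutral (gray) patches used for white balance, and named hue groups
#' (green / yellow / brown) with target hue angles used for hue calibration.
#'
#' @param patch_rgbs Numeric matrix `24 x 3` of reference RGB values.
#' @param gray_indices Integer indices of the neutral patches.
#' @param hue_groups Named numeric vector of target hue angles in degrees,
#'   e.g. `c(green = 120, yellow = 55, brown = 25)`.
#' @param hue_halfwidth Angular half-width in degrees of the band around each
#'   group's target hue within which pixels are corrected (default 30).
#' @return A `color_checker` object.
#' @export
color_checker_reference <- function(patch_rgbs, gray_indices, hue_groups,
                                    hue_halfwidth = 30) {
  patch_rgbs <- as.matrix(patch_rgbs)
  if (nrow(patch_rgbs) != 24L || ncol(patch_rgbs) != 3L)
    stop("a color checker has exactly 24 RGB patches", call. = FALSE)
  if (length(gray_indices) < 1L)
    stop("gray_indices must be nonempty", call. = FALSE)
  if (any(hue_groups < 0 | hue_groups >= 360))
    stop("target hues must lie in [0, 360)", call. = FALSE)
  structure(list(patch_rgbs = patch_rgbs,
                 gray_indices = as.integer(gray_indices),
                 hue_groups = hue_groups,
                 hue_halfwidth = hue_halfwidth),
            class = "color_checker")
}

#' Read a color-checker reference from CSV
#'
#' Expects columns `index, R, G, B, group`; rows with group `gray` become the
#' neutral patches, and groups `green`, `yellow`, `brown` define hue-target
#' groups (target hue = hue angle of the group's mean reference color).
#'
#' @param path CSV file path. Defaults to the synthetic reference card shipped
#'   with the package.
#' @inheritParams color_checker_reference
#' @return A `color_checker` object.
#' @export
read_color_checker <- function(path = system.file("extdata",
                                                  "colorchecker_srgb_synthetic.csv",
                                                  package = "canopyseg"),
                               hue_halfwidth = 30) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- df[order(df$index), ]
  rgbs <- as.matrix(df[, c("R", "G", "B")])
  grays <- which(df$group == "gray")
  groups <- setdiff(unique(df$group), c("gray", "other"))
  hue_groups <- vapply(groups, function(gp) {
    mean_rgb <- colMeans(rgbs[df$group == gp, , drop = FALSE])
    hsv <- grDevices::rgb2hsv(mean_rgb[1], mean_rgb[2], mean_rgb[3],
                              maxColorValue = 255)
    hsv[1, 1] * 360
  }, numeric(1))
  color_checker_reference(rgbs, grays, hue_groups, hue_halfwidth)
}

#' White-balance an image against gray reference patches
#'
#' Per-channel linear gains map the mean observed gray onto the mean reference
#' gray; the corrected image is clipped to `[0, 255]`.
#'
#' @param image An [rgb_image()].
#' @param observed_grays Numeric matrix `k x 3` (or length-3 vector) of the
#'   gray patches as observed in the scene.
#' @param reference A `color_checker` object.
#' @return A white-balanced [rgb_image()].
#' @export
white_balance <- function(image, observed_grays, reference) {
  assert_rgb_image(image)
  stopifnot(inherits(reference, "color_checker"))
  obs <- matrix(as.numeric(observed_grays), ncol = 3L)
  if (nrow(obs) < 1L) stop("at least one observed gray is required", call. = FALSE)
  obs_mean <- colMeans(obs)
  if (any(obs_mean == 0))
    stop("degenerate gain: an observed gray channel mean is zero", call. = FALSE)
  ref_mean <- colMeans(reference$patch_rgbs[reference$gray_indices, , drop = FALSE])
  gains <- ref_mean / obs_mean
  out <- array(0, dim = dim(image))
  for (ch in 1:3) out[, , ch] <- pmin(255, pmax(0, image[, , ch] * gains[ch]))
  rgb_image(out)
}

#' Correct per-group hue shifts against the color checker
#'
#' For each hue group (green / yellow / brown), the angular offset between the
#' group's target hue and the hue observed on the checker is added to every
#' chromatic pixel whose hue lies within the group's band. Saturation and
#' value are untouched; achromatic pixels (S = 0) are left unchanged.
#'
#' @param image An [rgb_image()].
#' @param observed_hues Named numeric vector of observed hue angles in degrees,
#'   one per group present in `reference$hue_groups`.
#' @param reference A `color_checker` object.
#' @return A hue-corrected [rgb_image()].
#' @export
hue_correct <- function(image, observed_hues, reference) {
  assert_rgb_image(image)
  stopifnot(inherits(reference, "color_checker"))
  if (any(observed_hues < 0 | observed_hues >= 360))
    stop("observed hues must lie in [0, 360)", call. = FALSE)
  groups <- names(reference$hue_groups)
  if (!all(groups %in% names(observed_hues)))
    stop("observed_hues must cover the reference hue groups", call. = FALSE)

  h <- dim(image)[1]; w <- dim(image)[2]
  rgbmat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                  as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(t(rgbmat), maxColorValue = 255)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]

  ang_diff <- function(a, b) {
    d <- (a - b) %% 360
    ifelse(d > 180, d - 360, d)
  }
  for (gp in groups) {
    target <- reference$hue_groups[[gp]]
    offset <- ang_diff(target, observed_hues[[gp]])
    in_band <- sat > 0 & abs(ang_diff(hue, target)) <= reference$hue_halfwidth
    hue[in_band] <- (hue[in_band] + offset) %% 360
  }
  rgb01 <- hsv_to_rgb01(hue / 360, sat, val)
  out <- array(round(rgb01 * 255), dim = c(h, w, 3))
  rgb_image(out)
}

# HSV -> RGB in [0, 1], vectorized (h in [0, 1))
hsv_to_rgb01 <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r, g, b)
}
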