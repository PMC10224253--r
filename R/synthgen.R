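#' Synthetic scene configuration
#'
#' Describes the rendered study conditions: plant rosettes of overlapping
#' elliptical leaf lobes over a plain compost background (glasshouse) or a
#' cluttered soil background with straw and stone ellipses (field). Leaf hue
#' tracks nutrient status: healthy canopies sit in the green band
#' (100-140 deg), deficient ones drift through yellow toward brown
#' (30-60 deg). SPAD values are linked linearly to canopy greenness (mean
#' excess-green of the true foreground, rescaled to [0, 1]).
#'
#' @param height,width Canvas size in pixels.
#' @param scene_type `"glasshouse"` or `"field"`.
#' @param n_plants Number of plants.
#' @param leaves_per_plant Leaf lobes per plant.
#' @param leaf_axis_range Semi-major axis range of leaf ellipses, pixels.
#' @param foreground_hue_mean,foreground_hue_sd Leaf hue distribution in
#'   degrees (draws are truncated at three standard deviations).
#' @param nutrient_hue_range Hue angles (degrees) at fully deficient and
#'   fully healthy nutrient status, used by [generate_spad_cohort()].
#' @param clutter_density Field clutter ellipses per 1000 pixels.
#' @param illumination_gradient_amplitude Fractional amplitude of the linear
#'   illumination gradient.
#' @param pixel_noise_sd Additive Gaussian pixel noise, 8-bit units.
#' @param spad_link Numeric `c(a, b, sigma)`: `SPAD = a + b * greenness +
#'   N(0, sigma^2)`.
#' @return A `scene_config` object.
#' @export
scene_config <- function(height = 128L, width = 128L,
                         scene_type = c("glasshouse", "field"),
                         n_plants = NULL, leaves_per_plant = 10L,
                         leaf_axis_range = c(10, 24),
                         foreground_hue_mean = 120,
                         foreground_hue_sd = 8,
                         nutrient_hue_range = c(45, 125),
                         clutter_density = 6,
                         illumination_gradient_amplitude = 0.15,
                         pixel_noise_sd = 8,
                         spad_link = c(a = -110, b = 250, sigma = 2)) {
  scene_type <- match.arg(scene_type)
  n_plants <- n_plants %||% if (scene_type == "glasshouse") 3L else 6L
  if (foreground_hue_mean < 0 || foreground_hue_mean >= 360)
    stop("hue mean must lie in [0, 360)", call. = FALSE)
  if (pixel_noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (spad_link[3] < 0) stop("spad noise sigma must be >= 0", call. = FALSE)
  if (min(leaf_axis_range) < 2) stop("leaf axes must be >= 2 px", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 scene_type = scene_type, n_plants = as.integer(n_plants),
                 leaves_per_plant = as.integer(leaves_per_plant),
                 leaf_axis_range = leaf_axis_range,
                 foreground_hue_mean = foreground_hue_mean,
                 foreground_hue_sd = foreground_hue_sd,
                 nutrient_hue_range = nutrient_hue_range,
                 clutter_density = clutter_density,
                 illumination_gradient_amplitude =
                   illumination_gradient_amplitude,
                 pixel_noise_sd = pixel_noise_sd,
                 spad_link = spad_link),
            class = "scene_config")
}

# paint an ellipse onto matrices held in env `e` (fields R, G, B in [0,1]
# scale 0..255, optional truth); returns the painted logical within bbox
paint_ellipse <- function(e, cx, cy, a, b, theta, rgb255, v_jitter_sd = 0,
                          truth = FALSE) {
  h <- nrow(e$R); w <- ncol(e$R)
  rad <- max(a, b)
  rows <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
  cols <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
  if (length(rows) == 0L || length(cols) == 0L) return(invisible(NULL))
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(invisible(NULL))
  n_in <- sum(inside)
  jit <- if (v_jitter_sd > 0) stats::rnorm(n_in, 0, v_jitter_sd) else 0
  fac <- pmax(0.6, pmin(1.4, 1 + jit))
  sub <- function(M) M[rows, cols]
  for (ch in c("R", "G", "B")) {
    M <- sub(e[[ch]])
    M[inside] <- pmin(255, pmax(0, rgb255[[ch]] * fac))
    e[[ch]][rows, cols] <- M
  }
  if (truth) {
    Tm <- sub(e$truth)
    Tm[inside] <- TRUE
    e$truth[rows, cols] <- Tm
  }
  invisible(NULL)
}

hue_rgb255 <- function(hue_deg, s, v) {
  rgb01 <- hsv_to_rgb01(hue_deg / 360, s, v)
  list(R = rgb01[1] * 255, G = rgb01[2] * 255, B = rgb01[3] * 255)
}

#' Render a synthetic plant scene with ground truth
#'
#' Renders the background (textured compost browns, plus straw/stone clutter
#' for field scenes), then the plants as overlapping rotated leaf ellipses
#' with hues drawn from the configured distribution, applies a smooth linear
#' illumination gradient and additive Gaussian pixel noise. The truth mask
#' records exactly the rendered leaf pixels (before noise). Identical
#' config + seed always reproduces the identical scene.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return A `synthetic_scene`: list with `image` ([rgb_image()]), `truth`
#'   ([binary_mask()]), `nutrient_level`, `spad_true` (noise-free SPAD from
#'   the configured link; `NA` when there is no foreground), `greenness`,
#'   `seed`.
#' @export
generate_scene <- function(config, seed = 0L) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width
  margin <- max(config$leaf_axis_range) + 2
  if (config$n_plants > 0 && (2 * margin >= h || 2 * margin >= w))
    stop("layout error: plants cannot fit the canvas at this leaf size",
         call. = FALSE)

  e <- new.env()
  withr::with_seed(seed, {
    # -- background
    if (config$scene_type == "glasshouse") {
      base_h <- stats::runif(1, 20, 31); base_s <- stats::runif(1, 0.42, 0.55)
      base_v <- stats::runif(1, 0.2, 0.3)
    } else {
      base_h <- stats::runif(1, 24, 34); base_s <- stats::runif(1, 0.45, 0.6)
      base_v <- stats::runif(1, 0.3, 0.4)
    }
    vmat <- matrix(pmin(1, pmax(0.02, base_v + stats::rnorm(h * w, 0, 0.035))),
                   h, w)
    # compost texture blobs perturb local brightness
    n_blob <- max(1L, round(h * w / 800))
    for (i in seq_len(n_blob)) {
      bx <- stats::runif(1, 1, w); by <- stats::runif(1, 1, h)
      ba <- stats::runif(1, 3, 10); bb <- ba * stats::runif(1, 0.5, 1)
      bth <- stats::runif(1, 0, pi)
      rows <- max(1L, floor(by - ba)):min(h, ceiling(by + ba))
      cols <- max(1L, floor(bx - ba)):min(w, ceiling(bx + ba))
      dy <- matrix(rows - by, length(rows), length(cols))
      dx <- matrix(cols - bx, length(rows), length(cols), byrow = TRUE)
      u <- dx * cos(bth) + dy * sin(bth); v <- -dx * sin(bth) + dy * cos(bth)
      inside <- (u / ba)^2 + (v / bb)^2 <= 1
      dv <- stats::runif(1, -0.06, 0.06)
      sub <- vmat[rows, cols]
      sub[inside] <- pmin(1, pmax(0.02, sub[inside] + dv))
      vmat[rows, cols] <- sub
    }
    rgb01 <- hsv_to_rgb01(rep(base_h / 360, h * w), rep(base_s, h * w),
                          as.vector(vmat))
    e$R <- matrix(rgb01[, 1] * 255, h, w)
    e$G <- matrix(rgb01[, 2] * 255, h, w)
    e$B <- matrix(rgb01[, 3] * 255, h, w)
    e$truth <- matrix(FALSE, h, w)

    # -- field clutter: straw (elongated, yellow) and stones (gray)
    if (config$scene_type == "field") {
      n_clutter <- round(config$clutter_density * h * w / 1000)
      for (i in seq_len(n_clutter)) {
        cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
        if (stats::runif(1) < 0.6) {
          col <- hue_rgb255(stats::runif(1, 42, 52), stats::runif(1, 0.45, 0.6),
                            stats::runif(1, 0.65, 0.85))
          paint_ellipse(e, cx, cy, stats::runif(1, 8, 22),
                        stats::runif(1, 1.2, 2.8), stats::runif(1, 0, pi),
                        col, v_jitter_sd = 0.05)
        } else {
          col <- hue_rgb255(stats::runif(1, 0, 360), stats::runif(1, 0.02, 0.08),
                            stats::runif(1, 0.45, 0.7))
          paint_ellipse(e, cx, cy, stats::runif(1, 3, 8),
                        stats::runif(1, 2, 6), stats::runif(1, 0, pi),
                        col, v_jitter_sd = 0.05)
        }
      }
    }

    # -- plants: overlapping leaf ellipses around each center
    aspect <- if (config$scene_type == "glasshouse") c(0.35, 0.55) else c(0.2, 0.4)
    for (p in seq_len(config$n_plants)) {
      cx <- stats::runif(1, margin + 1, w - margin)
      cy <- stats::runif(1, margin + 1, h - margin)
      for (l in seq_len(config$leaves_per_plant)) {
        phi <- stats::runif(1, 0, 2 * pi)
        a <- stats::runif(1, config$leaf_axis_range[1], config$leaf_axis_range[2])
        b <- a * stats::runif(1, aspect[1], aspect[2])
        d <- stats::runif(1, 0.15, 0.55) * a
        hue <- config$foreground_hue_mean + config$foreground_hue_sd *
          pmax(-3, pmin(3, stats::rnorm(1)))
        hue <- hue %% 360
        s <- pmin(0.9, pmax(0.35, stats::rnorm(1, 0.62, 0.07)))
        v <- pmin(0.8, pmax(0.3, stats::rnorm(1, 0.55, 0.07)))
        paint_ellipse(e, cx + d * cos(phi), cy + d * sin(phi), a, b,
                      phi + stats::rnorm(1, 0, 0.2), hue_rgb255(hue, s, v),
                      v_jitter_sd = 0.04, truth = TRUE)
      }
    }

    # -- illumination gradient (hue-preserving multiplicative plane)
    amp <- config$illumination_gradient_amplitude
    if (amp > 0) {
      psi <- stats::runif(1, 0, 2 * pi)
      xs <- matrix(seq_len(w) / w - 0.5, h, w, byrow = TRUE)
      ys <- matrix(seq_len(h) / h - 0.5, h, w)
      proj <- cos(psi) * xs + sin(psi) * ys
      tt <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-12)
      fac <- 1 - amp + 2 * amp * tt
      e$R <- pmin(e$R * fac, 255); e$G <- pmin(e$G * fac, 255)
      e$B <- pmin(e$B * fac, 255)
    }

    # -- sensor noise
    if (config$pixel_noise_sd > 0) {
      for (ch in c("R", "G", "B")) {
        e[[ch]] <- pmin(pmax(e[[ch]] +
                               stats::rnorm(h * w, 0, config$pixel_noise_sd),
                             0), 255)
      }
    }
  })

  img <- rgb_image(array(c(round(e$R), round(e$G), round(e$B)),
                         dim = c(h, w, 3)))
  truth <- binary_mask(matrix(ifelse(e$truth, 255L, 0L), h, w))
  g <- scene_greenness(img, truth)
  spad_true <- if (is.na(g)) NA_real_ else
    config$spad_link[1] + config$spad_link[2] * g
  hue <- config$foreground_hue_mean
  level <- if (hue >= 95) "healthy" else if (hue >= 65) "intermediate" else
    "deficient"
  structure(list(image = img, truth = truth, nutrient_level = level,
                 spad_true = unname(spad_true), greenness = g,
                 seed = as.integer(seed), config = config),
            class = "synthetic_scene")
}

#' Mean rescaled excess-green of the true foreground
#'
#' Canopy "greenness": the mean per-pixel `ExG = 2G - R - B` over the truth
#' foreground, rescaled from `[-510, 510]` to `[0, 1]`. `NA` when the mask is
#' empty.
#'
#' @param image An [rgb_image()].
#' @param truth A [binary_mask()].
#' @return Scalar in `[0, 1]`, or `NA`.
#' @export
scene_greenness <- function(image, truth) {
  fg <- truth == 255L
  if (!any(fg)) return(NA_real_)
  exg <- 2 * image[, , 2][fg] - image[, , 1][fg] - image[, , 3][fg]
  (mean(exg) + 510) / 1020
}

integral_image <- function(m) {
  ii <- apply(m, 2, cumsum)
  ii <- t(apply(ii, 1, cumsum))
  rbind(0, cbind(0, ii))
}

#' Sample pure labeled patches from fresh synthetic scenes
#'
#' Generates scenes under `config` and crops `size x size` windows lying
#' entirely inside the truth foreground (label `"foreground"`) or entirely in
#' the background (label `"background"`), so patch labels are guaranteed
#' pure. Scenes are generated until the requested counts are met, up to a
#' bounded scene budget.
#'
#' @param config A [scene_config()].
#' @param n_fg,n_bg Requested patch counts.
#' @param seed Integer seed.
#' @param size Patch side length (default 20).
#' @param per_scene Cap of patches sampled per scene and label (default 25).
#' @return List of [patch()] objects (`n_fg + n_bg` of them).
#' @export
generate_patchset <- function(config, n_fg, n_bg, seed = 0L, size = 20L,
                              per_scene = 25L) {
  stopifnot(inherits(config, "scene_config"))
  max_scenes <- max(40L, ceiling((n_fg + n_bg) / 4))
  source <- config$scene_type
  patches <- list()
  got_fg <- 0L; got_bg <- 0L
  withr::with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, max_scenes)
    for (sc in seq_len(max_scenes)) {
      if (got_fg >= n_fg && got_bg >= n_bg) break
      scene <- generate_scene(config, scene_seeds[sc])
      fg01 <- matrix(as.integer(scene$truth == 255L), nrow(scene$truth))
      ii <- integral_image(fg01)
      h <- nrow(fg01); w <- ncol(fg01)
      if (h < size || w < size) stop("canvas smaller than patch", call. = FALSE)
      tops <- seq_len(h - size + 1L); lefts <- seq_len(w - size + 1L)
      wsum <- ii[tops + size, lefts + size, drop = FALSE] -
        ii[tops + size, lefts, drop = FALSE] -
        ii[tops, lefts + size, drop = FALSE] + ii[tops, lefts, drop = FALSE]
      take <- function(valid_idx, want, label) {
        if (want <= 0L || length(valid_idx) == 0L) return(0L)
        pick <- valid_idx[sample.int(length(valid_idx),
                                     min(want, per_scene, length(valid_idx)))]
        for (k in pick) {
          i <- ((k - 1L) %% length(tops)) + 1L
          j <- ((k - 1L) %/% length(tops)) + 1L
          crop <- rgb_image(unclass(scene$image)[i:(i + size - 1L),
                                                 j:(j + size - 1L), ,
                                                 drop = FALSE])
          patches[[length(patches) + 1L]] <<-
            patch(crop, label = label, source = source,
                  patch_id = sprintf("scene%03d-%s-%d", sc, label, k))
        }
        length(pick)
      }
      got_fg <- got_fg + take(which(wsum == size * size), n_fg - got_fg,
                              "foreground")
      got_bg <- got_bg + take(which(wsum == 0L), n_bg - got_bg, "background")
    }
  })
  if (got_fg < n_fg || got_bg < n_bg)
    stop(sprintf(
      "sampling error: only %d/%d foreground and %d/%d background pure patches found within the scene budget",
      got_fg, n_fg, got_bg, n_bg), call. = FALSE)
  patches
}

#' Generate a SPAD-linked cohort of scenes
#'
#' Renders `n` scenes whose nutrient status spans the configured hue range
#' (evenly spaced levels in shuffled order) and assigns each a measured SPAD
#' value `a + b * greenness + N(0, sigma^2)` per the config's `spad_link`.
#'
#' @param config A [scene_config()].
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return List with `scenes` (list of `synthetic_scene`) and `table`
#'   (data frame: `image_id`, `nutrient` in `[0, 1]`, `greenness`, `spad`).
#' @export
generate_spad_cohort <- function(config, n, seed = 0L) {
  stopifnot(inherits(config, "scene_config"), n >= 1)
  a <- config$spad_link[1]; b <- config$spad_link[2]
  sigma <- config$spad_link[3]
  hue_lo <- config$nutrient_hue_range[1]
  hue_hi <- config$nutrient_hue_range[2]
  withr::with_seed(seed, {
    u <- if (n == 1L) 0.5 else sample(seq(0, 1, length.out = n))
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
    spad_noise <- stats::rnorm(n, 0, sigma)
    scenes <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cfg <- config
      cfg$foreground_hue_mean <- hue_lo + u[i] * (hue_hi - hue_lo)
      scenes[[i]] <- generate_scene(cfg, scene_seeds[i])
      g <- scenes[[i]]$greenness
      rows[[i]] <- data.frame(image_id = sprintf("scene%04d", i),
                              nutrient = u[i], greenness = g,
                              spad = a + b * g + spad_noise[i])
    }
  })
  list(scenes = scenes, table = do.call(rbind, rows))
}

#' Extract CVI feature rows for a SPAD cohort
#'
#' Computes the eleven region CVIs for every scene over a segmentation mask
#' (the ground-truth mask by default) and binds them to the cohort table.
#' Scenes whose mask has no foreground are excluded with a warning.
#'
#' @param cohort Result of [generate_spad_cohort()].
#' @param masks Optional list of [binary_mask()] (one per scene); defaults to
#'   each scene's truth mask.
#' @param ... Passed to [cvi_from_region()].
#' @return Data frame: cohort columns plus one column per registry CVI.
#' @export
build_spad_samples <- function(cohort, masks = NULL, ...) {
  scenes <- cohort$scenes
  keep <- logical(length(scenes))
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    mask <- if (is.null(masks)) scenes[[i]]$truth else masks[[i]]
    if (!any(mask == 255L)) next
    rec <- cvi_from_region(scenes[[i]]$image, mask, ...)
    rows[[i]] <- as.data.frame(as.list(rec$values))
    keep[i] <- TRUE
  }
  if (!all(keep))
    warning(sprintf("%d scene(s) excluded: empty segmentation mask",
                    sum(!keep)), call. = FALSE)
  cbind(cohort$table[keep, , drop = FALSE], do.call(rbind, rows[keep]))
}
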