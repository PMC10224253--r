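test_that("scene rendering is seeded, bounded and mask-consistent", {
  cfg <- quiet_cfg()
  s1 <- generate_scene(cfg, seed = 1)
  expect_equal(dim(s1$image), c(96L, 96L, 3L))
  expect_equal(dim(s1$truth), c(96L, 96L))
  expect_true(all(s1$truth %in% c(0L, 255L)))
  expect_gt(sum(s1$truth == 255L), 0)

  # byte-identical reproduction under the same seed
  s2 <- generate_scene(cfg, seed = 1)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(unclass(s1$truth), unclass(s2$truth))

  # different seeds differ
  s3 <- generate_scene(cfg, seed = 2)
  expect_false(identical(unclass(s1$image), unclass(s3$image)))

  # no plants -> empty truth, undefined SPAD
  empty <- generate_scene(quiet_cfg(n_plants = 0L), seed = 1)
  expect_equal(sum(empty$truth == 255L), 0L)
  expect_true(is.na(empty$spad_true))

  # oversized leaves cannot fit
  expect_error(generate_scene(scene_config(height = 40L, width = 40L,
                                           leaf_axis_range = c(30, 40)),
                              seed = 1),
               "layout error")
})

test_that("noise-free healthy scenes keep every foreground hue in the green band", {
  cfg <- quiet_cfg(pixel_noise_sd = 0, illumination_gradient_amplitude = 0,
                   foreground_hue_mean = 120, foreground_hue_sd = 8)
  s <- generate_scene(cfg, seed = 3)
  fg <- s$truth == 255L
  rgbmat <- cbind(unclass(s$image)[, , 1][fg], unclass(s$image)[, , 2][fg],
                  unclass(s$image)[, , 3][fg])
  hue <- grDevices::rgb2hsv(t(rgbmat), maxColorValue = 255)[1, ] * 360
  band <- 120 + c(-3, 3) * 8
  # 8-bit rounding wobbles the hue slightly at low saturation; allow 3 degrees
  expect_true(all(hue >= band[1] - 3 & hue <= band[2] + 3))
})

test_that("patch sets are pure, sized and seed-sensitive", {
  cfg <- quiet_cfg()
  ps <- generate_patchset(cfg, n_fg = 12L, n_bg = 9L, seed = 5)
  expect_length(ps, 21L)
  labs <- vapply(ps, `[[`, "", "label")
  expect_equal(sum(labs == "foreground"), 12L)
  expect_equal(sum(labs == "background"), 9L)
  expect_true(all(vapply(ps, function(p) all(dim(p$crop) == c(20, 20, 3)),
                         logical(1))))

  ps2 <- generate_patchset(cfg, n_fg = 12L, n_bg = 9L, seed = 5)
  expect_identical(lapply(ps, `[[`, "crop"), lapply(ps2, `[[`, "crop"))
  ps3 <- generate_patchset(cfg, n_fg = 12L, n_bg = 9L, seed = 6)
  expect_false(identical(lapply(ps, `[[`, "crop"), lapply(ps3, `[[`, "crop")))

  # a single foreground patch taken with zero noise is wholly leaf-colored:
  # every pixel of a noise-free fg patch is chromatic green, far from compost
  clean <- quiet_cfg(pixel_noise_sd = 0, illumination_gradient_amplitude = 0)
  one <- generate_patchset(clean, n_fg = 1L, n_bg = 0L, seed = 7)
  hue <- grDevices::rgb2hsv(t(matrix(as.numeric(one[[1]]$crop), ncol = 3)),
                            maxColorValue = 255)[1, ] * 360
  expect_true(all(hue > 80 & hue < 160))
})

test_that("foreground and background colors are separable by a shallow tree", {
  cfg <- quiet_cfg()
  ps <- generate_patchset(cfg, n_fg = 40L, n_bg = 40L, seed = 8)
  ds <- assemble_patches(ps, verbose = FALSE)
  df <- data.frame(G = ds$features[, "rgb.G"], H = ds$features[, "hsv.H"],
                   y = factor(ds$labels))
  fit <- rpart::rpart(y ~ G + H, data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = 2, cp = 0,
                                                     xval = 0))
  acc <- mean(predict(fit, type = "class") == df$y)
  expect_gte(acc, 0.99)
})

test_that("SPAD cohorts span nutrient levels with a linear greenness link", {
  cfg <- quiet_cfg()
  co <- generate_spad_cohort(cfg, n = 80, seed = 0)
  expect_equal(nrow(co$table), 80L)
  expect_length(co$scenes, 80L)
  # nutrient levels span [0, 1]
  expect_equal(range(co$table$nutrient), c(0, 1))
  # positive link: greenness correlates positively with measured SPAD
  expect_gt(pearson_cor(co$table$greenness, co$table$spad), 0.9)

  # noiseless link is exactly recomputable from the stored greenness
  cfg0 <- quiet_cfg(spad_link = c(-110, 250, 0))
  co0 <- generate_spad_cohort(cfg0, n = 5, seed = 1)
  expect_equal(co0$table$spad, -110 + 250 * co0$table$greenness)

  one <- generate_spad_cohort(cfg, n = 1, seed = 2)
  expect_equal(nrow(one$table), 1L)

  expect_error(scene_config(spad_link = c(0, 1, -1)), "sigma")
})

test_that("cohort CVI tables carry one column per registry index", {
  cfg <- quiet_cfg()
  co <- generate_spad_cohort(cfg, n = 12, seed = 3)
  s <- suppressWarnings(build_spad_samples(co))
  expect_true(all(cvi_registry() %in% names(s)))
  expect_equal(nrow(s), 12L)
  # region CVIs recompute from the scene itself
  rec <- cvi_from_region(co$scenes[[1]]$image, co$scenes[[1]]$truth)
  expect_equal(s$ExG[s$image_id == "scene0001"], unname(rec$values["ExG"]))
})
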