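# Synthetic scene generator: determinism, ground-truth consistency,
# dataset helpers.

test_that("identity pose renders the leaf at the expected pixel extent", {
  # 0.05 cm/px; 7.0 cm major axis -> 140 px extent of the ground-truth mask
  sc <- render_scene(trait_scene("leaf", px_per_cm = 20))
  leaf <- sc$gt$parts[[1]]
  expect_equal(ncol(leaf$mask$bitmap), 140, tolerance = 1)
  expect_equal(nrow(leaf$mask$bitmap), 110, tolerance = 1)
  expect_equal(sc$gt$truth$LA_cm2, pi * 3.5 * 2.75, tolerance = 1e-12)
})

test_that("renders are bit-identical for the same spec and seed", {
  sp <- trait_scene("flower", pose = random_pose(61), seed = 61)
  s1 <- render_scene(sp); s2 <- render_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$gt$marker_corners, s2$gt$marker_corners)
})

test_that("ground-truth masks and boxes are mutually consistent", {
  for (tr in c("CD", "leaf", "fruit")) {
    sc <- render_scene(trait_scene(tr, pose = random_pose(70 + nchar(tr))))
    for (p in sc$gt$parts) {
      # the exact geometric box and the rasterised tight box agree within 1 px
      expect_lt(max(abs(p$mask$box - p$box)), 1)
      # and the stored bitmap is tight: first/last rows and columns non-empty
      expect_true(any(p$mask$bitmap[1, ])); expect_true(any(p$mask$bitmap[nrow(p$mask$bitmap), ]))
      expect_true(any(p$mask$bitmap[, 1])); expect_true(any(p$mask$bitmap[, ncol(p$mask$bitmap)]))
    }
  }
})

test_that("content that cannot fit a fixed frame raises spt_part_out_of_frame", {
  sp <- trait_scene("PH")
  sp$image_size <- c(80, 60)
  expect_error(render_scene(sp), class = "spt_part_out_of_frame")
})

test_that("weight dataset: zero noise lies exactly on the line with R^2 = 1", {
  d <- generate_weight_dataset(50, slope = 3, intercept = -1, noise_sd = 0, seed = 2)
  expect_equal(d$weight_g, 3 * d$area_cm2 - 1, tolerance = 1e-12)
  expect_equal(fit_weight_model(d$area_cm2, d$weight_g)$r_squared, 1, tolerance = 1e-12)
})

test_that("weight dataset is seed-deterministic and n = 2 fails downstream", {
  d1 <- generate_weight_dataset(20, seed = 4); d2 <- generate_weight_dataset(20, seed = 4)
  expect_identical(d1, d2)
  d3 <- generate_weight_dataset(2, seed = 4)
  expect_error(fit_weight_model(d3$area_cm2, d3$weight_g))
})

test_that("validation pairs: clean generation gives r = 1 and 100% frequency", {
  p <- generate_validation_pairs(40, error_sd = 0, dropout_rate = 0, seed = 6)
  rep <- validate_trait(p$measured, p$predicted, p$attempts)
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$detection_frequency_pct, 100)
})

test_that("dropout thins pairs binomially at 70 attempts", {
  n_ok <- sapply(1:60, function(s)
    length(generate_validation_pairs(70, dropout_rate = 0.1, seed = s)$measured))
  expect_true(all(n_ok <= 70))
  # mean success rate within 4 sigma of 0.9
  se <- sqrt(0.1 * 0.9 / (70 * 60))
  expect_lt(abs(mean(n_ok) / 70 - 0.9), 4 * se)
})

test_that("error SD chosen by the attenuation formula hits a target r of 0.9", {
  sd_true <- 4
  err_sd <- sd_true * sqrt(1 / 0.9^2 - 1)
  p <- generate_validation_pairs(4000, error_sd = err_sd, seed = 12)
  rep <- validate_trait(p$measured, p$predicted, p$attempts)
  expect_lt(abs(rep$pearson_r - 0.9), 0.03)
})

test_that("the RNG state of the caller is left untouched", {
  set.seed(314); before <- .Random.seed
  invisible(generate_weight_dataset(10, seed = 99))
  invisible(random_pose(5))
  expect_identical(.Random.seed, before)
})
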