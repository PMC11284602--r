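# Trait extraction in physical units.

test_that("crown diameter: 30 px box at 0.05 cm/px is 15.0 mm", {
  H <- scale_homography(0.05)
  d <- spt_detection("crown", c(10, 10, 40, 30))
  m <- crown_diameter(d, H)
  expect_equal(m$value, 15.0, tolerance = 1e-9)
  expect_equal(m$units, "mm")
  expect_error(spt_detection("crown", c(10, 10, 10, 30)), "positive area")
  expect_error(crown_diameter(spt_detection("leaf", c(0, 0, 2, 2)), H),
               class = "spt_label_mismatch")
})

test_that("endpoint distance: 20 cm vertical and a 3-4-5 triangle", {
  H <- scale_homography(1)  # 1 cm per px: centers in px are centers in cm
  mk <- function(lab, cx, cy) spt_detection(lab, c(cx - 1, cy - 1, cx + 1, cy + 1))
  expect_equal(endpoint_distance(mk("plant_bottom", 0, 0), mk("plant_top", 0, 20), H),
               20, tolerance = 1e-9)
  expect_equal(endpoint_distance(mk("plant_bottom", 0, 0), mk("plant_top", 3, 4), H),
               5, tolerance = 1e-9)
  ph <- plant_height(mk("plant_bottom", 0, 0), mk("plant_top", 0, 20), H)
  expect_equal(ph$value, 20); expect_equal(ph$units, "cm")
  expect_error(plant_height(mk("crown", 0, 0), mk("plant_top", 0, 20), H),
               class = "spt_label_mismatch")
  expect_error(petiole_length(mk("petiole_bottom", 0, 0), mk("crown", 0, 2), H),
               class = "spt_label_mismatch")
})

test_that("leaf metrics: rectangle exactly, circle to 2%", {
  H <- scale_homography(0.05)
  rect <- matrix(FALSE, 80, 140); rect[21:60, 21:120] <- TRUE  # 100 x 40 px
  lm <- leaf_metrics(rect, H, resolution_cm_per_px = 0.05)
  expect_equal(lm$LA$value, 10.0, tolerance = 1e-9)
  expect_equal(lm$LL$value, 5.0, tolerance = 1e-9)
  expect_equal(lm$LW$value, 2.0, tolerance = 1e-9)
  expect_equal(lm$LA$units, "cm2"); expect_equal(lm$LL$units, "cm")

  # filled circle, radius 1.5 cm = 30 px
  xs <- matrix(0:99, 100, 100, byrow = TRUE); ys <- matrix(0:99, 100, 100)
  circ <- (xs - 49.5)^2 + (ys - 49.5)^2 <= 30^2
  lmc <- leaf_metrics(circ, H, resolution_cm_per_px = 0.05)
  expect_lt(abs(lmc$LA$value / (pi * 1.5^2) - 1), 0.02)
  expect_lt(abs(lmc$LL$value / 3 - 1), 0.02)
  expect_lt(abs(lmc$LW$value / 3 - 1), 0.02)
  expect_gte(lmc$LL$value, lmc$LW$value)

  expect_error(leaf_metrics(matrix(FALSE, 5, 5), H), class = "spt_empty_mask")
})

test_that("region area counts rectified cells times cell area", {
  H <- scale_homography(0.05)
  m <- matrix(FALSE, 60, 60); m[11:50, 11:60] <- TRUE  # 2000 px
  a <- region_area(m, H, "FlA", resolution_cm_per_px = 0.05)
  expect_equal(a$value, 5.0, tolerance = 1e-9)
  expect_equal(a$units, "cm2")
  expect_error(region_area(matrix(FALSE, 4, 4), H, "FrA"), class = "spt_empty_mask")
})

test_that("measure_image orchestrates the full pipeline per trait", {
  sc <- render_scene(trait_scene("CD", pose = random_pose(41)))
  ms <- measure_image(sc$image, "CD", oracle_backend(sc$gt))
  expect_length(ms, 1)
  expect_lt(abs(ms[[1]]$value / sc$gt$truth$CD_mm - 1), 0.01)
  expect_equal(ms[[1]]$backend_id, "oracle")
  expect_true(is.finite(ms[[1]]$scale_cm_per_px))

  sc3 <- render_scene(trait_scene("fruit", n_fruits = 3, pose = random_pose(42)))
  ms3 <- measure_image(sc3$image, "FrA", oracle_backend(sc3$gt))
  expect_length(ms3, 3)

  expect_error(measure_image(new_image(50, 50), "CD", classical_backend()),
               class = "spt_marker_not_found")
})

test_that("undetected parts give an empty measurement list, not an error", {
  sc <- render_scene(trait_scene("CD", pose = random_pose(43)))
  # classical backend asked for fruit in a crown-only scene
  expect_length(measure_image(sc$image, "FrA", classical_backend()), 0)
})

test_that("LL >= LW and LA <= LL*LW hold for convex masks across poses", {
  for (i in 1:4) {
    sc <- render_scene(trait_scene("leaf", pose = random_pose(50 + i)))
    be <- oracle_backend(sc$gt)
    ll <- measure_one(sc$image, "LL", be)
    lw <- measure_one(sc$image, "LW", be)
    la <- measure_one(sc$image, "LA", be)
    expect_gte(ll, lw)
    expect_lte(la, ll * lw)
  }
})

test_that("scaling physical sizes by s scales lengths by s and areas by s^2", {
  pose <- scene_pose(tilt_deg = 12, azimuth_deg = 120)
  s <- 1.3
  for (tr in c("PL", "leaf")) {
    sc1 <- render_scene(trait_scene(tr, pose = pose))
    sc2 <- render_scene(trait_scene(tr, pose = pose, size_scale = s))
    b1 <- oracle_backend(sc1$gt); b2 <- oracle_backend(sc2$gt)
    if (tr == "PL") {
      expect_equal(measure_one(sc2$image, "PL", b2) / measure_one(sc1$image, "PL", b1),
                   s, tolerance = 0.01)
    } else {
      expect_equal(measure_one(sc2$image, "LL", b2) / measure_one(sc1$image, "LL", b1),
                   s, tolerance = 0.01)
      expect_equal(measure_one(sc2$image, "LA", b2) / measure_one(sc1$image, "LA", b1),
                   s^2, tolerance = 0.02)
    }
  }
})

test_that("unit discipline is fixed per trait", {
  expect_equal(trait_measurement("CD", 1)$units, "mm")
  expect_equal(trait_measurement("PH", 1)$units, "cm")
  expect_equal(trait_measurement("LA", 1)$units, "cm2")
  expect_equal(trait_measurement("FrA", 1)$units, "cm2")
  expect_error(trait_measurement("CD", -1))
  expect_error(trait_measurement("XX", 1))
})
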