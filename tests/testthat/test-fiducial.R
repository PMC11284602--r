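# Fiducial calibration: homography solve, metric mapping, marker detection,
# mask rectification.

test_that("homography from an axis-aligned 94-px marker is a pure 0.05 cm/px scale", {
  mk <- marker_detection(rbind(c(0, 0), c(94, 0), c(94, 94), c(0, 94)))
  H <- estimate_homography(mk)
  expect_equal(H$scale_cm_per_px, 0.05, tolerance = 1e-12)
  expect_equal(H$matrix / H$matrix[3, 3],
               diag(c(0.05, 0.05, 1)), tolerance = 1e-9)
  p <- to_metric(c(3 / 0.05, 4 / 0.05), H)
  expect_equal(as.vector(p), c(3, 4), tolerance = 1e-9)
})

test_that("corners given in cm yield the identity-up-to-units map", {
  s <- 4.7
  mk <- marker_detection(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  H <- estimate_homography(mk)
  expect_equal(H$matrix / H$matrix[3, 3], diag(3), tolerance = 1e-9)
  expect_equal(as.vector(to_metric(c(3, 4), H)), c(3, 4), tolerance = 1e-9)
})

test_that("generate-then-recover: the solved matrix matches the known inverse up to scale", {
  set.seed(11)
  s <- 4.7
  base <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  for (i in 1:20) {
    corners <- random_corner_set()
    Hknown <- strawpheno:::solve_homography(base, corners)  # plane -> image
    H <- estimate_homography(marker_detection(corners))
    got <- H$matrix / H$matrix[3, 3]
    want <- solve(Hknown); want <- want / want[3, 3]
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-8)), 1e-8)
  }
})

test_that("4-point round trip reproduces the physical square to 1e-6 cm", {
  set.seed(7)
  s <- 4.7
  phys <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  for (i in 1:200) {
    corners <- random_corner_set()
    H <- estimate_homography(marker_detection(corners))
    expect_lt(max(abs(to_metric(corners, H) - phys)), 1e-6)
  }
})

test_that("degenerate corner sets are rejected", {
  expect_error(estimate_homography(
    marker_detection(rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1)))),
    class = "spt_degenerate_corners")
  # collinear triple caught at construction or solve stage
  expect_error(marker_detection(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
               class = "spt_degenerate_corners")
})

test_that("to_metric maps marker corners to the physical 4.7 cm square", {
  corners <- random_corner_set()
  H <- estimate_homography(marker_detection(corners))
  expect_equal(to_metric(corners, H),
               rbind(c(0, 0), c(4.7, 0), c(4.7, 4.7), c(0, 4.7)),
               tolerance = 1e-7, ignore_attr = TRUE)
  # midpoint of the top edge maps to (side/2, 0): projective invariance of
  # the solved correspondence does NOT hold for midpoints in general, but
  # the midpoint of the *image* top edge maps onto the top edge line
  mid_plane <- to_metric((corners[1, ] + corners[2, ]) / 2, H)
  expect_equal(mid_plane[2], 0, tolerance = 1e-6)
})

test_that("points on the line at infinity raise spt_point_at_infinity", {
  corners <- random_corner_set()
  H <- estimate_homography(marker_detection(corners))
  A <- H$matrix
  # construct a point with vanishing homogeneous coordinate: w = A31 x + A32 y + A33 = 0
  x <- 1000
  y <- -(A[3, 1] * x + A[3, 3]) / A[3, 2]
  expect_error(to_metric(c(x, y), H), class = "spt_point_at_infinity")
})

test_that("detect_marker finds an axis-aligned marker at sub-pixel accuracy, in order", {
  img <- render_axis_marker(160, 150, x0 = 10, y0 = 10, side = 100)
  mk <- detect_marker(img)
  want <- rbind(c(10, 10), c(110, 10), c(110, 110), c(10, 110))
  expect_lt(max(abs(mk$corners - want)), 0.5)
  # canonical order: TL, TR, BR, BL
  expect_true(all(sqrt(rowSums((mk$corners - want)^2)) < 0.5))
})

test_that("detect_marker achieves <= 0.5 px against generator ground truth", {
  for (i in 1:5) {
    sc <- render_scene(trait_scene("flower", pose = random_pose(200 + i)))
    mk <- detect_marker(sc$image)
    expect_lt(max(sqrt(rowSums((mk$corners - sc$gt$marker_corners)^2))), 0.5)
  }
})

test_that("blank and ambiguous images raise the right conditions", {
  expect_error(detect_marker(new_image(60, 60)), class = "spt_marker_not_found")
  two <- render_axis_marker(300, 120, x0 = 10, y0 = 10, side = 90)
  two2 <- render_axis_marker(300, 120, x0 = 180, y0 = 10, side = 90)
  both <- pmin(two, two2)
  expect_error(detect_marker(both), class = "spt_ambiguous_marker")
})

test_that("rectify_mask is the identity at matching scale, counts the marker area, and passes empties through", {
  H1 <- scale_homography(1)   # 1 cm per px
  m <- matrix(FALSE, 20, 25); m[5:12, 7:19] <- TRUE
  r <- rectify_mask(m, H1, 1)
  expect_equal(dim(r$bitmap), dim(m))
  expect_identical(unname(r$bitmap), unname(m))

  # full marker square at 0.047 cm/px: ~100x100 block, count within 2% of 10,000
  H <- scale_homography(0.047)
  px <- round(4.7 / 0.047)
  full <- matrix(FALSE, px + 20, px + 20)
  full[10 + seq_len(px), 10 + seq_len(px)] <- TRUE
  r2 <- rectify_mask(full, H, 0.047)
  expect_lt(abs(sum(r2$bitmap) - 10000) / 10000, 0.02)

  r3 <- rectify_mask(matrix(FALSE, 10, 10), H, 0.047)
  expect_equal(sum(r3$bitmap), 0)
  expect_equal(length(r3$bitmap), 0L)
})

test_that("rendering the same scene at 2x resolution changes metric output by < 0.5%", {
  pose <- scene_pose(tilt_deg = 18, azimuth_deg = 35, distance_cm = 100)
  v <- sapply(c(24, 48), function(res) {
    sc <- render_scene(trait_scene("leaf", pose = pose, px_per_cm = res))
    measure_one(sc$image, "LA", oracle_backend(sc$gt))
  })
  expect_lt(abs(v[2] / v[1] - 1), 0.005)
})
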