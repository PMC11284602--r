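#' Synthetic scene generation
#'
#' Renders planar test scenes with the structure the measurement pipeline
#' assumes: a square fiducial marker of known side length imaged under a
#' projective pose, plus coplanar plant-proxy parts (flat colored
#' rectangles, ellipses and disks) of known physical dimensions.  Every
#' render returns pixel-exact ground truth (marker corners, per-part boxes,
#' masks and true trait values), so the geometry and statistics pipeline is
#' testable end to end without any real photographs or trained models.
#'
#' Proxies are deliberately not photorealistic: the artifact under test is
#' the calibration/measurement pipeline, not a learned detector.
#'
#' @name synthetic_scenes
NULL

#' Default part colors used by the generator and the classical backend
#' @return named list of RGB triples in `[0,1]`
#' @export
trait_palette <- function() {
  list(crown          = c(0.45, 0.26, 0.10),
       plant_top      = c(0.10, 0.35, 0.80),
       plant_bottom   = c(0.00, 0.65, 0.95),
       petiole_top    = c(0.55, 0.10, 0.70),
       petiole_bottom = c(0.90, 0.45, 0.85),
       leaf           = c(0.13, 0.55, 0.13),
       flower         = c(0.95, 0.85, 0.10),
       fruit          = c(0.85, 0.10, 0.10))
}

part_labels <- function() c("crown", "plant_top", "plant_bottom", "petiole_top",
                            "petiole_bottom", "leaf", "flower", "fruit", "marker")

#' Describe one plant-proxy part on the marker plane
#'
#' Plane coordinates are in cm with the marker occupying `[0, side] x
#' [0, side]` (x right, y down).
#'
#' @param label part class, one of the closed vocabulary (see
#'   [part_labels()])
#' @param shape `"rect"`, `"ellipse"` or `"disk"`
#' @param center plane center in cm
#' @param w,h rect full width/height (cm)
#' @param a,b ellipse full axis lengths (cm; `a` is the major axis)
#' @param r disk radius (cm)
#' @param angle_deg in-plane rotation of the shape
#' @param color RGB fill; defaults to [trait_palette()] entry for `label`
#' @export
scene_part <- function(label, shape, center, w = NULL, h = NULL,
                       a = NULL, b = NULL, r = NULL, angle_deg = 0,
                       color = NULL) {
  stopifnot(label %in% setdiff(part_labels(), "marker"),
            shape %in% c("rect", "ellipse", "disk"))
  semi <- switch(shape,
    rect    = { stopifnot(w > 0, h > 0); c(w / 2, h / 2) },
    ellipse = { stopifnot(a > 0, b > 0, a >= b); c(a / 2, b / 2) },
    disk    = { stopifnot(r > 0); c(r, r) })
  if (is.null(color)) color <- trait_palette()[[label]]
  structure(list(label = label, shape = shape, center = as.numeric(center),
                 semi = semi, angle = angle_deg * pi / 180, color = color),
            class = "scene_part")
}

#' Camera pose for a planar scene
#'
#' The pose is a tilt of magnitude `tilt_deg` about an in-plane axis at
#' `azimuth_deg` (so `tilt_deg` is the full angle between the optical axis
#' and the plane normal), an in-plane scene rotation `rot_deg`, and a
#' viewing distance, composed into a plane-to-image homography.  The
#' optical axis passes through `aim_cm` (set by [scene_spec()]) and the
#' camera is *rolled so the plane's vertical axis appears vertical at the
#' aim point* — mimicking a photographer aiming at the target part and
#' framing it upright.  Alternatively, explicit `tilt_x_deg`/`tilt_y_deg`
#' Euler tilts may be given.  Tilt is capped at 60 degrees to keep the
#' marker detectable.
#'
#' @param rot_deg in-plane rotation of the scene content; the measurement
#'   protocol assumes upright framing, so the default is 0
#' @param tilt_deg tilt magnitude (degrees) about an in-plane axis
#' @param azimuth_deg direction of the tilt axis (degrees)
#' @param tilt_x_deg,tilt_y_deg alternative Euler-style tilts about the
#'   image x / y axes (used when either is nonzero)
#' @param distance_cm camera-to-plane distance along the optical axis
#' @export
scene_pose <- function(rot_deg = 0, tilt_deg = 0, azimuth_deg = 0,
                       tilt_x_deg = 0, tilt_y_deg = 0, distance_cm = 100) {
  stopifnot(abs(tilt_deg) <= 60, abs(tilt_x_deg) <= 60, abs(tilt_y_deg) <= 60,
            distance_cm > 0)
  structure(list(rot = rot_deg * pi / 180, tilt = tilt_deg * pi / 180,
                 azim = azimuth_deg * pi / 180,
                 tx = tilt_x_deg * pi / 180, ty = tilt_y_deg * pi / 180,
                 d = distance_cm),
            class = "scene_pose")
}

#' Draw a random pose with bounded total tilt
#' @param seed integer seed
#' @param max_tilt_deg bound on the total tilt angle (degrees)
#' @param rot_range in-plane rotation range (degrees)
#' @param distance_range viewing distance range (cm)
#' @export
random_pose <- function(seed, max_tilt_deg = 30, rot_range = c(0, 0),
                        distance_range = c(80, 140)) {
  with_seed(seed, scene_pose(
    rot_deg     = stats::runif(1, rot_range[1], rot_range[2]),
    tilt_deg    = stats::runif(1, 0, max_tilt_deg),
    azimuth_deg = stats::runif(1, 0, 360),
    distance_cm = stats::runif(1, distance_range[1], distance_range[2])))
}

# evaluate fn with a temporary RNG state derived from seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Assemble a scene specification
#'
#' @param parts list of [scene_part()]s
#' @param pose a [scene_pose()]
#' @param px_per_cm nominal image resolution at the aim point
#' @param side_cm marker physical side length
#' @param aim_cm plane point on the optical axis; defaults to the centroid
#'   of the part centers (the camera is pointed at the target)
#' @param image_size optional `c(width, height)` in px; when `NULL` the
#'   frame is auto-sized to the content plus a margin
#' @param background background RGB
#' @param seed integer; the render itself is deterministic, the seed is
#'   recorded for provenance and used by helpers that randomize the spec
#' @export
scene_spec <- function(parts, pose = scene_pose(), px_per_cm = 20,
                       side_cm = 4.7, aim_cm = NULL, image_size = NULL,
                       background = c(0.93, 0.93, 0.90), seed = 1L) {
  stopifnot(length(parts) >= 0, px_per_cm > 0, side_cm > 0)
  if (is.null(aim_cm)) {
    aim_cm <- if (length(parts))
      colMeans(do.call(rbind, lapply(parts, `[[`, "center")))
    else c(side_cm / 2, side_cm / 2)
  }
  structure(list(parts = parts, pose = pose, px_per_cm = px_per_cm,
                 side_cm = side_cm, aim_cm = as.numeric(aim_cm),
                 image_size = image_size, background = background,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# plane(cm) -> image(px) homography for a spec (before frame translation)
pose_homography <- function(spec) {
  p <- spec$pose
  rot2 <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Rz <- rot2(p$rot)
  if (p$tx != 0 || p$ty != 0) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(p$tx), -sin(p$tx)), c(0, sin(p$tx), cos(p$tx)))
    Ry <- rbind(c(cos(p$ty), 0, sin(p$ty)), c(0, 1, 0), c(-sin(p$ty), 0, cos(p$ty)))
    Rt <- Ry %*% Rx
  } else {
    # tilt of magnitude `tilt` about the in-plane axis at azimuth `azim`
    Rx <- rbind(c(1, 0, 0), c(0, cos(p$tilt), -sin(p$tilt)),
                c(0, sin(p$tilt), cos(p$tilt)))
    Rt <- rot2(p$azim) %*% Rx %*% rot2(-p$azim)
  }
  R <- Rt %*% Rz
  t <- c(0, 0, p$d) - R[, 1:2] %*% spec$aim_cm
  f <- spec$px_per_cm * p$d
  H0 <- diag(c(f, f, 1)) %*% cbind(R[, 1], R[, 2], t)
  # camera roll: level the frame so the plane's y axis maps to image
  # vertical at the aim point (the photographer frames the target upright)
  eps <- 1e-4
  p0 <- apply_homography(H0, spec$aim_cm)
  p1 <- apply_homography(H0, spec$aim_cm + c(0, eps))
  dy <- p1 - p0
  roll <- atan2(dy[1], dy[2])
  rot2(roll) %*% H0
}

# exact image-frame bounding box of a part under H (plane->image, px)
part_image_bbox <- function(part, H) {
  if (part$shape == "rect") {
    ca <- cos(part$angle); sa <- sin(part$angle)
    Rm <- rbind(c(ca, -sa), c(sa, ca))
    crn <- t(part$center + Rm %*% t(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) *
                                    rep(part$semi, each = 4)))
    p <- apply_homography(H, crn)
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  } else {
    conic_bbox(part, H)
  }
}

# exact bbox of the projective image of an ellipse, via the dual conic
conic_bbox <- function(part, H) {
  ca <- cos(part$angle); sa <- sin(part$angle)
  a <- part$semi[1]; b <- part$semi[2]; x0 <- part$center[1]; y0 <- part$center[2]
  # plane -> unit-circle coordinates
  Mi <- rbind(c(ca / a,  sa / a, -(x0 * ca + y0 * sa) / a),
              c(-sa / b, ca / b,  (x0 * sa - y0 * ca) / b),
              c(0, 0, 1))
  Cp <- t(Mi) %*% diag(c(1, 1, -1)) %*% Mi
  Hi <- solve(H)                       # image -> plane
  Ci <- t(Hi) %*% Cp %*% Hi
  D <- solve(Ci)
  solve_tangent <- function(d11, d13, d33) {
    disc <- d13^2 - d11 * d33
    if (disc < 0) stop("degenerate projected conic")
    (d13 + c(-1, 1) * sqrt(disc)) / d33
  }
  xs <- solve_tangent(D[1, 1], D[1, 3], D[3, 3])
  ys <- solve_tangent(D[2, 2], D[2, 3], D[3, 3])
  c(min(xs), min(ys), max(xs), max(ys))
}

# plane coordinates of the pixel-center grid xs (cols) x ys (rows) under Hinv
plane_grid <- function(Hinv, xs, ys) {
  nu <- length(xs); nv <- length(ys)
  U <- matrix(xs, nv, nu, byrow = TRUE)
  V <- matrix(ys, nv, nu)
  W <- Hinv[3, 1] * U + Hinv[3, 2] * V + Hinv[3, 3]
  list(X = (Hinv[1, 1] * U + Hinv[1, 2] * V + Hinv[1, 3]) / W,
       Y = (Hinv[2, 1] * U + Hinv[2, 2] * V + Hinv[2, 3]) / W)
}

part_membership <- function(part, X, Y) {
  ca <- cos(part$angle); sa <- sin(part$angle)
  dx <- X - part$center[1]; dy <- Y - part$center[2]
  u <- ca * dx + sa * dy; v <- -sa * dx + ca * dy
  if (part$shape == "rect") {
    u >= -part$semi[1] & u < part$semi[1] & v >= -part$semi[2] & v < part$semi[2]
  } else {
    (u / part$semi[1])^2 + (v / part$semi[2])^2 <= 1
  }
}

#' Render a scene and its ground truth
#'
#' Deterministic given the spec: pixels are colored by membership of their
#' center point in each projected shape (marker first, then parts).  The
#' fiducial is drawn as a dark square with a light square cue in its
#' top-left quadrant so corner order is unambiguous.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (RGB array) and `gt`, a ground-truth record
#'   holding `marker_corners` (4x2 px, canonical order), `H` (the true
#'   plane-to-image homography), per-part exact image boxes, masks
#'   ([spt_mask()]) and physical shape parameters, and `truth`, the named
#'   list of true trait values in reporting units
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- spec$side_cm
  H0 <- pose_homography(spec)
  marker_plane <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  # frame: translate so content fits (or centers, for a fixed size)
  content <- apply_homography(H0, marker_plane)
  pboxes0 <- lapply(spec$parts, part_image_bbox, H = H0)
  for (b in pboxes0) content <- rbind(content, c(b[1], b[2]), c(b[3], b[4]))
  margin <- 8
  if (is.null(spec$image_size)) {
    wpx <- ceiling(diff(range(content[, 1]))) + 2 * margin + 1
    hpx <- ceiling(diff(range(content[, 2]))) + 2 * margin + 1
    tx <- margin - min(content[, 1])
    ty <- margin - min(content[, 2])
  } else {
    wpx <- spec$image_size[1]; hpx <- spec$image_size[2]
    tx <- (wpx - 1) / 2 - mean(range(content[, 1]))
    ty <- (hpx - 1) / 2 - mean(range(content[, 2]))
  }
  H <- rbind(c(1, 0, tx), c(0, 1, ty), c(0, 0, 1)) %*% H0
  content[, 1] <- content[, 1] + tx; content[, 2] <- content[, 2] + ty
  if (min(content) < 1 || max(content[, 1]) > wpx - 2 || max(content[, 2]) > hpx - 2) {
    bad <- which(content[, 1] < 1 | content[, 1] > wpx - 2 |
                 content[, 2] < 1 | content[, 2] > hpx - 2)[1]
    lab <- if (bad <= 4) "marker" else spec$parts[[ceiling((bad - 4) / 2)]]$label
    err_part_out_of_frame(lab)
  }
  Hinv <- solve(H)
  img <- new_image(wpx, hpx, spec$background)

  # anti-aliased paint: 16-sample N-rooks subpixel coverage (16 distinct
  # offsets per axis, so near-axis-aligned edges do not alias the way a
  # regular subgrid does; real photographs have soft edges and sub-pixel
  # marker localisation depends on them).  The ground-truth mask keeps the
  # crisp pixel-center membership rule.
  nrooks <- {
    dx <- ((0:15) + 0.5) / 16 - 0.5
    perm <- c(0, 8, 4, 12, 2, 10, 6, 14, 1, 9, 5, 13, 3, 11, 7, 15) + 1
    cbind(dx, dx[perm])
  }
  draw <- function(img, bbox, member_fun, color) {
    cset <- max(1, floor(bbox[1] - 1)):min(wpx, ceiling(bbox[3] + 3))
    rset <- max(1, floor(bbox[2] - 1)):min(hpx, ceiling(bbox[4] + 3))
    nr <- length(rset); nc <- length(cset)
    cv <- matrix(0, nr, nc)
    for (k in 1:16) {
      g <- plane_grid(Hinv, cset - 1 + nrooks[k, 1], rset - 1 + nrooks[k, 2])
      cv <- cv + member_fun(g$X, g$Y)
    }
    cv <- cv / 16
    gc <- plane_grid(Hinv, cset - 1, rset - 1)
    m <- member_fun(gc$X, gc$Y)
    for (k in 1:3) {
      ch <- img[, , k]
      sub <- ch[rset, cset]
      ch[rset, cset] <- sub * (1 - cv) + color[k] * cv
      img[, , k] <- ch
    }
    list(img = img, mask_crop = m, rset = rset, cset = cset)
  }

  # fiducial: dark square minus light cue hole in the top-left quadrant
  mc_img <- apply_homography(H, marker_plane)
  mb <- c(min(mc_img[, 1]), min(mc_img[, 2]), max(mc_img[, 1]), max(mc_img[, 2]))
  hole_half <- 0.10 * s; hole_c <- c(0.25, 0.25) * s
  marker_fun <- function(X, Y) {
    inside <- X >= 0 & X < s & Y >= 0 & Y < s
    hole <- abs(X - hole_c[1]) < hole_half & abs(Y - hole_c[2]) < hole_half
    inside & !hole
  }
  dr <- draw(img, mb, marker_fun, c(0.05, 0.05, 0.05))
  img <- dr$img

  gt_parts <- vector("list", length(spec$parts))
  for (i in seq_along(spec$parts)) {
    pt <- spec$parts[[i]]
    bbox <- part_image_bbox(pt, H)
    dr <- draw(img, bbox, function(X, Y) part_membership(pt, X, Y), pt$color)
    img <- dr$img
    m <- dr$mask_crop
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0L) err_part_out_of_frame(pt$label)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    bitmap <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    crop_box <- c(x0 = dr$cset[cc[1]] - 1.5, y0 = dr$rset[rr[1]] - 1.5,
                  x1 = dr$cset[cc[2]] - 0.5, y1 = dr$rset[rr[2]] - 0.5)
    gt_parts[[i]] <- list(label = pt$label, shape = pt$shape,
                          center_cm = pt$center, semi_cm = pt$semi,
                          angle = pt$angle,
                          box = c(x0 = bbox[1], y0 = bbox[2],
                                  x1 = bbox[3], y1 = bbox[4]),
                          mask = spt_mask(crop_box, bitmap))
  }
  gt <- structure(list(marker_corners = mc_img, side_cm = s, H = H,
                       px_per_cm = spec$px_per_cm,
                       parts = gt_parts, truth = scene_truth(spec),
                       seed = spec$seed),
                  class = "scene_ground_truth")
  list(image = img, gt = gt)
}

# true trait values, in reporting units, implied by the part geometry
scene_truth <- function(spec) {
  parts <- spec$parts
  labs <- vapply(parts, `[[`, "", "label")
  out <- list()
  if ("crown" %in% labs) {
    p <- parts[[match("crown", labs)]]
    out$CD_mm <- 10 * 2 * p$semi[1]
  }
  pair_dist <- function(l1, l2) {
    sqrt(sum((parts[[match(l1, labs)]]$center - parts[[match(l2, labs)]]$center)^2))
  }
  if (all(c("plant_bottom", "plant_top") %in% labs))
    out$PH_cm <- pair_dist("plant_bottom", "plant_top")
  if (all(c("petiole_bottom", "petiole_top") %in% labs))
    out$PL_cm <- pair_dist("petiole_bottom", "petiole_top")
  if ("leaf" %in% labs) {
    p <- parts[[match("leaf", labs)]]
    out$LA_cm2 <- pi * p$semi[1] * p$semi[2]
    out$LL_cm <- 2 * p$semi[1]
    out$LW_cm <- 2 * p$semi[2]
  }
  area_of <- function(p) {
    if (p$shape == "rect") 4 * p$semi[1] * p$semi[2] else pi * p$semi[1] * p$semi[2]
  }
  if ("flower" %in% labs)
    out$FlA_cm2 <- vapply(parts[labs == "flower"], area_of, numeric(1))
  if ("fruit" %in% labs)
    out$FrA_cm2 <- vapply(parts[labs == "fruit"], area_of, numeric(1))
  out
}

#' Standard single-trait scene
#'
#' Builds the default scene for one trait with physical sizes typical of
#' the greenhouse measurements the pipeline targets (crown diameter
#' 14.4 mm, plant height 24.6 cm, petiole length 15.1 cm, leaf
#' 7.0 x 5.5 cm, flower 3.26 cm^2, fruit 6.52 cm^2) and a per-trait image
#' resolution emulating the natural shooting distance (close-ups for small
#' parts).  The camera is aimed at the target part; the marker sits to its
#' left, coplanar.
#'
#' @param trait one of `"CD" "PH" "PL" "leaf" "flower" "fruit"`
#' @param pose a [scene_pose()]
#' @param size_scale multiply all physical part sizes (not the marker) by
#'   this factor
#' @param n_fruits number of fruit disks (fruit scenes only)
#' @param px_per_cm override the per-trait default resolution
#' @param seed recorded in the spec
#' @return a [scene_spec()]
#' @export
trait_scene <- function(trait = c("CD", "PH", "PL", "leaf", "flower", "fruit"),
                        pose = scene_pose(), size_scale = 1, n_fruits = 1,
                        px_per_cm = NULL, seed = 1L) {
  trait <- match.arg(trait)
  s <- 4.7
  gap <- 1.2
  k <- size_scale
  res_default <- c(CD = 40, PH = 16, PL = 18, leaf = 24, flower = 40, fruit = 32)
  if (is.null(px_per_cm)) px_per_cm <- res_default[[trait]]
  parts <- switch(trait,
    CD = list(scene_part("crown", "rect", c(s + gap + 0.9 * k, s / 2),
                         w = 1.44 * k, h = 0.9 * k)),
    PH = {
      cx <- s + gap + 1.2
      list(scene_part("plant_bottom", "rect", c(cx, s / 2 + 12.3 * k),
                      w = 1.2, h = 1.2),
           scene_part("plant_top", "rect", c(cx, s / 2 - 12.3 * k),
                      w = 1.2, h = 1.2))
    },
    PL = {
      cx <- s + gap + 1.0
      list(scene_part("petiole_bottom", "rect", c(cx, s / 2 + 7.55 * k),
                      w = 0.9, h = 0.9),
           scene_part("petiole_top", "rect", c(cx, s / 2 - 7.55 * k),
                      w = 0.9, h = 0.9))
    },
    leaf = list(scene_part("leaf", "ellipse", c(s + gap + 3.6 * k, s / 2),
                           a = 7.0 * k, b = 5.5 * k)),
    flower = list(scene_part("flower", "disk", c(s + gap + 1.1 * k, s / 2),
                             r = sqrt(3.26 / pi) * k)),
    fruit = {
      r <- sqrt(6.52 / pi) * k
      lapply(seq_len(n_fruits), function(i)
        scene_part("fruit", "disk",
                   c(s + gap + r + (i - 1) * (2 * r + 0.8), s / 2), r = r))
    })
  scene_spec(parts, pose = pose, px_per_cm = px_per_cm, side_cm = s, seed = seed)
}

#' Paired fruit areas and fresh weights from a linear ground-truth model
#'
#' Areas are drawn uniformly over `area_range` and weights follow
#' `slope * area + intercept` plus Gaussian noise, emulating the
#' fruit-harvest calibration set used to fit the weight regression.
#'
#' @param n number of fruits
#' @param slope g per cm^2
#' @param intercept g
#' @param noise_sd Gaussian noise SD in g
#' @param seed integer seed
#' @param area_range fruit area range in cm^2
#' @return data.frame with `area_cm2`, `weight_g`
#' @export
generate_weight_dataset <- function(n, slope = 3.0, intercept = -1.0,
                                    noise_sd = 2.0, seed = 1L,
                                    area_range = c(1, 15)) {
  stopifnot(n >= 1)
  with_seed(seed, {
    areas <- stats::runif(n, area_range[1], area_range[2])
    weights <- slope * areas + intercept + stats::rnorm(n, 0, noise_sd)
    data.frame(area_cm2 = areas, weight_g = weights)
  })
}

#' Measured/predicted validation pairs with detection dropout
#'
#' Emulates the validation protocol: `n` attempted measurements of known
#' true values, where the tool fails to detect the part with probability
#' `dropout_rate` (feeding the detection-frequency statistic) and otherwise
#' reports the true value plus Gaussian error.
#'
#' @param n number of attempts
#' @param true_values length-`n` vector of conventional (reference) values;
#'   defaults to `rnorm(n, 15, 4)`
#' @param error_sd measurement error SD of the tool
#' @param dropout_rate probability an attempt yields no detection
#' @param seed integer seed
#' @return list with `measured`, `predicted` (successful attempts only)
#'   and `attempts = n`
#' @export
generate_validation_pairs <- function(n, true_values = NULL, error_sd = 1.0,
                                      dropout_rate = 0.0, seed = 1L) {
  stopifnot(n >= 1, dropout_rate >= 0, dropout_rate < 1)
  with_seed(seed, {
    if (is.null(true_values)) true_values <- stats::rnorm(n, 15, 4)
    stopifnot(length(true_values) == n)
    ok <- stats::runif(n) >= dropout_rate
    list(measured = true_values[ok],
         predicted = true_values[ok] + stats::rnorm(sum(ok), 0, error_sd),
         attempts = n)
  })
}
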