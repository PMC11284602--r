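#' Fiducial-marker calibration
#'
#' A square marker of known physical side length (default 4.7 cm) is placed
#' in the scene, coplanar with the plant parts to be measured.  Its four
#' corners determine a plane homography mapping image pixels to metric
#' coordinates on the marker plane, which is the basis of every trait
#' measurement.  Measurements are only valid for content lying on (parallel
#' to) the marker plane; the package documents but cannot verify this
#' coplanarity contract.
#'
#' @name fiducial
NULL

#' Construct a marker detection
#'
#' @param corners 4x2 numeric matrix of image points in canonical order:
#'   top-left, top-right, bottom-right, bottom-left of the *physical*
#'   marker (0-based pixel-center coordinates)
#' @param side_cm physical side length of the square marker in cm
#' @return object of class `marker_detection`
#' @export
marker_detection <- function(corners, side_cm = 4.7) {
  corners <- matrix(as.numeric(corners), 4, 2)
  stopifnot(all(is.finite(corners)), side_cm > 0)
  a <- polygon_area(corners)
  if (abs(a) <= .Machine$double.eps * 100)
    err_degenerate_corners("marker corner polygon has zero area")
  if (!is_convex_quad(corners))
    err_degenerate_corners("marker corners do not form a convex quadrilateral")
  structure(list(corners = corners, side_cm = side_cm),
            class = "marker_detection")
}

# signed shoelace area of a polygon given as n x 2 matrix
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

is_convex_quad <- function(p) {
  z <- numeric(4)
  for (i in 1:4) {
    a <- p[i, ]; b <- p[i %% 4 + 1, ]; d <- p[(i + 1) %% 4 + 1, ]
    z[i] <- (b[1] - a[1]) * (d[2] - b[2]) - (b[2] - a[2]) * (d[1] - b[1])
  }
  all(z > 0) || all(z < 0)
}

#' Estimate the pixel-to-metric plane homography from marker corners
#'
#' Exact direct-linear-transform solve: four point correspondences determine
#' a projective map up to scale.  The detected corners are mapped onto the
#' physical marker square `(0,0), (s,0), (s,s), (0,s)` in cm (x right,
#' y down, origin at the marker's top-left corner).
#'
#' Only a projective correction is identifiable from four coplanar points;
#' radial lens distortion is deliberately not modelled.
#'
#' @param marker a [marker_detection()]
#' @return object of class `plane_homography` with fields `matrix` (3x3,
#'   image px -> plane cm), `scale_cm_per_px` (side_cm divided by the mean
#'   detected side length in px; reporting only — all measurement math uses
#'   the full matrix), `side_cm`, `corners`
#' @export
estimate_homography <- function(marker) {
  stopifnot(inherits(marker, "marker_detection"))
  src <- marker$corners
  s <- marker$side_cm
  dst <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  # collinearity screen: any 3 of the 4 corners
  combs <- utils::combn(4, 3)
  diag_len <- max(dist(src))
  for (i in seq_len(ncol(combs))) {
    p <- src[combs[, i], ]
    tri2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    if (tri2 < 1e-9 * diag_len^2) err_degenerate_corners()
  }
  H <- solve_homography(src, dst)
  # round-trip residual guard (should be ~machine precision for 4 points)
  res <- max(abs(apply_homography(H, src) - dst))
  if (!is.finite(res) || res > 1e-6)
    err_degenerate_corners(sprintf("homography residual %.3g cm exceeds 1e-6", res))
  side_px <- sqrt(rowSums((src[c(2, 3, 4, 1), ] - src)^2))
  structure(list(matrix = H,
                 scale_cm_per_px = s / mean(side_px),
                 side_cm = s,
                 corners = src),
            class = "plane_homography")
}

# DLT for n >= 4 correspondences; returns 3x3 H with src -> dst,
# normalised so H[3,3] == 1 when possible.
solve_homography <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i,     ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  if (abs(det(H)) < 1e-14) err_degenerate_corners("homography is singular")
  H
}

apply_homography <- function(H, pts) {
  pts <- to_pts_matrix(pts)
  P <- H %*% rbind(t(pts), 1)
  w <- P[3, ]
  if (any(abs(w) < 1e-12)) err_point_at_infinity()
  cbind(P[1, ] / w, P[2, ] / w)
}

to_pts_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = length(pts) > 2)
  stopifnot(ncol(pts) == 2)
  pts
}

#' Map image points to metric plane coordinates
#'
#' Projective application with homogeneous normalisation.  Distances between
#' returned points are physical distances (cm) for content coplanar with the
#' marker.
#'
#' @param points n x 2 matrix (or length-2 vector) of 0-based pixel-center
#'   image coordinates
#' @param H a `plane_homography`
#' @return n x 2 matrix of plane coordinates in cm
#' @export
to_metric <- function(points, H) {
  stopifnot(inherits(H, "plane_homography"))
  apply_homography(H$matrix, points)
}

#' Inverse mapping: metric plane coordinates back to image pixels
#' @inheritParams to_metric
#' @param points n x 2 matrix of plane cm coordinates
#' @export
from_metric <- function(points, H) {
  stopifnot(inherits(H, "plane_homography"))
  apply_homography(solve(H$matrix), points)
}

#' Rectify a binary mask onto the metric plane
#'
#' Resamples an image-frame mask onto a regular grid on the marker plane by
#' nearest-neighbor lookup, so that pixel counting happens on the
#' distortion-corrected plane where every grid cell has equal physical area.
#'
#' @param mask logical matrix in the image frame (full frame), or an
#'   [spt_mask()] registered to a box crop
#' @param H a `plane_homography`
#' @param resolution_cm_per_px output grid spacing in cm
#' @return list with `bitmap` (logical matrix on the metric grid), `origin_cm`
#'   (plane coordinates of the first cell center), `res_cm` and `cell_area_cm2`;
#'   an empty input yields an empty (0 x 0) bitmap, not an error
#' @export
rectify_mask <- function(mask, H, resolution_cm_per_px) {
  stopifnot(inherits(H, "plane_homography"), resolution_cm_per_px > 0)
  res <- resolution_cm_per_px
  if (inherits(mask, "spt_mask")) {
    off <- c(mask$box[["x0"]] + 0.5, mask$box[["y0"]] + 0.5)  # center of first crop pixel
    bm <- mask$bitmap
  } else {
    stopifnot(is.matrix(mask))
    off <- c(0, 0)
    bm <- mask
  }
  empty <- list(bitmap = matrix(FALSE, 0, 0), origin_cm = c(0, 0),
                res_cm = res, cell_area_cm2 = res^2)
  if (length(bm) == 0L || !any(bm)) return(empty)
  h <- nrow(bm); w <- ncol(bm)
  # plane bounding box: extremes of a projective image of a rectangle occur
  # at its corners (lines map to lines)
  crn <- rbind(c(-0.5, -0.5), c(w - 0.5, -0.5), c(w - 0.5, h - 0.5), c(-0.5, h - 0.5))
  crn[, 1] <- crn[, 1] + off[1]; crn[, 2] <- crn[, 2] + off[2]
  pl <- to_metric(crn, H)
  xs <- seq(min(pl[, 1]) + res / 2, max(pl[, 1]), by = res)
  ys <- seq(min(pl[, 2]) + res / 2, max(pl[, 2]), by = res)
  if (length(xs) == 0L || length(ys) == 0L) return(empty)
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  ip <- from_metric(grid, H)
  cc <- round(ip[, 1] - off[1]) + 1L   # crop column index
  rr <- round(ip[, 2] - off[2]) + 1L
  ok <- cc >= 1L & cc <= w & rr >= 1L & rr <= h
  val <- logical(nrow(grid))
  val[ok] <- bm[cbind(rr[ok], cc[ok])]
  out <- matrix(val, nrow = length(ys), ncol = length(xs))
  list(bitmap = out, origin_cm = c(xs[1], ys[1]), res_cm = res,
       cell_area_cm2 = res^2)
}

# ---------------------------------------------------------------------------
# Marker detection on rendered/synthetic scenes.

#' Detect the square fiducial marker in an image
#'
#' Screens dark 4-connected components for convex quadrilaterals, refines the
#' four edges by total-least-squares line fits on boundary pixels (with an
#' analytic half-sample debias along each edge normal) and intersects
#' adjacent edges to obtain sub-pixel corners.  Canonical corner order
#' (top-left, top-right, bottom-right, bottom-left of the physical marker)
#' is resolved from the light orientation cue that the synthetic fiducial
#' carries in its top-left quadrant.  Real QR symbol decoding is out of
#' scope; a backend may supply externally decoded corners via
#' [marker_detection()].
#'
#' @param image RGB array
#' @param side_cm physical marker side length (cm)
#' @param min_area_px minimum candidate component area
#' @param dark_threshold grayscale threshold below which pixels count as
#'   marker ink
#' @return a [marker_detection()]
#' @export
detect_marker <- function(image, side_cm = 4.7, min_area_px = 200,
                          dark_threshold = 0.5) {
  gray <- to_gray(image)
  # marker ink is achromatic; a chroma screen keeps dark *colored* plant
  # parts from being proposed as marker candidates
  chroma <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
            pmin(image[, , 1], image[, , 2], image[, , 3])
  dark <- gray < dark_threshold & chroma < 0.15
  if (!any(dark) || all(dark)) err_marker_not_found("image has no dark/light contrast")
  lab <- label_components(dark)
  ncomp <- max(lab)
  cands <- list()
  for (k in seq_len(ncomp)) {
    m <- lab == k
    npix <- sum(m)
    if (npix < min_area_px) next
    q <- fit_quad(m, npix, gray)
    if (!is.null(q)) cands[[length(cands) + 1L]] <- q
  }
  if (length(cands) == 0L) err_marker_not_found()
  if (length(cands) > 1L) err_ambiguous_marker(length(cands))
  corners <- cands[[1]]
  corners <- orient_corners(corners, gray, dark_threshold, side_cm)
  marker_detection(corners, side_cm = side_cm)
}

# Fit a convex quadrilateral to one component; returns 4x2 corners in
# positive cyclic order, or NULL if the component fails the screens.
fit_quad <- function(mask, npix, gray) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  cx <- mean(x); cy <- mean(y)
  # farthest-point heuristic for initial corners
  d2 <- (hx - cx)^2 + (hy - cy)^2
  i1 <- which.max(d2)
  d2 <- (hx - hx[i1])^2 + (hy - hy[i1])^2
  i2 <- which.max(d2)
  # signed distance from line i1-i2
  ex <- hx[i2] - hx[i1]; ey <- hy[i2] - hy[i1]
  sd <- (hx - hx[i1]) * ey - (hy - hy[i1]) * ex
  i3 <- which.max(sd); i4 <- which.min(sd)
  if (sd[i3] <= 0 || sd[i4] >= 0) return(NULL)
  P <- cbind(hx[c(i1, i2, i3, i4)], hy[c(i1, i2, i3, i4)])
  ang <- atan2(P[, 2] - mean(P[, 2]), P[, 1] - mean(P[, 1]))
  P <- P[order(ang), , drop = FALSE]
  if (!is_convex_quad(P)) return(NULL)
  qa <- abs(polygon_area(P))
  if (qa <= 0) return(NULL)
  # solidity screen: marker is a filled square (minus a small cue hole)
  if (npix / qa < 0.70 || npix / qa > 1.08) return(NULL)
  sides <- sqrt(rowSums((P[c(2, 3, 4, 1), ] - P)^2))
  if (min(sides) < 8) return(NULL)
  if (max(sides) / min(sides) > 4) return(NULL)
  refine_quad(gray, P)
}

# Sub-pixel refinement: per edge, sample the mid-level gray crossing of the
# anti-aliased edge profile on scanlines, fit a total-least-squares line to
# the crossing points, then corner = adjacent edge intersection.
refine_quad <- function(gray, P) {
  h <- nrow(gray); w <- ncol(gray)
  cen <- colMeans(P)
  lines <- vector("list", 4)
  for (e in 1:4) {
    a <- P[e, ]; b <- P[e %% 4 + 1, ]
    ab <- b - a; len <- sqrt(sum(ab^2)); u <- ab / len
    nrm <- c(-u[2], u[1])
    if (sum(nrm * (cen - a)) > 0) nrm <- -nrm       # orient outward
    ts <- seq(0.15 * len, 0.85 * len, by = max(1, len / 60))
    xscan <- abs(nrm[1]) >= abs(nrm[2])
    pts <- matrix(NA_real_, length(ts), 2)
    for (i in seq_along(ts)) {
      p <- a + ts[i] * u
      if (xscan) {
        r <- round(p[2]) + 1L
        c0 <- round(p[1]) + 1L
        if (r < 1 || r > h) next
        rng <- max(1, c0 - 3):min(w, c0 + 3)
        if (nrm[1] > 0) rng <- rev(rng)      # order: outside -> inside
        prof <- gray[r, rng]
        cx <- profile_crossing(prof)
        if (!is.na(cx))
          pts[i, ] <- c(rng[1] - 1 + (rng[2] - rng[1]) * cx, r - 1)
      } else {
        c0 <- round(p[1]) + 1L
        r0 <- round(p[2]) + 1L
        if (c0 < 1 || c0 > w) next
        rng <- max(1, r0 - 3):min(h, r0 + 3)
        if (nrm[2] > 0) rng <- rev(rng)
        prof <- gray[rng, c0]
        cx <- profile_crossing(prof)
        if (!is.na(cx))
          pts[i, ] <- c(c0 - 1, rng[1] - 1 + (rng[2] - rng[1]) * cx)
      }
    }
    pts <- pts[is.finite(pts[, 1]), , drop = FALSE]
    if (nrow(pts) < 5) { lines[[e]] <- list(p = a, u = u); next }
    ev <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
    if (sum(ev * u) < 0) ev <- -ev
    lines[[e]] <- list(p = colMeans(pts), u = ev)
  }
  Q <- matrix(0, 4, 2)
  for (e in 1:4) {
    l1 <- lines[[(e + 2) %% 4 + 1]]   # edge before vertex P[e,]
    l2 <- lines[[e]]                  # edge after
    Q[e, ] <- intersect_lines(l1, l2)
    if (any(!is.finite(Q[e, ]))) Q[e, ] <- P[e, ]
  }
  if (!is_convex_quad(Q)) return(P)
  Q
}

# sub-pixel edge position (in steps, 0-based) along an outside->inside
# profile, by the coverage-moment method: with box-filtered (anti-aliased)
# sampling of a straight edge, the summed ink fraction equals the covered
# length, so the edge sits at n - 1/2 - sum(alpha).  Exact for ideal
# edges regardless of the edge blur width; NA when contrast is too low or
# the profile is not a single bright-to-dark transition.
profile_crossing <- function(prof) {
  n <- length(prof)
  lo <- min(prof); hi <- max(prof)
  if (hi - lo < 0.2) return(NA_real_)
  if (prof[1] != hi || prof[n] != lo) return(NA_real_)
  alpha <- (hi - prof) / (hi - lo)
  if (is.unsorted(alpha, strictly = FALSE)) return(NA_real_)
  pos <- n - 0.5 - sum(alpha)
  if (pos < 0.5 || pos > n - 1.5) return(NA_real_)
  pos
}

intersect_lines <- function(l1, l2) {
  A <- rbind(c(l1$u[1], -l2$u[1]), c(l1$u[2], -l2$u[2]))
  dt <- det(A)
  if (abs(dt) < 1e-9) return(c(NA, NA))
  t <- solve(A, l2$p - l1$p)
  l1$p + t[1] * l1$u
}

# Resolve cyclic shift using the light cue hole in the marker's top-left
# quadrant; corners arrive in consistent cyclic order (camera preserves
# orientation), only the starting corner is unknown.
orient_corners <- function(corners, gray, dark_threshold, side_cm) {
  ang <- atan2(corners[, 2] - mean(corners[, 2]),
               corners[, 1] - mean(corners[, 1]))
  corners <- corners[order(ang), , drop = FALSE]
  if (polygon_area(corners) < 0) corners <- corners[4:1, , drop = FALSE]
  # light pixels strictly inside the quad
  xr <- range(corners[, 1]); yr <- range(corners[, 2])
  cset <- max(1, floor(xr[1] + 1)):min(ncol(gray), ceiling(xr[2] + 1))
  rset <- max(1, floor(yr[1] + 1)):min(nrow(gray), ceiling(yr[2] + 1))
  sub <- gray[rset, cset, drop = FALSE]
  gx <- rep(cset - 1, each = length(rset))
  gy <- rep(rset - 1, times = length(cset))
  inside <- rep(TRUE, length(gx))
  for (e in 1:4) {
    a <- corners[e, ]; b <- corners[e %% 4 + 1, ]
    inside <- inside &
      ((b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])) > 0
  }
  hole <- inside & as.vector(sub) >= dark_threshold
  if (!any(hole))
    err_marker_not_found("marker candidate lacks an orientation cue")
  hc <- c(mean(gx[hole]), mean(gy[hole]))
  target <- c(0.25, 0.25) * side_cm
  best <- NULL; bestd <- Inf
  for (shift in 0:3) {
    idx <- ((0:3 + shift) %% 4) + 1
    cand <- corners[idx, , drop = FALSE]
    Hm <- try(solve_homography(cand, rbind(c(0, 0), c(side_cm, 0),
                                           c(side_cm, side_cm), c(0, side_cm))),
              silent = TRUE)
    if (inherits(Hm, "try-error")) next
    p <- apply_homography(Hm, hc)
    d <- sqrt(sum((p - target)^2))
    if (d < bestd) { bestd <- d; best <- cand }
  }
  if (is.null(best) || bestd > 0.2 * side_cm)
    err_marker_not_found("orientation cue position inconsistent with a marker")
  best
}
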