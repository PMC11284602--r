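# Independent oracles used across test files.

# Exact 1-D k-means by dynamic programming over sorted values (O(k n^2)).
# Returns cluster assignments in input order, relabelled 1 = largest mean,
# matching the kmeans_clusters() labelling contract.
dp_kmeans_1d <- function(values, k) {
  n <- length(values)
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) { # cost of x[i..j] as one cluster
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- D[m - 1, i - 1] + sse(i, j)
      if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- i }
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (m in k:2) { i <- B[m, j]; bounds[m] <- i - 1L; j <- i - 1L }
  bounds[1] <- 0L
  lab_sorted <- integer(n)
  means <- numeric(k)
  for (m in 1:k) {
    idx <- (bounds[m] + 1):bounds[m + 1]
    lab_sorted[idx] <- m
    means[m] <- mean(x[idx])
  }
  relab <- match(seq_len(k), order(means, decreasing = TRUE))
  out <- integer(n)
  out[ord] <- relab[lab_sorted]
  out
}

# Analytic anti-aliased rendering of an axis-aligned dark square marker
# (with the light orientation-cue hole) on a light background: coverage is
# the exact box/pixel overlap, so edge positions are exact by construction.
render_axis_marker <- function(width, height, x0, y0, side,
                               bg = 0.92, ink = 0.05) {
  overlap1d <- function(centers, a, b)
    pmin(centers + 0.5, b) - pmax(centers - 0.5, a)
  xs <- 0:(width - 1); ys <- 0:(height - 1)
  covx <- pmax(0, overlap1d(xs, x0, x0 + side))
  covy <- pmax(0, overlap1d(ys, y0, y0 + side))
  cov <- outer(covy, covx)
  hole_half <- 0.10 * side
  hx <- x0 + 0.25 * side; hy <- y0 + 0.25 * side
  hcovx <- pmax(0, overlap1d(xs, hx - hole_half, hx + hole_half))
  hcovy <- pmax(0, overlap1d(ys, hy - hole_half, hy + hole_half))
  cov <- cov - outer(hcovy, hcovx)
  g <- bg * (1 - cov) + ink * cov
  array(rep(g, 3), dim = c(height, width, 3))
}

# plane_homography for a plain scale: s_cm_per_px cm per pixel, no tilt
scale_homography <- function(s_cm_per_px, side_cm = 4.7) {
  px <- side_cm / s_cm_per_px
  estimate_homography(marker_detection(
    rbind(c(0, 0), c(px, 0), c(px, px), c(0, px)), side_cm = side_cm))
}

# random convex, non-degenerate marker corner set: the projective image of
# the physical square under a random bounded homography
random_corner_set <- function() {
  repeat {
    s <- 4.7
    base <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
    H <- diag(3) + matrix(stats::runif(9, -0.05, 0.05), 3, 3)
    H[1:2, 3] <- stats::runif(2, 20, 200)
    H[1:2, 1:2] <- H[1:2, 1:2] * stats::runif(1, 5, 40)
    P <- t(H %*% rbind(t(base), 1))
    if (any(abs(P[, 3]) < 1e-3)) next
    P <- P[, 1:2] / P[, 3]
    ok <- tryCatch({ marker_detection(P, s); TRUE }, error = function(e) FALSE)
    if (ok) return(P)
  }
}

measure_one <- function(image, trait, backend, ...) {
  m <- measure_image(image, trait, backend, ...)
  expect_length(m, 1)
  m[[1]]$value
}
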