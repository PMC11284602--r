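#' Trait extraction
#'
#' Converts detections and masks plus the marker calibration into the six
#' phenotypic traits, in their conventional reporting units: crown diameter
#' (CD, mm), plant height (PH, cm), petiole length (PL, cm), leaf area /
#' length / width (LA cm^2, LL cm, LW cm), flower area (FlA, cm^2) and
#' fruit area (FrA, cm^2).
#'
#' Box-based traits (CD, PH, PL) map box landmarks through the homography;
#' area traits rectify the segmentation mask onto the metric plane and
#' count grid cells.  All math goes through the full homography, never the
#' scalar scale.
#'
#' @name traits
NULL

trait_units <- c(CD = "mm", PH = "cm", PL = "cm", LA = "cm2", LL = "cm",
                 LW = "cm", FlA = "cm2", FrA = "cm2")

#' Construct a trait measurement record
#' @param trait one of `names(trait_units)`: CD, PH, PL, LA, LL, LW, FlA, FrA
#' @param value nonnegative scalar in the trait's fixed unit
#' @param image_id,backend_id,confidence,scale_cm_per_px provenance
#' @export
trait_measurement <- function(trait, value, image_id = NA_character_,
                              backend_id = NA_character_, confidence = NA_real_,
                              scale_cm_per_px = NA_real_) {
  stopifnot(trait %in% names(trait_units), is.finite(value), value >= 0)
  structure(list(trait = trait, value = value, units = trait_units[[trait]],
                 image_id = image_id, backend_id = backend_id,
                 confidence = confidence, scale_cm_per_px = scale_cm_per_px),
            class = "trait_measurement")
}

#' Collect trait measurements into a data frame
#' @param measurements list of [trait_measurement()]
#' @return data.frame with the stable results-CSV column order
#' @export
measurements_to_df <- function(measurements) {
  cols <- c("image_id", "trait", "value", "units", "confidence", "backend",
            "scale_cm_per_px")
  if (!length(measurements)) {
    df <- data.frame(image_id = character(0), trait = character(0),
                     value = numeric(0), units = character(0),
                     confidence = numeric(0), backend = character(0),
                     scale_cm_per_px = numeric(0))
    return(df[, cols])
  }
  do.call(rbind, lapply(measurements, function(m)
    data.frame(image_id = m$image_id, trait = m$trait, value = m$value,
               units = m$units, confidence = m$confidence,
               backend = m$backend_id, scale_cm_per_px = m$scale_cm_per_px)))
}

box_edge_midpoints <- function(box) {
  ym <- (box[["y0"]] + box[["y1"]]) / 2
  rbind(c(box[["x0"]], ym), c(box[["x1"]], ym))
}

box_center <- function(box) {
  c((box[["x0"]] + box[["x1"]]) / 2, (box[["y0"]] + box[["y1"]]) / 2)
}

#' Crown diameter from a crown detection (mm)
#'
#' The crown is annotated as a box enclosing its thickest part, and the
#' diameter is its rectified left-edge-to-right-edge width: the midpoints
#' of the box's left and right edges are mapped through the homography and
#' the width is their separation along the rectified horizontal axis.  The
#' width *component* (rather than the Euclidean chord) is used because
#' under residual camera tilt the two midpoints land at slightly different
#' rectified heights, and including that offset would bias the diameter
#' upward second-order in the tilt.
#'
#' @param crown an [spt_detection()] labelled `crown`
#' @param H a `plane_homography`
#' @param ... provenance fields passed to [trait_measurement()]
#' @export
crown_diameter <- function(crown, H, ...) {
  if (crown$label != "crown") err_label_mismatch("crown", crown$label)
  p <- to_metric(box_edge_midpoints(crown$box), H)
  trait_measurement("CD", 10 * abs(p[2, 1] - p[1, 1]),
                    confidence = crown$confidence,
                    scale_cm_per_px = H$scale_cm_per_px, ...)
}

#' Metric distance between the centers of two endpoint boxes (cm)
#'
#' Shared kernel for plant height and petiole length: both are annotated
#' with one box at each extremity, and the trait is the plane distance
#' between the box centers.
#'
#' @param bottom,top [spt_detection()]s marking the two endpoints
#' @param H a `plane_homography`
#' @return distance in cm (plain numeric)
#' @export
endpoint_distance <- function(bottom, top, H) {
  p <- to_metric(rbind(box_center(bottom$box), box_center(top$box)), H)
  sqrt(sum((p[2, ] - p[1, ])^2))
}

#' Plant height (cm): crown-to-topmost-leaf box distance
#' @inheritParams crown_diameter
#' @param bottom detection labelled `plant_bottom`
#' @param top detection labelled `plant_top`
#' @export
plant_height <- function(bottom, top, H, ...) {
  if (bottom$label != "plant_bottom") err_label_mismatch("plant_bottom", bottom$label)
  if (top$label != "plant_top") err_label_mismatch("plant_top", top$label)
  trait_measurement("PH", endpoint_distance(bottom, top, H),
                    confidence = min(bottom$confidence, top$confidence),
                    scale_cm_per_px = H$scale_cm_per_px, ...)
}

#' Petiole length (cm): crown-attachment to leaflet-junction distance
#' @inheritParams plant_height
#' @param bottom detection labelled `petiole_bottom`
#' @param top detection labelled `petiole_top`
#' @export
petiole_length <- function(bottom, top, H, ...) {
  if (bottom$label != "petiole_bottom")
    err_label_mismatch("petiole_bottom", bottom$label)
  if (top$label != "petiole_top") err_label_mismatch("petiole_top", top$label)
  trait_measurement("PL", endpoint_distance(bottom, top, H),
                    confidence = min(bottom$confidence, top$confidence),
                    scale_cm_per_px = H$scale_cm_per_px, ...)
}

# Default rectification grid: half the marker-derived scale, clamped.
# Half because nearest-neighbor resampling at the native scale leaves a
# grid-phase area bias above 1% for the smallest parts (flower-sized),
# which halving the spacing removes; see the methods vignette.
default_resolution <- function(H) min(max(H$scale_cm_per_px / 2, 0.005), 0.2)

#' Leaf area, length and width from a leaf mask
#'
#' The mask is rectified onto the metric plane; LA is the foreground cell
#' count times the cell area, LL is the foreground extent along the
#' principal (largest-variance) axis and LW the extent along the
#' perpendicular axis, with `LL >= LW` enforced by ordering.  Principal-axis
#' extents (rather than maximum Feret diameters) are cheaper, stable, and
#' identical for the elliptical leaves the generator draws.
#'
#' @param mask an [spt_mask()] (or full-frame logical matrix)
#' @param H a `plane_homography`
#' @param resolution_cm_per_px rectification grid spacing; defaults to half
#'   the marker-derived scale (clamped to `[0.005, 0.2]` cm/px) — extents
#'   are extreme-value statistics and need a finer grid than areas do
#' @param ... provenance fields
#' @return named list of three [trait_measurement()]s: `LA`, `LL`, `LW`
#' @export
leaf_metrics <- function(mask, H, resolution_cm_per_px = NULL, ...) {
  if (is.null(resolution_cm_per_px)) resolution_cm_per_px <- default_resolution(H)
  r <- rectify_mask(mask, H, resolution_cm_per_px)
  if (!any(r$bitmap)) err_empty_mask()
  res <- r$res_cm
  la <- sum(r$bitmap) * r$cell_area_cm2
  idx <- which(r$bitmap, arr.ind = TRUE)
  xy <- cbind(r$origin_cm[1] + (idx[, 2] - 1) * res,
              r$origin_cm[2] + (idx[, 1] - 1) * res)
  if (nrow(xy) > 1) {
    ev <- eigen(cov(xy), symmetric = TRUE)$vectors
  } else ev <- diag(2)
  pr1 <- xy %*% ev[, 1]; pr2 <- xy %*% ev[, 2]
  ext <- sort(c(diff(range(pr1)), diff(range(pr2))) + res, decreasing = TRUE)
  list(LA = trait_measurement("LA", la, scale_cm_per_px = H$scale_cm_per_px, ...),
       LL = trait_measurement("LL", ext[1], scale_cm_per_px = H$scale_cm_per_px, ...),
       LW = trait_measurement("LW", ext[2], scale_cm_per_px = H$scale_cm_per_px, ...))
}

#' Flower or fruit area from a mask (cm^2)
#' @inheritParams leaf_metrics
#' @param trait `"FlA"` or `"FrA"`
#' @export
region_area <- function(mask, H, trait = c("FlA", "FrA"),
                        resolution_cm_per_px = NULL, ...) {
  trait <- match.arg(trait)
  if (is.null(resolution_cm_per_px)) resolution_cm_per_px <- default_resolution(H)
  r <- rectify_mask(mask, H, resolution_cm_per_px)
  if (!any(r$bitmap)) err_empty_mask()
  trait_measurement(trait, sum(r$bitmap) * r$cell_area_cm2,
                    scale_cm_per_px = H$scale_cm_per_px, ...)
}

trait_labels_needed <- function(trait) {
  switch(trait,
         CD = "crown",
         PH = c("plant_bottom", "plant_top"),
         PL = c("petiole_bottom", "petiole_top"),
         LA = , LL = , LW = "leaf",
         FlA = "flower",
         FrA = "fruit")
}

#' Measure one trait on one image
#'
#' Full pipeline orchestration: locate the marker, build the calibration,
#' run the backend's detector (and segmenter for area traits) and extract
#' the trait.  Single-valued traits (CD, PH, PL) use the highest-confidence
#' detection of each required part; per-instance traits (LA/LL/LW, FlA,
#' FrA) yield one measurement per detected instance.  An image in which the
#' required parts are not detected yields an empty list, not an error —
#' that absence is exactly what the detection-frequency statistic counts.
#'
#' @param image RGB array containing a fiducial marker
#' @param trait one of CD, PH, PL, LA, LL, LW, FlA, FrA
#' @param backend a backend object (see [backends])
#' @param side_cm marker side length
#' @param image_id provenance id recorded on each measurement
#' @param marker optional externally supplied [marker_detection()] (skips
#'   image-based marker search)
#' @param resolution_cm_per_px optional rectification grid override
#' @return list of [trait_measurement()]s (possibly empty)
#' @export
measure_image <- function(image, trait, backend, side_cm = 4.7,
                          image_id = "image", marker = NULL,
                          resolution_cm_per_px = NULL) {
  stopifnot(trait %in% names(trait_units))
  if (is.null(marker)) marker <- detect_marker(image, side_cm = side_cm)
  H <- estimate_homography(marker)
  need <- trait_labels_needed(trait)
  dets <- detect(backend, image, need)
  by_label <- split(dets, vapply(dets, `[[`, "", "label"))
  if (!all(need %in% names(by_label))) return(list())
  bid <- backend$id %||% class(backend)[1]
  prov <- list(image_id = image_id, backend_id = bid)
  top1 <- function(lab) by_label[[lab]][[1]]   # detect() sorts by confidence
  if (trait == "CD") {
    return(list(crown_diameter(top1("crown"), H, image_id = image_id,
                               backend_id = bid)))
  }
  if (trait %in% c("PH", "PL")) {
    fn <- if (trait == "PH") plant_height else petiole_length
    return(list(fn(top1(need[1]), top1(need[2]), H, image_id = image_id,
                   backend_id = bid)))
  }
  # per-instance mask traits
  out <- list()
  for (d in by_label[[need]]) {
    m <- segment(backend, image, d)
    if (!any(m$bitmap)) next
    if (trait %in% c("LA", "LL", "LW")) {
      lm <- leaf_metrics(m, H, resolution_cm_per_px,
                         image_id = image_id, backend_id = bid)
      mm <- lm[[trait]]
      mm$confidence <- d$confidence
      out[[length(out) + 1L]] <- mm
    } else {
      mm <- region_area(m, H, trait, resolution_cm_per_px,
                        image_id = image_id, backend_id = bid)
      mm$confidence <- d$confidence
      out[[length(out) + 1L]] <- mm
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
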