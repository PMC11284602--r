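#' Pluggable detection/segmentation backends
#'
#' The measurement pipeline is agnostic to where detections and masks come
#' from.  In production the stages would be a trained object detector and a
#' semantic segmentation network; here the same contract is served by two
#' desk-scale backends:
#'
#' * the **oracle** backend replays the synthetic generator's ground truth
#'   verbatim (confidence 1), isolating the geometry pipeline from detector
#'   error;
#' * the **classical** backend finds the color-coded proxy parts by RGB
#'   thresholding and connected components, exercising the pipeline with a
#'   realistic, imperfect detector.
#'
#' A learned-model backend can be added behind the same two generics
#' without touching the trait code.
#'
#' @name backends
NULL

#' Construct a detection
#' @param label part class from the closed vocabulary ([part_labels()])
#' @param box half-open pixel box `c(x0, y0, x1, y1)` in 0-based
#'   pixel-center coordinates
#' @param confidence detection confidence in `[0, 1]`
#' @export
spt_detection <- function(label, box, confidence = 1) {
  stopifnot(label %in% part_labels(),
            length(box) == 4, confidence >= 0, confidence <= 1)
  box <- as.numeric(box)
  names(box) <- c("x0", "y0", "x1", "y1")
  if (!(box["x1"] > box["x0"] && box["y1"] > box["y0"]))
    stop("detection box must have positive area")
  structure(list(label = label, box = box, confidence = confidence),
            class = "spt_detection")
}

#' Construct a segmentation mask registered to a box crop
#' @param box the half-open pixel box the bitmap is registered to
#' @param bitmap logical matrix whose dimensions equal the box dimensions
#' @export
spt_mask <- function(box, bitmap) {
  box <- as.numeric(box)
  names(box) <- c("x0", "y0", "x1", "y1")
  stopifnot(is.matrix(bitmap))
  if (nrow(bitmap) != round(box["y1"] - box["y0"]) ||
      ncol(bitmap) != round(box["x1"] - box["x0"]))
    stop("bitmap dimensions must equal box dimensions")
  structure(list(box = box, bitmap = bitmap), class = "spt_mask")
}

#' Detect parts in an image
#' @param backend a backend object
#' @param image RGB array
#' @param wanted_labels character vector of labels to look for
#' @return list of [spt_detection()], sorted by descending confidence;
#'   absence of a label simply yields no entry (no error), which feeds the
#'   detection-frequency statistic
#' @export
detect <- function(backend, image, wanted_labels) UseMethod("detect")

#' Segment one detection into a binary mask
#' @inheritParams detect
#' @param detection an [spt_detection()] lying within the image bounds
#' @return an [spt_mask()] over the detection crop
#' @export
segment <- function(backend, image, detection) UseMethod("segment")

check_box_in_image <- function(box, image) {
  h <- img_height(image); w <- img_width(image)
  if (box["x0"] < -0.5 || box["y0"] < -0.5 ||
      box["x1"] > w - 0.5 || box["y1"] > h - 0.5)
    err_box_out_of_bounds(box, dim(image))
}

# -- oracle ------------------------------------------------------------------

#' Oracle backend: replays generator ground truth
#' @param gt a `scene_ground_truth` from [render_scene()]
#' @export
oracle_backend <- function(gt) {
  stopifnot(inherits(gt, "scene_ground_truth"))
  structure(list(gt = gt, id = "oracle"), class = c("oracle_backend", "spt_backend"))
}

#' @export
detect.oracle_backend <- function(backend, image, wanted_labels) {
  parts <- backend$gt$parts
  out <- list()
  for (p in parts) {
    if (p$label %in% wanted_labels)
      out[[length(out) + 1L]] <- spt_detection(p$label, p$box, 1.0)
  }
  if ("marker" %in% wanted_labels) {
    mc <- backend$gt$marker_corners
    out[[length(out) + 1L]] <- spt_detection("marker",
      c(min(mc[, 1]), min(mc[, 2]), max(mc[, 1]), max(mc[, 2])), 1.0)
  }
  out
}

#' @export
segment.oracle_backend <- function(backend, image, detection) {
  check_box_in_image(detection$box, image)
  # return the stored ground-truth mask whose exact box best matches
  cand <- Filter(function(p) p$label == detection$label, backend$gt$parts)
  if (!length(cand)) err_empty_mask()
  ctr <- c(mean(detection$box[c(1, 3)]), mean(detection$box[c(2, 4)]))
  d <- vapply(cand, function(p)
    sum((c(mean(p$box[c(1, 3)]), mean(p$box[c(2, 4)])) - ctr)^2), numeric(1))
  p <- cand[[which.min(d)]]
  if (!is.null(p$mask)) return(p$mask)
  rasterize_gt_mask(p, backend$gt$H)
}

# re-rasterise a ground-truth mask from its shape parameters (used when the
# ground truth was restored from a JSON sidecar, which stores no bitmaps)
rasterize_gt_mask <- function(p, H) {
  b <- p$box
  cset <- floor(b[["x0"]] + 0.5):ceiling(b[["x1"]] + 0.5)
  rset <- floor(b[["y0"]] + 0.5):ceiling(b[["y1"]] + 0.5)
  g <- plane_grid(solve(H), cset, rset)
  part <- list(label = p$label, shape = p$shape, center = p$center_cm,
               semi = p$semi_cm, angle = p$angle %||% 0)
  m <- part_membership(part, g$X, g$Y)
  crop_box <- c(cset[1] - 0.5, rset[1] - 0.5,
                cset[length(cset)] + 0.5, rset[length(rset)] + 0.5)
  spt_mask(crop_box, m)
}

# -- classical ---------------------------------------------------------------

#' Classical backend: color thresholding + connected components
#' @param palette named list label -> RGB reference color; defaults to the
#'   generator palette ([trait_palette()])
#' @param tol maximum Euclidean RGB distance counted as a color match
#' @param min_area_px minimum component size kept as a detection
#' @export
classical_backend <- function(palette = trait_palette(), tol = 0.22,
                              min_area_px = 12) {
  structure(list(palette = palette, tol = tol, min_area_px = min_area_px,
                 id = "classical"),
            class = c("classical_backend", "spt_backend"))
}

color_distance <- function(image, color) {
  sqrt((image[, , 1] - color[1])^2 + (image[, , 2] - color[2])^2 +
       (image[, , 3] - color[3])^2)
}

#' @export
detect.classical_backend <- function(backend, image, wanted_labels) {
  out <- list()
  for (lab in wanted_labels) {
    if (is.null(backend$palette[[lab]])) next
    d <- color_distance(image, backend$palette[[lab]])
    m <- d < backend$tol
    if (!any(m)) next
    comp <- label_components(m)
    for (k in seq_len(max(comp))) {
      ck <- comp == k
      n <- sum(ck)
      if (n < backend$min_area_px) next
      bb <- mask_bbox(ck)
      conf <- max(0, min(1, 1 - mean(d[ck]) / backend$tol))
      out[[length(out) + 1L]] <- spt_detection(lab, bb, conf)
    }
  }
  conf <- vapply(out, `[[`, numeric(1), "confidence")
  out[order(-conf)]
}

#' @export
segment.classical_backend <- function(backend, image, detection) {
  check_box_in_image(detection$box, image)
  b <- detection$box
  cset <- (round(b["x0"] + 0.5):round(b["x1"] - 0.5)) + 1L  # matrix cols
  rset <- (round(b["y0"] + 0.5):round(b["y1"] - 0.5)) + 1L
  crop <- image[rset, cset, , drop = FALSE]
  color <- backend$palette[[detection$label]]
  if (is.null(color)) err_empty_mask()
  m <- color_distance(crop, color) < backend$tol
  crop_box <- c(cset[1] - 1.5, rset[1] - 1.5,
                cset[length(cset)] - 0.5, rset[length(rset)] - 0.5)
  spt_mask(crop_box, m)
}

#' Resolve a backend by name
#' @param name `"oracle"` or `"classical"`
#' @param gt ground truth, required for the oracle backend
#' @param ... passed to the backend constructor
#' @export
get_backend <- function(name = c("classical", "oracle"), gt = NULL, ...) {
  name <- match.arg(name)
  if (name == "oracle") {
    if (is.null(gt)) stop("oracle backend requires ground truth")
    oracle_backend(gt)
  } else classical_backend(...)
}
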