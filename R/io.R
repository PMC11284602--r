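#' Annotation readers, results writers and sidecar files
#'
#' Two VGG Image Annotator dialects are supported: the v1.0.5 CSV export
#' (single-target, unlabeled regions; JSON fragments inside CSV cells) and
#' the v2.x JSON project export (multi-target, labeled regions).
#' Measurement results go to a stable-column CSV; calibrations and weight
#' models are persisted as small JSON sidecars.
#'
#' @name io
NULL

#' Construct an annotation record
#'
#' @param image_id source image identifier (filename)
#' @param shape_type `"box"` or `"polygon"`
#' @param box `c(x, y, w, h)` for boxes (VIA convention: top-left corner
#'   plus size, pixels)
#' @param vertices n x 2 matrix for polygons (`n >= 3`)
#' @param label class name; mandatory for the v2 dialect, forbidden for v1
#' @param source_dialect `"v1_csv"` or `"v2_json"`
#' @export
annotation_record <- function(image_id, shape_type, box = NULL,
                              vertices = NULL, label = NA_character_,
                              source_dialect = c("v2_json", "v1_csv")) {
  source_dialect <- match.arg(source_dialect)
  shape_type <- match.arg(shape_type, c("box", "polygon"))
  if (shape_type == "box") {
    stopifnot(length(box) == 4)
    if (!(box[3] > 0 && box[4] > 0)) stop("box must have positive width and height")
  } else {
    stopifnot(is.matrix(vertices), ncol(vertices) == 2)
    if (nrow(vertices) < 3) stop("polygon needs at least 3 vertices")
  }
  if (source_dialect == "v2_json" && (is.na(label) || !nzchar(label)))
    err_missing_label(image_id)
  if (source_dialect == "v1_csv") label <- NA_character_
  structure(list(image_id = image_id, shape_type = shape_type,
                 box = if (!is.null(box)) as.numeric(box),
                 vertices = vertices, label = label,
                 source_dialect = source_dialect),
            class = "annotation_record")
}

parse_shape_attributes <- function(sa, row, dialect, image_id, label = NA) {
  nm <- sa$name
  if (is.null(nm)) err_malformed_row(row, "missing shape name")
  if (nm == "rect") {
    b <- c(sa$x, sa$y, sa$width, sa$height)
    if (length(b) != 4 || any(!is.finite(unlist(b))))
      err_malformed_row(row, "rect needs x, y, width, height")
    if (sa$width <= 0 || sa$height <= 0)
      err_malformed_row(row, "rect width/height must be positive")
    annotation_record(image_id, "box", box = unlist(b), label = label,
                      source_dialect = dialect)
  } else if (nm == "polygon") {
    px <- unlist(sa$all_points_x); py <- unlist(sa$all_points_y)
    if (length(px) != length(py) || length(px) < 3)
      err_malformed_row(row, "polygon needs >= 3 vertices")
    annotation_record(image_id, "polygon", vertices = cbind(px, py),
                      label = label, source_dialect = dialect)
  } else err_malformed_row(row, paste0("unsupported shape '", nm, "'"))
}

#' Read a VIA 1.0.5 CSV export (single-target, unlabeled dialect)
#'
#' Region geometry lives in JSON fragments inside the
#' `region_shape_attributes` column.  Rows whose fragment cannot be parsed
#' or describes an invalid shape raise a `spt_malformed_row` condition
#' carrying the row number; rows with an empty region set (`"{}"`) are
#' skipped.
#'
#' @param path CSV file path
#' @return list of [annotation_record()]s (all with `label = NA`)
#' @export
read_via_v1_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  names(df) <- sub("^#", "", names(df))
  need <- c("filename", "region_shape_attributes")
  if (!all(need %in% names(df)))
    stop("not a VIA v1 CSV: missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    cell <- df$region_shape_attributes[i]
    if (!nzchar(cell) || cell == "{}") next
    sa <- tryCatch(jsonlite::fromJSON(cell),
                   error = function(e) err_malformed_row(i, "invalid JSON fragment"))
    out[[length(out) + 1L]] <-
      parse_shape_attributes(sa, i, "v1_csv", df$filename[i])
  }
  out
}

#' Read a VIA 2.x JSON project export (multi-target, labeled dialect)
#'
#' Accepts either a full project file (with `_via_img_metadata`) or the
#' bare image-metadata map.  Every region must carry a class label in its
#' `region_attributes` (`spt_missing_label` otherwise).
#'
#' @param path JSON file path
#' @return list of [annotation_record()]s
#' @export
read_via_v2_json <- function(path) {
  stopifnot(file.exists(path))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) err_malformed_json(conditionMessage(e)))
  meta <- if (!is.null(doc[["_via_img_metadata"]])) doc[["_via_img_metadata"]] else doc
  if (!is.list(meta) || !length(meta)) err_malformed_json("no image metadata found")
  out <- list()
  row <- 0L
  for (entry in meta) {
    if (!is.list(entry) || is.null(entry$filename)) err_malformed_json("image entry lacks a filename")
    for (rg in entry$regions) {
      row <- row + 1L
      ra <- rg$region_attributes
      label <- NA_character_
      if (is.list(ra) && length(ra)) {
        cand <- if (!is.null(ra$label)) ra$label else ra[[1]]
        if (is.character(cand) && nzchar(cand)) label <- cand
      }
      if (is.na(label)) err_missing_label(entry$filename)
      out[[length(out) + 1L]] <-
        parse_shape_attributes(rg$shape_attributes, row, "v2_json",
                               entry$filename, label = label)
    }
  }
  out
}

#' Write annotation records as a VIA 2.x JSON project
#' @param records list of [annotation_record()]s (labels required)
#' @param path destination JSON path
#' @export
write_via_v2_json <- function(records, path) {
  by_img <- split(records, vapply(records, `[[`, "", "image_id"))
  meta <- lapply(names(by_img), function(id) {
    regions <- lapply(by_img[[id]], function(r) {
      sa <- if (r$shape_type == "box") {
        list(name = "rect", x = r$box[1], y = r$box[2],
             width = r$box[3], height = r$box[4])
      } else {
        list(name = "polygon",
             all_points_x = r$vertices[, 1], all_points_y = r$vertices[, 2])
      }
      list(shape_attributes = sa,
           region_attributes = list(label = r$label))
    })
    list(filename = id, size = -1, regions = regions,
         file_attributes = structure(list(), names = character(0)))
  })
  names(meta) <- paste0(names(by_img), "-1")
  jsonlite::write_json(list(`_via_img_metadata` = meta), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ground-truth scene to labeled annotation records
#'
#' Box-measured parts become `rect` regions; mask-measured parts (leaf,
#' flower, fruit) become polygons sampled on the projected shape outline,
#' matching the annotation scheme of the v2 dialect.
#'
#' @param gt a `scene_ground_truth`
#' @param image_id filename to record
#' @param n_vertices polygon vertex count for curved outlines
#' @export
gt_to_annotations <- function(gt, image_id = "scene.png", n_vertices = 24) {
  recs <- list()
  for (p in gt$parts) {
    if (p$label %in% c("leaf", "flower", "fruit")) {
      th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
      plane <- cbind(p$center_cm[1] + p$semi_cm[1] * cos(th),
                     p$center_cm[2] + p$semi_cm[2] * sin(th))
      v <- apply_homography(gt$H, plane)
      recs[[length(recs) + 1L]] <-
        annotation_record(image_id, "polygon", vertices = v, label = p$label)
    } else {
      b <- p$box
      recs[[length(recs) + 1L]] <-
        annotation_record(image_id, "box",
                          box = c(b[["x0"]], b[["y0"]],
                                  b[["x1"]] - b[["x0"]], b[["y1"]] - b[["y0"]]),
                          label = p$label)
    }
  }
  recs
}

#' Tally annotation records
#' @param records list of [annotation_record()]s
#' @return list with `per_label` (named integer vector; unlabeled v1
#'   records count under `"(unlabeled)"`), `total` (sum of the per-label
#'   counts) and `n_images` (distinct image ids)
#' @export
count_annotations <- function(records) {
  if (!length(records))
    return(list(per_label = integer(0), total = 0L, n_images = 0L))
  labs <- vapply(records, function(r)
    if (is.na(r$label)) "(unlabeled)" else r$label, "")
  per <- table(labs)
  list(per_label = stats::setNames(as.integer(per), names(per)),
       total = length(records),
       n_images = length(unique(vapply(records, `[[`, "", "image_id"))))
}

# -- results / report CSV ----------------------------------------------------

#' Write trait measurements to the results CSV
#'
#' Stable column order: image_id, trait, value, units, confidence, backend,
#' scale_cm_per_px.  An empty measurement list yields a header-only file.
#'
#' @param measurements list of [trait_measurement()]s (or a data.frame from
#'   [measurements_to_df()])
#' @param path destination CSV
#' @export
write_results_csv <- function(measurements, path) {
  df <- if (is.data.frame(measurements)) measurements
        else measurements_to_df(measurements)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-trait validation reports to CSV
#' @param reports list of `validation_report`s
#' @param path destination CSV
#' @export
write_validation_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(trait = r$trait, n = r$n, pearson_r = r$pearson_r,
               p_pearson = r$p_pearson, r_squared = r$r_squared,
               rmse = r$rmse, bias = r$bias, t_stat = r$t_stat,
               p_paired = r$p_paired,
               detection_frequency_pct = r$detection_frequency_pct)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cluster/ANOVA summary CSV
#' @param cl a `cluster_result`
#' @param values the clustered values (same order as `cl$assignments`)
#' @param path destination CSV
#' @param anova optional [anova_tukey()] result on the clusters
#' @export
write_cluster_csv <- function(cl, values, path, anova = NULL) {
  df <- data.frame(value = values, cluster = cl$assignments)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(anova)) {
    spath <- sub("\\.csv$", "_summary.csv", path)
    sm <- data.frame(cluster = seq_len(cl$k), mean = cl$cluster_means,
                     n = cl$sizes,
                     letters = anova$letters,
                     anova_F = anova$F, anova_p = anova$p)
    utils::write.csv(sm, spath, row.names = FALSE)
  }
  invisible(path)
}

# -- calibration sidecar -----------------------------------------------------

#' Persist / restore a plane calibration as a JSON sidecar
#' @param H a `plane_homography`
#' @param path JSON file path
#' @export
write_calibration <- function(H, path) {
  stopifnot(inherits(H, "plane_homography"))
  jsonlite::write_json(list(matrix_row_major = as.vector(t(H$matrix)),
                            scale_cm_per_px = H$scale_cm_per_px,
                            side_cm = H$side_cm,
                            corners = H$corners),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(matrix = matrix(x$matrix_row_major, 3, 3, byrow = TRUE),
                 scale_cm_per_px = x$scale_cm_per_px,
                 side_cm = x$side_cm,
                 corners = matrix(x$corners, 4, 2)),
            class = "plane_homography")
}
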