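# Structured condition classes.  Every operational failure raised by the
# package carries a specific class (plus "strawpheno_error") so callers and
# tests can discriminate failure modes with tryCatch()/expect_error().

spt_abort <- function(class, message, ...) {
  stop(errorCondition(message,
                      ...,
                      class = c(class, "strawpheno_error", "error", "condition")))
}

#' @noRd
err_marker_not_found   <- function(msg = "no fiducial marker candidate found")
  spt_abort("spt_marker_not_found", msg)
err_ambiguous_marker   <- function(n)
  spt_abort("spt_ambiguous_marker",
            sprintf("%d marker candidates survive screening; expected 1", n))
err_degenerate_corners <- function(msg = "three or more marker corners are collinear")
  spt_abort("spt_degenerate_corners", msg)
err_point_at_infinity  <- function()
  spt_abort("spt_point_at_infinity",
            "homogeneous coordinate vanished while mapping point to plane")
err_box_out_of_bounds  <- function(box, dim)
  spt_abort("spt_box_out_of_bounds",
            sprintf("detection box [%g,%g)x[%g,%g) exceeds image %dx%d",
                    box[1], box[3], box[2], box[4], dim[2], dim[1]))
err_empty_mask         <- function()
  spt_abort("spt_empty_mask", "mask has no foreground pixels")
err_label_mismatch     <- function(expected, got)
  spt_abort("spt_label_mismatch",
            sprintf("expected detection labelled '%s', got '%s'", expected, got))
err_degenerate_fit     <- function()
  spt_abort("spt_degenerate_fit", "all areas identical; regression undefined")
err_insufficient_pairs <- function(n)
  spt_abort("spt_insufficient_pairs",
            sprintf("need at least 3 paired values, got %d", n))
err_too_few_samples    <- function(n, k)
  spt_abort("spt_too_few_samples",
            sprintf("k-means with k=%d needs at least %d samples, got %d", k, k, n))
err_degenerate_groups  <- function()
  spt_abort("spt_degenerate_groups", "total variance of groups is zero")
err_malformed_row      <- function(row, why)
  spt_abort("spt_malformed_row", sprintf("malformed annotation row %d: %s", row, why),
            row = row)
err_missing_label      <- function(image_id)
  spt_abort("spt_missing_label",
            sprintf("v2 region in image '%s' has no class label", image_id))
err_malformed_json     <- function(why)
  spt_abort("spt_malformed_json", paste0("cannot parse VIA v2 JSON: ", why))
err_part_out_of_frame  <- function(label)
  spt_abort("spt_part_out_of_frame",
            sprintf("scene part '%s' does not fit inside the image frame", label))
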