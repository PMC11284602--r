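#' Fruit-area to fresh-weight regression
#'
#' A simple calibration model turning the image-measured fruit area (cm^2)
#' into predicted fresh weight (g).  Ordinary least squares on the raw
#' scale is the default; a log-log variant is available behind a flag for
#' users who prefer a power-law allometry.  Predictions are floored at 0 g.
#'
#' @name weight_model
NULL

#' Fit the fruit-area to fresh-weight model
#'
#' @param areas fruit areas in cm^2
#' @param weights fresh weights in g
#' @param log_log if `TRUE`, fit `log(weight) ~ log(area)` instead of the
#'   raw-scale line (requires strictly positive data)
#' @return object of class `weight_model` with fields `slope` (g/cm^2, or
#'   the power-law exponent), `intercept` (g, or log-scale), `r_squared`,
#'   `n`, `sigma` (residual SD) and `log_log`
#' @export
fit_weight_model <- function(areas, weights, log_log = FALSE) {
  stopifnot(length(areas) == length(weights))
  ok <- is.finite(areas) & is.finite(weights)
  areas <- areas[ok]; weights <- weights[ok]
  n <- length(areas)
  if (n < 3) stop("need at least 3 area/weight pairs")
  if (log_log) {
    stopifnot(all(areas > 0), all(weights > 0))
    x <- log(areas); y <- log(weights)
  } else {
    x <- areas; y <- weights
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx <= .Machine$double.eps * max(1, mean(x)^2) * n) err_degenerate_fit()
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, n = n,
                 sigma = sqrt(ss_res / max(1, n - 2)),
                 log_log = log_log),
            class = "weight_model")
}

#' Predict fresh weight from fruit area
#' @param model a [fit_weight_model()] result
#' @param area fruit area(s) in cm^2, `>= 0`
#' @return predicted weight(s) in g, floored at 0
#' @export
predict_weight <- function(model, area) {
  stopifnot(inherits(model, "weight_model"), all(area >= 0))
  if (model$log_log) {
    w <- exp(model$intercept + model$slope * log(pmax(area, .Machine$double.xmin)))
    w[area == 0] <- 0
    w
  } else {
    pmax(0, model$intercept + model$slope * area)
  }
}

#' @export
print.weight_model <- function(x, ...) {
  form <- if (x$log_log) "log(weight) = %.4g + %.4g log(area)"
          else "weight = %.4g + %.4g area"
  cat(sprintf(paste0(form, "  (R^2 = %.3f, n = %d)\n"),
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Persist / restore a weight model as a JSON sidecar
#' @param model a `weight_model`
#' @param path JSON file path
#' @export
write_weight_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weight_model
#' @export
read_weight_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("slope", "intercept", "r_squared", "n", "sigma", "log_log")],
            class = "weight_model")
}
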