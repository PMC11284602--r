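#' Image containers and raster utilities
#'
#' Images are plain numeric arrays `height x width x 3` with channel values
#' in `[0, 1]`.  Pixel coordinates are 0-based and refer to pixel centers:
#' the pixel stored at matrix position `[r, c]` has center `(x, y) =
#' (c - 1, r - 1)` and covers the half-open cell
#' `[x - 0.5, x + 0.5) x [y - 0.5, y + 0.5)`.
#'
#' @param width,height image dimensions in pixels
#' @param color background color, length-3 RGB in `[0,1]`
#' @return a `height x width x 3` numeric array
#' @export
new_image <- function(width, height, color = c(1, 1, 1)) {
  stopifnot(width >= 1, height >= 1, length(color) == 3)
  array(rep(color, each = height * width), dim = c(height, width, 3))
}

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]

#' Convert an RGB image to a grayscale matrix (channel mean).
#' @param img RGB array
#' @return numeric matrix
#' @export
to_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

# -- connected components ----------------------------------------------------

#' Label 4-connected components of a logical mask
#'
#' Run-based two-pass labelling with union-find; labels are renumbered
#' 1..n_components in first-encounter order.
#'
#' @param mask logical matrix
#' @return integer matrix of the same shape, 0 = background
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  prev_runs <- NULL  # matrix: start, end, label-id
  for (r in seq_len(h)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(as.logical(row))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs <- cbind(starts[keep], ends[keep], 0L)
    for (i in seq_len(nrow(runs))) {
      id <- 0L
      if (!is.null(prev_runs)) {
        for (j in seq_len(nrow(prev_runs))) {
          if (prev_runs[j, 1] <= runs[i, 2] && prev_runs[j, 2] >= runs[i, 1]) {
            if (id == 0L) id <- uf_find(prev_runs[j, 3])
            else uf_union(id, prev_runs[j, 3])
          }
        }
      }
      if (id == 0L) {
        parent <- c(parent, length(parent) + 1L)
        id <- length(parent)
      }
      runs[i, 3] <- id
      lab[r, runs[i, 1]:runs[i, 2]] <- id
    }
    prev_runs <- runs
  }
  if (length(parent) == 0L) return(lab)
  roots <- vapply(seq_along(parent), uf_find, integer(1))
  renum <- integer(length(parent))
  renum[unique(roots)] <- seq_along(unique(roots))
  nz <- lab != 0L
  lab[nz] <- renum[roots[lab[nz]]]
  lab
}

# Tight half-open pixel box of the TRUE cells of a mask, in 0-based pixel
# coordinates: a pixel with center x covers [x-0.5, x+0.5).
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  c(x0 = min(idx[, 2]) - 1.5, y0 = min(idx[, 1]) - 1.5,
    x1 = max(idx[, 2]) - 0.5, y1 = max(idx[, 1]) - 0.5)
}

# -- file I/O ----------------------------------------------------------------

#' Read a raster image (PNG, JPEG or PNM)
#'
#' PNG/JPEG require the optional \pkg{png}/\pkg{jpeg} packages; the portable
#' anymap formats (P2/P3/P5/P6) are read natively and need no extra package.
#'
#' @param path file path; format chosen by extension
#' @return `h x w x 3` numeric array in `[0,1]`
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package; use PNM instead")
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package; use PNM instead")
    a <- jpeg::readJPEG(path)
  } else if (ext %in% c("pnm", "ppm", "pgm")) {
    a <- read_pnm(path)
  } else stop("unsupported image extension: ", ext)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write a raster image (PNG or PNM)
#' @param img `h x w x 3` array in `[0,1]`
#' @param path destination; `.png` needs the \pkg{png} package, `.ppm/.pnm`
#'   is written natively (binary P6)
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package; use .ppm instead")
    png::writePNG(img, path)
  } else if (ext %in% c("pnm", "ppm")) {
    write_pnm(img, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {  # next whitespace-delimited token, skipping # comments
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("unexpected EOF in PNM header")
      if (grepl("^\\s$", ch)) next
      if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE)
                                if (c2 == "\n") break }; next }
      buf <- ch
      repeat {
        c2 <- readChar(con, 1, useBytes = TRUE)
        if (length(c2) == 0 || c2 == "" || grepl("^\\s$", c2)) break
        buf <- paste0(buf, c2)
      }
      return(buf)
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("not a supported PNM: ", magic)
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    raw <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  } else {
    raw <- integer(0)
    while (length(raw) < n) {
      line <- readLines(con, 1)
      if (length(line) == 0) break
      line <- sub("#.*", "", line)
      raw <- c(raw, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
    }
    raw <- raw[!is.na(raw)]
  }
  if (length(raw) < n) stop("truncated PNM payload")
  v <- raw[seq_len(n)] / mx
  if (nch == 1L) {
    matrix(v, h, w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3))
    for (k in 1:3) a[, , k] <- matrix(v[seq(k, n, by = 3)], h, w, byrow = TRUE)
    a
  }
}

write_pnm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  v <- array(0L, dim = c(3, w, h))
  for (k in 1:3) v[k, , ] <- t(round(pmin(pmax(img[, , k], 0), 1) * 255))
  writeBin(as.integer(v), con, size = 1)
  invisible(path)
}
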