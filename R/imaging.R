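# Mean-color extraction from powder images.
#
# Images are H x W x 3 numeric arrays on the 0-255 scale (read_image() rescales
# the 0-1 arrays returned by the png/tiff readers). Pixel coordinates are
# 0-based, x rightward and y downward, matching common imaging conventions.

.check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  invisible(NULL)
}

#' Read a PNG or TIFF image as a 0-255 RGB array
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An H x W x 3 numeric array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  .check_image(img)
  img * 255
}

#' Mean RGB over a circular region of interest
#'
#' Averages the image over the disc of pixels whose centers satisfy
#' `(x - cx)^2 + (y - cy)^2 <= radius^2` — the container region holding the
#' powder. The container is located upstream (its center and radius are
#' inputs); this function only does the averaging.
#'
#' @param image H x W x 3 numeric array, 0-255 scale.
#' @param cx,cy Circle center in pixels, 0-based (`cx` rightward along
#'   columns, `cy` downward along rows).
#' @param radius Circle radius in pixels, > 0.
#' @return A tibble with one row and columns `r`, `g`, `b`.
#' @export
roi_mean_rgb <- function(image, cx, cy, radius) {
  .check_image(image)
  stopifnot(radius > 0)
  h <- dim(image)[1]
  w <- dim(image)[2]
  ys <- 0:(h - 1)
  xs <- 0:(w - 1)
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
  if (!any(inside)) {
    stop("circular ROI contains no pixel centers", call. = FALSE)
  }
  means <- vapply(1:3, function(ch) mean(image[, , ch][inside]), numeric(1))
  tibble::tibble(r = means[1], g = means[2], b = means[3])
}

#' Whiteboard white-balance calibration
#'
#' Rescales each channel so the measured whiteboard color maps to 255 —
#' channel `c` is multiplied by `255 / whiteboard_c` — then clips to
#' `[0, 255]`. Applied to the whole image before ROI averaging, it removes
#' illumination color cast using a near-100%-reflectance white reference.
#'
#' @param image H x W x 3 numeric array, 0-255 scale.
#' @param whiteboard Length-3 numeric vector `(r, g, b)` of the measured
#'   whiteboard color; all channels must be positive.
#' @return The calibrated image array.
#' @export
whiteboard_calibrate <- function(image, whiteboard) {
  .check_image(image)
  whiteboard <- as.numeric(whiteboard)
  stopifnot(length(whiteboard) == 3)
  if (any(whiteboard <= 0)) {
    stop("whiteboard channels must be positive", call. = FALSE)
  }
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * (255 / whiteboard[ch])
  pmin(pmax(out, 0), 255)
}

#' Extract a query color from a powder image
#'
#' Convenience wrapper: read the image, optionally whiteboard-calibrate it,
#' then average over the circular container ROI. Returns a query-table row
#' ready for [predict_formula()].
#'
#' @param path Image path (PNG/TIFF).
#' @param cx,cy,radius Circular ROI, as in [roi_mean_rgb()].
#' @param whiteboard Optional length-3 whiteboard color for calibration.
#' @param sample_id Identifier for the output row.
#' @return A one-row tibble with columns `sample_id`, `r`, `g`, `b`.
#' @export
extract_query <- function(path, cx, cy, radius, whiteboard = NULL,
                          sample_id = basename(path)) {
  img <- read_image(path)
  if (!is.null(whiteboard)) img <- whiteboard_calibrate(img, whiteboard)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                   roi_mean_rgb(img, cx, cy, radius))
}
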