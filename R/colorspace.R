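# Color representations and distances.
#
# Camera RGB is treated as sRGB (IEC 61966-2-1 companding) under the D65 2°
# observer; the white point is taken as the image of (1,1,1) under the sRGB
# matrix so that pure white maps to exactly L = 100, a = b = 0.

.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.white_xyz <- as.numeric(.srgb_to_xyz %*% c(1, 1, 1))

.check_rgb <- function(r, g, b, what = "channel") {
  vals <- c(r, g, b)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255)) {
    stop("RGB ", what, " values must lie in [0, 255]", call. = FALSE)
  }
  invisible(NULL)
}

#' Convert RGB colors to CIELAB
#'
#' Converts 0-255 RGB channel values to CIELAB coordinates using sRGB
#' companding and the D65 2-degree white point. White (255, 255, 255) maps to
#' exactly (100, 0, 0) and black to (0, 0, 0). CIELAB is the space in which
#' color differences between a granule and its candidate placebo are measured,
#' because Euclidean distance there (delta E) tracks perceived difference far
#' better than distance in RGB.
#'
#' @param r,g,b Numeric vectors of channel intensities in `[0, 255]`.
#'   Real values are accepted so that channel means carry through.
#' @return A tibble with columns `L` (lightness, 0-100), `a` (green-red axis)
#'   and `b` (blue-yellow axis), one row per input color.
#' @examples
#' rgb_to_lab(255, 255, 255)
#' rgb_to_lab(c(224, 92), c(205, 134), c(166, 152))
#' @export
rgb_to_lab <- function(r, g, b) {
  .check_rgb(r, g, b)
  rgb01 <- cbind(r, g, b) / 255
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92, ((rgb01 + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz)
  fr <- sweep(xyz, 2, .white_xyz, "/")
  f <- ifelse(fr > (6 / 29)^3, fr^(1 / 3), fr * (29 / 6)^2 / 3 + 4 / 29)
  tibble::tibble(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

#' CIELAB color difference (delta E)
#'
#' Euclidean distance between two colors in CIELAB space,
#' \eqn{\Delta E = \sqrt{(L-L_0)^2 + (a-a_0)^2 + (b-b_0)^2}} — the CIE76
#' formula. It is the primary machine criterion for how closely a placebo
#' matches its reference granule.
#'
#' @param L1,a1,b1 CIELAB coordinates of the first color (vectorized).
#' @param L2,a2,b2 CIELAB coordinates of the second color.
#' @return Non-negative numeric vector of color differences.
#' @examples
#' delta_e(83, 1, 22, 84, 0, 24)  # 2.4495
#' @export
delta_e <- function(L1, a1, b1, L2, a2, b2) {
  sqrt((L1 - L2)^2 + (a1 - a2)^2 + (b1 - b2)^2)
}

#' Cosine similarity between RGB colors
#'
#' The cosine of the angle between two raw 0-255 RGB channel vectors:
#' \eqn{\cos\theta = u \cdot v / (\|u\|\,\|v\|)}. A value of 1 means the two
#' colors share the same hue direction regardless of intensity scale; it
#' complements delta E, which is sensitive to lightness.
#'
#' @param r1,g1,b1 Channels of the first color (vectorized, in `[0, 255]`).
#' @param r2,g2,b2 Channels of the second color.
#' @return Numeric vector in `[0, 1]` for non-negative channel vectors.
#' @examples
#' cosine_similarity(146, 127, 83, 152, 134, 92)  # 0.9998
#' @export
cosine_similarity <- function(r1, g1, b1, r2, g2, b2) {
  .check_rgb(r1, g1, b1)
  .check_rgb(r2, g2, b2)
  nu <- sqrt(r1^2 + g1^2 + b1^2)
  nv <- sqrt(r2^2 + g2^2 + b2^2)
  if (any(nu == 0) || any(nv == 0)) {
    stop("cosine similarity is undefined for an all-zero RGB vector",
         call. = FALSE)
  }
  (r1 * r2 + g1 * g2 + b1 * b2) / (nu * nv)
}

#' Perceptibility bands for delta E
#'
#' The textile/dyeing thresholds used to grade a color difference: boundaries
#' at 1, 3, 6, 9 and 12 delta-E units. Bands are half-open `[lower, upper)` so
#' every non-negative difference falls in exactly one band.
#'
#' @return A tibble with columns `label`, `lower` (inclusive) and `upper`
#'   (exclusive).
#' @export
delta_e_bands <- function() {
  tibble::tibble(
    label = c("nearly_undetectable", "very_small", "slight",
              "fair", "clear", "different"),
    lower = c(0, 1, 3, 6, 9, 12),
    upper = c(1, 3, 6, 9, 12, Inf)
  )
}

#' Classify a delta E value into a perceptibility band
#'
#' @param d Non-negative numeric vector of delta E values.
#' @return Factor with levels from [delta_e_bands()], one per input.
#' @examples
#' classify_delta_e(c(0.5, 2.4495, 12.5))
#' @export
classify_delta_e <- function(d) {
  if (anyNA(d) || any(d < 0)) {
    stop("delta E must be non-negative", call. = FALSE)
  }
  bands <- delta_e_bands()
  idx <- findInterval(d, bands$lower)  # half-open [lower, upper)
  factor(bands$label[idx], levels = bands$label)
}

# Round-half-up at `digits`, matching how the reference tables print values
# (base round() is round-half-even).
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
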