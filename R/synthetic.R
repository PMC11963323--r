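# Forward pigment-mixing simulator.
#
# Beer-Lambert-style subtractive mixing: each pigment attenuates each channel
# exponentially at a per-mg rate, channel = base * exp(-sum K[channel, pigment]
# * dose) + Gaussian noise, clipped to [0, 255]. Exponential attenuation is
# bounded, strictly monotone in every dose, and nonlinear enough that tree
# ensembles outperform linear models on the inverse problem — mirroring the
# behavior of real pigmented powders.

#' Default channel-attenuation matrix
#'
#' Per-mg attenuation coefficients, 3 channels x 4 pigments. Directions follow
#' pigment optics: caramel (brown) attenuates B > G > R; lemon yellow
#' attenuates mostly B; carmine mostly G; indigo mostly R then G (its doses
#' stay below 1 mg).
#'
#' @return A 3 x 4 numeric matrix with rows `r`, `g`, `b` and columns
#'   `caramel_mg`, `lemon_yellow_mg`, `carmine_mg`, `indigo_mg`.
#' @export
default_attenuation <- function() {
  matrix(
    c(0.00150, 0.0002, 0.0005, 0.080,
      0.00135, 0.0005, 0.0023, 0.040,
      0.00190, 0.0040, 0.0012, 0.02),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("r", "g", "b"), .pigment_cols)
  )
}

#' Construct a forward pigment-mixing model
#'
#' @param K 3 x 4 positive attenuation matrix (per mg), rows r/g/b, columns in
#'   pigment order; see [default_attenuation()].
#' @param base_color Length-3 RGB of the pure excipient powder (lactose/
#'   dextrin), default `c(253, 252, 251)` — a warm off-white.
#' @param noise_sd Gaussian measurement noise SD in channel units (default 2).
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(K = default_attenuation(),
                          base_color = c(253, 252, 251), noise_sd = 2) {
  K <- as.matrix(K)
  stopifnot(all(dim(K) == c(3, 4)), all(K > 0),
            length(base_color) == 3,
            all(base_color > 0), all(base_color <= 255),
            noise_sd >= 0)
  dimnames(K) <- list(c("r", "g", "b"), .pigment_cols)
  structure(list(K = K, base_color = stats::setNames(as.numeric(base_color),
                                                     c("r", "g", "b")),
                 noise_sd = noise_sd),
            class = "forward_model")
}

#' Simulate the color of a pigment formula
#'
#' Applies the forward model to one or more formulas:
#' `channel = base * exp(-K %*% doses) + noise`, clipped to `[0, 255]`.
#' Deterministic when `noise_sd = 0`; callers control noise reproducibility
#' with `set.seed()` (the generator functions do this for you).
#'
#' @param fm A `forward_model`.
#' @param doses Data frame or matrix with the four pigment dose columns (mg).
#' @return A tibble with columns `r`, `g`, `b`.
#' @export
forward_mix <- function(fm, doses) {
  stopifnot(inherits(fm, "forward_model"))
  d <- as.matrix(as.data.frame(doses)[.pigment_cols])
  if (any(d < 0)) stop("pigment doses must be non-negative", call. = FALSE)
  expo <- d %*% t(fm$K)                       # n x 3
  rgb <- sweep(exp(-expo), 2, fm$base_color, "*")
  if (fm$noise_sd > 0) {
    rgb <- rgb + matrix(stats::rnorm(length(rgb), 0, fm$noise_sd),
                        nrow(rgb), 3)
  }
  rgb <- pmin(pmax(rgb, 0), 255)
  tibble::tibble(r = rgb[, 1], g = rgb[, 2], b = rgb[, 3])
}

# Draw formulas from the two-regime design. Light regime: low caramel and
# modest co-pigments (pale yellowish-brown powders); dark regime: heavy
# caramel with proportionally larger lemon-yellow and carmine, giving the
# dark brown population. Indigo stays below 1 mg and is zero for most samples.
.draw_formulas <- function(n, design = c("paperlike", "uniform"),
                           p_dark = 0.45) {
  design <- match.arg(design)
  if (design == "uniform") {
    return(tibble::tibble(
      caramel_mg = stats::runif(n, 0, 800),
      lemon_yellow_mg = stats::runif(n, 0, 155),
      carmine_mg = stats::runif(n, 0, 265),
      indigo_mg = ifelse(stats::runif(n) < 0.7, 0, stats::runif(n, 0, 1)),
      excipient_g = 20
    ))
  }
  dark <- stats::runif(n) < p_dark
  caramel <- ifelse(dark, stats::runif(n, 200, 800), stats::runif(n, 0, 200))
  lemon <- ifelse(dark, stats::runif(n, 0, 155), stats::runif(n, 0, 25))
  carmine <- ifelse(dark, stats::runif(n, 0, 265), stats::runif(n, 0, 60))
  indigo <- ifelse(stats::runif(n) < 0.7, 0, stats::runif(n, 0, 1))
  tibble::tibble(
    caramel_mg = caramel, lemon_yellow_mg = lemon,
    carmine_mg = carmine, indigo_mg = indigo, excipient_g = 20
  )
}

#' Generate a simulated granule library
#'
#' Draws pigment formulas from a two-regime (light/dark) design spanning the
#' published dose ranges, pushes them through the forward model, and returns a
#' training table. The two regimes give the color library its two-population
#' structure, so that k-means at k = 2 separates light from dark granules.
#'
#' @param n Number of samples (default 323, the size of the simulated-granule
#'   library the model is built from).
#' @param fm A `forward_model` (default [forward_model()]).
#' @param design `"paperlike"` (two-regime, default) or `"uniform"`.
#' @param seed Integer seed; output is fully reproducible from it.
#' @return A training tibble: `sample_id`, `r`, `g`, `b`, the four dose
#'   columns, `excipient_g`, `source = "simulated"`.
#' @export
simulate_granules <- function(n = 323, fm = forward_model(),
                              design = "paperlike", seed = 42L) {
  if (n < 2) stop("need n >= 2 simulated granules", call. = FALSE)
  set.seed(seed)
  formulas <- .draw_formulas(n, design)
  colors <- forward_mix(fm, formulas)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("sim%03d", seq_len(n))),
    colors,
    formulas
  ) |>
    dplyr::mutate(source = "simulated")
}

#' Generate query colors with hidden ground-truth formulas
#'
#' Fresh samples from the same two-regime design, standing in for new granules
#' whose pigment composition must be recovered. Ground truth is returned in
#' the same table (columns `*_mg`) so recovery can be scored; drop those
#' columns to obtain a blind query table.
#'
#' @param n Number of queries.
#' @param fm A `forward_model`.
#' @param design As in [simulate_granules()].
#' @param seed Integer seed (use a different seed from the training library).
#' @return A tibble like [simulate_granules()] with `source = "query"`.
#' @export
generate_queries <- function(n, fm = forward_model(), design = "paperlike",
                             seed = 43L) {
  if (n == 0) {
    return(simulate_granules(2, fm, design, seed)[0, ] |>
             dplyr::mutate(source = character()))
  }
  simulate_granules(max(n, 2), fm, design, seed)[seq_len(n), ] |>
    dplyr::mutate(source = "query",
                  sample_id = sprintf("query%03d", seq_len(n)))
}
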