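# Z-score standardizer for RGB features. Training-set statistics are the only
# statistics ever used: query colors are standardized with the stored means and
# SDs, never refit.

#' Fit a z-score standardizer to RGB colors
#'
#' Computes per-channel means and standard deviations (sample SD, `n - 1`
#' denominator) from a training table. The fitted object standardizes new
#' colors with these training statistics so that scaling is consistent between
#' training and prediction.
#'
#' @param data Data frame with numeric columns `r`, `g`, `b`.
#' @return An object of class `standardizer` holding `mean`, `sd` and the
#'   feature column names.
#' @examples
#' s <- fit_standardizer(tibble::tibble(r = c(0, 2), g = c(0, 2), b = c(0, 2)))
#' standardize(s, tibble::tibble(r = 1, g = 1, b = 1))
#' @export
fit_standardizer <- function(data) {
  cols <- c("r", "g", "b")
  stopifnot(all(cols %in% names(data)))
  x <- as.matrix(data[cols])
  if (nrow(x) < 2) {
    stop("need at least 2 samples to fit a standardizer", call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("channel(s) ", paste(cols[sdv == 0], collapse = ", "),
         " are constant across samples; cannot standardize a degenerate feature",
         call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv, cols = cols), class = "standardizer")
}

#' Standardize or back-transform RGB colors
#'
#' `standardize()` maps colors to z-scores using the training statistics;
#' `unstandardize()` is its exact inverse. New data outside the training range
#' gets finite z-scores; nothing is clipped.
#'
#' @param s A fitted `standardizer`.
#' @param data Data frame with columns `r`, `g`, `b` (`standardize`) or a
#'   matrix/data frame of z-scores with the same three columns
#'   (`unstandardize`).
#' @return A numeric matrix (`standardize`) or tibble of colors
#'   (`unstandardize`), rows parallel to the input.
#' @export
standardize <- function(s, data) {
  stopifnot(inherits(s, "standardizer"))
  x <- as.matrix(as.data.frame(data)[s$cols])
  sweep(sweep(x, 2, s$mean, "-"), 2, s$sd, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(s, data) {
  stopifnot(inherits(s, "standardizer"))
  x <- as.matrix(as.data.frame(data)[s$cols])
  out <- sweep(sweep(x, 2, s$sd, "*"), 2, s$mean, "+")
  tibble::as_tibble(as.data.frame(out))
}

#' @export
print.standardizer <- function(x, ...) {
  cat("<standardizer> channels:", paste(x$cols, collapse = ", "), "\n")
  cat("  mean:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  cat("  sd:  ", paste(signif(x$sd, 6), collapse = ", "), "\n")
  invisible(x)
}
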