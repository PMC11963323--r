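# Similarity assessment between reference granules and candidate placebos:
# per-pair delta E (on CIELAB), cosine similarity (on raw RGB), perceptibility
# bands, aggregate means and threshold counts, and the paired-t statistics of
# the human sensory comparison.

#' Evaluate reference/placebo color pairs
#'
#' Computes, for each pair, the CIELAB color difference (delta E), its
#' perceptibility band, and the RGB cosine similarity, plus the aggregates
#' used to judge the match overall: mean delta E, mean COS, and the counts of
#' pairs with delta E < 6 and delta E <= 3. When Lab coordinates are supplied
#' (columns `ref_L`, `ref_a`, `ref_b_lab`, `plc_L`, `plc_a`, `plc_b_lab`)
#' they are used directly — measured Lab values are authoritative; otherwise
#' Lab is derived from RGB via [rgb_to_lab()].
#'
#' @param pairs Tibble with RGB columns `ref_r`, `ref_g`, `ref_b`, `plc_r`,
#'   `plc_g`, `plc_b`, optional Lab columns as above, and optionally `pair`
#'   identifiers.
#' @return An object of class `similarity_report`: list with `pairs` (per-row
#'   tibble including `delta_e`, `band`, `cos`) and `summary` (one-row tibble
#'   with `n`, `mean_delta_e`, `mean_cos`, `n_delta_e_lt6`, `n_delta_e_le3`).
#' @examples
#' evaluate_pairs(example_validation_pairs())
#' @export
evaluate_pairs <- function(pairs) {
  if (nrow(pairs) == 0) stop("no color pairs to evaluate", call. = FALSE)
  need <- c("ref_r", "ref_g", "ref_b", "plc_r", "plc_g", "plc_b")
  stopifnot(all(need %in% names(pairs)))
  lab_cols <- c("ref_L", "ref_a", "ref_b_lab", "plc_L", "plc_a", "plc_b_lab")
  if (!all(lab_cols %in% names(pairs))) {
    ref_lab <- rgb_to_lab(pairs$ref_r, pairs$ref_g, pairs$ref_b)
    plc_lab <- rgb_to_lab(pairs$plc_r, pairs$plc_g, pairs$plc_b)
    pairs$ref_L <- ref_lab$L; pairs$ref_a <- ref_lab$a
    pairs$ref_b_lab <- ref_lab$b
    pairs$plc_L <- plc_lab$L; pairs$plc_a <- plc_lab$a
    pairs$plc_b_lab <- plc_lab$b
  }
  rows <- pairs |>
    dplyr::mutate(
      delta_e = delta_e(.data$ref_L, .data$ref_a, .data$ref_b_lab,
                        .data$plc_L, .data$plc_a, .data$plc_b_lab),
      band = classify_delta_e(.data$delta_e),
      cos = cosine_similarity(.data$ref_r, .data$ref_g, .data$ref_b,
                              .data$plc_r, .data$plc_g, .data$plc_b)
    )
  summary <- tibble::tibble(
    n = nrow(rows),
    mean_delta_e = mean(rows$delta_e),
    mean_cos = mean(rows$cos),
    n_delta_e_lt6 = sum(rows$delta_e < 6),
    n_delta_e_le3 = sum(rows$delta_e <= 3)
  )
  structure(list(pairs = rows, summary = summary),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>", x$summary$n, "pairs\n")
  cat(sprintf("  mean delta E %.4f | mean COS %.4f | dE<6: %d | dE<=3: %d\n",
              x$summary$mean_delta_e, x$summary$mean_cos,
              x$summary$n_delta_e_lt6, x$summary$n_delta_e_le3))
  invisible(x)
}

#' Per-pair rows of a similarity report
#'
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @return The per-pair tibble with `delta_e` and `cos` rendered at 4 decimal
#'   places (half-up), full precision retained in the report object.
#' @method tidy similarity_report
#' @export
tidy.similarity_report <- function(x, ...) {
  dplyr::mutate(x$pairs,
                delta_e = round_half_up(.data$delta_e, 4),
                cos = round_half_up(.data$cos, 4))
}

#' One-row summary of a similarity report
#'
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @return The one-row aggregate tibble.
#' @method glance similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  x$summary
}

#' Paired t-test on sensory similarity scores
#'
#' Classical paired t-test (df = n - 1) on the difference between two raters'
#' score vectors for drug A and drug B, two-sided, at significance level
#' `alpha`. Identical vectors give t = 0, p = 1; a constant nonzero
#' difference has zero variance and raises a degenerate-test error.
#'
#' @param a,b Equal-length numeric score vectors (the 0-3 sensory scale).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `t`, `df`, `p_value`, `reject`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("paired scores must have equal length >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = length(d) - 1L, p_value = 1,
                            reject = FALSE))
    }
    stop("degenerate paired t-test: nonzero differences with zero variance",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, reject = ht$p.value < alpha)
}

#' Mean manual similarity
#'
#' Arithmetic mean of per-formulation manual COS similarity values, rendered
#' at 4 decimal places (half-up).
#'
#' @param cos_values Non-empty numeric vector of similarity values.
#' @return Scalar mean at 4 dp.
#' @examples
#' manual_summary(example_manual_scores()$cos)  # 0.9366
#' @export
manual_summary <- function(cos_values) {
  if (length(cos_values) == 0) {
    stop("no manual similarity values supplied", call. = FALSE)
  }
  round_half_up(mean(cos_values), 4)
}
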