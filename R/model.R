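# The fitted color-matching model: standardizer -> k-means clustering ->
# per-cluster regression competition -> per-cluster, per-pigment winners.

#' Fit the cluster-then-regress color-matching model
#'
#' End-to-end training on a pigment/color library: (1) fit a z-score
#' standardizer to the RGB channels; (2) scan cluster counts over `k_range`
#' and keep the k-means model with the best silhouette; (3) within each
#' cluster, run the five-family regression competition under repeated k-fold
#' CV with grid search; (4) refit each cluster's winner on the full cluster,
#' one estimator per pigment.
#'
#' @param data Training tibble with columns `r`, `g`, `b` and the four dose
#'   columns `caramel_mg`, `lemon_yellow_mg`, `carmine_mg`, `indigo_mg` (mg
#'   per `excipient_g` gram batch).
#' @param k_range Candidate cluster counts (default 2:11).
#' @param k Optional forced cluster count, bypassing selection.
#' @param folds,repeats Cross-validation folds (5) and partition redraws (3).
#' @param seed Integer seed; fans out deterministically to per-stage seeds.
#' @param grids Hyperparameter grids, see [default_grids()].
#' @return An object of class `color_match_model` with elements
#'   `standardizer`, `k_scan`, `clusters` (the chosen `cluster_model`),
#'   `cv_tables` (per-cluster CV score tibble), `winners`, `estimators`,
#'   and `meta`.
#' @examples
#' \donttest{
#' library <- simulate_granules(n = 323, seed = 1)
#' fit <- fit_color_model(library, seed = 1)
#' predict_formula(fit, tibble::tibble(sample_id = "q", r = 180, g = 160, b = 120))
#' }
#' @export
fit_color_model <- function(data, k_range = 2:11, k = NULL, folds = 5L,
                            repeats = 3L, seed = 42L,
                            grids = default_grids()) {
  .validate_granules(data, kind = "training", require_formula = FALSE)
  if (!all(.pigment_cols %in% names(data))) {
    stop("training data must carry the four pigment dose columns",
         call. = FALSE)
  }
  s <- fit_standardizer(data)
  feats <- standardize(s, data)
  scan <- scan_k(feats, k_range = k_range, seed = seed)
  chosen_k <- if (is.null(k)) scan$chosen_k else as.integer(k)
  cm <- scan$models[[paste0("k", chosen_k)]]
  if (is.null(cm)) cm <- kmeans_fit(feats, chosen_k, seed = seed)
  targets <- as.matrix(data[.pigment_cols])
  cv_tables <- list()
  winners <- character(cm$k)
  estimators <- vector("list", cm$k)
  for (cl in seq_len(cm$k)) {
    idx <- cm$labels == cl
    tab <- compete(feats[idx, , drop = FALSE], targets[idx, , drop = FALSE],
                   folds = folds, repeats = repeats,
                   seed = seed + 10000L * cl, grids = grids)
    winners[cl] <- select_winner(tab)
    best_params <- tab$params[[match(winners[cl], tab$model)]]
    estimators[[cl]] <- .fit_cluster_final(
      feats[idx, , drop = FALSE], targets[idx, , drop = FALSE],
      winners[cl], best_params, seed = seed + 10000L * cl)
    cv_tables[[cl]] <- tab
  }
  structure(
    list(
      standardizer = s,
      k_scan = scan,
      clusters = cm,
      cv_tables = cv_tables,
      winners = winners,
      estimators = estimators,
      meta = list(seed = as.integer(seed), folds = as.integer(folds),
                  repeats = as.integer(repeats), k = cm$k,
                  sd_denominator = "n-1",
                  feature_space = "standardized RGB",
                  trained_at = format(Sys.time(), tz = "UTC"))
    ),
    class = "color_match_model")
}

#' Predict pigment formulas for query colors
#'
#' Standardizes each query color with the training statistics, assigns it to
#' its nearest cluster centroid, and applies that cluster's winning per-pigment
#' estimators. Negative dose predictions are clamped to 0 and doses are
#' rounded to 2 decimal places (manufacturing precision); the excipient batch
#' is fixed at 20.00 g.
#'
#' @param model A fitted `color_match_model`.
#' @param data Query tibble with columns `r`, `g`, `b` (and optionally
#'   `sample_id`).
#' @param excipient_g Excipient batch mass in grams (default 20).
#' @return A tibble with `sample_id`, `cluster`, the four dose columns (mg, 2
#'   dp) and `excipient_g`.
#' @export
predict_formula <- function(model, data, excipient_g = 20) {
  stopifnot(inherits(model, "color_match_model"))
  if (nrow(data) == 0) {
    return(tibble::tibble(
      sample_id = character(), cluster = integer(),
      caramel_mg = numeric(), lemon_yellow_mg = numeric(),
      carmine_mg = numeric(), indigo_mg = numeric(),
      excipient_g = numeric()))
  }
  .check_rgb(data$r, data$g, data$b, what = "query channel")
  feats <- standardize(model$standardizer, data)
  cl <- assign_cluster(model$clusters, feats)
  doses <- matrix(0, nrow(data), length(.pigment_cols),
                  dimnames = list(NULL, .pigment_cols))
  for (c_i in unique(cl)) {
    idx <- cl == c_i
    for (p in .pigment_cols) {
      doses[idx, p] <- .predict_family(model$estimators[[c_i]][[p]],
                                       feats[idx, , drop = FALSE])
    }
  }
  doses <- round_half_up(pmax(doses, 0), 2)
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(data)) data$sample_id else
      paste0("query", seq_len(nrow(data))),
    cluster = cl,
    caramel_mg = doses[, "caramel_mg"],
    lemon_yellow_mg = doses[, "lemon_yellow_mg"],
    carmine_mg = doses[, "carmine_mg"],
    indigo_mg = doses[, "indigo_mg"],
    excipient_g = round_half_up(excipient_g, 2)
  )
}

#' @export
print.color_match_model <- function(x, ...) {
  cat("<color_match_model>\n")
  cat("  k =", x$clusters$k,
      "(silhouette", signif(x$clusters$mean_silhouette, 4), ")\n")
  for (cl in seq_along(x$winners)) {
    cat("  cluster", cl, "winner:", x$winners[cl],
        sprintf("(mean RMSE %.4f, mean R2 %.4f)\n",
                x$cv_tables[[cl]]$mean_rmse[match(x$winners[cl],
                                                  x$cv_tables[[cl]]$model)],
                x$cv_tables[[cl]]$mean_r2[match(x$winners[cl],
                                                x$cv_tables[[cl]]$model)]))
  }
  invisible(x)
}

#' Tidy the cross-validation score table of a fitted model
#'
#' One row per cluster x model family, in the layout of a model-comparison
#' table: cluster, model, mean RMSE, mean R-squared.
#'
#' @param x A `color_match_model`.
#' @param ... Unused.
#' @return A tibble with columns `cluster`, `model`, `mean_rmse`, `mean_r2`,
#'   `winner` (logical).
#' @method tidy color_match_model
#' @export
tidy.color_match_model <- function(x, ...) {
  purrr::imap(x$cv_tables, function(tab, cl) {
    dplyr::mutate(tab[c("model", "mean_rmse", "mean_r2")],
                  cluster = as.integer(cl), .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(winner = .data$model == x$winners[.data$cluster])
}

#' One-row model summary
#'
#' @param x A `color_match_model`.
#' @param ... Unused.
#' @return A one-row tibble: chosen `k`, mean silhouette, SSE, the winning
#'   family names, and the winners' mean RMSE / R-squared averaged over
#'   clusters.
#' @method glance color_match_model
#' @export
glance.color_match_model <- function(x, ...) {
  win_rows <- purrr::imap(x$cv_tables, function(tab, cl) {
    tab[match(x$winners[cl], tab$model), ]
  }) |> dplyr::bind_rows()
  tibble::tibble(
    k = x$clusters$k,
    mean_silhouette = x$clusters$mean_silhouette,
    sse = x$clusters$sse,
    winners = paste(x$winners, collapse = ","),
    winner_mean_rmse = mean(win_rows$mean_rmse),
    winner_mean_r2 = mean(win_rows$mean_r2)
  )
}
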