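# End-to-end orchestration: simulate -> fit -> predict -> evaluate, plus the
# run configuration object. A single master seed fans out deterministically to
# per-stage seeds so each stage is independently reproducible.

.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, fit = 202L, query = 303L, explain = 404L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run configuration for the color-matching pipeline
#'
#' @param seed Master seed; per-stage seeds derive from it.
#' @param k_range Candidate cluster counts.
#' @param folds,repeats Cross-validation settings.
#' @param n_train Library size for simulation (default 323).
#' @param n_query Held-out query count for recovery scoring.
#' @param noise_sd Forward-model measurement noise SD (channel units).
#' @param grids Hyperparameter grids.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 42L, k_range = 2:11, folds = 5L, repeats = 3L,
                       n_train = 323L, n_query = 50L, noise_sd = 2,
                       grids = default_grids()) {
  stopifnot(folds >= 2, n_train >= max(k_range))
  structure(list(seed = as.integer(seed), k_range = k_range,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 n_train = as.integer(n_train), n_query = as.integer(n_query),
                 noise_sd = noise_sd, grids = grids),
            class = "run_config")
}

#' Fit the model from a training table or CSV
#'
#' Pipeline `fit` stage: read (if given a path) and validate the training
#' library, fit the full cluster-then-regress model, and return it with its
#' k-scan report and CV score tables.
#'
#' @param training A training tibble or path to a training CSV.
#' @param config A [run_config()].
#' @return A `color_match_model`.
#' @export
run_fit <- function(training, config = run_config()) {
  data <- if (is.character(training)) {
    read_granules(training, kind = "training")
  } else {
    training
  }
  fit_color_model(data, k_range = config$k_range, folds = config$folds,
                  repeats = config$repeats,
                  seed = .stage_seed(config$seed, "fit"),
                  grids = config$grids)
}

#' Predict formulas for a query table or CSV
#'
#' @param model A fitted `color_match_model` or path to a saved archive.
#' @param queries Query tibble or path to a query CSV (header-only file gives
#'   an empty output).
#' @return Formula tibble as [predict_formula()].
#' @export
run_predict <- function(model, queries) {
  if (is.character(model)) model <- load_color_model(model)
  data <- if (is.character(queries)) {
    read_granules(queries, kind = "query")
  } else {
    queries
  }
  predict_formula(model, data)
}

#' Full reproduction harness
#'
#' Simulate a training library, fit the model, predict held-out queries,
#' and evaluate: per-pigment recovery R-squared on the true doses, and the
#' round-trip delta E between each query color and the color obtained by
#' pushing the predicted formula back through the (noise-free) forward model.
#'
#' @param config A [run_config()].
#' @return A list: `model`, `library`, `queries`, `predicted`, `recovery`
#'   (per-pigment tibble), and `summary` (one-row tibble with `chosen_k`,
#'   `mean_silhouette`, per-pigment `r2_*`, `mean_roundtrip_delta_e`,
#'   `prop_delta_e_lt6`).
#' @export
run_all <- function(config = run_config()) {
  fm <- forward_model(noise_sd = config$noise_sd)
  library_tbl <- simulate_granules(config$n_train, fm,
                                   seed = .stage_seed(config$seed, "simulate"))
  model <- run_fit(library_tbl, config)
  queries <- generate_queries(config$n_query, fm,
                              seed = .stage_seed(config$seed, "query"))
  predicted <- predict_formula(model, queries)
  recovery <- purrr::map(.pigment_cols, function(p) {
    truth <- queries[[p]]
    est <- predicted[[p]]
    tibble::tibble(
      pigment = p,
      r2 = if (sum((truth - mean(truth))^2) == 0) NA_real_ else
        r_squared(truth, est),
      rmse = rmse(truth, est)
    )
  }) |> dplyr::bind_rows()
  rt <- roundtrip_delta_e(fm, queries, predicted)
  summary <- tibble::tibble(
    chosen_k = model$clusters$k,
    mean_silhouette = model$clusters$mean_silhouette,
    r2_caramel = recovery$r2[recovery$pigment == "caramel_mg"],
    r2_lemon_yellow = recovery$r2[recovery$pigment == "lemon_yellow_mg"],
    r2_carmine = recovery$r2[recovery$pigment == "carmine_mg"],
    r2_indigo = recovery$r2[recovery$pigment == "indigo_mg"],
    mean_roundtrip_delta_e = mean(rt),
    prop_delta_e_lt6 = mean(rt < 6)
  )
  list(model = model, library = library_tbl, queries = queries,
       predicted = predicted, recovery = recovery,
       roundtrip_delta_e = rt, summary = summary)
}

#' Round-trip color error of predicted formulas
#'
#' Renders each predicted formula with the noise-free forward model and
#' returns the CIELAB delta E between the rendered color and the query color
#' it was predicted from — the end-to-end measure of how well the predicted
#' pigment doses reproduce the target color.
#'
#' @param fm The `forward_model` that generated the queries.
#' @param queries Query tibble with `r`, `g`, `b`.
#' @param predicted Formula tibble from [predict_formula()].
#' @return Numeric vector of delta E values, one per query.
#' @export
roundtrip_delta_e <- function(fm, queries, predicted) {
  fm0 <- forward_model(K = fm$K, base_color = fm$base_color, noise_sd = 0)
  rendered <- forward_mix(fm0, predicted)
  lab_q <- rgb_to_lab(queries$r, queries$g, queries$b)
  lab_r <- rgb_to_lab(rendered$r, rendered$g, rendered$b)
  delta_e(lab_q$L, lab_q$a, lab_q$b, lab_r$L, lab_r$a, lab_r$b)
}
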