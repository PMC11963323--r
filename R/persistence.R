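# Model archive: a directory holding a JSON manifest (schema version,
# standardizer statistics, centroids, CV tables, winner names), the fitted
# estimators, and a probe set used for load-time self-verification.

.archive_version <- "1"

#' Save a fitted color-matching model
#'
#' Writes a directory archive: `manifest.json` (schema version, standardizer,
#' centroids, chosen k, CV score tables, winners — all floats at full double
#' precision), `estimators.rds` (the fitted per-cluster, per-pigment
#' estimators), and `probes.csv` (20 probe colors with the model's own
#' predictions, re-checked at load time).
#'
#' @param model A `color_match_model`.
#' @param path Directory to create (overwritten if it exists).
#' @param n_probes Number of probe colors stored for self-verification.
#' @return `path`, invisibly.
#' @export
save_color_model <- function(model, path, n_probes = 20L) {
  stopifnot(inherits(model, "color_match_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  set.seed(model$meta$seed)
  mu <- model$standardizer$mean
  sdv <- model$standardizer$sd
  probes <- tibble::tibble(
    sample_id = paste0("probe", seq_len(n_probes)),
    r = pmin(pmax(stats::rnorm(n_probes, mu["r"], sdv["r"]), 0), 255),
    g = pmin(pmax(stats::rnorm(n_probes, mu["g"], sdv["g"]), 0), 255),
    b = pmin(pmax(stats::rnorm(n_probes, mu["b"], sdv["b"]), 0), 255)
  )
  pred <- predict_formula(model, probes)
  readr::write_csv(dplyr::bind_cols(probes, pred[-1]),
                   file.path(path, "probes.csv"))
  manifest <- list(
    schema_version = .archive_version,
    package = "placebocolor",
    meta = model$meta,
    standardizer = list(mean = as.list(mu), sd = as.list(sdv)),
    k = model$clusters$k,
    centroids = apply(model$clusters$centers, 1, as.list, simplify = FALSE),
    sse = model$clusters$sse,
    mean_silhouette = model$clusters$mean_silhouette,
    k_scan = model$k_scan$metrics,
    winners = model$winners,
    cv_tables = purrr::map(model$cv_tables,
                           ~ .x[c("model", "mean_rmse", "mean_r2")])
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(list(standardizer = model$standardizer, k_scan = model$k_scan,
               clusters = model$clusters, cv_tables = model$cv_tables,
               winners = model$winners, estimators = model$estimators,
               meta = model$meta),
          file.path(path, "estimators.rds"))
  invisible(path)
}

#' Load a saved color-matching model
#'
#' Reads the archive written by [save_color_model()], checks the schema
#' version, and re-predicts the stored probe set: any probe whose dose
#' prediction deviates by more than 1e-9 mg (or whose cluster assignment
#' differs) fails the integrity check.
#'
#' @param path Archive directory.
#' @return The restored `color_match_model`.
#' @export
load_color_model <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  est_path <- file.path(path, "estimators.rds")
  probe_path <- file.path(path, "probes.csv")
  if (!all(file.exists(manifest_path, est_path, probe_path))) {
    stop("model archive at '", path, "' is missing files; corrupted?",
         call. = FALSE)
  }
  manifest <- tryCatch(jsonlite::read_json(manifest_path),
                       error = function(e) {
                         stop("unreadable manifest: ", conditionMessage(e),
                              call. = FALSE)
                       })
  if (!identical(manifest$schema_version, .archive_version)) {
    stop("model archive schema version mismatch (got ",
         manifest$schema_version, ", expected ", .archive_version, ")",
         call. = FALSE)
  }
  payload <- tryCatch(readRDS(est_path), error = function(e) {
    stop("corrupted estimator store: ", conditionMessage(e), call. = FALSE)
  })
  model <- structure(payload, class = "color_match_model")
  probes <- readr::read_csv(probe_path, show_col_types = FALSE,
                            progress = FALSE)
  pred <- predict_formula(model, probes)
  for (col in .pigment_cols) {
    if (max(abs(pred[[col]] - probes[[col]])) > 1e-9) {
      stop("model archive failed probe verification on ", col, call. = FALSE)
    }
  }
  if (!identical(as.integer(pred$cluster), as.integer(probes$cluster))) {
    stop("model archive failed probe cluster verification", call. = FALSE)
  }
  model
}
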