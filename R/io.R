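# CSV readers/writers for granule sample tables.
#
# Fixed dialect: comma separator, dot decimal, mandatory header. Column order
# sample_id,r,g,b[,caramel_mg,lemon_yellow_mg,carmine_mg,indigo_mg,excipient_g].

.pigment_cols <- c("caramel_mg", "lemon_yellow_mg", "carmine_mg", "indigo_mg")
.dose_cols <- c(.pigment_cols, "excipient_g")

.validate_granules <- function(df, kind, require_formula) {
  need <- c("sample_id", "r", "g", "b")
  if (require_formula) need <- c(need, .dose_cols)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(df)
  num_cols <- intersect(c("r", "g", "b", .dose_cols), names(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric value in column '", col, "' at data row ", bad,
           call. = FALSE)
    }
  }
  for (col in c("r", "g", "b")) {
    bad <- which(df[[col]] < 0 | df[[col]] > 255)
    if (length(bad) > 0) {
      stop("channel '", col, "' out of [0, 255] at data row ", bad[1],
           call. = FALSE)
    }
  }
  for (col in intersect(.pigment_cols, names(df))) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative dose in column '", col, "' at data row ", bad[1],
           call. = FALSE)
    }
  }
  if ("excipient_g" %in% names(df) && any(df$excipient_g <= 0)) {
    bad <- which(df$excipient_g <= 0)[1]
    stop("excipient_g must be positive at data row ", bad, call. = FALSE)
  }
  df
}

#' Read a granule sample table from CSV
#'
#' Reads and validates a sample library (`kind = "training"`: RGB plus pigment
#' doses per 20.00 g excipient batch), a query table (`kind = "query"`: RGB
#' only), or an evaluation table. Channel bounds and dose non-negativity are
#' enforced; errors name the offending row and column.
#'
#' @param path Path to a UTF-8 CSV file with header.
#' @param kind One of `"training"`, `"query"`, `"evaluation"`. Training tables
#'   must carry the four pigment dose columns and `excipient_g`.
#' @return A tibble, one row per sample.
#' @export
read_granules <- function(path, kind = c("training", "query", "evaluation")) {
  kind <- match.arg(kind)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .validate_granules(df, kind, require_formula = kind == "training")
}

#' Write a granule sample table to CSV
#'
#' Inverse of [read_granules()]: the written file reads back field-for-field,
#' doses at full double precision.
#'
#' @param data Tibble of samples (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_granules <- function(data, path) {
  has_formula <- all(.dose_cols %in% names(data))
  .validate_granules(data, kind = if (has_formula) "training" else "query",
                     require_formula = has_formula)
  keep <- intersect(
    c("sample_id", "r", "g", "b", .dose_cols, "cluster", "source"),
    names(data)
  )
  readr::write_csv(data[keep], path)
  invisible(path)
}

#' Printed external-validation color pairs
#'
#' The ten reference-granule / placebo color pairs used for external
#' validation, shipped with the package as plain CSV: RGB and CIELAB
#' coordinates for each side of each pair. These printed Lab values are
#' treated as authoritative inputs for delta-E evaluation.
#'
#' @return A tibble with columns `pair`, `ref_r/g/b`, `ref_L/a/b`,
#'   `plc_r/g/b`, `plc_L/a/b`.
#' @export
example_validation_pairs <- function() {
  path <- system.file("extdata", "validation_pairs.csv",
                      package = "placebocolor", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Printed manual similarity scores
#'
#' Per-formulation results of the 20-rater sensory comparison between
#' reference granules and placebos: mean and SD of the 0-3 similarity score
#' for each drug, the paired-test p-value, and the reported per-formulation
#' COS similarity.
#'
#' @return A tibble with columns `pair`, `tcm_mean`, `tcm_sd`, `placebo_mean`,
#'   `placebo_sd`, `p_value`, `cos`.
#' @export
example_manual_scores <- function() {
  path <- system.file("extdata", "manual_scores.csv",
                      package = "placebocolor", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
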