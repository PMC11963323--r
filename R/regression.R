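# Per-cluster regression competition: five model families (linear, ridge,
# SVR, random forest, gradient boosting) compete under repeated 5-fold CV
# with grid search; the winner inverts standardized RGB to pigment doses.
#
# Scores are computed from pooled out-of-fold predictions per repeat, per
# pigment, then macro-averaged over repeats and pigments. Pooling keeps R^2
# defined even when a near-constant target (indigo) happens to be constant
# within a single fold.

#' Root mean squared error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{m}\sum_i (y_i - \hat y_i)^2}}.
#'
#' @param y,yhat Numeric vectors of equal length (at least 2).
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}. The mean
#' predictor scores exactly 0; a constant observed vector leaves the ratio
#' undefined and raises an error.
#'
#' @param y,yhat Numeric vectors of equal length (at least 2).
#' @return Scalar no greater than 1.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stop("y and yhat must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for a constant observed vector", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

.safe_r2 <- function(y, yhat) {
  if (sum((y - mean(y))^2) == 0) return(NA_real_)
  r_squared(y, yhat)
}

#' Default hyperparameter grids for the model competition
#'
#' @return Named list of model families, each a list of candidate parameter
#'   sets. Families are tried in the fixed order linear, ridge, svr,
#'   random_forest, gradient_boosting (also the tie-break order).
#' @export
default_grids <- function() {
  as_grid <- function(df) purrr::map(seq_len(nrow(df)), ~ as.list(df[.x, ]))
  list(
    linear = list(list()),
    ridge = purrr::map(c(0.1, 1, 10), ~ list(lambda = .x)),
    svr = as_grid(expand.grid(cost = c(1, 10, 100), epsilon = c(0.1, 1))),
    random_forest = as_grid(expand.grid(num_trees = c(100, 300),
                                        max_depth = c(0, 5, 10),
                                        min_node = c(1, 3))),
    gradient_boosting = as_grid(expand.grid(nrounds = c(100, 300),
                                            eta = c(0.05, 0.1),
                                            max_depth = c(2, 3)))
  )
}

.family_order <- c("linear", "ridge", "svr", "random_forest",
                   "gradient_boosting")

# Fit one family on (x, y); returns an object predictable by .predict_family.
.fit_family <- function(family, params, x, y, seed = 42L) {
  x <- as.matrix(x)
  set.seed(seed)
  fit <- switch(family,
    linear = {
      qr <- stats::lm.fit(cbind(1, x), y)
      list(coef = qr$coefficients)
    },
    ridge = {
      # decreasing lambda path including the requested value; predictions use
      # the exact requested s
      glmnet::glmnet(x, y, alpha = 0,
                     lambda = sort(unique(c(10, 1, 0.1, params$lambda)),
                                   decreasing = TRUE)) |>
        (\(m) list(model = m, s = params$lambda))()
    },
    # cost and epsilon are on the raw dose scale (mg), so the target is not
    # internally rescaled; features are already standardized upstream
    svr = {
      # a target living entirely inside the epsilon tube leaves no support
      # vectors ("Model is empty"); predict the training mean in that case
      m <- tryCatch(
        e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, epsilon = params$epsilon,
                   scale = FALSE, fitted = FALSE),
        error = function(e) list(constant = mean(y)))
      if (!is.null(m$tot.nSV) && m$tot.nSV == 0) list(constant = mean(y)) else m
    },
    random_forest = ranger::ranger(
      y = y, x = as.data.frame(x),
      num.trees = params$num_trees,
      max.depth = params$max_depth,        # 0 = unlimited
      min.node.size = params$min_node,
      seed = seed, num.threads = 1),
    gradient_boosting = xgboost::xgboost(
      x, y,
      nrounds = params$nrounds, learning_rate = params$eta,
      max_depth = params$max_depth,
      objective = "reg:squarederror",
      nthreads = 1, verbosity = 0),
    stop("unknown model family: ", family, call. = FALSE)
  )
  structure(list(family = family, params = params, fit = fit),
            class = "pigment_estimator")
}

.predict_family <- function(est, x) {
  x <- as.matrix(x)
  switch(est$family,
    linear = as.numeric(cbind(1, x) %*% est$fit$coef),
    ridge = as.numeric(stats::predict(est$fit$model, newx = x,
                                      s = est$fit$s)),
    svr = if (is.list(est$fit) && !is.null(est$fit$constant)) {
      rep(est$fit$constant, nrow(x))
    } else {
      as.numeric(stats::predict(est$fit, x))
    },
    random_forest = stats::predict(est$fit,
                                   data = as.data.frame(x))$predictions,
    gradient_boosting = as.numeric(stats::predict(est$fit, x))
  )
}

# Disjoint exhaustive fold assignment, reproducible from the seed.
.make_folds <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

# Out-of-fold prediction matrix for one family/params over one fold split.
.oof_predict <- function(family, params, x, targets, fold_id, seed) {
  oof <- matrix(NA_real_, nrow(targets), ncol(targets),
                dimnames = dimnames(targets))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    for (j in seq_len(ncol(targets))) {
      est <- .fit_family(family, params, x[tr, , drop = FALSE],
                         targets[tr, j], seed = seed + j)
      oof[!tr, j] <- .predict_family(est, x[!tr, , drop = FALSE])
    }
  }
  oof
}

#' Run the per-cluster model competition
#'
#' For each model family: hyperparameters are grid-searched by out-of-fold
#' RMSE on the first fold split, then the best parameter set is scored with
#' repeated k-fold cross-validation — each repeat redraws the fold partition,
#' the model trains on k-1 folds and predicts the held-out fold, and RMSE and
#' R-squared are computed per pigment from the pooled out-of-fold predictions
#' and averaged over pigments and repeats.
#'
#' @param features Numeric matrix of standardized RGB (rows = samples of one
#'   cluster).
#' @param targets Numeric matrix of pigment doses (columns caramel, lemon
#'   yellow, carmine, indigo), in mg.
#' @param folds Number of CV folds (default 5). Reduced with a warning when
#'   the cluster has fewer than `2 * folds` samples.
#' @param repeats Number of fold-partition redraws (default 3).
#' @param seed Integer seed; the whole competition is deterministic given it.
#' @param grids Hyperparameter grids, as [default_grids()].
#' @return A tibble (the CV score table) with columns `model`, `mean_rmse`,
#'   `mean_r2`, `params` (list), `per_pigment` (list of per-pigment tibbles),
#'   ordered by the fixed family order.
#' @export
compete <- function(features, targets, folds = 5L, repeats = 3L, seed = 42L,
                    grids = default_grids()) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  n <- nrow(features)
  stopifnot(nrow(targets) == n)
  if (n < 2 * folds) {
    folds <- max(2L, n %/% 2L)
    warning("cluster too small for requested folds; reduced to ", folds)
  }
  fold_sets <- purrr::map(seq_len(repeats),
                          ~ .make_folds(n, folds, seed + 1000L * .x))
  families <- intersect(.family_order, names(grids))
  rows <- purrr::map(families, function(fam) {
    grid <- grids[[fam]]
    # grid selection on the first fold split only
    sel_scores <- purrr::map_dbl(grid, function(params) {
      oof <- .oof_predict(fam, params, features, targets, fold_sets[[1]], seed)
      mean(purrr::map_dbl(seq_len(ncol(targets)),
                          ~ rmse(targets[, .x], oof[, .x])))
    })
    best <- grid[[which.min(sel_scores)]]
    # repeated-CV scoring of the selected parameters
    per_rep <- purrr::map(fold_sets, function(fid) {
      oof <- .oof_predict(fam, best, features, targets, fid, seed)
      tibble::tibble(
        pigment = colnames(targets),
        rmse = purrr::map_dbl(seq_len(ncol(targets)),
                              ~ rmse(targets[, .x], oof[, .x])),
        r2 = purrr::map_dbl(seq_len(ncol(targets)),
                            ~ .safe_r2(targets[, .x], oof[, .x]))
      )
    })
    per_pigment <- dplyr::bind_rows(per_rep) |>
      dplyr::group_by(.data$pigment) |>
      dplyr::summarise(rmse = mean(.data$rmse),
                       r2 = mean(.data$r2, na.rm = TRUE) |>
                         (\(v) ifelse(is.nan(v), NA_real_, v))(),
                       .groups = "drop")
    tibble::tibble(
      model = fam,
      mean_rmse = mean(per_pigment$rmse),
      mean_r2 = mean(per_pigment$r2, na.rm = TRUE),
      params = list(best),
      per_pigment = list(per_pigment)
    )
  })
  dplyr::bind_rows(rows)
}

#' Select the winning model family from a CV score table
#'
#' Minimal mean RMSE wins; ties go to the higher mean R-squared, then to the
#' fixed family order (linear, ridge, svr, random_forest, gradient_boosting).
#'
#' @param cv_table Tibble as returned by [compete()].
#' @return The winning model name (character scalar).
#' @export
select_winner <- function(cv_table) {
  stopifnot(nrow(cv_table) >= 1)
  ord <- order(cv_table$mean_rmse, -cv_table$mean_r2,
               match(cv_table$model, .family_order))
  cv_table$model[ord[1]]
}

# Refit the winner on the full cluster, one estimator per pigment.
.fit_cluster_final <- function(features, targets, winner, params, seed) {
  purrr::map(seq_len(ncol(targets)), function(j) {
    .fit_family(winner, params, features, targets[, j], seed = seed + j)
  }) |>
    stats::setNames(colnames(targets))
}
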