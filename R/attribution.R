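# Exact Shapley attribution of RGB channel contributions to pigment-dose
# predictions. With 3 features there are only 2^3 = 8 coalitions, so the
# Shapley values are computed exactly by enumeration — no sampling.
#
# The value of a coalition S is interventional (marginal): the mean prediction
# over background rows with the coalition's channels set to the query's values
# and the rest taken from the background row.

.coalition_value <- function(predict_fun, background, x, mask) {
  n <- nrow(background)
  grid <- background
  for (j in which(mask)) grid[, j] <- x[j]
  mean(predict_fun(grid))
}

#' Exact Shapley attribution for one color
#'
#' Computes the exact Shapley decomposition of `predict_fun(x)` minus the mean
#' background prediction into per-channel contributions, enumerating all
#' coalitions of the three RGB features with the classical weights
#' \eqn{|S|!(p-|S|-1)!/p!}. Satisfies efficiency exactly:
#' `sum(phi) == prediction - base_value` (to numerical precision).
#'
#' @param predict_fun Function taking an n x 3 feature matrix and returning n
#'   predictions.
#' @param background Non-empty numeric matrix of background feature rows (same
#'   space as `x`).
#' @param x Length-3 numeric feature vector to explain.
#' @return A list with `phi` (named length-3 vector, dose units),
#'   `base_value` (mean background prediction) and `prediction`.
#' @export
exact_shapley <- function(predict_fun, background, x) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background set is empty", call. = FALSE)
  p <- 3L
  stopifnot(length(x) == p, ncol(background) == p)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  vals <- apply(masks, 1, function(m) {
    .coalition_value(predict_fun, background, x, m)
  })
  key <- function(m) sum(m * 2^(0:(p - 1))) + 1
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(masks))) {
      m <- masks[r, ]
      if (m[i]) next
      s <- sum(m)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      m_with <- m
      m_with[i] <- TRUE
      phi[i] <- phi[i] + w * (vals[key(m_with)] - vals[key(m)])
    }
  }
  names(phi) <- colnames(background) %||% c("r", "g", "b")
  list(phi = phi,
       base_value = vals[key(rep(FALSE, p))],
       prediction = vals[key(rep(TRUE, p))])
}

#' Per-sample Shapley attributions for a fitted model
#'
#' Explains each sample's predicted dose of each pigment as per-channel
#' contributions, using the model's own cluster estimators and (a seeded
#' subsample of) the explained samples as background.
#'
#' @param model A fitted `color_match_model`.
#' @param data Tibble with columns `r`, `g`, `b` (colors to explain).
#' @param background_cap Maximum background rows (seeded subsample beyond it).
#' @param seed Seed for the background subsample.
#' @return A tibble with one row per sample x pigment: `sample`, `cluster`,
#'   `pigment`, `phi_r`, `phi_g`, `phi_b`, `base_value`, `prediction`.
#' @export
shapley_attributions <- function(model, data, background_cap = 200L,
                                 seed = 42L) {
  stopifnot(inherits(model, "color_match_model"))
  feats <- standardize(model$standardizer, data)
  cl <- assign_cluster(model$clusters, feats)
  out <- list()
  for (c_i in sort(unique(cl))) {
    idx <- which(cl == c_i)
    bg <- feats[idx, , drop = FALSE]
    if (nrow(bg) > background_cap) {
      set.seed(seed)
      bg <- bg[sample(nrow(bg), background_cap), , drop = FALSE]
    }
    for (p in .pigment_cols) {
      est <- model$estimators[[c_i]][[p]]
      pf <- function(m) .predict_family(est, m)
      shap <- purrr::map(idx, function(i) {
        sh <- exact_shapley(pf, bg, feats[i, ])
        tibble::tibble(sample = i, cluster = c_i, pigment = p,
                       phi_r = sh$phi[["r"]], phi_g = sh$phi[["g"]],
                       phi_b = sh$phi[["b"]], base_value = sh$base_value,
                       prediction = sh$prediction)
      })
      out <- c(out, shap)
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$sample, .data$pigment)
}

#' Dominant channel per pigment per cluster
#'
#' Global attribution summary: for each cluster and pigment, the channel with
#' the largest mean absolute Shapley contribution, and the sign of its
#' association (sign of the correlation between the channel's standardized
#' value and its contribution).
#'
#' @param model A fitted `color_match_model`.
#' @param data Tibble of colors to attribute over (typically the training
#'   library).
#' @param background_cap,seed Passed to [shapley_attributions()].
#' @return A tibble with `cluster`, `pigment`, `dominant_channel`,
#'   `mean_abs_phi_r/g/b`, `sign` (+1/-1).
#' @export
dominance_report <- function(model, data, background_cap = 200L, seed = 42L) {
  shap <- shapley_attributions(model, data, background_cap = background_cap,
                               seed = seed)
  feats <- standardize(model$standardizer, data)
  shap |>
    dplyr::group_by(.data$cluster, .data$pigment) |>
    dplyr::group_modify(function(df, key) {
      mabs <- c(r = mean(abs(df$phi_r)), g = mean(abs(df$phi_g)),
                b = mean(abs(df$phi_b)))
      dom <- names(mabs)[which.max(mabs)]
      fv <- feats[df$sample, dom]
      phi <- df[[paste0("phi_", dom)]]
      degenerate <- length(fv) < 2 || stats::sd(fv) == 0 ||
        stats::sd(phi) == 0
      assoc <- if (isTRUE(degenerate) || is.na(degenerate)) 0 else {
        sign(stats::cor(fv, phi))
      }
      tibble::tibble(dominant_channel = dom,
                     mean_abs_phi_r = mabs[["r"]],
                     mean_abs_phi_g = mabs[["g"]],
                     mean_abs_phi_b = mabs[["b"]],
                     sign = assoc)
    }) |>
    dplyr::ungroup()
}
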