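# k-means clustering of standardized colors with SSE and silhouette
# diagnostics, and joint k selection over a scanned range.
#
# Distances are Euclidean in standardized RGB space throughout. k-means is
# stats::kmeans with multiple random restarts; the best restart by SSE wins.

#' Fit k-means to standardized color features
#'
#' @param features Numeric matrix of standardized colors (rows = samples).
#' @param k Number of clusters, `2 <= k <= nrow(features)`.
#' @param seed Integer seed controlling the restarts.
#' @param nstart Number of random restarts (best SSE kept).
#' @param iter_max Maximum iterations per restart.
#' @return An object of class `cluster_model` with elements `k`, `centers`,
#'   `labels` (1-based), `sse`, `mean_silhouette` (NA when any cluster is
#'   empty of a companion, see [mean_silhouette()]), and `seed`.
#' @export
kmeans_fit <- function(features, k, seed = 42L, nstart = 10L, iter_max = 300L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  distinct <- unique(features)
  if (nrow(distinct) < k) {
    # Degenerate: fewer distinct points than clusters. Deterministic fallback:
    # each distinct point is a centroid (padding by repeating the first), and
    # every sample joins the lowest-index centroid at distance zero.
    centers <- distinct[rep(seq_len(nrow(distinct)),
                            length.out = k), , drop = FALSE]
    labels <- apply(.sq_dists(features, centers), 1, which.min)
    model <- structure(
      list(k = k, centers = centers, labels = as.integer(labels),
           sse = 0, mean_silhouette = NA_real_, seed = as.integer(seed)),
      class = "cluster_model")
    return(model)
  }
  if (nrow(distinct) == k) {
    # one centroid per distinct point is the exact optimum (SSE over
    # duplicates only); bypass the iterative fit
    labels <- apply(.sq_dists(features, distinct), 1, which.min)
    centers <- distinct
    sse <- cluster_sse(features, labels, centers)
    sil <- if (length(unique(labels)) >= 2) {
      mean_silhouette(features, labels)
    } else {
      NA_real_
    }
    return(structure(
      list(k = k, centers = centers, labels = as.integer(labels),
           sse = sse, mean_silhouette = sil, seed = as.integer(seed)),
      class = "cluster_model"))
  }
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = nstart,
                      iter.max = iter_max)
  sil <- if (k >= 2 && length(unique(km$cluster)) >= 2) {
    mean_silhouette(features, km$cluster)
  } else {
    NA_real_
  }
  structure(
    list(k = k, centers = km$centers, labels = as.integer(km$cluster),
         sse = km$tot.withinss, mean_silhouette = sil,
         seed = as.integer(seed)),
    class = "cluster_model")
}

# Squared Euclidean distances between rows of x and rows of centers.
.sq_dists <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Within-cluster sum of squared errors
#'
#' \eqn{SSE = \sum_i dist(x_i, u_{c(i)})^2}: cohesion of a clustering,
#' summing each point's squared Euclidean distance to its assigned centroid.
#'
#' @param features Numeric matrix of points.
#' @param labels Integer cluster assignments (1-based).
#' @param centers Matrix of centroids, one row per cluster.
#' @return Non-negative scalar.
#' @export
cluster_sse <- function(features, labels, centers) {
  features <- as.matrix(features)
  centers <- as.matrix(centers)
  sum((features - centers[labels, , drop = FALSE])^2)
}

#' Mean silhouette coefficient
#'
#' For each point, \eqn{s = (b - a) / \max(a, b)} where `a` is the mean
#' distance to the other members of its own cluster and `b` the smallest mean
#' distance to the members of any other cluster; the mean over points grades
#' the clustering (singletons score 0 by convention).
#'
#' @param features Numeric matrix of points.
#' @param labels Integer cluster assignments with at least 2 distinct values.
#' @return Scalar in `[-1, 1]`.
#' @export
mean_silhouette <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  if (all(tabulate(labels) <= 1)) return(0)  # all singletons: s = 0 each
  sil <- cluster::silhouette(labels, stats::dist(features))
  mean(sil[, "sil_width"])
}

#' Scan cluster counts and choose k
#'
#' Fits k-means for every candidate `k`, recording SSE and mean silhouette.
#' The chosen `k` maximizes the mean silhouette (ties broken toward smaller
#' `k`); the elbow of the SSE curve (largest second difference) is reported as
#' a diagnostic, mirroring the joint elbow/silhouette reading of the curves.
#'
#' @param features Numeric matrix of standardized colors.
#' @param k_range Candidate cluster counts (default 2 to 11). Truncated with a
#'   warning if it exceeds the sample count.
#' @param seed Integer seed.
#' @return An object of class `k_scan`: a list with `metrics` (tibble of `k`,
#'   `sse`, `silhouette`), `chosen_k`, `elbow_k`, `models` (per-k fits) and
#'   `rationale`.
#' @export
scan_k <- function(features, k_range = 2:11, seed = 42L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (max(k_range) > n) {
    warning("k range truncated to the sample count (", n, ")")
    k_range <- k_range[k_range <= n]
  }
  if (length(k_range) == 0) stop("no feasible k in range", call. = FALSE)
  models <- purrr::map(k_range, function(k) kmeans_fit(features, k, seed = seed))
  metrics <- tibble::tibble(
    k = as.integer(k_range),
    sse = purrr::map_dbl(models, "sse"),
    silhouette = purrr::map_dbl(models, "mean_silhouette")
  )
  chosen_k <- metrics$k[which.max(metrics$silhouette)]  # first max: smaller k
  elbow_k <- if (nrow(metrics) >= 3) {
    d2 <- diff(metrics$sse, differences = 2)
    metrics$k[which.max(d2) + 1]
  } else {
    metrics$k[1]
  }
  structure(
    list(
      metrics = metrics,
      chosen_k = chosen_k,
      elbow_k = elbow_k,
      models = stats::setNames(models, paste0("k", k_range)),
      rationale = sprintf(
        "k = %d attains the maximum mean silhouette (%.4f); SSE elbow at k = %d.",
        chosen_k, max(metrics$silhouette), elbow_k)
    ),
    class = "k_scan")
}

#' Assign new colors to fitted clusters
#'
#' Standardizes new colors with the training standardizer and labels each with
#' its nearest centroid (ties go to the lowest-index centroid).
#'
#' @param model A `cluster_model`.
#' @param data Data frame with columns `r`, `g`, `b`, or a matrix already in
#'   standardized space if `standardizer` is NULL.
#' @param standardizer The training [fit_standardizer()] object (NULL if
#'   `data` is already standardized).
#' @return Integer vector of 1-based cluster labels.
#' @export
assign_cluster <- function(model, data, standardizer = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  feats <- if (is.null(standardizer)) as.matrix(data) else {
    standardize(standardizer, data)
  }
  as.integer(apply(.sq_dists(feats, model$centers), 1, which.min))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, " SSE =", signif(x$sse, 6),
      " mean silhouette =", signif(x$mean_silhouette, 4), "\n")
  invisible(x)
}

#' @export
print.k_scan <- function(x, ...) {
  cat("<k_scan>", x$rationale, "\n")
  print(x$metrics)
  invisible(x)
}
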