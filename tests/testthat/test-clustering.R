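test_that("kmeans_fit recovers the obvious 2-partition with the exact SSE", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(11, 0, 0))
  m <- kmeans_fit(x, k = 2, seed = 1)
  expect_setequal(split(seq_len(4), m$labels) |> lengths(), c(2, 2))
  expect_equal(m$labels[1], m$labels[2])
  expect_equal(m$labels[3], m$labels[4])
  expect_equal(m$sse, 1.0, tolerance = 1e-12)  # 4 * 0.5^2
})

test_that("degenerate inputs are handled deterministically", {
  same <- matrix(1, nrow = 5, ncol = 3)
  m <- kmeans_fit(same, k = 2, seed = 1)
  expect_equal(m$sse, 0)
  expect_true(all(m$labels == m$labels[1]))
  # k = n puts every point in its own cluster
  x <- matrix(rnorm(12), 4, 3)
  m2 <- kmeans_fit(x, k = 4, seed = 1)
  expect_equal(m2$sse, 0, tolerance = 1e-12)
  expect_equal(sort(unique(m2$labels)), 1:4)
  expect_error(kmeans_fit(x, k = 5), "exceeds")
})

test_that("best-restart SSE attains the brute-force optimum on tiny instances", {
  hits <- 0
  for (trial in 1:20) {
    set.seed(trial)
    x <- matrix(runif(7 * 3, 0, 10), 7, 3)
    m <- kmeans_fit(x, k = 2, seed = trial)
    best <- oracle_best_sse_k2(x)
    expect_equal(oracle_sse(x, m$labels, m$centers), m$sse, tolerance = 1e-9)
    if (m$sse <= best + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of seeded trials
})

test_that("cluster_sse matches the definitional oracle", {
  expect_equal(cluster_sse(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1),
                           rbind(c(1, 0, 0))), 2)
  set.seed(31)
  x <- matrix(runif(30), 10, 3)
  labels <- sample(1:3, 10, replace = TRUE)
  centers <- rbind(colMeans(x[labels == 1, , drop = FALSE]),
                   colMeans(x[labels == 2, , drop = FALSE]),
                   colMeans(x[labels == 3, , drop = FALSE]))
  expect_equal(cluster_sse(x, labels, centers),
               oracle_sse(x, labels, centers), tolerance = 1e-12)
})

test_that("mean_silhouette matches hand computation and the pairwise oracle", {
  # colinear points 0, 1, 10, 11 split in the middle:
  # s = mean(9.5/10.5, 8.5/9.5, 8.5/9.5, 9.5/10.5) = 0.89975...
  x <- cbind(c(0, 1, 10, 11), 0, 0)
  s <- mean_silhouette(x, c(1, 1, 2, 2))
  expect_equal(s, mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-12)
  # singleton clusters score 0 by convention
  z1 <- rbind(c(0, 0, 0), c(5, 0, 0), c(5.5, 0, 0))
  sil <- mean_silhouette(z1, c(1, 2, 2))
  expect_equal(sil, oracle_mean_silhouette(z1, c(1, 2, 2)), tolerance = 1e-12)
  expect_error(mean_silhouette(x, c(1, 1, 1, 1)), "single cluster")
  set.seed(32)
  for (trial in 1:10) {
    z <- matrix(runif(24), 8, 3)
    labels <- sample(1:3, 8, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(mean_silhouette(z, labels),
                 oracle_mean_silhouette(z, labels), tolerance = 1e-12)
  }
})

test_that("scan_k recovers the generative component count", {
  two <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0)), n_per = 50, seed = 41)
  scan2 <- scan_k(two, k_range = 2:6, seed = 41)
  expect_equal(scan2$chosen_k, 2L)
  three <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                      n_per = 34, seed = 42)
  scan3 <- scan_k(three, k_range = 2:6, seed = 42)
  expect_equal(scan3$chosen_k, 3L)
  # SSE never increases with k
  expect_true(all(diff(scan2$metrics$sse) <= 1e-9))
  expect_true(all(diff(scan3$metrics$sse) <= 1e-9))
  # chosen k attains the silhouette maximum
  expect_equal(scan2$metrics$silhouette[scan2$metrics$k == scan2$chosen_k],
               max(scan2$metrics$silhouette))
})

test_that("scan_k truncates an infeasible k range with a warning", {
  x <- matrix(runif(15), 5, 3)
  expect_warning(scan <- scan_k(x, k_range = 2:11, seed = 1), "truncated")
  expect_lte(max(scan$metrics$k), 5)
})

test_that("assign_cluster labels by nearest centroid with low-index ties", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(11, 0, 0))
  m <- kmeans_fit(x, k = 2, seed = 1)
  expect_equal(assign_cluster(m, x), m$labels)
  # the exact midpoint between the two centroids takes the lower label index
  mid <- matrix((m$centers[1, ] + m$centers[2, ]) / 2, nrow = 1)
  expect_equal(assign_cluster(m, mid), 1L)
  # a fresh draw near a blob gets that blob's label
  blob_label <- m$labels[1]
  expect_equal(assign_cluster(m, matrix(c(0.4, 0, 0), 1)), blob_label)
})
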