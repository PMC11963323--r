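# Independent brute-force oracles. Each is coded from the defining formula,
# separately from the package implementation it checks.

# Inverse of the sRGB -> Lab chain: Lab -> XYZ -> linear RGB -> companded RGB.
oracle_lab_to_rgb <- function(L, a, b) {
  xyz_to_rgb <- solve(matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041
  ), nrow = 3, byrow = TRUE))
  white <- c(0.9504559, 1, 1.0890578)  # matrix row sums (D65)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx) * white[1], finv(fy) * white[2], finv(fz) * white[3])
  lin <- xyz %*% t(xyz_to_rgb)
  comp <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * lin^(1 / 2.4) - 0.055)
  comp * 255
}

# Mean silhouette by the definition, double loop over points and clusters.
oracle_mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# SSE by definition.
oracle_sse <- function(x, labels, centers) {
  x <- as.matrix(x)
  total <- 0
  for (i in seq_len(nrow(x))) {
    total <- total + sum((x[i, ] - centers[labels[i], ])^2)
  }
  total
}

# Globally optimal 2-cluster SSE by enumerating all label assignments.
oracle_best_sse_k2 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2) next
    centers <- rbind(colMeans(x[lab == 1, , drop = FALSE]),
                     colMeans(x[lab == 2, , drop = FALSE]))
    best <- min(best, oracle_sse(x, lab, centers))
  }
  best
}

# Shapley values via the permutation formulation: mean over all 3! orderings
# of each feature's marginal contribution, with interventional coalition
# values. Independent of the coalition-weight implementation.
oracle_shapley <- function(predict_fun, background, x) {
  background <- as.matrix(background)
  p <- length(x)
  value <- function(mask) {
    grid <- background
    for (j in which(mask)) grid[, j] <- x[j]
    mean(predict_fun(grid))
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  phi <- numeric(p)
  for (perm in perms) {
    mask <- rep(FALSE, p)
    prev <- value(mask)
    for (j in perm) {
      mask[j] <- TRUE
      cur <- value(mask)
      phi[j] <- phi[j] + (cur - prev) / length(perms)
      prev <- cur
    }
  }
  phi
}

# Paired t-test p-value from the hand formula plus the t distribution.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Well-separated Gaussian blobs for k-recovery tests.
make_blobs <- function(centers, n_per, sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(stats::rnorm(n_per * 3, sd = sd), n_per, 3) +
      matrix(centers[i, ], n_per, 3, byrow = TRUE)
  }))
}

# Small training tibble through the noise-free forward model.
make_tiny_library <- function(n = 60, seed = 1, noise_sd = 0) {
  simulate_granules(n, forward_model(noise_sd = noise_sd), seed = seed)
}

# Lean hyperparameter grids to keep unit-test competitions fast.
tiny_grids <- function() {
  list(
    linear = list(list()),
    ridge = list(list(lambda = 1)),
    random_forest = list(list(num_trees = 100, max_depth = 5, min_node = 3))
  )
}
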