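test_that("additive predictors separate exactly", {
  set.seed(61)
  bg <- matrix(runif(60, -2, 2), 20, 3, dimnames = list(NULL, c("r", "g", "b")))
  x <- c(0.5, -1, 2)
  f <- function(m) m[, 1] + m[, 2] + m[, 3]
  sh <- exact_shapley(f, bg, x)
  expect_equal(unname(sh$phi), unname(x - colMeans(bg)), tolerance = 1e-12)
  expect_equal(sum(sh$phi), sh$prediction - sh$base_value, tolerance = 1e-12)
  # constant predictor attributes nothing
  sh0 <- exact_shapley(function(m) rep(3, nrow(m)), bg, x)
  expect_equal(unname(sh0$phi), c(0, 0, 0))
})

test_that("exact Shapley matches the permutation oracle on nonlinear models", {
  set.seed(62)
  bg <- matrix(runif(45, -1, 1), 15, 3, dimnames = list(NULL, c("r", "g", "b")))
  f <- function(m) exp(-m[, 1]) * (1 + m[, 2]^2) - 0.5 * m[, 1] * m[, 3]
  for (i in 1:5) {
    x <- runif(3, -1, 1)
    sh <- exact_shapley(f, bg, x)
    expect_equal(unname(sh$phi), oracle_shapley(f, bg, x), tolerance = 1e-9)
    expect_equal(sum(sh$phi), sh$prediction - sh$base_value, tolerance = 1e-9)
  }
})

test_that("Shapley axioms hold: efficiency, dummy, symmetry", {
  set.seed(63)
  bg <- matrix(runif(30, 0, 1), 10, 3, dimnames = list(NULL, c("r", "g", "b")))
  # dummy: a predictor ignoring g attributes exactly zero to g
  f_dummy <- function(m) m[, 1]^2 - 3 * m[, 3]
  sh <- exact_shapley(f_dummy, bg, c(0.3, 0.9, 0.1))
  expect_identical(sh$phi[["g"]], 0)
  # symmetry: identical columns and equal inputs receive equal credit
  bg_sym <- bg; bg_sym[, 3] <- bg_sym[, 1]
  f_sym <- function(m) (m[, 1] + m[, 3])^2
  sh_sym <- exact_shapley(f_sym, bg_sym, c(0.4, 0.7, 0.4))
  expect_equal(sh_sym$phi[["r"]], sh_sym$phi[["b"]], tolerance = 1e-12)
  expect_error(exact_shapley(f_dummy, bg[0, ], c(1, 1, 1)), "empty")
})

test_that("efficiency holds for fitted tree-ensemble predictors", {
  lib <- make_tiny_library(n = 60, seed = 64, noise_sd = 2)
  model <- fit_color_model(lib, k_range = 2:2, seed = 64,
                           grids = list(random_forest = list(
                             list(num_trees = 50, max_depth = 5,
                                  min_node = 3))))
  shap <- shapley_attributions(model, lib[1:8, ], background_cap = 30,
                               seed = 64)
  expect_equal(shap$phi_r + shap$phi_g + shap$phi_b,
               shap$prediction - shap$base_value, tolerance = 1e-9)
})

test_that("dominance report flags the generating channel", {
  # a dose driven solely by the b channel must be dominated by b, and the
  # association sign must match the direction of the dependence
  set.seed(65)
  bg <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("r", "g", "b")))
  f <- function(m) -5 * m[, 3]
  phis <- t(vapply(seq_len(10),
                   function(i) exact_shapley(f, bg, rnorm(3))$phi,
                   numeric(3)))
  expect_equal(colnames(phis)[which.max(colMeans(abs(phis)))], "b")
  expect_equal(unname(colMeans(abs(phis))[1:2]), c(0, 0))
  # single sample: the report reduces to that sample's |phi| ranking
  lib <- make_tiny_library(n = 50, seed = 65, noise_sd = 0)
  model <- fit_color_model(lib, k_range = 2:2, seed = 65,
                           grids = tiny_grids())
  one <- dominance_report(model, lib[3, ], background_cap = 10, seed = 65)
  shap_one <- shapley_attributions(model, lib[3, ], background_cap = 10,
                                   seed = 65)
  for (i in seq_len(nrow(one))) {
    row <- shap_one[shap_one$pigment == one$pigment[i], ]
    mabs <- c(r = abs(row$phi_r), g = abs(row$phi_g), b = abs(row$phi_b))
    expect_equal(one$dominant_channel[i], names(mabs)[which.max(mabs)])
  }
})
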