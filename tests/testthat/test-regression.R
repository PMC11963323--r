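test_that("rmse and r_squared match the defining formulas", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(0, 2), c(1, 1)), 1)            # SS_res = 2, m = 2
  expect_equal(r_squared(c(0, 2), c(1, 1)), 0)       # mean predictor
  set.seed(51)
  for (i in 1:20) {
    y <- rnorm(15); yhat <- rnorm(15)
    expect_equal(rmse(y, yhat), sqrt(sum((y - yhat)^2) / 15),
                 tolerance = 1e-12)
    expect_equal(r_squared(y, yhat),
                 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rmse(1, 1), "length")
})

test_that("cross-validation folds are disjoint, exhaustive, seeded", {
  f1 <- placebocolor:::.make_folds(47, 5, seed = 7)
  f2 <- placebocolor:::.make_folds(47, 5, seed = 7)
  f3 <- placebocolor:::.make_folds(47, 5, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_setequal(unique(f1), 1:5)
  expect_true(all(table(f1) %in% c(9, 10)))
})

test_that("a realizable linear inverse map gives the linear family r2 = 1", {
  # noise-free linear color <- dose system, inverted: dose is an exact linear
  # function of the channels
  set.seed(52)
  n <- 60
  caramel <- runif(n, 0, 100); lemon <- runif(n, 0, 50)
  carmine <- runif(n, 0, 80)
  doses <- cbind(caramel_mg = caramel, lemon_yellow_mg = lemon,
                 carmine_mg = carmine,
                 # three channels determine at most three independent doses;
                 # tie the fourth to the others so the inverse stays linear
                 indigo_mg = 0.3 * caramel + 0.1 * lemon)
  A <- matrix(c(-0.2, -0.1, -0.05, -0.3,
                -0.05, -0.3, -0.2, -0.1,
                -0.1, -0.02, -0.3, -0.25), nrow = 3, byrow = TRUE)
  colors <- 250 + doses %*% t(A) / 10
  feats <- scale(colors)
  tab <- compete(feats, doses, folds = 5, repeats = 2, seed = 52,
                 grids = list(linear = list(list())))
  expect_equal(tab$mean_r2, 1, tolerance = 1e-6)
  expect_lt(tab$mean_rmse, 1e-3)
})

test_that("shuffled targets score near zero for every family", {
  lib <- make_tiny_library(n = 80, seed = 53, noise_sd = 2)
  set.seed(53)
  targets <- as.matrix(lib[sample(80), c("caramel_mg", "lemon_yellow_mg",
                                         "carmine_mg", "indigo_mg")])
  feats <- standardize(fit_standardizer(lib), lib)
  tab <- compete(feats, targets, folds = 5, repeats = 1, seed = 53,
                 grids = tiny_grids())
  expect_true(all(tab$mean_r2 <= 0.1))
})

test_that("select_winner picks minimal RMSE with deterministic tie-breaks", {
  tab <- tibble::tibble(
    model = c("linear", "random_forest", "gradient_boosting", "svr", "ridge"),
    mean_rmse = c(56.5449, 20.6466, 30.7755, 78.7574, 56.5589),
    mean_r2 = c(0.4618, 0.9305, 0.8382, 0.2451, 0.4614))
  expect_equal(select_winner(tab), "random_forest")
  tie <- tibble::tibble(model = c("svr", "ridge", "linear"),
                        mean_rmse = c(1, 1, 1), mean_r2 = c(0.5, 0.5, 0.5))
  expect_equal(select_winner(tie), "linear")  # fixed family order
  one <- tibble::tibble(model = "ridge", mean_rmse = 2, mean_r2 = 0.9)
  expect_equal(select_winner(one), "ridge")
})

test_that("compete reduces folds with a warning on small clusters", {
  lib <- make_tiny_library(n = 8, seed = 54, noise_sd = 0)
  feats <- standardize(fit_standardizer(lib), lib)
  targets <- as.matrix(lib[, c("caramel_mg", "lemon_yellow_mg",
                               "carmine_mg", "indigo_mg")])
  expect_warning(
    tab <- compete(feats, targets, folds = 5, repeats = 1, seed = 54,
                   grids = list(linear = list(list()))),
    "reduced")
  expect_equal(nrow(tab), 1)
})

test_that("fitted model predicts training formulas and clamps negatives", {
  lib <- make_tiny_library(n = 80, seed = 55, noise_sd = 0)
  model <- fit_color_model(lib, k_range = 2:3, seed = 55,
                           grids = tiny_grids())
  # four estimators per cluster
  expect_true(all(vapply(model$estimators, length, integer(1)) == 4))
  # winner has the minimal mean RMSE in its cluster's table
  for (cl in seq_along(model$winners)) {
    tab <- model$cv_tables[[cl]]
    expect_equal(tab$mean_rmse[match(model$winners[cl], tab$model)],
                 min(tab$mean_rmse))
  }
  # noise-free training colors map back near their training doses
  pred <- predict_formula(model, lib)
  expect_gt(cor(pred$caramel_mg, lib$caramel_mg), 0.97)
  expect_true(all(pred$caramel_mg >= 0))
  expect_true(all(pred$excipient_g == 20))
  # doses are printed at manufacturing precision
  expect_equal(pred$caramel_mg, round(pred$caramel_mg, 2))
  # refits are deterministic at a fixed seed
  model2 <- fit_color_model(lib, k_range = 2:3, seed = 55,
                            grids = tiny_grids())
  expect_equal(predict_formula(model2, lib), pred)
})

test_that("predict_formula handles empty and invalid queries", {
  lib <- make_tiny_library(n = 60, seed = 56, noise_sd = 2)
  model <- fit_color_model(lib, k_range = 2:2, seed = 56,
                           grids = tiny_grids())
  empty <- predict_formula(model, lib[0, c("sample_id", "r", "g", "b")])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("caramel_mg", "excipient_g") %in% names(empty)))
  expect_error(predict_formula(model, tibble::tibble(r = 300, g = 0, b = 0)),
               "0, 255")
})
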