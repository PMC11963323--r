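test_that("forward_mix reproduces closed-form attenuation", {
  # zero doses, zero noise: the base color exactly
  fm <- forward_model(noise_sd = 0)
  zero <- tibble::tibble(caramel_mg = 0, lemon_yellow_mg = 0, carmine_mg = 0,
                         indigo_mg = 0)
  expect_equal(as.numeric(forward_mix(fm, zero)),
               unname(fm$base_color), tolerance = 1e-12)
  # single pigment: channel = base * exp(-K * dose)
  K <- matrix(c(0.001, rep(1e-9, 3),
                1e-9, rep(1e-9, 3),
                1e-9, rep(1e-9, 3)), nrow = 3, byrow = TRUE)
  fm2 <- forward_model(K = K, base_color = c(255, 255, 255), noise_sd = 0)
  one <- tibble::tibble(caramel_mg = 500, lemon_yellow_mg = 0,
                        carmine_mg = 0, indigo_mg = 0)
  expect_equal(unname(forward_mix(fm2, one)$r), 255 * exp(-0.5),
               tolerance = 1e-6)
  expect_error(forward_mix(fm, dplyr::mutate(zero, caramel_mg = -1)),
               "non-negative")
})

test_that("every channel strictly decreases in every dose (noise off)", {
  fm <- forward_model(noise_sd = 0)
  base_formula <- tibble::tibble(caramel_mg = 100, lemon_yellow_mg = 20,
                                 carmine_mg = 30, indigo_mg = 0.2)
  before <- as.numeric(forward_mix(fm, base_formula))
  for (col in c("caramel_mg", "lemon_yellow_mg", "carmine_mg", "indigo_mg")) {
    bumped <- base_formula
    bumped[[col]] <- bumped[[col]] + 10
    after <- as.numeric(forward_mix(fm, bumped))
    expect_true(all(after < before))
  }
})

test_that("the simulated library matches its design contract", {
  lib <- simulate_granules(323, seed = 1)
  expect_equal(nrow(lib), 323)
  expect_true(all(c("caramel_mg", "lemon_yellow_mg", "carmine_mg",
                    "indigo_mg") %in% names(lib)))
  expect_true(all(lib$source == "simulated"))
  # reproducible byte-for-byte from the seed
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_granules(simulate_granules(100, seed = 5), path1)
  write_granules(simulate_granules(100, seed = 5), path2)
  expect_identical(readLines(path1), readLines(path2))
  expect_error(simulate_granules(1), "n >= 2")
})

test_that("generated color spans sit near the published simulated ranges", {
  lib <- simulate_granules(323, seed = 1)
  expect_lt(abs(min(lib$r) - 63), 15)
  expect_lt(abs(min(lib$g) - 54), 15)
  expect_lt(abs(min(lib$b) - 32), 15)
  expect_lt(abs(max(lib$r) - 255), 15)
  expect_lt(abs(max(lib$g) - 255), 15)
  expect_lt(abs(max(lib$b) - 255), 15)
})

test_that("the two-regime design yields two well-separated color clusters", {
  lib <- simulate_granules(323, seed = 1)
  feats <- standardize(fit_standardizer(lib), lib)
  m <- kmeans_fit(feats, k = 2, seed = 1)
  expect_gte(m$mean_silhouette, 0.5)
})

test_that("generate_queries returns fresh samples with retained truth", {
  q <- generate_queries(10, seed = 77)
  expect_equal(nrow(q), 10)
  expect_true(all(q$source == "query"))
  expect_true(all(q$caramel_mg >= 0))
  expect_equal(nrow(generate_queries(0)), 0)
  # different seeds give different colors
  expect_false(identical(generate_queries(10, seed = 78)$r, q$r))
})
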