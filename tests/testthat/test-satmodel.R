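# Satellite network: pairing, forward algebra, Levenberg-Marquardt
# training, prediction, data-volume experiment.

make_linear_pairs <- function(n = 1500, noise = 0, seed = 2) {
  withr::with_seed(seed, {
    X <- matrix(runif(3 * n), ncol = 3)
    colnames(X) <- satellite_bands()
    df <- as.data.frame(X)
    df$label <- 0.2 * df$green + 0.5 * df$red + 0.3 * df$nir +
      rnorm(n, sd = noise)
    df$label <- pmin(pmax(df$label, 0), 1)
    df
  })
}

test_that("pairing keeps exactly the cells valid in both rasters", {
  arr <- array(0.3, c(10, 10, 3), dimnames = list(NULL, NULL, satellite_bands()))
  sat <- scene_raster(arr, gsd = 2, bands = satellite_bands())
  lab <- scene_raster(matrix(runif(100), 10, 10), gsd = 2)
  p <- build_pairs(sat, lab, stage = "jointing")
  expect_equal(nrow(p), 100L)
  expect_equal(p$label, as.numeric(lab$values))
  expect_equal(unique(p$stage), "jointing")
  lab$values[4, 7] <- NA
  expect_equal(nrow(build_pairs(sat, lab)), 99L)
  sat2 <- scene_raster(arr, gsd = 10, bands = satellite_bands())
  expect_error(build_pairs(sat2, lab), "different grids")
  # pairs carry the source cell values untransformed
  expect_equal(p$green, rep(0.3, 100))
})

test_that("forward pass matches independent algebra to 1e-10", {
  nh <- 6L; p <- 3L
  theta <- withr::with_seed(5, runif(wheatfvc:::n_par(p, nh), -1, 1))
  X <- withr::with_seed(6, matrix(rnorm(60), 20, p))
  got <- wheatfvc:::bpnn_forward(theta, X, nh)$y
  # hand-rolled: y = sigmoid(X W1 + b1) W2 + b2
  W1 <- matrix(theta[1:(p * nh)], p, nh)
  b1 <- theta[p * nh + 1:nh]
  W2 <- theta[p * nh + nh + 1:nh]
  b2 <- theta[p * nh + 2 * nh + 1]
  want <- as.numeric((1 / (1 + exp(-(X %*% W1 + matrix(b1, 20, nh, byrow = TRUE))))) %*% W2) + b2
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("constant labels train to a constant predictor", {
  df <- make_linear_pairs(400)
  df$label <- 0.37
  m <- train_bpnn(df, bpnn_config(goal_rmse = 1e-5, max_iter = 200, seed = 1))
  expect_lt(m$final$train_rmse, 1e-3)
  expect_lt(max(abs(predict(m, df) - 0.37)), 1e-2)
})

test_that("an exact linear map is learned to held-out RMSE below 1e-3", {
  df <- make_linear_pairs(1500, noise = 0)
  m <- train_bpnn(df, bpnn_config(goal_rmse = 1e-4, max_iter = 500, seed = 4))
  expect_lt(m$final$test_rmse, 1e-3)
  expect_equal(length(m$split$train), 1200L)
  expect_equal(length(m$split$validation), 150L)
})

test_that("training is deterministic given the seed and records a trace", {
  df <- make_linear_pairs(600, noise = 0.02)
  cfg <- bpnn_config(max_iter = 100, seed = 9)
  m1 <- train_bpnn(df, cfg)
  m2 <- train_bpnn(df, cfg)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$trace, m2$trace)
  expect_true(m1$stop_reason %in% c("goal", "patience", "max_iter", "stalled"))
  expect_true(all(c("iter", "train_rmse", "val_rmse", "lambda") %in%
                    names(m1$trace)))
  # training-split predictions reproduce the recorded final RMSE
  pr <- predict(m1, df[m1$split$train, ], clip = FALSE)
  expect_equal(sqrt(mean((pr - df$label[m1$split$train])^2)),
               m1$final$train_rmse, tolerance = 1e-12)
})

test_that("prediction clips to [0, 1] and reports the clip count", {
  df <- make_linear_pairs(400, noise = 0.02)
  m <- train_bpnn(df, bpnn_config(max_iter = 50, seed = 3))
  X <- as.matrix(df[satellite_bands()]) + 2   # far outside training range
  pred <- predict(m, X)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_true(is.numeric(attr(pred, "n_clipped")))
  # constant input gives a constant prediction
  arr <- array(0.4, c(4, 4, 3), dimnames = list(NULL, NULL, satellite_bands()))
  cm <- predict_fvc_map(m, scene_raster(arr, gsd = 2, bands = satellite_bands()))
  expect_equal(length(unique(as.numeric(cm$values))), 1L)
})

test_that("data-volume experiment is deterministic and improves with size", {
  df <- make_linear_pairs(2600, noise = 0.05, seed = 12)
  cfg <- bpnn_config(max_iter = 60, seed = 1)
  dv1 <- data_volume_experiment(df, sizes = c(150, 2000), repeats = 2,
                                config = cfg, seed = 7)
  dv2 <- data_volume_experiment(df, sizes = c(150, 2000), repeats = 2,
                                config = cfg, seed = 7)
  expect_identical(dv1$results, dv2$results)
  expect_equal(nrow(dv1$results), 4L)
  expect_equal(dv1$summary$size, c(150, 2000))
  expect_lte(dv1$summary$mean_rmse[2], dv1$summary$mean_rmse[1])
  expect_warning(
    dv3 <- data_volume_experiment(df, sizes = c(150, 1e6), repeats = 1,
                                  config = cfg, seed = 7),
    "skipped")
  expect_equal(unique(dv3$results$size), 150)
})
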