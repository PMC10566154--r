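# UAS cover models: NDVI dichotomy, random-forest and support-vector
# regression, half-Gaussian histogram method, map prediction.

test_that("NDVI arithmetic and edge cases", {
  red <- matrix(c(0.2, 0, 0.1), 1, 3)
  nir <- matrix(c(0.2, 0.4, 0.5), 1, 3)
  nd <- compute_ndvi(red, nir)
  expect_equal(as.numeric(nd), c(0, 1, 2 / 3))
  z <- compute_ndvi(matrix(0, 1, 1), matrix(0, 1, 1))
  expect_true(is.na(as.numeric(z)))
  expect_error(compute_ndvi(matrix(0, 2, 2), matrix(0, 1, 1)), "differ")
})

test_that("dichotomy model unmixes NDVI linearly and clips", {
  p <- dichotomy_params(0.1, 0.9)
  expect_equal(dichotomy_fvc(matrix(0.9), p)[1], 1)
  expect_equal(dichotomy_fvc(matrix(0.1), p)[1], 0)
  expect_equal(dichotomy_fvc(matrix(0.5), p)[1], 0.5)
  expect_equal(dichotomy_fvc(matrix(c(-0.2, 0.95)), p),
               matrix(c(0, 1)))            # clipped
  expect_error(dichotomy_params(0.5, 0.5), "exceed")
})

test_that("endmember selection uses percentiles with literal override", {
  nd <- matrix(seq(0, 1, length.out = 101), 1)
  p <- select_endmembers(nd)
  expect_equal(p$ndvi_s, 0.05, tolerance = 1e-9)
  expect_equal(p$ndvi_v, 0.95, tolerance = 1e-9)
  lit <- select_endmembers(nd, ndvi_s = 0.12, ndvi_v = 0.88)
  expect_equal(c(lit$ndvi_s, lit$ndvi_v), c(0.12, 0.88))
  expect_error(select_endmembers(matrix(0.5, 2, 2)), "degenerate")
})

test_that("dichotomy is exact on a noiseless NDVI-linear scene", {
  sc <- tiny_scene(seed = 5)
  spectra <- endmember_spectra(noise_sd = 0, ndvi_linear = TRUE)
  truth <- generate_fvc_field(sc)
  refl <- render_reflectance(truth, spectra)
  nd <- compute_ndvi(refl)
  ndvi_of <- function(s) (s[["nir"]] - s[["red"]]) / (s[["nir"]] + s[["red"]])
  p <- dichotomy_params(ndvi_of(spectra$soil), ndvi_of(spectra$vegetation))
  est <- dichotomy_fvc(nd, p)
  expect_lt(max(abs(est$values - truth$values)), 1e-6)
})

test_that("a degenerate single-tree forest memorises distinct samples", {
  df <- withr::with_seed(20, {
    d <- as.data.frame(matrix(runif(4 * 12), 12, 4))
    names(d) <- uas_bands()
    d$fvc <- runif(12)
    d
  })
  fit <- suppressWarnings(
    train_rfr(df, mtry_grid = 4, ntree_grid = 1, k_folds = 2,
              nodesize = 1, bootstrap = FALSE, min_samples = 10, seed = 1))
  expect_equal(unname(predict(fit, df)), df$fvc, tolerance = 1e-10)
})

test_that("forest training error does not exceed hold-out error", {
  spectra <- endmember_spectra(noise_sd = 0.02)
  df <- scene_samples(tiny_scene(seed = 31), spectra, n = 160, seed = 31)
  tr <- df[1:120, ]; ho <- df[121:160, ]
  fit <- train_rfr(tr, ntree_grid = c(100, 200), seed = 2)
  rmse_tr <- sqrt(mean((predict(fit, tr) - tr$fvc)^2))
  rmse_ho <- sqrt(mean((predict(fit, ho) - ho$fvc)^2))
  expect_lte(rmse_tr, rmse_ho)
  # linear-mixture scenes are learnable to the stated regime
  expect_lte(fit$cv_rmse, 0.06)
  # deterministic given the seed
  fit2 <- train_rfr(tr, ntree_grid = c(100, 200), seed = 2)
  expect_identical(fit$cv, fit2$cv)
  expect_identical(fit$best, fit2$best)
})

test_that("SVR prediction equals the explicit kernel expansion", {
  spectra <- endmember_spectra(noise_sd = 0.01)
  df <- scene_samples(tiny_scene(seed = 33), spectra, n = 80, seed = 33)
  fit <- train_svr(df, gamma_grid = c(0.5, 1), cost_grid = c(1, 4),
                   k_folds = 5, seed = 3)
  X <- as.matrix(df[uas_bands()])
  Xs <- scale(X, fit$center, fit$scale)
  sv <- fit$model$SV
  K <- exp(-fit$best$gamma *
             as.matrix(dist(rbind(Xs, sv)))[seq_len(nrow(Xs)),
                                            nrow(Xs) + seq_len(nrow(sv))]^2)
  manual <- as.numeric(K %*% fit$model$coefs) - fit$model$rho
  expect_equal(unname(predict(fit, df)), unname(pmin(pmax(manual, 0), 1)),
               tolerance = 1e-8)
  # grid search picks the row of the CV table with minimal RMSE,
  # ties toward smaller cost then gamma
  ord <- order(fit$cv$rmse, fit$cv$cost, fit$cv$gamma)
  expect_equal(unlist(fit$best), unlist(fit$cv[ord[1], c("gamma", "cost")]))
  # near-duplicate of a training point predicts inside the epsilon tube
  i <- which.min(abs(df$fvc - stats::median(df$fvc)))
  expect_lt(abs(predict(fit, df[i, ]) - df$fvc[i]), 0.1 + 0.05)
})

test_that("half-Gaussian flank method agrees with the mixture threshold", {
  model <- photo_color_model(veg_a_mean = -18, veg_a_sd = 4,
                             bg_a_mean = 12, bg_a_sd = 4)
  a <- withr::with_seed(6, matrix(c(rnorm(3e4, -18, 4), rnorm(3e4, 12, 4)),
                                  240, 250))
  hg <- hagfvc(a)
  expect_false(hg$degenerate)
  expect_true(hg$fvc >= 0 && hg$fvc <= 1)
  m <- fit_a_mixture(a)
  thr <- solve_threshold(m)$threshold
  bin_w <- diff(range(a)) / 256
  expect_lt(abs(hg$threshold - thr), bin_w)
  expect_lt(abs(hg$fvc - 0.5), 0.02)
  # an all-vegetation tile has no background flank
  ph1 <- render_ground_photo(1, seed = 2)
  expect_true(hagfvc(ph1$photo)$degenerate)
})

test_that("map prediction clips, propagates nodata and checks bands", {
  spectra <- endmember_spectra(noise_sd = 0.01)
  sc <- tiny_scene(seed = 41)
  truth <- generate_fvc_field(sc)
  refl <- render_reflectance(truth, spectra, seed = 42)
  df <- scene_samples(sc, spectra, n = 120, seed = 41, cell_m = 2)
  fit <- train_rfr(df, ntree_grid = 100, seed = 4)
  refl_na <- refl
  refl_na$values[3, 7, 2] <- NA
  est <- predict_fvc_map(fit, refl_na)
  expect_true(is.na(est$values[3, 7]))
  expect_true(all(est$values[!is.na(est$values)] >= 0 &
                    est$values[!is.na(est$values)] <= 1))
  # at the 2 m analysis scale (sensor noise zonally averaged) the map
  # recovers synthetic truth within the working-accuracy regime over the
  # wheat plots (the forest's training domain; bare paths are extrapolation)
  est_2m <- predict_fvc_map(fit, upscale_zonal(refl, cell_m = 2))
  truth_2m <- upscale_zonal(truth, cell_m = 2)
  wheat <- truth_2m$values > 0
  expect_lte(as.numeric(fvc_rmse(est_2m$values[wheat], truth_2m$values[wheat])),
             0.06)
  bad <- scene_raster(array(0.3, c(4, 4, 2), dimnames = list(NULL, NULL, c("red", "nir"))),
                      gsd = 1, bands = c("red", "nir"))
  expect_error(predict_fvc_map(fit, bad), "lacks")
  # constant raster gives a constant map
  const <- scene_raster(array(0.25, c(3, 3, 4), dimnames = list(NULL, NULL, uas_bands())),
                        gsd = 1, bands = uas_bands())
  expect_equal(length(unique(as.numeric(predict_fvc_map(fit, const)$values))), 1L)
})
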