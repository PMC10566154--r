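# Synthetic scene generator: cover fields, spectral mixing, sensor
# degradation, photo rendering and sampling layouts.

test_that("cover field honours range, paths and determinism", {
  sc <- tiny_scene(seed = 11)
  f1 <- generate_fvc_field(sc)
  f2 <- generate_fvc_field(sc)
  expect_identical(f1$values, f2$values)

  mask <- wheatfvc:::plot_mask(sc, nrow(f1$values), ncol(f1$values))
  expect_true(all(f1$values[!mask] == 0))
  expect_true(all(f1$values[mask] >= sc$fvc_range[1] - 1e-12))
  expect_true(all(f1$values[mask] <= sc$fvc_range[2] + 1e-12))

  # degenerate range: constant cover on plots
  scc <- scene_config(sc$plots, sc$extent, fvc_range = c(0.5, 0.5),
                      gsd = sc$gsd, seed = 3)
  fc <- generate_fvc_field(scc)
  expect_true(all(fc$values[mask] == 0.5))
  expect_true(all(fc$values[!mask] == 0))
})

test_that("cover field variogram rises then flattens near the correlation length", {
  L <- 6
  sc <- scene_config(data.frame(xmin = 0, xmax = 80, ymin = 0, ymax = 40),
                     extent = c(80, 40), fvc_range = c(0.2, 0.8),
                     correlation_length_m = L, gsd = 0.25, seed = 9)
  f <- generate_fvc_field(sc)
  z <- f$values
  semivar <- function(lag_m) {
    k <- round(lag_m / sc$gsd)
    d <- z[, seq_len(ncol(z) - k)] - z[, -seq_len(k)]
    mean(d^2) / 2
  }
  g <- vapply(c(0.25, 0.5, 1, 2, 3) * L, semivar, numeric(1))
  expect_true(all(diff(g[1:4]) > 0))          # increasing out to ~2L
  expect_lt(g[5] / g[4], 1.15)                # plateau beyond
  mu <- mean(z[z > 0])
  expect_gte(mu, 0.2); expect_lte(mu, 0.8)
})

test_that("scene configuration rejects degenerate layouts", {
  expect_error(scene_config(data.frame(xmin = 0, xmax = 0, ymin = 0, ymax = 10),
                            extent = c(20, 20)), "zero-area")
  expect_error(scene_config(data.frame(xmin = c(0, 5), xmax = c(10, 15),
                                       ymin = c(0, 0), ymax = c(10, 10)),
                            extent = c(20, 20)), "overlap")
  expect_error(scene_config(data.frame(xmin = 0, xmax = 30, ymin = 0, ymax = 10),
                            extent = c(20, 20)), "outside")
  expect_error(tiny_scene(correlation_length_m = -1), "positive")
})

test_that("reflectance follows the linear mixing rule exactly at zero noise", {
  sc <- tiny_scene(seed = 2)
  spectra0 <- endmember_spectra(noise_sd = 0)
  # pure vegetation pixel reproduces the vegetation spectrum
  ones <- scene_raster(matrix(1, 4, 4), gsd = 1)
  r1 <- render_reflectance(ones, spectra0)
  for (b in uas_bands())
    expect_equal(unique(as.numeric(get_band(r1, b))),
                 unname(spectra0$vegetation[[b]]))
  # half cover: direct arithmetic on the mixing rule
  spec_half <- endmember_spectra(
    vegetation = c(red = 0.1, nir = 0.5), soil = c(red = 0.3, nir = 0.3),
    noise_sd = 0)
  half <- scene_raster(matrix(0.5, 3, 3), gsd = 1)
  rh <- render_reflectance(half, spec_half, bands = c("red", "nir"))
  expect_equal(unique(as.numeric(get_band(rh, "red"))), 0.2)
  expect_equal(unique(as.numeric(get_band(rh, "nir"))), 0.4)
  expect_error(render_reflectance(ones, spec_half, bands = c("green")),
               "not in spectra")
})

test_that("sensor noise differs by seed but preserves band means", {
  f <- scene_raster(matrix(0.5, 60, 60), gsd = 1)
  spectra <- endmember_spectra(noise_sd = 0.02)
  ra <- render_reflectance(f, spectra, seed = 1)
  rb <- render_reflectance(f, spectra, seed = 2)
  expect_false(identical(ra$values, rb$values))
  se_diff <- 0.02 * sqrt(2 / 3600)
  for (b in uas_bands())
    expect_lt(abs(mean(get_band(ra, b)) - mean(get_band(rb, b))), 3 * se_diff)
})

test_that("block-mean degradation averages exactly and conserves the mean", {
  cm <- scene_raster(matrix(0.37, 6, 8), gsd = 1)
  expect_true(all(render_satellite_from_fine(cm, 2)$values == 0.37))
  m <- scene_raster(matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2), gsd = 1)
  expect_equal(as.numeric(render_satellite_from_fine(m, 2)$values), 0.25)
  set.seed(4)
  r <- scene_raster(matrix(runif(48), 6, 8), gsd = 0.5)
  coarse <- render_satellite_from_fine(r, 2)
  expect_equal(mean(coarse$values), mean(r$values))
  expect_equal(coarse$gsd, 1)
  expect_error(render_satellite_from_fine(scene_raster(matrix(0, 5, 4), 1), 2),
               "divisible")
})

test_that("ground photos realise the target cover and a* statistics", {
  ph0 <- render_ground_photo(0, seed = 1)
  expect_true(all(!ph0$mask))
  ph <- render_ground_photo(0.6, size = c(80, 80), seed = 5)
  expect_equal(mean(ph$mask), 0.6, tolerance = 1 / (80 * 80))
  expect_identical(ph$photo, render_ground_photo(0.6, size = c(80, 80), seed = 5)$photo)
  # sRGB -> Lab round trip recovers the class a* mean (no gamut clipping)
  expect_equal(ph$clip_fraction, 0)
  model <- photo_color_model()
  a <- rgb_to_a_channel(ph$photo)
  n_veg <- sum(ph$mask)
  expect_lt(abs(mean(a[ph$mask]) - model$veg_a_mean),
            3 * model$veg_a_sd / sqrt(n_veg))
  expect_lt(abs(mean(a[!ph$mask]) - model$bg_a_mean),
            3 * model$bg_a_sd / sqrt(sum(!ph$mask)))
})

test_that("five-point sampling layout matches its definition", {
  sc <- tiny_scene(seed = 21)
  f <- generate_fvc_field(sc)
  tbl <- place_ground_samples(sc, n_sites = 1, seed = 3, fvc = f)
  expect_equal(nrow(tbl), 5L)
  expect_equal(tbl$subsample_id, 1:5)
  # centre sub-square is the 2 m reference; mean of five is the 10 m one
  agg <- aggregate_site(tbl$truth_fvc, center = 1)
  expect_equal(agg$fvc_2m, tbl$truth_fvc[1])
  expect_equal(agg$fvc_10m, mean(tbl$truth_fvc))
  # truth values are the square means of the underlying field
  for (k in 1:5)
    expect_equal(tbl$truth_fvc[k],
                 wheatfvc:::square_mean(f, tbl$x[k], tbl$y[k], 1))
  # all sub-squares fall inside some plot
  expect_true(all(wheatfvc:::point_in_plots(tbl$x, tbl$y, sc$plots)))
  # a scene whose plots cannot hold the site square errors out
  small <- scene_config(data.frame(xmin = 0, xmax = 6, ymin = 0, ymax = 6),
                        extent = c(8, 8), gsd = 0.25)
  expect_error(place_ground_samples(small, 1), "site square")
})
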