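# Ground-photo cover extraction: colour conversion, mixture fit, threshold
# and aggregation.

test_that("a* channel has the expected sign conventions", {
  gray <- array(128 / 255, c(2, 2, 3))
  expect_equal(max(abs(rgb_to_a_channel(gray))), 0, tolerance = 1e-6)
  green <- array(rep(c(0, 1, 0), each = 4), c(2, 2, 3))
  expect_true(all(rgb_to_a_channel(green) < 0))
  expect_error(rgb_to_a_channel(matrix(0, 3, 3)), "RGB")
})

test_that("mixture fit recovers known parameters within 5% at n = 1e5", {
  truth <- list(w1 = 0.6, b1 = -20, d1 = 4, b2 = 10, d2 = 5)
  a <- withr::with_seed(1, c(rnorm(6e4, truth$b1, truth$d1),
                             rnorm(4e4, truth$b2, truth$d2)))
  m <- fit_a_mixture(a)
  expect_false(m$degenerate)
  expect_lt(abs(m$w1 - truth$w1) / truth$w1, 0.05)
  expect_lt(abs(m$beta1 - truth$b1) / abs(truth$b1), 0.05)
  expect_lt(abs(m$delta1 - truth$d1) / truth$d1, 0.05)
  expect_lt(abs(m$beta2 - truth$b2) / abs(truth$b2), 0.05)
  expect_lt(abs(m$delta2 - truth$d2) / truth$d2, 0.05)
  expect_lt(abs(m$w2 - 0.4) / 0.4, 0.05)
  # the fitted density is a proper mixture: unit mass over the support
  mass <- m$w1 * diff(pnorm(m$support, m$beta1, m$delta1)) +
    m$w2 * diff(pnorm(m$support, m$beta2, m$delta2))
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("single-class data is flagged degenerate", {
  a <- withr::with_seed(2, rnorm(2e4, -15, 4))
  m <- fit_a_mixture(a)
  expect_true(m$degenerate)
  expect_error(solve_threshold(m), "degenerate")
})

test_that("threshold solves the equal weighted-density equation", {
  sym <- structure(list(w1 = 0.5, w2 = 0.5, beta1 = -10, beta2 = 6,
                        delta1 = 3, delta2 = 3, degenerate = FALSE),
                   class = "a_mixture")
  expect_equal(solve_threshold(sym)$threshold, -2, tolerance = 1e-8)

  m <- structure(list(w1 = 0.6, w2 = 0.4, beta1 = -20, beta2 = 10,
                      delta1 = 4, delta2 = 5, degenerate = FALSE),
                 class = "a_mixture")
  thr <- solve_threshold(m)$threshold
  # brute-force grid oracle on the two weighted densities
  xs <- seq(m$beta1, m$beta2, by = 1e-4)
  gap <- abs(m$w1 * dnorm(xs, m$beta1, m$delta1) -
             m$w2 * dnorm(xs, m$beta2, m$delta2))
  expect_equal(thr, xs[which.min(gap)], tolerance = 1e-3)

  # classification at the threshold attains the analytic Bayes error
  n <- 2e5
  draw <- withr::with_seed(3, {
    veg <- runif(n) < m$w1
    x <- ifelse(veg, rnorm(n, m$beta1, m$delta1), rnorm(n, m$beta2, m$delta2))
    list(veg = veg, x = x)
  })
  mc_err <- mean((draw$x < thr) != draw$veg)
  bayes <- m$w1 * (1 - pnorm(thr, m$beta1, m$delta1)) +
    m$w2 * pnorm(thr, m$beta2, m$delta2)
  expect_lt(abs(mc_err - bayes), 0.01)
})

test_that("photo cover estimation recovers synthetic truth", {
  ph <- render_ground_photo(0.6, size = c(96, 96), seed = 7)
  r <- photo_fvc(ph)
  expect_lt(abs(r$fvc - 0.6), 0.02)
  expect_identical(r$fvc_threshold, mean(r$mask))
  expect_true(r$fvc >= 0 && r$fvc <= 1)

  # estimate is a pixel-set function: invariant to rotation by 90 degrees
  rot <- aperm(ph$photo[dim(ph$photo)[1]:1, , , drop = FALSE], c(2, 1, 3))
  expect_equal(photo_fvc(rot)$fvc, r$fvc, tolerance = 1e-6)

  # manual threshold above every a* value labels everything vegetation
  ph1 <- render_ground_photo(1, seed = 8)
  r1 <- photo_fvc(ph1, manual_threshold = 1000)
  expect_equal(r1$fvc, 1)
})

test_that("raising the threshold never decreases the pixel-count estimate", {
  ph <- render_ground_photo(0.5, size = c(64, 64), seed = 9)
  a <- rgb_to_a_channel(ph$photo)
  thrs <- seq(min(a) - 1, max(a) + 1, length.out = 25)
  fvc <- vapply(thrs, function(t) photo_fvc(ph, manual_threshold = t)$fvc,
                numeric(1))
  expect_true(all(diff(fvc) >= 0))
  expect_equal(fvc[1], 0); expect_equal(fvc[25], 1)
})

test_that("site aggregation averages five photos, centre only at 2 m", {
  expect_equal(aggregate_site(c(0.2, 0.4, 0.6, 0.8, 1.0)),
               list(fvc_2m = 0.2, fvc_10m = 0.6))
  expect_equal(aggregate_site(c(0.3, 0.9, 0.1, 0.5, 0.7), center = 1)$fvc_2m, 0.3)
  expect_equal(aggregate_site(rep(0.44, 5)), list(fvc_2m = 0.44, fvc_10m = 0.44))
  expect_error(aggregate_site(c(0.1, 0.2)), "five")
  expect_warning(out <- aggregate_site(c(0.1, NA, 0.3, 0.4, 0.5)), "dropped")
  expect_null(out)
})
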