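# Cover estimation from upscaled UAS reflectance: NDVI pixel-dichotomy model,
# random-forest and support-vector regression with seeded k-fold grid search,
# and the half-Gaussian histogram method for RGB tiles.

#' Normalised difference vegetation index
#'
#' `(NIR - red) / (NIR + red)` per cell; cells with a zero denominator are
#' nodata.
#'
#' @param x multi-band `scene_raster` containing `red` and `nir` bands, or a
#'   numeric matrix of red reflectance.
#' @param nir numeric matrix of NIR reflectance when `x` is a matrix.
#' @return single-band `scene_raster` (or matrix, matching the input form).
#' @export
compute_ndvi <- function(x, nir = NULL) {
  if (is_scene_raster(x)) {
    red <- get_band(x, "red"); nirm <- get_band(x, "nir")
  } else {
    red <- x; nirm <- nir
    if (is.null(nirm)) stop_wfvc("supply nir when x is a matrix")
  }
  if (!all(dim(red) == dim(nirm))) stop_wfvc("red and nir shapes differ")
  den <- nirm + red
  out <- (nirm - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  if (is_scene_raster(x)) scene_raster(out, x$gsd, x$origin) else out
}

#' Dichotomy (linear unmixing) endmember parameters
#'
#' @param ndvi_s NDVI of pure bare soil.
#' @param ndvi_v NDVI of full vegetation cover; must exceed `ndvi_s`.
#' @return an object of class `dichotomy_params`.
#' @export
dichotomy_params <- function(ndvi_s, ndvi_v) {
  if (any(c(ndvi_s, ndvi_v) < -1 | c(ndvi_s, ndvi_v) > 1))
    stop_wfvc("endmember NDVIs must lie in [-1, 1]")
  if (ndvi_v <= ndvi_s) stop_wfvc("ndvi_v must exceed ndvi_s")
  structure(list(ndvi_s = ndvi_s, ndvi_v = ndvi_v), class = "dichotomy_params")
}

#' Pixel-dichotomy cover estimate from NDVI
#'
#' Linear unmixing of each cell's NDVI between a bare-soil and a
#' full-vegetation endmember:
#' `FVC = (NDVI - NDVI_s) / (NDVI_v - NDVI_s)`, clipped to `[0, 1]`.
#'
#' @param ndvi single-band `scene_raster` or matrix of NDVI values.
#' @param params a [dichotomy_params()].
#' @return cover raster/matrix in `[0, 1]`, nodata propagated.
#' @export
dichotomy_fvc <- function(ndvi, params) {
  stopifnot(inherits(params, "dichotomy_params"))
  v <- if (is_scene_raster(ndvi)) ndvi$values else ndvi
  out <- clamp01((v - params$ndvi_s) / (params$ndvi_v - params$ndvi_s))
  if (is_scene_raster(ndvi)) scene_raster(out, ndvi$gsd, ndvi$origin) else out
}

#' Select dichotomy endmembers from an NDVI raster
#'
#' Takes the soil and vegetation endmember NDVIs as low/high percentiles of
#' the valid NDVI values (default 5th/95th), a common field practice when no
#' pure-class reference is at hand. Literal values override the percentile
#' rule.
#'
#' @param ndvi single-band `scene_raster` or matrix of NDVI.
#' @param lo_pct,hi_pct percentiles, `0 <= lo < hi <= 100`.
#' @param ndvi_s,ndvi_v optional literal overrides.
#' @return a [dichotomy_params()].
#' @export
select_endmembers <- function(ndvi, lo_pct = 5, hi_pct = 95,
                              ndvi_s = NULL, ndvi_v = NULL) {
  if (!is.null(ndvi_s) && !is.null(ndvi_v))
    return(dichotomy_params(ndvi_s, ndvi_v))
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100))
    stop_wfvc("need 0 <= lo_pct < hi_pct <= 100")
  v <- if (is_scene_raster(ndvi)) as.numeric(ndvi$values) else as.numeric(ndvi)
  v <- v[is.finite(v)]
  if (!length(v)) stop_wfvc("NDVI raster holds no valid values")
  q <- stats::quantile(v, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[1] >= q[2])
    stop_wfvc("degenerate endmembers: NDVI percentiles coincide (constant raster?)")
  dichotomy_params(ndvi_s %||% q[1], ndvi_v %||% q[2])
}

# pooled k-fold CV RMSE for a fit/predict pair; folds assigned by caller
cv_rmse_pooled <- function(X, y, folds, fit_fun) {
  err <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mdl <- fit_fun(X[tr, , drop = FALSE], y[tr])
    p <- stats::predict(mdl, X[!tr, , drop = FALSE])
    err <- c(err, p - y[!tr])
  }
  sqrt(mean(err^2))
}

check_samples <- function(samples, bands, response) {
  if (!all(bands %in% names(samples)))
    stop_wfvc("samples lack band columns: %s",
              paste(setdiff(bands, names(samples)), collapse = ", "))
  if (!response %in% names(samples)) stop_wfvc("missing response column '%s'", response)
  y <- samples[[response]]
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop_wfvc("responses must be finite cover fractions in [0, 1]")
  invisible(TRUE)
}

prepare_folds <- function(n, k_folds) {
  if (n < k_folds) {
    warning(sprintf("fewer samples (%d) than folds (%d); reducing folds", n, k_folds))
    k_folds <- max(2L, n)
  }
  sample(rep_len(seq_len(k_folds), n))
}

#' Train a random-forest cover regressor with seeded CV grid search
#'
#' Regression forest with variance-reduction splits mapping multispectral
#' reflectance to cover fraction. The `(mtry, ntree)` pair is chosen by
#' k-fold cross-validated RMSE over the supplied grids (ties broken toward
#' the simpler model: fewer trees, then smaller mtry), and the final forest
#' is refit on all samples with the winning pair. All resampling is driven
#' by `seed`.
#'
#' @param samples data.frame with one column per band plus the response.
#' @param bands predictor column names.
#' @param response response column name (cover fraction in `[0, 1]`).
#' @param mtry_grid candidate numbers of candidate features per split;
#'   defaults to `1:length(bands)`.
#' @param ntree_grid candidate forest sizes.
#' @param k_folds cross-validation folds (reduced with a warning when there
#'   are fewer samples).
#' @param seed integer seed for fold assignment and tree resampling.
#' @param nodesize minimum node size of the trees.
#' @param bootstrap draw bootstrap samples per tree (`FALSE` grows every
#'   tree on the full sample, useful for degenerate single-tree checks).
#' @param min_samples minimum sample count accepted.
#' @return an object of class `fvc_rfr`: the fitted forest plus the CV
#'   table, winning parameters and seed.
#' @export
train_rfr <- function(samples, bands = uas_bands(), response = "fvc",
                      mtry_grid = NULL, ntree_grid = seq(100L, 500L, by = 100L),
                      k_folds = 10L, seed = 1L, nodesize = 5L,
                      bootstrap = TRUE, min_samples = 20L) {
  check_samples(samples, bands, response)
  n <- nrow(samples)
  if (n < min_samples) stop_wfvc("need at least %d samples, got %d", min_samples, n)
  X <- as.matrix(samples[bands]); y <- samples[[response]]
  mtry_grid <- mtry_grid %||% seq_along(bands)
  if (any(mtry_grid < 1L | mtry_grid > length(bands)))
    stop_wfvc("mtry_grid must lie in 1..%d", length(bands))
  grid <- expand.grid(mtry = as.integer(mtry_grid), ntree = as.integer(ntree_grid))
  res <- with_seed(seed, {
    folds <- prepare_folds(n, k_folds)
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      cv_rmse_pooled(X, y, folds, function(Xt, yt)
        randomForest::randomForest(
          Xt, yt, ntree = grid$ntree[i], mtry = grid$mtry[i],
          nodesize = nodesize, replace = bootstrap,
          sampsize = if (bootstrap) nrow(Xt) else nrow(Xt)))
    }, numeric(1))
    ord <- order(cv, grid$ntree, grid$mtry)
    best <- grid[ord[1L], ]
    final <- randomForest::randomForest(
      X, y, ntree = best$ntree, mtry = best$mtry, nodesize = nodesize,
      replace = bootstrap, sampsize = nrow(X))
    list(cv = cbind(grid, rmse = cv), best = best, final = final,
         folds = max(folds))
  })
  structure(list(model = res$final, best = as.list(res$best), cv = res$cv,
                 cv_rmse = min(res$cv$rmse), bands = bands, seed = seed,
                 k_folds = res$folds),
            class = "fvc_rfr")
}

#' @export
predict.fvc_rfr <- function(object, newdata, ...) {
  if (is_scene_raster(newdata)) return(predict_fvc_map(object, newdata))
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[object$bands])
  clamp01(stats::predict(object$model, newdata))
}

#' @export
print.fvc_rfr <- function(x, ...) {
  cat(sprintf("<fvc_rfr> ntree %d, mtry %d (CV RMSE %.4f over %d folds)\n",
              x$best$ntree, x$best$mtry, x$cv_rmse, x$k_folds))
  invisible(x)
}

#' Train an RBF support-vector cover regressor with seeded CV grid search
#'
#' Epsilon-SVR with a radial basis kernel on z-scored predictors. The
#' `(gamma, cost)` pair minimising the k-fold cross-validated RMSE is
#' selected (ties broken toward smaller cost, then smaller gamma) and the
#' final machine refit on all samples. The prediction is the kernel
#' expansion over the support vectors plus the bias.
#'
#' @inheritParams train_rfr
#' @param gamma_grid candidate RBF kernel widths.
#' @param cost_grid candidate penalty costs.
#' @param epsilon epsilon-tube half width.
#' @return an object of class `fvc_svr`.
#' @export
train_svr <- function(samples, bands = uas_bands(), response = "fvc",
                      gamma_grid = c(0.2, 0.4, 0.8, 1.6, 3.2),
                      cost_grid = c(1, 2, 3, 4, 8),
                      k_folds = 10L, seed = 1L, epsilon = 0.1,
                      min_samples = 20L) {
  check_samples(samples, bands, response)
  n <- nrow(samples)
  if (n < min_samples) stop_wfvc("need at least %d samples, got %d", min_samples, n)
  X <- as.matrix(samples[bands]); y <- samples[[response]]
  ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  res <- with_seed(seed, {
    folds <- prepare_folds(n, k_folds)
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      cv_rmse_pooled(Xs, y, folds, function(Xt, yt)
        e1071::svm(Xt, yt, type = "eps-regression", kernel = "radial",
                   gamma = grid$gamma[i], cost = grid$cost[i],
                   epsilon = epsilon, scale = FALSE))
    }, numeric(1))
    ord <- order(cv, grid$cost, grid$gamma)
    best <- grid[ord[1L], ]
    final <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                        gamma = best$gamma, cost = best$cost,
                        epsilon = epsilon, scale = FALSE)
    list(cv = cbind(grid, rmse = cv), best = best, final = final,
         folds = max(folds))
  })
  structure(list(model = res$final, best = as.list(res$best), cv = res$cv,
                 cv_rmse = min(res$cv$rmse), center = ctr, scale = scl,
                 bands = bands, seed = seed, k_folds = res$folds),
            class = "fvc_svr")
}

#' @export
predict.fvc_svr <- function(object, newdata, ...) {
  if (is_scene_raster(newdata)) return(predict_fvc_map(object, newdata))
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[object$bands])
  Xs <- scale(newdata, object$center, object$scale)
  clamp01(as.numeric(stats::predict(object$model, Xs)))
}

#' @export
print.fvc_svr <- function(x, ...) {
  cat(sprintf("<fvc_svr> gamma %g, cost %g (CV RMSE %.4f over %d folds)\n",
              x$best$gamma, x$best$cost, x$cv_rmse, x$k_folds))
  invisible(x)
}

# least-squares half-Gaussian fit on one histogram flank
fit_flank <- function(x, d, peak_x, side) {
  keep <- if (side == "left") x <= peak_x else x >= peak_x
  xs <- x[keep]; dsub <- d[keep]
  pop <- sum(dsub > 0)
  A0 <- max(dsub); s0 <- max(stats::sd(xs), diff(range(x)) / 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(dsub ~ A * exp(-(xs - mu)^2 / (2 * s^2)),
                      start = list(A = A0, mu = peak_x, s = s0),
                      lower = c(1e-12, min(x), 1e-6),
                      upper = c(Inf, max(x), diff(range(x))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  list(fit = fit, populated = pop)
}

#' Half-Gaussian histogram cover estimate for an RGB tile
#'
#' Works directly on the a* channel of an RGB orthophoto tile: a vegetation
#' half-Gaussian is least-squares fitted to the outer left flank of the a*
#' histogram (`a* <= mu_v`) and a background half-Gaussian to the outer
#' right flank (`a* >= mu_b`), the flanks being identified from the two
#' outermost histogram peaks. The segmentation threshold is the
#' equal-density point of the two reconstructed full Gaussians inside
#' `(mu_v, mu_b)`, and the cover estimate is the fraction of pixels below
#' it. Tiles whose flanks populate fewer than `min_flank_bins` histogram
#' bins (e.g. an all-vegetation tile) are flagged degenerate with `fvc = NA`.
#'
#' @param photo RGB array, [render_ground_photo()] result, or a numeric
#'   matrix of a* values.
#' @param bins histogram bins.
#' @param min_flank_bins minimum populated bins per flank.
#' @return list with `fvc`, `threshold`, `mask`, `params`
#'   (`mu_v, sigma_v, mu_b, sigma_b, w_v, w_b`) and `degenerate`.
#' @export
hagfvc <- function(photo, bins = 256L, min_flank_bins = 30L) {
  a <- if (is.matrix(photo)) photo else rgb_to_a_channel(photo)
  av <- as.numeric(a); av <- av[is.finite(av)]
  degenerate_out <- function() list(fvc = NA_real_, threshold = NA_real_,
                                    mask = NULL, params = NULL, degenerate = TRUE)
  rng <- range(av)
  if (diff(rng) <= 0) return(degenerate_out())
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  hh <- graphics::hist(av, breaks = br, plot = FALSE, include.lowest = TRUE)
  x <- hh$mids; d <- hh$density
  peaks <- find_peaks(x, d)
  if (length(peaks) < 2L) return(degenerate_out())
  # anchor the flanks on the two dominant peaks (vegetation and background);
  # a genuine two-class histogram must dip between them
  top2 <- sort(peaks[order(d[peaks], decreasing = TRUE)[1:2]])
  mu_v0 <- x[top2[1L]]; mu_b0 <- x[top2[2L]]
  between <- d[top2[1L]:top2[2L]]
  if (min(between) > 0.75 * min(d[top2])) return(degenerate_out())

  left <- fit_flank(x, d, mu_v0, "left")
  right <- fit_flank(x, d, mu_b0, "right")
  if (left$populated < min_flank_bins || right$populated < min_flank_bins ||
      is.null(left$fit) || is.null(right$fit))
    return(degenerate_out())
  cl <- stats::coef(left$fit); cr <- stats::coef(right$fit)
  mu_v <- unname(cl["mu"]); s_v <- unname(cl["s"])
  mu_b <- unname(cr["mu"]); s_b <- unname(cr["s"])
  if (mu_v >= mu_b) return(degenerate_out())
  # implied full-Gaussian masses, normalised to weights
  wv <- unname(cl["A"]) * s_v * sqrt(2 * pi)
  wb <- unname(cr["A"]) * s_b * sqrt(2 * pi)
  w_v <- wv / (wv + wb); w_b <- 1 - w_v
  g <- function(t) w_v * stats::dnorm(t, mu_v, s_v) - w_b * stats::dnorm(t, mu_b, s_b)
  thr <- if (g(mu_v) > 0 && g(mu_b) < 0)
    stats::uniroot(g, c(mu_v, mu_b), tol = 1e-10)$root
  else (mu_v + mu_b) / 2
  mask <- a < thr
  list(fvc = mean(av < thr), threshold = thr, mask = mask,
       params = list(mu_v = mu_v, sigma_v = s_v, mu_b = mu_b, sigma_b = s_b,
                     w_v = w_v, w_b = w_b),
       degenerate = FALSE)
}

#' Predict a wall-to-wall cover map from a fitted model
#'
#' Applies a fitted cover regressor (`fvc_rfr`, `fvc_svr`, or `fvc_bpnn`)
#' cell-wise to a multi-band reflectance raster. Predictions are clipped to
#' `[0, 1]`; cells with any nodata band are nodata.
#'
#' @param model fitted model carrying a `bands` field and a `predict`
#'   method.
#' @param raster multi-band `scene_raster` containing the model's bands.
#' @return single-band cover `scene_raster`.
#' @export
predict_fvc_map <- function(model, raster) {
  stopifnot(is_scene_raster(raster))
  bands <- model$bands
  if (is.null(bands)) stop_wfvc("model carries no band list")
  missing <- setdiff(bands, raster$bands %||% character(0))
  if (length(missing))
    stop_wfvc("raster lacks model bands: %s", paste(missing, collapse = ", "))
  X <- vapply(bands, function(b) as.numeric(get_band(raster, b)),
              numeric(prod(raster_dim(raster))))
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    nd <- as.data.frame(X[ok, , drop = FALSE])
    names(nd) <- bands
    out[ok] <- clamp01(as.numeric(stats::predict(model, nd)))
  }
  scene_raster(matrix(out, raster_dim(raster)[1]), raster$gsd, raster$origin)
}
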