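# Ground-photo cover extraction: RGB -> CIE L*a*b* a* channel, two-Gaussian
# histogram fit, equal-density threshold, and site-level aggregation.

#' Extract the CIE a* channel of an RGB photo
#'
#' Converts sRGB (D65) to CIE L*a*b* and returns the a* (green-red opponent)
#' channel, on which green vegetation separates from soil/residue background:
#' vegetation sits at negative a*, background near or above zero.
#'
#' @param photo H x W x 3 array in `[0, 1]` or 8-bit `[0, 255]`, or the list
#'   returned by [render_ground_photo()].
#' @return numeric H x W matrix of a* values.
#' @export
rgb_to_a_channel <- function(photo) {
  if (is.list(photo) && !is.null(photo$photo)) photo <- photo$photo
  if (!(is.array(photo) && length(dim(photo)) == 3L && dim(photo)[3L] == 3L))
    stop_wfvc("photo must be an H x W x 3 RGB array")
  if (max(photo, na.rm = TRUE) > 1) photo <- photo / 255
  h <- dim(photo)[1L]; w <- dim(photo)[2L]
  m <- cbind(as.numeric(photo[, , 1L]), as.numeric(photo[, , 2L]),
             as.numeric(photo[, , 3L]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  matrix(lab[, 2L], h, w)
}

# local maxima of a smoothed density trace, above a relative floor
find_peaks <- function(x, d, floor_frac = 0.05) {
  k <- rep(1 / 5, 5)
  n <- length(d)
  pad <- c(rep(d[1L], 2L), d, rep(d[n], 2L))
  ds <- as.numeric(stats::filter(pad, k, sides = 2))[3L:(n + 2L)]
  up <- c(TRUE, diff(ds) >= 0)
  dn <- c(diff(ds) <= 0, TRUE)
  idx <- which(up & dn & ds > floor_frac * max(ds))
  # merge flat runs
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L)]
  idx
}

#' Fit a two-Gaussian mixture to an a*-value histogram
#'
#' The a* values are binned into `bins` equal-width density-normalised bins
#' and the six-parameter two-Gaussian density
#' `w1 N(x; beta1, delta1) + (1 - w1) N(x; beta2, delta2)` is fitted to the
#' histogram by nonlinear least squares, started from both the two largest
#' local maxima and a k-means split of the raw values (the better-fitting
#' solution is kept). Components are
#' reported with `beta1 <= beta2`, so component 1 is the vegetation
#' (greener, lower a*) class. A fit whose two means are closer than the
#' larger standard deviation, whose weights collapse, or whose density has
#' no real valley between the means is flagged degenerate.
#'
#' @param a numeric vector or matrix of a* values (>= 1000 values
#'   recommended).
#' @param bins number of histogram bins.
#' @return an object of class `a_mixture`: list with `w1, w2, beta1, beta2,
#'   delta1, delta2, converged, degenerate, resid_norm, bins, support`.
#' @export
fit_a_mixture <- function(a, bins = 256L) {
  a <- as.numeric(a)
  a <- a[is.finite(a)]
  if (length(a) < 10L) stop_wfvc("need at least 10 finite a* values")
  rng <- range(a)
  if (diff(rng) <= 0)
    return(structure(list(w1 = 1, w2 = 0, beta1 = rng[1], beta2 = rng[1],
                          delta1 = NA_real_, delta2 = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          resid_norm = NA_real_, bins = bins, support = rng),
                     class = "a_mixture"))
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  hh <- graphics::hist(a, breaks = br, plot = FALSE, include.lowest = TRUE)
  x <- hh$mids; d <- hh$density
  bw <- diff(br[1:2])

  # candidate starting points: the two largest histogram peaks, and k-means
  # on the raw values (robust when the binned density is noisy)
  starts <- list()
  peaks <- find_peaks(x, d)
  mk_start <- function(m1, m2) {
    if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp }
    mid <- (m1 + m2) / 2
    s1 <- stats::sd(a[a < mid]); s2 <- stats::sd(a[a >= mid])
    if (!is.finite(s1) || s1 <= 0) s1 <- bw
    if (!is.finite(s2) || s2 <= 0) s2 <- bw
    w1 <- min(max(mean(a < mid), 0.02), 0.98)
    list(w = w1, m1p = m1, s1p = s1, m2p = m2, s2p = s2)
  }
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(d[peaks], decreasing = TRUE)[1:2]]
    starts$peaks <- mk_start(x[top2[1L]], x[top2[2L]])
  }
  km <- tryCatch(with_seed(42L, stats::kmeans(a, centers = 2L, nstart = 5L)),
                 error = function(e) NULL)
  if (!is.null(km)) starts$kmeans <- mk_start(km$centers[1L], km$centers[2L])
  if (!length(starts)) starts$range <- mk_start(rng[1] + diff(rng) / 4,
                                                rng[2] - diff(rng) / 4)

  dat <- data.frame(x = x, d = d)
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        d ~ w * stats::dnorm(x, m1p, s1p) + (1 - w) * stats::dnorm(x, m2p, s2p),
        data = dat, start = st,
        lower = c(1e-4, rng[1] - 5 * bw, bw / 4, rng[1] - 5 * bw, bw / 4),
        upper = c(1 - 1e-4, rng[2] + 5 * bw, diff(rng), rng[2] + 5 * bw, diff(rng)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
      fit <- cand
  }

  if (is.null(fit)) {
    cf <- unlist(starts[[length(starts)]])   # moment fallback
    converged <- FALSE
    resid_norm <- NA_real_
  } else {
    cf <- stats::coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
    resid_norm <- sqrt(sum(stats::resid(fit)^2))
  }
  w <- unname(cf["w"]); b1 <- unname(cf["m1p"]); d1 <- unname(cf["s1p"])
  b2 <- unname(cf["m2p"]); d2 <- unname(cf["s2p"])
  if (b1 > b2) { tmp <- b1; b1 <- b2; b2 <- tmp
                 tmp <- d1; d1 <- d2; d2 <- tmp
                 w <- 1 - w }
  # valley check: a genuine bimodal density dips between the two means
  xs <- seq(b1, b2, length.out = 101L)
  dens <- w * stats::dnorm(xs, b1, d1) + (1 - w) * stats::dnorm(xs, b2, d2)
  peak_low <- min(dens[1L], dens[101L])
  no_valley <- min(dens) > 0.75 * peak_low
  degenerate <- !converged || (b2 - b1) < max(d1, d2) ||
    w < 0.02 || w > 0.98 || no_valley

  structure(list(w1 = w, w2 = 1 - w, beta1 = b1, beta2 = b2,
                 delta1 = d1, delta2 = d2,
                 converged = converged, degenerate = degenerate,
                 resid_norm = resid_norm, bins = bins, support = rng),
            class = "a_mixture")
}

#' @export
print.a_mixture <- function(x, ...) {
  cat(sprintf("<a_mixture> w1 %.3f  beta1 %.2f (sd %.2f) | w2 %.3f  beta2 %.2f (sd %.2f)%s\n",
              x$w1, x$beta1, x$delta1, x$w2, x$beta2, x$delta2,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Segmentation threshold between the two mixture components
#'
#' Returns the a* value in `(beta1, beta2)` where the weighted component
#' densities are equal, `w1 N(x; beta1, delta1) = w2 N(x; beta2, delta2)`
#' (the misclassification-minimising boundary between the means). If the
#' weighted densities do not cross inside the interval, the midpoint is
#' returned with `midpoint_fallback = TRUE`.
#'
#' @param m an [fit_a_mixture()] result with `beta1 < beta2`, not degenerate.
#' @return list with `threshold` and `midpoint_fallback`.
#' @export
solve_threshold <- function(m) {
  stopifnot(inherits(m, "a_mixture"))
  if (m$degenerate)
    stop_wfvc("degenerate mixture: components indistinguishable, supply a manual threshold")
  g <- function(x) m$w1 * stats::dnorm(x, m$beta1, m$delta1) -
                   m$w2 * stats::dnorm(x, m$beta2, m$delta2)
  lo <- m$beta1; hi <- m$beta2
  if (g(lo) > 0 && g(hi) < 0) {
    root <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    list(threshold = root, midpoint_fallback = FALSE)
  } else {
    warning("weighted densities do not cross between the means; using the midpoint")
    list(threshold = (lo + hi) / 2, midpoint_fallback = TRUE)
  }
}

#' Estimate cover fraction from one ground photo
#'
#' Runs the full chain: sRGB to a*, two-Gaussian histogram fit, equal-density
#' threshold, pixel mask. Two estimates are reported: `fvc_threshold`, the
#' fraction of pixels below the threshold, and `fvc_weight`, the fitted
#' vegetation mixture weight `w1`. The headline `fvc` defaults to the
#' mixture weight, which stays unbiased when the two components overlap (the
#' thresholded count misassigns the overlap tails); `estimator =
#' "threshold"` selects the pixel count instead. A `manual_threshold`
#' bypasses the fit-based threshold (for photos where the histogram fit is
#' unreliable, e.g. waterlogged plots) and makes the pixel count the
#' headline estimate.
#'
#' @param photo RGB array or [render_ground_photo()] result.
#' @param bins histogram bins for the mixture fit.
#' @param estimator `"weight"` or `"threshold"`.
#' @param manual_threshold optional a* threshold overriding the fit.
#' @return an object of class `segmentation_result`: list with `fvc`,
#'   `fvc_threshold`, `fvc_weight`, `threshold`, `mask`, `mixture`,
#'   `estimator`, `diagnostics`.
#' @export
photo_fvc <- function(photo, bins = 256L,
                      estimator = c("weight", "threshold"),
                      manual_threshold = NULL) {
  estimator <- match.arg(estimator)
  a <- rgb_to_a_channel(photo)

  if (!is.null(manual_threshold)) {
    mix <- tryCatch(fit_a_mixture(a, bins), error = function(e) NULL)
    thr <- manual_threshold
    mask <- a < thr
    fvc_thr <- mean(mask)
    fvc_w <- if (!is.null(mix) && !mix$degenerate) mix$w1 else NA_real_
    return(structure(list(fvc = fvc_thr, fvc_threshold = fvc_thr,
                          fvc_weight = fvc_w, threshold = thr, mask = mask,
                          mixture = mix, estimator = "threshold",
                          diagnostics = list(manual = TRUE,
                                             midpoint_fallback = FALSE,
                                             bins = bins)),
                     class = "segmentation_result"))
  }

  mix <- fit_a_mixture(a, bins)
  if (mix$degenerate)
    stop_wfvc(paste0("mixture fit degenerate (components indistinguishable); ",
                     "supply manual_threshold from visual judgment"))
  ts <- solve_threshold(mix)
  mask <- a < ts$threshold
  fvc_thr <- mean(mask)
  fvc <- if (estimator == "weight") mix$w1 else fvc_thr
  structure(list(fvc = fvc, fvc_threshold = fvc_thr, fvc_weight = mix$w1,
                 threshold = ts$threshold, mask = mask, mixture = mix,
                 estimator = estimator,
                 diagnostics = list(manual = FALSE,
                                    midpoint_fallback = ts$midpoint_fallback,
                                    resid_norm = mix$resid_norm, bins = bins)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> fvc %.3f (weight %.3f, threshold-count %.3f) at a* < %.2f\n",
              x$fvc, x$fvc_weight, x$fvc_threshold, x$threshold))
  invisible(x)
}

#' Aggregate the five photos of a sampling site
#'
#' The 10 m-scale reference value is the arithmetic mean of the five 2 m
#' sub-square estimates; the 2 m-scale reference is the centre sub-square
#' alone. A site with a missing estimate is dropped (returns `NULL` with a
#' warning).
#'
#' @param results numeric vector of five cover estimates, or a list of five
#'   [photo_fvc()] results.
#' @param center index of the centre sub-square (default 1).
#' @return list with `fvc_2m` and `fvc_10m`, or `NULL` if the site is
#'   dropped.
#' @export
aggregate_site <- function(results, center = 1L) {
  if (is.list(results) && !is.numeric(results))
    results <- vapply(results, function(r) {
      if (inherits(r, "segmentation_result")) r$fvc else as.numeric(r)
    }, numeric(1))
  if (length(results) != 5L)
    stop_wfvc("a site aggregates exactly five sub-square results, got %d",
              length(results))
  if (anyNA(results)) {
    warning("site dropped: missing photo estimate")
    return(NULL)
  }
  list(fvc_2m = results[[center]], fvc_10m = mean(results))
}
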