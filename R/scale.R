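# Scale bridging: cubic-convolution interpolation of coarse satellite grids
# down to the 2 m target grid, and zonal-mean aggregation of fine grids up to
# coarser cells.

#' Cubic convolution interpolation kernel
#'
#' Piecewise-cubic interpolating kernel (the a = -1 member of the cubic
#' convolution family, a cubic approximation of sinc):
#' `|x|^3 - 2|x|^2 + 1` for `|x| < 1`,
#' `-|x|^3 + 5|x|^2 - 8|x| + 4` for `1 <= |x| <= 2`, and 0 beyond. `x` is
#' the signed distance (in source-pixel units) between the interpolation
#' point and a source sample. The kernel interpolates (`W(0) = 1`,
#' `W(1) = W(2) = 0`) and its four active taps sum to one for every
#' fractional offset, so constant rasters are reproduced exactly.
#'
#' @param x numeric vector of signed distances.
#' @return kernel weights, same shape as `x`.
#' @export
cubic_kernel <- function(x) {
  ax <- abs(x)
  w <- numeric(length(ax))
  i1 <- ax < 1
  i2 <- !i1 & ax <= 2
  w[i1] <- ax[i1]^3 - 2 * ax[i1]^2 + 1
  w[i2] <- -ax[i2]^3 + 5 * ax[i2]^2 - 8 * ax[i2] + 4
  dim(w) <- dim(x)
  w
}

# one band; clamp (replicate) padding at the borders.
# pixel-centre mapping: src = (dst + 0.5)/factor - 0.5 (0-based), which
# places the centre fine pixel of each block exactly on the source pixel for
# odd factors.
downscale_band <- function(src, factor, renormalize = FALSE) {
  nr_s <- nrow(src); nc_s <- ncol(src)
  nr <- nr_s * factor; nc <- nc_s * factor
  sr <- (seq_len(nr) - 0.5) / factor - 0.5
  sc <- (seq_len(nc) - 0.5) / factor - 0.5
  i0 <- floor(sr); u <- sr - i0
  j0 <- floor(sc); v <- sc - j0
  wu <- cbind(cubic_kernel(u + 1), cubic_kernel(u), cubic_kernel(u - 1), cubic_kernel(u - 2))
  wv <- cbind(cubic_kernel(v + 1), cubic_kernel(v), cubic_kernel(v - 1), cubic_kernel(v - 2))
  acc <- matrix(0, nr, nc)
  if (renormalize) { wsum <- matrix(0, nr, nc) }
  for (a in 0:3) {
    ri <- clamp(i0 - 1L + a, 0L, nr_s - 1L) + 1L
    for (b in 0:3) {
      cj <- clamp(j0 - 1L + b, 0L, nc_s - 1L) + 1L
      vals <- src[ri, cj, drop = FALSE]
      w <- tcrossprod(wu[, a + 1L], wv[, b + 1L])
      if (renormalize) {
        ok <- !is.na(vals)
        acc[ok] <- acc[ok] + w[ok] * vals[ok]
        wsum[ok] <- wsum[ok] + w[ok]
      } else {
        acc <- acc + w * vals   # NA in the 4x4 neighbourhood propagates
      }
    }
  }
  if (renormalize) {
    out <- acc / wsum
    out[abs(wsum) < 1e-12] <- NA_real_
    out
  } else acc
}

#' Downscale a coarse raster by cubic convolution interpolation
#'
#' Interpolates each target value from its 4 x 4 source neighbourhood with
#' [cubic_kernel()] row/column weights (a separable `A B C` product). The
#' geotransform is refined by `1/factor` with the same origin. For an odd
#' `factor` the centre fine pixel of each block reproduces the source pixel
#' value exactly, so coarse radiometry is preserved at block centres.
#' Borders use replicate (clamp) padding. By default any nodata cell inside
#' the 4 x 4 neighbourhood makes the target nodata; with
#' `renormalize_nodata = TRUE` the remaining weights are renormalised
#' instead.
#'
#' @param coarse a `scene_raster` with at least 4 x 4 cells.
#' @param factor integer refinement factor >= 2 (5 for 10 m to 2 m).
#' @param renormalize_nodata logical; see above.
#' @return `scene_raster` with `gsd / factor`.
#' @export
downscale_bicubic <- function(coarse, factor = 5L, renormalize_nodata = FALSE) {
  stopifnot(is_scene_raster(coarse))
  factor <- as.integer(factor)
  if (factor < 2L) stop_wfvc("factor must be >= 2")
  d <- raster_dim(coarse)
  if (any(d < 4L)) stop_wfvc("raster must be at least 4 x 4 for cubic convolution")
  if (is.matrix(coarse$values)) {
    out <- downscale_band(coarse$values, factor, renormalize_nodata)
    return(scene_raster(out, coarse$gsd / factor, coarse$origin))
  }
  arr <- array(NA_real_, c(d * factor, n_bands(coarse)),
               dimnames = list(NULL, NULL, coarse$bands))
  for (b in coarse$bands)
    arr[, , b] <- downscale_band(coarse$values[, , b], factor, renormalize_nodata)
  scene_raster(arr, coarse$gsd / factor, coarse$origin, bands = coarse$bands)
}

# group fine cells into target cells by centre containment; returns NULL on
# disjoint extents
zonal_groups <- function(fine, cell, origin) {
  xs <- cell_x(fine); ys <- cell_y(fine)
  cg <- floor((xs - origin[1]) / cell) + 1L
  rg <- floor((origin[2] - ys) / cell) + 1L
  list(rg = rg, cg = cg)
}

#' Aggregate a fine raster onto a coarser target grid by zonal means
#'
#' Each target cell takes the mean of the fine pixels whose centres fall
#' inside it (half-open cell extents, so membership is unambiguous). Nodata
#' fine pixels are excluded from the mean; target cells with no contributing
#' pixel are nodata. The target grid is aligned to `grid` when given,
#' otherwise to the fine raster's own origin with cell size `cell_m`; only
#' complete cells inside the fine extent are produced in the latter case.
#'
#' @param fine a `scene_raster` with `gsd` strictly smaller than the target
#'   cell.
#' @param cell_m target cell size in metres (ignored when `grid` is given).
#' @param grid optional `scene_raster` whose grid (origin, gsd, dimensions)
#'   the output must match.
#' @return `scene_raster` on the target grid.
#' @export
upscale_zonal <- function(fine, cell_m = 2, grid = NULL) {
  stopifnot(is_scene_raster(fine))
  if (!is.null(grid)) {
    stopifnot(is_scene_raster(grid))
    cell <- grid$gsd; origin <- grid$origin
    nR <- nrow(grid$values); nC <- ncol(grid$values)
  } else {
    cell <- cell_m; origin <- fine$origin
    nR <- floor(raster_dim(fine)[1] * fine$gsd / cell + 1e-9)
    nC <- floor(raster_dim(fine)[2] * fine$gsd / cell + 1e-9)
  }
  if (cell <= fine$gsd)
    stop_wfvc("target cell (%g m) must exceed the fine gsd (%g m)", cell, fine$gsd)
  if (nR < 1L || nC < 1L) stop_wfvc("target grid has no complete cell")
  gr <- zonal_groups(fine, cell, origin)
  keep_r <- gr$rg >= 1L & gr$rg <= nR
  keep_c <- gr$cg >= 1L & gr$cg <= nC
  if (!any(keep_r) || !any(keep_c))
    stop_wfvc("fine raster and target grid extents are disjoint")

  agg_band <- function(m) {
    m <- m[keep_r, keep_c, drop = FALSE]
    rg <- gr$rg[keep_r]; cg <- gr$cg[keep_c]
    grp <- rep(rg, times = length(cg)) + (rep(cg, each = length(rg)) - 1L) * nR
    v <- as.numeric(m)
    ok <- !is.na(v)
    sums <- rowsum(ifelse(ok, v, 0), grp)
    cnts <- rowsum(as.numeric(ok), grp)
    out <- rep(NA_real_, nR * nC)
    gid <- as.integer(rownames(sums))
    mu <- sums / cnts
    mu[cnts == 0] <- NA_real_
    out[gid] <- mu
    matrix(out, nR, nC)
  }
  if (is.matrix(fine$values))
    return(scene_raster(agg_band(fine$values), cell, origin))
  arr <- array(NA_real_, c(nR, nC, n_bands(fine)),
               dimnames = list(NULL, NULL, fine$bands))
  for (b in fine$bands) arr[, , b] <- agg_band(fine$values[, , b])
  scene_raster(arr, cell, origin, bands = fine$bands)
}

#' Aggregate a 2 m cover raster to 10 m blocks
#'
#' Block mean over aligned `factor x factor` (default 5 x 5) groups of cells.
#' Blocks containing nodata, and trailing partial blocks, are nodata/dropped.
#'
#' @param fvc_2m single-band `scene_raster` of cover fractions.
#' @param factor integer block size (5 for 2 m to 10 m).
#' @return `scene_raster` at `gsd * factor`.
#' @export
upscale_fvc_10m <- function(fvc_2m, factor = 5L) {
  stopifnot(is_scene_raster(fvc_2m), is.matrix(fvc_2m$values))
  out <- block_mean(fvc_2m$values, factor)
  bad <- !is.na(out) & (out < -1e-9 | out > 1 + 1e-9)
  if (any(bad)) stop_wfvc("aggregated cover outside [0, 1]")
  scene_raster(clamp01(out), fvc_2m$gsd * factor, fvc_2m$origin)
}
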