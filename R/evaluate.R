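# Accuracy metrics and the two analysis experiments: boundary-vs-interior
# error stratification and the upscaling-downscaling vs upscale-only
# strategy comparison.

drop_na_pairs <- function(pred, obs) {
  if (length(pred) != length(obs)) stop_wfvc("pred and obs lengths differ")
  ok <- is.finite(pred) & is.finite(obs)
  list(pred = pred[ok], obs = obs[ok], n_dropped = sum(!ok))
}

#' Root mean square error
#'
#' `sqrt(mean((pred - obs)^2))` over the pairs where both values are valid;
#' the number of dropped nodata pairs is attached as attribute `n_dropped`.
#'
#' @param pred,obs numeric vectors (or rasters, flattened) of equal length.
#' @return non-negative scalar.
#' @export
fvc_rmse <- function(pred, obs) {
  if (is_scene_raster(pred)) pred <- as.numeric(pred$values)
  if (is_scene_raster(obs)) obs <- as.numeric(obs$values)
  d <- drop_na_pairs(pred, obs)
  if (!length(d$pred)) stop_wfvc("no valid prediction/observation pairs")
  structure(sqrt(mean((d$pred - d$obs)^2)), n_dropped = d$n_dropped)
}

#' Coefficient of determination
#'
#' Computed as `1 - SS_res / SS_tot` with `SS_tot` around the observation
#' mean -- the standard prediction R^2, which equals the regression-SS ratio
#' only for an OLS fit with intercept. A perfect prediction gives 1, the
#' observation mean gives 0, and worse-than-mean predictions go negative.
#'
#' @inheritParams fvc_rmse
#' @return scalar `<= 1`.
#' @export
fvc_r2 <- function(pred, obs) {
  if (is_scene_raster(pred)) pred <- as.numeric(pred$values)
  if (is_scene_raster(obs)) obs <- as.numeric(obs$values)
  d <- drop_na_pairs(pred, obs)
  if (length(d$obs) < 2L || stats::var(d$obs) == 0)
    stop_wfvc("observations have zero variance; R2 undefined")
  structure(1 - sum((d$pred - d$obs)^2) / sum((d$obs - mean(d$obs))^2),
            n_dropped = d$n_dropped)
}

eval_report <- function(pred, obs, stratum) {
  d <- drop_na_pairs(pred, obs)
  r2 <- if (length(d$obs) >= 2L && stats::var(d$obs) > 0)
    1 - sum((d$pred - d$obs)^2) / sum((d$obs - mean(d$obs))^2) else NA_real_
  data.frame(stratum = stratum, n = length(d$pred),
             rmse = if (length(d$pred)) sqrt(mean((d$pred - d$obs)^2)) else NA_real_,
             r2 = r2)
}

# distance from points to the nearest plot-rectangle boundary line
rect_boundary_distance <- function(x, y, plots) {
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(plots))) {
    p <- plots[k, ]
    dx_out <- pmax(p$xmin - x, x - p$xmax, 0)
    dy_out <- pmax(p$ymin - y, y - p$ymax, 0)
    outside <- dx_out > 0 | dy_out > 0
    dk <- numeric(length(x))
    dk[outside] <- sqrt(dx_out[outside]^2 + dy_out[outside]^2)
    ins <- !outside
    dk[ins] <- pmin(x[ins] - p$xmin, p$xmax - x[ins],
                    y[ins] - p$ymin, p$ymax - y[ins])
    d <- pmin(d, dk)
  }
  d
}

point_in_plots <- function(x, y, plots) {
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(plots))) {
    p <- plots[k, ]
    inside <- inside | (x >= p$xmin & x < p$xmax & y >= p$ymin & y < p$ymax)
  }
  inside
}

#' Stratified boundary-vs-interior accuracy
#'
#' Splits the map cells into a boundary stratum (cell centres within
#' `radius_m` of any plot boundary line, on either side) and an interior
#' stratum (inside a plot and farther than `radius_m` from every edge),
#' samples `n_points` cells per stratum without replacement (all cells with
#' a warning when a stratum is smaller), and reports RMSE and R^2 per
#' stratum. This quantifies how much of the map error concentrates at field
#' edges, where the coarse sensor mixes wheat and bare-path signal.
#'
#' @param pred,truth single-band `scene_raster`s on the same grid.
#' @param plots data.frame of plot rectangles (`xmin, xmax, ymin, ymax`).
#' @param radius_m boundary half-width in metres.
#' @param n_points cells sampled per stratum.
#' @param seed integer seed fixing the sampled sets.
#' @return data.frame with one row per stratum (`boundary`, `interior`):
#'   `stratum, n, rmse, r2`.
#' @export
boundary_interior_eval <- function(pred, truth, plots, radius_m = 5,
                                   n_points = 150L, seed = 1L) {
  stopifnot(is_scene_raster(pred), is_scene_raster(truth))
  if (!all(raster_dim(pred) == raster_dim(truth)))
    stop_wfvc("prediction and truth grids differ")
  xs <- rep(cell_x(pred), each = nrow(pred$values))
  ys <- rep(cell_y(pred), times = ncol(pred$values))
  dist <- rect_boundary_distance(xs, ys, plots)
  inside <- point_in_plots(xs, ys, plots)
  pv <- as.numeric(pred$values); tv <- as.numeric(truth$values)
  valid <- is.finite(pv) & is.finite(tv)
  strata <- list(boundary = which(valid & dist <= radius_m),
                 interior = which(valid & inside & dist > radius_m))
  out <- with_seed(seed, {
    rows <- lapply(names(strata), function(s) {
      cand <- strata[[s]]
      if (!length(cand)) stop_wfvc("stratum '%s' holds no valid cells", s)
      take <- if (length(cand) <= n_points) {
        warning(sprintf("stratum '%s' smaller than n_points (%d < %d); using all",
                        s, length(cand), n_points))
        cand
      } else sample(cand, n_points)
      eval_report(pv[take], tv[take], s)
    })
    do.call(rbind, rows)
  })
  out
}

#' Compare scale-conversion strategies
#'
#' Tabulates accuracy for evaluation entries produced under different
#' scale-bridging strategies (typically `up-down`, the
#' upscaling-downscaling pipeline evaluated at 2 m and aggregated to 10 m,
#' against `up-only`, the same network trained and evaluated on native 10 m
#' pairs), and reports the relative RMSE change of `up-down` against
#' `up-only` wherever both strategies share a stage. The change convention
#' is `(RMSE_uponly - RMSE_updown) / RMSE_uponly * 100`, i.e. positive =
#' reduction.
#'
#' @param entries list of entries, each a list with fields `pred`, `obs`
#'   (vectors or rasters), `strategy`, `stage`, `scale`.
#' @return list with `metrics` (strategy, stage, scale, n, rmse, r2) and
#'   `change` (stage, scale pairs where both strategies are present, with
#'   `rmse_reduction_pct`).
#' @export
strategy_comparison <- function(entries) {
  rows <- lapply(entries, function(e) {
    if (is.null(e$pred) || is.null(e$obs)) {
      message("strategy entry skipped: missing model output")
      return(NULL)
    }
    p <- if (is_scene_raster(e$pred)) as.numeric(e$pred$values) else e$pred
    o <- if (is_scene_raster(e$obs)) as.numeric(e$obs$values) else e$obs
    r <- eval_report(p, o, stratum = "all")
    data.frame(strategy = e$strategy, stage = e$stage %||% NA_character_,
               scale = e$scale, n = r$n, rmse = r$rmse, r2 = r$r2)
  })
  metrics <- do.call(rbind, rows)
  change <- NULL
  if (!is.null(metrics)) {
    ud <- metrics[metrics$strategy == "up-down", ]
    uo <- metrics[metrics$strategy == "up-only", ]
    if (nrow(ud) && nrow(uo)) {
      ch <- merge(ud, uo, by = c("stage", "scale"),
                  suffixes = c("_updown", "_uponly"))
      if (nrow(ch)) {
        ch$rmse_reduction_pct <-
          (ch$rmse_uponly - ch$rmse_updown) / ch$rmse_uponly * 100
        change <- ch[, c("stage", "scale", "rmse_updown", "rmse_uponly",
                         "rmse_reduction_pct")]
      }
    }
  }
  list(metrics = metrics, change = change)
}
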