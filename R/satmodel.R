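# Satellite cover retrieval: a small feedforward network (3 inputs, 6
# logistic-sigmoid hidden nodes, linear output) trained by full-batch
# Levenberg-Marquardt on (downscaled satellite reflectance, UAS-derived
# cover label) pairs, plus the data-volume sensitivity experiment.

#' Network training configuration
#'
#' Defaults follow the published retrieval setup: 6 sigmoid hidden nodes,
#' linear output, Levenberg-Marquardt calibration of the synaptic weights,
#' a validation RMSE goal of 0.06, at most 5000 iterations, early stop
#' after 15 iterations without change in validation RMSE, and an 8:1:1
#' train/validation/test split.
#'
#' @param n_hidden hidden nodes.
#' @param goal_rmse validation RMSE at which training stops.
#' @param max_iter iteration cap.
#' @param patience iterations of unchanged validation RMSE before stopping.
#' @param split train/validation/test fractions summing to 1.
#' @param lambda0 initial Levenberg-Marquardt damping.
#' @param change_tol relative RMSE change below which an iteration counts
#'   as "unchanged" for the patience rule.
#' @param max_reject consecutive rejected damping trials before aborting.
#' @param init_range weights initialised uniform in `(-init_range,
#'   init_range)`.
#' @param seed integer seed controlling the split and the initialisation.
#' @return an object of class `bpnn_config`.
#' @export
bpnn_config <- function(n_hidden = 6L, goal_rmse = 0.06, max_iter = 5000L,
                        patience = 15L, split = c(0.8, 0.1, 0.1),
                        lambda0 = 1e-3, change_tol = 1e-5, max_reject = 30L,
                        init_range = 0.5, seed = 1L) {
  if (n_hidden < 1L) stop_wfvc("n_hidden must be >= 1")
  if (goal_rmse <= 0) stop_wfvc("goal_rmse must be positive")
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-9 || any(split < 0))
    stop_wfvc("split must be three non-negative fractions summing to 1")
  structure(list(n_hidden = as.integer(n_hidden), goal_rmse = goal_rmse,
                 max_iter = as.integer(max_iter), patience = as.integer(patience),
                 split = split, lambda0 = lambda0, change_tol = change_tol,
                 max_reject = as.integer(max_reject), init_range = init_range,
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

#' Pair satellite reflectance with cover labels cell by cell
#'
#' One training pair per grid cell where both the reflectance bands and the
#' label are valid; the two rasters must share the grid exactly.
#'
#' @param sat multi-band reflectance `scene_raster`.
#' @param labels single-band cover `scene_raster` on the same grid.
#' @param stage optional stage tag recorded per pair.
#' @return data.frame with `cell, row, col`, one column per band, `label`,
#'   and `stage`.
#' @export
build_pairs <- function(sat, labels, stage = NULL) {
  stopifnot(is_scene_raster(sat), is_scene_raster(labels))
  if (!all(raster_dim(sat) == raster_dim(labels)) ||
      abs(sat$gsd - labels$gsd) > 1e-9 ||
      any(abs(sat$origin - labels$origin) > 1e-9))
    stop_wfvc("satellite and label rasters are on different grids")
  d <- raster_dim(sat)
  n <- prod(d)
  X <- vapply(sat$bands, function(b) as.numeric(get_band(sat, b)), numeric(n))
  y <- as.numeric(labels$values)
  ok <- stats::complete.cases(X) & is.finite(y)
  idx <- which(ok)
  out <- data.frame(cell = idx,
                    row = ((idx - 1L) %% d[1]) + 1L,
                    col = ((idx - 1L) %/% d[1]) + 1L)
  for (b in sat$bands) out[[b]] <- X[idx, b]
  out$label <- y[idx]
  out$stage <- stage %||% NA_character_
  out
}

# ---- network algebra --------------------------------------------------------

n_par <- function(p, nh) p * nh + nh + nh + 1L

unpack_theta <- function(theta, p, nh) {
  list(W1 = matrix(theta[seq_len(p * nh)], p, nh),
       b1 = theta[p * nh + seq_len(nh)],
       W2 = theta[p * nh + nh + seq_len(nh)],
       b2 = theta[p * nh + 2L * nh + 1L])
}

bpnn_forward <- function(theta, X, nh) {
  pr <- unpack_theta(theta, ncol(X), nh)
  A <- sweep(X %*% pr$W1, 2L, pr$b1, "+")
  Z <- 1 / (1 + exp(-A))
  list(y = as.numeric(Z %*% pr$W2) + pr$b2, Z = Z, W2 = pr$W2)
}

bpnn_jacobian <- function(X, fw, nh) {
  n <- nrow(X); p <- ncol(X)
  S <- fw$Z * (1 - fw$Z)
  G <- sweep(S, 2L, fw$W2, "*")            # d y / d a_j
  J <- matrix(0, n, n_par(p, nh))
  for (j in seq_len(nh))
    J[, (j - 1L) * p + seq_len(p)] <- X * G[, j]
  J[, p * nh + seq_len(nh)] <- G           # b1
  J[, p * nh + nh + seq_len(nh)] <- fw$Z   # W2
  J[, p * nh + 2L * nh + 1L] <- 1          # b2
  J
}

rmse_vec <- function(e) sqrt(mean(e^2))

#' Train the satellite cover network
#'
#' Fits the 3-6-1 feedforward network by full-batch Levenberg-Marquardt
#' (damped Gauss-Newton on the residual Jacobian; the network has at most a
#' few dozen weights, so the normal equations are tiny). Inputs are
#' z-scored with statistics from the training split; targets are left on
#' the cover scale and predictions are clipped to `[0, 1]`. Training stops
#' once the validation RMSE is at or below the goal and has stopped
#' improving materially (stopping at the first dip below the goal would
#' freeze a half-converged network), when it stays unchanged for
#' `patience` iterations regardless of the goal, or at `max_iter`; the
#' per-iteration trace and the stop reason are recorded. Deterministic
#' given the config seed.
#'
#' @param pairs data.frame from [build_pairs()] (or any frame with the band
#'   columns and a label column).
#' @param config a [bpnn_config()].
#' @param bands predictor columns.
#' @param label label column.
#' @param min_pairs minimum accepted number of pairs.
#' @return an object of class `fvc_bpnn`: weights, scalers, config, split
#'   indices, trace, stop reason and split RMSEs.
#' @export
train_bpnn <- function(pairs, config = bpnn_config(),
                       bands = satellite_bands(), label = "label",
                       min_pairs = 100L) {
  stopifnot(inherits(config, "bpnn_config"))
  if (!all(bands %in% names(pairs)))
    stop_wfvc("pairs lack band columns: %s",
              paste(setdiff(bands, names(pairs)), collapse = ", "))
  if (!label %in% names(pairs)) stop_wfvc("missing label column '%s'", label)
  n <- nrow(pairs)
  if (n < min_pairs) stop_wfvc("need at least %d pairs, got %d", min_pairs, n)
  X <- as.matrix(pairs[bands]); y <- pairs[[label]]
  nh <- config$n_hidden; p <- ncol(X)

  res <- with_seed(config$seed, {
    idx <- sample.int(n)
    n_tr <- floor(config$split[1] * n)
    n_va <- floor(config$split[2] * n)
    i_tr <- idx[seq_len(n_tr)]
    i_va <- idx[n_tr + seq_len(n_va)]
    i_te <- idx[-seq_len(n_tr + n_va)]
    ctr <- colMeans(X[i_tr, , drop = FALSE])
    scl <- apply(X[i_tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)
    Xtr <- Xs[i_tr, , drop = FALSE]; ytr <- y[i_tr]
    Xva <- if (length(i_va)) Xs[i_va, , drop = FALSE] else Xtr
    yva <- if (length(i_va)) y[i_va] else ytr

    theta <- stats::runif(n_par(p, nh), -config$init_range, config$init_range)
    lambda <- config$lambda0
    fw <- bpnn_forward(theta, Xtr, nh)
    sse <- sum((fw$y - ytr)^2)
    trace <- vector("list", config$max_iter)
    stop_reason <- "max_iter"
    still <- 0L
    prev_val <- Inf
    it <- 0L
    while (it < config$max_iter) {
      it <- it + 1L
      r <- fw$y - ytr
      J <- bpnn_jacobian(Xtr, fw, nh)
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, r)
      dia <- rep(1, ncol(JtJ))   # identity damping: (J'J + lambda I)
      accepted <- FALSE
      rejects <- 0L
      while (!accepted) {
        step <- tryCatch(
          solve(JtJ + lambda * diag(dia, nrow = length(dia)), Jtr),
          error = function(e) NULL)
        if (!is.null(step)) {
          theta_new <- theta - as.numeric(step)
          fw_new <- bpnn_forward(theta_new, Xtr, nh)
          sse_new <- sum((fw_new$y - ytr)^2)
        } else sse_new <- NaN
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new; fw <- fw_new; sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
        } else {
          # non-finite or worse: raise damping and retry
          lambda <- lambda * 10
          rejects <- rejects + 1L
          if (rejects >= config$max_reject) break
        }
      }
      tr_rmse <- sqrt(sse / length(ytr))
      val_rmse <- rmse_vec(bpnn_forward(theta, Xva, nh)$y - yva)
      trace[[it]] <- c(iter = it, train_rmse = tr_rmse, val_rmse = val_rmse,
                       lambda = lambda)
      rel <- abs(prev_val - val_rmse) / max(val_rmse, 1e-12)
      if (!accepted) {
        stop_reason <- if (val_rmse <= config$goal_rmse) "goal" else "stalled"
        break
      }
      # the goal binds once the validation RMSE is at (or below) the goal and
      # no longer improving materially -- stopping at the first dip below the
      # goal would freeze a half-converged network
      if (val_rmse <= config$goal_rmse && rel < config$change_tol) {
        stop_reason <- "goal"; break
      }
      still <- if (rel < config$change_tol) still + 1L else 0L
      prev_val <- val_rmse
      if (still >= config$patience) { stop_reason <- "patience"; break }
    }
    trace <- as.data.frame(do.call(rbind, trace[seq_len(it)]))
    list(theta = theta, ctr = ctr, scl = scl, trace = trace,
         stop_reason = stop_reason,
         i_tr = i_tr, i_va = i_va, i_te = i_te)
  })

  fitted_of <- function(ii) {
    if (!length(ii)) return(numeric(0))
    Xs <- scale(X[ii, , drop = FALSE], res$ctr, res$scl)
    bpnn_forward(res$theta, Xs, nh)$y
  }
  final <- list(
    train_rmse = rmse_vec(fitted_of(res$i_tr) - y[res$i_tr]),
    val_rmse = if (length(res$i_va)) rmse_vec(fitted_of(res$i_va) - y[res$i_va]) else NA_real_,
    test_rmse = if (length(res$i_te)) rmse_vec(fitted_of(res$i_te) - y[res$i_te]) else NA_real_)

  structure(list(theta = res$theta, n_hidden = nh, bands = bands,
                 center = res$ctr, scale = res$scl, config = config,
                 trace = res$trace, stop_reason = res$stop_reason,
                 split = list(train = res$i_tr, validation = res$i_va,
                              test = res$i_te),
                 final = final, label = label),
            class = "fvc_bpnn")
}

#' Predict cover from satellite reflectance with a trained network
#'
#' @param object an `fvc_bpnn`.
#' @param newdata data.frame/matrix with the model bands, or a multi-band
#'   `scene_raster` (dispatched through [predict_fvc_map()]).
#' @param clip clip predictions into `[0, 1]` (the count of clipped values
#'   is attached as attribute `n_clipped`).
#' @param ... unused.
#' @return numeric predictions (or a cover raster).
#' @export
predict.fvc_bpnn <- function(object, newdata, clip = TRUE, ...) {
  if (is_scene_raster(newdata)) return(predict_fvc_map(object, newdata))
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[object$bands])
  Xs <- scale(newdata, object$center, object$scale)
  yhat <- bpnn_forward(object$theta, Xs, object$n_hidden)$y
  if (clip) {
    n_clipped <- sum(yhat < 0 | yhat > 1, na.rm = TRUE)
    yhat <- clamp01(yhat)
    attr(yhat, "n_clipped") <- n_clipped
  }
  yhat
}

#' @export
print.fvc_bpnn <- function(x, ...) {
  cat(sprintf("<fvc_bpnn> %d-%d-1, %d iterations, stop: %s\n",
              length(x$bands), x$n_hidden, nrow(x$trace), x$stop_reason))
  cat(sprintf("  RMSE train %.4f | validation %.4f | test %.4f\n",
              x$final$train_rmse, x$final$val_rmse, x$final$test_rmse))
  invisible(x)
}

#' Data-volume sensitivity experiment
#'
#' Quantifies how the retrieval accuracy depends on the number of training
#' pairs: a fixed held-out evaluation set is split off once, then for each
#' requested size the network is trained on a fresh random subsample (without
#' replacement) of the remaining pool, repeated `repeats` times, and the
#' held-out RMSE recorded. Sizes exceeding the pool are skipped with a
#' warning. Deterministic given `seed`.
#'
#' @param pairs data.frame from [build_pairs()].
#' @param sizes training-set sizes to probe.
#' @param repeats repetitions per size.
#' @param config a [bpnn_config()] template (its seed is re-derived per run).
#' @param holdout_frac fraction of pairs reserved for evaluation.
#' @param seed integer master seed.
#' @param bands,label columns as in [train_bpnn()].
#' @return list with `results` (size, rep, rmse per run) and `summary`
#'   (mean and sd of RMSE per size).
#' @export
data_volume_experiment <- function(pairs, sizes, repeats = 5L,
                                   config = bpnn_config(),
                                   holdout_frac = 0.1, seed = 1L,
                                   bands = satellite_bands(), label = "label") {
  n <- nrow(pairs)
  hold <- with_seed(seed, sample.int(n, max(1L, round(holdout_frac * n))))
  pool <- setdiff(seq_len(n), hold)
  eval_x <- as.matrix(pairs[hold, bands])
  eval_y <- pairs[[label]][hold]
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    if (size > length(pool)) {
      warning(sprintf("size %d exceeds available pool (%d); skipped",
                      size, length(pool)))
      next
    }
    for (rep_i in seq_len(repeats)) {
      run_seed <- seed + 1000L * si + rep_i
      sub <- with_seed(run_seed, sample(pool, size))
      cfg <- config
      cfg$seed <- run_seed
      mdl <- train_bpnn(pairs[sub, , drop = FALSE], cfg, bands = bands,
                        label = label, min_pairs = min(100L, size))
      pred <- predict(mdl, eval_x)
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, rep = rep_i, rmse = rmse_vec(pred - eval_y))
    }
  }
  results <- do.call(rbind, rows) %||% data.frame(size = integer(), rep = integer(),
                                                  rmse = numeric())
  summary <- if (nrow(results)) {
    agg_m <- stats::aggregate(rmse ~ size, results, mean)
    agg_s <- stats::aggregate(rmse ~ size, results, stats::sd)
    data.frame(size = agg_m$size, mean_rmse = agg_m$rmse, sd_rmse = agg_s$rmse)
  } else data.frame(size = integer(), mean_rmse = numeric(), sd_rmse = numeric())
  list(results = results, summary = summary)
}
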