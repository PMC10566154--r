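# End-to-end orchestration of the ground-UAS-satellite workflow on a
# synthetic scene: simulate -> extract ground cover from photos -> bridge
# scales -> fit the UAS label model -> train the satellite network ->
# evaluate, with optional artifact writing and a provenance manifest.

#' Pipeline configuration
#'
#' Bundles the scene, the spectral and photo models, the sampling design and
#' the estimator settings of a full run. All randomness is derived from
#' `seed` (the scene keeps its own seed inside `scene`).
#'
#' @param scene a [scene_config()]; defaults to the two-plot
#'   [default_scene()] at the jointing stage.
#' @param spectra an [endmember_spectra()].
#' @param photo_model a [photo_color_model()].
#' @param n_sites number of five-point ground sampling sites.
#' @param photo_size pixel size of rendered ground photos.
#' @param sat_gsd satellite ground sampling distance, metres.
#' @param target_gsd target analysis cell, metres.
#' @param rfr_args list of extra arguments for [train_rfr()].
#' @param bpnn a [bpnn_config()] template (its seed is re-derived).
#' @param train_fraction fraction of sites used to train the label model
#'   (the rest validate it).
#' @param eval_boundary run the boundary/interior stratification.
#' @param compare_uponly also train the upscale-only comparator network on
#'   native 10 m pairs.
#' @param boundary_radius_m,boundary_n_points stratification settings.
#' @param out_dir optional directory for artifacts (rasters, tables, models,
#'   manifest).
#' @param write_photos also write the rendered photos as PNG (slow; only
#'   with `out_dir`).
#' @param seed master seed of the run.
#' @return an object of class `fvc_pipeline_config`.
#' @export
pipeline_config <- function(scene = default_scene(), spectra = endmember_spectra(),
                            photo_model = photo_color_model(),
                            n_sites = 30L, photo_size = c(96L, 96L),
                            sat_gsd = 10, target_gsd = 2,
                            rfr_args = list(), bpnn = bpnn_config(),
                            train_fraction = 0.8,
                            eval_boundary = TRUE, compare_uponly = FALSE,
                            boundary_radius_m = 5, boundary_n_points = 150L,
                            out_dir = NULL, write_photos = FALSE, seed = 1L) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(spectra, "endmember_spectra"),
            inherits(photo_model, "photo_color_model"),
            inherits(bpnn, "bpnn_config"))
  if (sat_gsd <= target_gsd) stop_wfvc("sat_gsd must exceed target_gsd")
  if ((sat_gsd / target_gsd) %% 1 != 0)
    stop_wfvc("sat_gsd must be an integer multiple of target_gsd")
  structure(list(scene = scene, spectra = spectra, photo_model = photo_model,
                 n_sites = as.integer(n_sites), photo_size = photo_size,
                 sat_gsd = sat_gsd, target_gsd = target_gsd,
                 rfr_args = rfr_args, bpnn = bpnn,
                 train_fraction = train_fraction,
                 eval_boundary = eval_boundary, compare_uponly = compare_uponly,
                 boundary_radius_m = boundary_radius_m,
                 boundary_n_points = as.integer(boundary_n_points),
                 out_dir = out_dir, write_photos = write_photos,
                 seed = as.integer(seed)),
            class = "fvc_pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 3L)   # canonical serialisation for hashing only
  unname(tools::md5sum(tmp))
}

#' Run the full cover-estimation workflow on a synthetic scene
#'
#' Executes, in order: scene simulation (true cover field, UAS reflectance,
#' satellite reflectance at 10 m), ground sampling with rendered photos and
#' histogram-based cover extraction, scale bridging (cubic-convolution
#' downscaling of the satellite grid to 2 m, zonal upscaling of the UAS
#' grid to 2 m), label-model training (random forest on the ground samples)
#' and wall-to-wall 2 m labelling, satellite network training on the
#' (reflectance, label) pairs, prediction, and evaluation against labels
#' and against the synthetic truth at 2 m and 10 m. Optionally trains the
#' upscale-only comparator on native 10 m pairs and stratifies errors by
#' boundary/interior.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `fvc_pipeline_result` (a list of rasters,
#'   tables, fitted models, an `eval` table and a provenance `manifest`).
#' @export
run_fvc_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fvc_pipeline_config"))
  s <- config$seed
  scene <- config$scene
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  # -- simulate ---------------------------------------------------------------
  truth_fine <- generate_fvc_field(scene)
  uas_fine <- render_reflectance(truth_fine, config$spectra, uas_bands(),
                                 seed = s + 1L)
  sat_factor_fine <- round(config$sat_gsd / scene$gsd)
  if (abs(sat_factor_fine * scene$gsd - config$sat_gsd) > 1e-9)
    stop_wfvc("scene gsd does not divide the satellite gsd")
  # true cover degraded to the sensor grid, then observed with sensor noise
  truth_sat_fvc <- render_satellite_from_fine(truth_fine, sat_factor_fine)
  sat_10m <- render_reflectance(truth_sat_fvc, config$spectra,
                                satellite_bands(), seed = s + 2L)
  log_stage("simulate: %d x %d fine cells, %d x %d satellite cells",
            nrow(truth_fine$values), ncol(truth_fine$values),
            nrow(sat_10m$values), ncol(sat_10m$values))

  # -- ground sampling and photo extraction -----------------------------------
  samples <- place_ground_samples(scene, config$n_sites, seed = s + 3L,
                                  fvc = truth_fine)
  est <- vapply(seq_len(nrow(samples)), function(k) {
    ph <- render_ground_photo(samples$truth_fvc[k], config$photo_model,
                              size = config$photo_size, seed = s + 100L + k)
    photo_fvc(ph)$fvc
  }, numeric(1))
  samples$fvc_real <- est
  log_stage("ground: %d sites, %d photos, mean |error| %.4f",
            config$n_sites, nrow(samples), mean(abs(est - samples$truth_fvc)))

  # -- scale bridging ---------------------------------------------------------
  factor <- as.integer(config$sat_gsd / config$target_gsd)
  sat_2m <- downscale_bicubic(sat_10m, factor = factor)
  uas_2m <- upscale_zonal(uas_fine, cell_m = config$target_gsd)
  truth_2m <- upscale_zonal(truth_fine, cell_m = config$target_gsd)
  truth_10m <- upscale_fvc_10m(truth_2m, factor = factor)

  # -- label model on ground samples ------------------------------------------
  cellrc <- function(r, x, y) {
    c(row = 1L + as.integer(floor((r$origin[2] - y) / r$gsd)),
      col = 1L + as.integer(floor((x - r$origin[1]) / r$gsd)))
  }
  rc <- t(vapply(seq_len(nrow(samples)),
                 function(k) cellrc(uas_2m, samples$x[k], samples$y[k]),
                 integer(2)))
  train_tbl <- samples
  for (b in uas_bands())
    train_tbl[[b]] <- get_band(uas_2m, b)[cbind(rc[, 1], rc[, 2])]
  train_tbl$fvc <- train_tbl$fvc_real

  site_ids <- unique(train_tbl$site_id)
  n_train_sites <- max(1L, round(config$train_fraction * length(site_ids)))
  train_sites <- with_seed(s + 4L, sample(site_ids, n_train_sites))
  is_train <- train_tbl$site_id %in% train_sites
  rfr <- do.call(train_rfr, c(list(samples = train_tbl[is_train, ],
                                   seed = s + 5L), config$rfr_args))
  label_val_rmse <- if (any(!is_train)) {
    as.numeric(fvc_rmse(predict(rfr, train_tbl[!is_train, ]),
                        train_tbl$fvc[!is_train]))
  } else NA_real_
  labels_2m <- predict_fvc_map(rfr, uas_2m)
  log_stage("labels: RFR ntree %d mtry %d, CV RMSE %.4f, site-holdout RMSE %.4f",
            rfr$best$ntree, rfr$best$mtry, rfr$cv_rmse,
            label_val_rmse %||% NA_real_)

  # -- satellite network ------------------------------------------------------
  pairs <- build_pairs(sat_2m, labels_2m, stage = scene$stage)
  bcfg <- config$bpnn
  bcfg$seed <- s + 6L
  bpnn <- train_bpnn(pairs, bcfg)
  pred_2m <- predict_fvc_map(bpnn, sat_2m)
  pred_10m <- upscale_fvc_10m(pred_2m, factor = factor)
  log_stage("network: %d pairs, %d iterations, stop %s, val RMSE %.4f",
            nrow(pairs), nrow(bpnn$trace), bpnn$stop_reason, bpnn$final$val_rmse)

  # -- evaluation -------------------------------------------------------------
  i_te <- bpnn$split$test
  test_cells <- pairs$cell[i_te]
  pred_all <- as.numeric(pred_2m$values)
  truth_all <- as.numeric(truth_2m$values)
  ev <- rbind(
    eval_report(predict(bpnn, pairs[i_te, ]), pairs$label[i_te], "test_vs_labels"),
    eval_report(pred_all[test_cells], truth_all[test_cells], "test_vs_truth_2m"),
    eval_report(pred_all, truth_all, "all_vs_truth_2m"),
    eval_report(as.numeric(pred_10m$values), as.numeric(truth_10m$values),
                "all_vs_truth_10m"))
  if (config$eval_boundary) {
    bi <- boundary_interior_eval(pred_2m, truth_2m, scene$plots,
                                 radius_m = config$boundary_radius_m,
                                 n_points = config$boundary_n_points,
                                 seed = s + 7L)
    ev <- rbind(ev, bi)
  }

  strategy <- NULL
  bpnn10 <- NULL
  if (config$compare_uponly) {
    labels_10m <- upscale_fvc_10m(labels_2m, factor = factor)
    pairs10 <- build_pairs(sat_10m, labels_10m, stage = scene$stage)
    bcfg10 <- config$bpnn
    bcfg10$seed <- s + 8L
    bpnn10 <- train_bpnn(pairs10, bcfg10, min_pairs = 50L)
    pred_10m_uponly <- predict_fvc_map(bpnn10, sat_10m)
    strategy <- strategy_comparison(list(
      list(pred = pred_2m, obs = truth_2m, strategy = "up-down",
           stage = scene$stage, scale = "2m"),
      list(pred = pred_10m, obs = truth_10m, strategy = "up-down",
           stage = scene$stage, scale = "10m"),
      list(pred = pred_10m_uponly, obs = truth_10m, strategy = "up-only",
           stage = scene$stage, scale = "10m")))
    ev <- rbind(ev, eval_report(as.numeric(pred_10m_uponly$values),
                                as.numeric(truth_10m$values),
                                "uponly_vs_truth_10m"))
  }

  result <- structure(list(
    config = config, scene = scene,
    truth_fine = truth_fine, truth_2m = truth_2m, truth_10m = truth_10m,
    uas_2m = uas_2m, sat_10m = sat_10m, sat_2m = sat_2m,
    samples = train_tbl, label_model = rfr, label_val_rmse = label_val_rmse,
    labels_2m = labels_2m, pairs = pairs, bpnn = bpnn, bpnn_uponly = bpnn10,
    pred_2m = pred_2m, pred_10m = pred_10m,
    eval = ev, strategy = strategy,
    elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "fvc_pipeline_result")
  result$manifest <- build_manifest(result)

  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

build_manifest <- function(result) {
  cfg <- result$config
  list(package = "wheatfvc",
       config_md5 = config_hash(cfg),
       seed = cfg$seed, scene_seed = cfg$scene$seed,
       stage = cfg$scene$stage,
       n_sites = cfg$n_sites, n_pairs = nrow(result$pairs),
       bpnn_iterations = nrow(result$bpnn$trace),
       bpnn_stop = result$bpnn$stop_reason,
       eval = result$eval)
}

write_pipeline_artifacts <- function(result) {
  cfg <- result$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)
  write_raster(result$truth_2m, p("truth_fvc_2m"))
  write_raster(result$labels_2m, p("fvc_uas_2m"))
  write_raster(result$pred_2m, p("fvc_satellite_2m"))
  write_raster(result$pred_10m, p("fvc_satellite_10m"))
  write_raster(result$sat_2m, p("satellite_2m"))
  utils::write.csv(result$samples, p("ground_samples.csv"), row.names = FALSE)
  utils::write.csv(result$eval, p("evaluation.csv"), row.names = FALSE)
  if (!is.null(result$strategy))
    utils::write.csv(result$strategy$metrics, p("strategy_metrics.csv"),
                     row.names = FALSE)
  model_dump <- list(theta = result$bpnn$theta, bands = result$bpnn$bands,
                     center = as.list(result$bpnn$center),
                     scale = as.list(result$bpnn$scale),
                     n_hidden = result$bpnn$n_hidden,
                     stop_reason = result$bpnn$stop_reason,
                     seed = result$bpnn$config$seed)
  jsonlite::write_json(model_dump, p("bpnn_model.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(result$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  if (isTRUE(cfg$write_photos)) {
    ph_dir <- p("photos")
    dir.create(ph_dir, showWarnings = FALSE)
    for (k in seq_len(nrow(result$samples))) {
      ph <- render_ground_photo(result$samples$truth_fvc[k], cfg$photo_model,
                                size = cfg$photo_size, seed = cfg$seed + 100L + k)
      write_photo(ph, file.path(ph_dir, sprintf("site%02d_sub%d.png",
                                                result$samples$site_id[k],
                                                result$samples$subsample_id[k])))
    }
  }
  invisible(cfg$out_dir)
}

#' @export
print.fvc_pipeline_result <- function(x, ...) {
  cat(sprintf("<fvc_pipeline_result> stage %s, %d pairs, %.1f s\n",
              x$scene$stage, nrow(x$pairs), x$elapsed_s))
  print(x$eval, row.names = FALSE)
  invisible(x)
}
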