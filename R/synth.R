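# Synthetic scene generator: seeded cover fields over rectangular wheat plots
# separated by bare paths, linear vegetation/soil spectral mixing, block-mean
# degradation to the satellite scale, two-Gaussian a*-channel ground photos,
# and five-point ground sampling layouts. Every generator is a pure function
# of (configuration, seed).

#' Winter-wheat band sets
#'
#' Band names used throughout the package: the four-band agricultural
#' multispectral camera (green 550, red 660, red-edge 735, NIR 790 nm) and
#' the three satellite surface-reflectance bands used for cover retrieval.
#'
#' @return character vector of band names.
#' @export
uas_bands <- function() c("green", "red", "rededge", "nir")

#' @rdname uas_bands
#' @export
satellite_bands <- function() c("green", "red", "nir")

#' Scene configuration
#'
#' Describes a synthetic wheat field: rectangular plots inside a rectangular
#' scene, everything outside a plot being a bare path with zero vegetation
#' cover. The cover field inside plots is spatially correlated with a
#' controllable length scale and value range; the phenological stage selects
#' the default range (jointing: sparse-to-moderate canopy; booting: dense
#' canopy).
#'
#' @param plots data.frame with columns `xmin, xmax, ymin, ymax` (metres).
#' @param extent length-2 numeric `c(width, height)` of the scene in metres.
#' @param fvc_range length-2 numeric `(lo, hi)` of cover inside plots;
#'   defaults by `stage` to `c(0.25, 0.75)` (jointing) or `c(0.65, 0.95)`
#'   (booting).
#' @param correlation_length_m approximate range of spatial autocorrelation
#'   of the cover field, in metres.
#' @param stage `"jointing"` or `"booting"`.
#' @param gsd fine-grid ground sampling distance in metres.
#' @param seed integer seed owned by the scene.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(plots, extent, fvc_range = NULL,
                         correlation_length_m = 12,
                         stage = c("jointing", "booting"),
                         gsd = 0.05, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(fvc_range))
    fvc_range <- if (stage == "jointing") c(0.25, 0.75) else c(0.65, 0.95)
  plots <- as.data.frame(plots)
  need <- c("xmin", "xmax", "ymin", "ymax")
  if (!all(need %in% names(plots))) stop_wfvc("plots needs columns %s", paste(need, collapse = ", "))
  if (nrow(plots) < 1L) stop_wfvc("at least one plot is required")
  w <- plots$xmax - plots$xmin; h <- plots$ymax - plots$ymin
  if (any(w <= 0 | h <= 0)) stop_wfvc("degenerate layout: zero-area plot")
  if (any(plots$xmin < 0 | plots$ymin < 0 |
          plots$xmax > extent[1] | plots$ymax > extent[2]))
    stop_wfvc("plot extends outside the scene")
  if (nrow(plots) > 1L) {
    for (i in seq_len(nrow(plots) - 1L)) for (j in (i + 1L):nrow(plots)) {
      if (plots$xmin[i] < plots$xmax[j] && plots$xmax[i] > plots$xmin[j] &&
          plots$ymin[i] < plots$ymax[j] && plots$ymax[i] > plots$ymin[j])
        stop_wfvc("plots %d and %d overlap", i, j)
    }
  }
  if (length(fvc_range) != 2L || fvc_range[1] > fvc_range[2] ||
      fvc_range[1] < 0 || fvc_range[2] > 1)
    stop_wfvc("fvc_range must be (lo, hi) with 0 <= lo <= hi <= 1")
  if (correlation_length_m <= 0) stop_wfvc("correlation_length_m must be positive")
  if (gsd <= 0) stop_wfvc("gsd must be positive")
  structure(list(plots = plots, extent = as.numeric(extent),
                 fvc_range = as.numeric(fvc_range),
                 correlation_length_m = correlation_length_m,
                 stage = stage, gsd = gsd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Default two-plot scene
#'
#' A 400 m x 200 m scene holding two large wheat plots separated by a bare
#' path corridor, emulating the contiguous fields of an agricultural
#' demonstration base: plot interiors dominate the area while the path
#' provides a sharp cover boundary for edge-effect experiments. The default
#' fine grid of 0.5 m keeps 16 fine pixels per 2 m target cell.
#'
#' @param stage phenological stage, `"jointing"` or `"booting"`.
#' @param width,height scene extent in metres.
#' @param path_width width of the central bare path, metres.
#' @param gsd fine-grid cell size in metres.
#' @param correlation_length_m autocorrelation range of the cover field.
#' @param seed integer seed.
#' @return a `scene_config`.
#' @export
default_scene <- function(stage = "jointing", width = 400, height = 200,
                          path_width = 4, gsd = 0.5,
                          correlation_length_m = 12, seed = 1L) {
  half <- (width - path_width) / 2
  plots <- data.frame(xmin = c(0, half + path_width), xmax = c(half, width),
                      ymin = 0, ymax = height)
  scene_config(plots, extent = c(width, height), stage = stage, gsd = gsd,
               correlation_length_m = correlation_length_m, seed = seed)
}

#' Endmember spectra for linear vegetation/soil mixing
#'
#' Per-band surface reflectance of the two pure cover classes plus per-band
#' sensor noise. Defaults give a vegetation NDVI of about 0.9 and a soil
#' NDVI of about 0.1, typical of a green wheat canopy over bare loam; all
#' values are configurable. With `ndvi_linear = TRUE` the soil spectrum is
#' adjusted so that red + NIR is equal for both endmembers, which makes
#' pixel NDVI exactly linear in cover fraction (useful for exactness tests
#' of the NDVI dichotomy model).
#'
#' @param vegetation,soil named reflectance vectors in `[0, 1]`; names are
#'   band names.
#' @param noise_sd per-band Gaussian noise standard deviation (recycled).
#' @param ndvi_linear logical; equalise red + NIR across endmembers.
#' @return an object of class `endmember_spectra`.
#' @export
endmember_spectra <- function(
    vegetation = c(green = 0.08, red = 0.03, rededge = 0.30, nir = 0.55),
    soil = c(green = 0.15, red = 0.20, rededge = 0.22, nir = 0.25),
    noise_sd = 0.01, ndvi_linear = FALSE) {
  if (is.null(names(vegetation)) || is.null(names(soil)))
    stop_wfvc("endmember spectra must be named by band")
  if (!setequal(names(vegetation), names(soil)))
    stop_wfvc("vegetation and soil must cover the same bands")
  soil <- soil[names(vegetation)]
  if (any(vegetation < 0 | vegetation > 1 | soil < 0 | soil > 1))
    stop_wfvc("reflectances must lie in [0, 1]")
  if (all(c("red", "nir") %in% names(vegetation))) {
    if (vegetation[["nir"]] <= vegetation[["red"]])
      stop_wfvc("vegetation NIR must exceed vegetation red")
    ndvi <- function(s) (s[["nir"]] - s[["red"]]) / (s[["nir"]] + s[["red"]])
    if (ndvi_linear) {
      # preserve soil NDVI, set soil red+nir equal to the vegetation sum
      tot <- vegetation[["red"]] + vegetation[["nir"]]
      nd_s <- ndvi(soil)
      soil[["nir"]] <- tot * (1 + nd_s) / 2
      soil[["red"]] <- tot * (1 - nd_s) / 2
    }
    if (ndvi(soil) >= ndvi(vegetation))
      stop_wfvc("soil NDVI must be below vegetation NDVI")
  }
  noise_sd <- rep_len(noise_sd, length(vegetation))
  names(noise_sd) <- names(vegetation)
  if (any(noise_sd < 0)) stop_wfvc("noise_sd must be >= 0")
  structure(list(vegetation = vegetation, soil = soil, noise_sd = noise_sd),
            class = "endmember_spectra")
}

#' a*-channel colour model for ground photos
#'
#' Photo pixels are drawn in CIE L*a*b*: the a* (green-red opponent) channel
#' follows a two-Gaussian mixture -- vegetation at a lower (greener) mean than
#' the background -- while L* and b* are held constant per class so the a*
#' histogram is the sole information channel, as assumed by the histogram
#' segmentation method.
#'
#' @param veg_a_mean,veg_a_sd vegetation a* mean and standard deviation.
#' @param bg_a_mean,bg_a_sd background (soil/residue) a* mean and sd.
#' @param veg_L,bg_L per-class L* lightness constants.
#' @param veg_b,bg_b per-class b* constants.
#' @return an object of class `photo_color_model`.
#' @export
photo_color_model <- function(veg_a_mean = -18, veg_a_sd = 4,
                              bg_a_mean = 8, bg_a_sd = 5,
                              veg_L = 45, bg_L = 62,
                              veg_b = 32, bg_b = 16) {
  if (veg_a_mean >= bg_a_mean)
    stop_wfvc("vegetation a* mean must be below the background mean")
  if (veg_a_sd <= 0 || bg_a_sd <= 0) stop_wfvc("a* standard deviations must be positive")
  structure(list(veg_a_mean = veg_a_mean, veg_a_sd = veg_a_sd,
                 bg_a_mean = bg_a_mean, bg_a_sd = bg_a_sd,
                 veg_L = veg_L, bg_L = bg_L, veg_b = veg_b, bg_b = bg_b),
            class = "photo_color_model")
}

# logical matrix: cell centre inside any plot rectangle (half-open intervals)
plot_mask <- function(config, nr, nc) {
  xs <- (seq_len(nc) - 0.5) * config$gsd
  ys <- config$extent[2] - (seq_len(nr) - 0.5) * config$gsd
  mask <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(config$plots))) {
    p <- config$plots[k, ]
    inx <- xs >= p$xmin & xs < p$xmax
    iny <- ys >= p$ymin & ys < p$ymax
    mask[iny, inx] <- TRUE
  }
  mask
}

#' Generate the fine-grid true cover field of a scene
#'
#' Seeded white noise is smoothed with a Gaussian kernel (standard deviation
#' half the configured correlation length) and rescaled over the plot cells
#' to the configured cover range; path corridors are set to zero cover. The
#' result is deterministic given the scene's seed.
#'
#' @param config a [scene_config()].
#' @return single-band `scene_raster` of cover fractions in `[0, 1]`.
#' @export
generate_fvc_field <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- round(config$extent[2] / config$gsd)
  nc <- round(config$extent[1] / config$gsd)
  z <- with_seed(config$seed, matrix(stats::rnorm(nr * nc), nr, nc))
  z <- gauss_blur(z, (config$correlation_length_m / 2) / config$gsd)
  mask <- plot_mask(config, nr, nc)
  lo <- config$fvc_range[1]; hi <- config$fvc_range[2]
  out <- matrix(0, nr, nc)
  if (hi > lo) {
    zz <- z[mask]
    out[mask] <- lo + (hi - lo) * (z[mask] - min(zz)) / (max(zz) - min(zz))
  } else {
    out[mask] <- lo
  }
  scene_raster(out, gsd = config$gsd, origin = c(0, config$extent[2]))
}

#' Render surface reflectance from a cover field
#'
#' Linear endmember mixing: per pixel and band,
#' `r = FVC * veg + (1 - FVC) * soil + eps`, with `eps ~ N(0, noise_sd)`,
#' clipped to `[0, 1]`. Nodata cover cells propagate to all bands.
#'
#' @param fvc single-band `scene_raster` of cover fractions.
#' @param spectra an [endmember_spectra()].
#' @param bands band names to render; must be present in the spectra.
#' @param seed integer seed for the sensor noise.
#' @return multi-band `scene_raster` on the same grid.
#' @export
render_reflectance <- function(fvc, spectra, bands = names(spectra$vegetation),
                               seed = 1L) {
  stopifnot(is_scene_raster(fvc), inherits(spectra, "endmember_spectra"))
  missing <- setdiff(bands, names(spectra$vegetation))
  if (length(missing))
    stop_wfvc("bands not in spectra: %s", paste(missing, collapse = ", "))
  f <- fvc$values
  nr <- nrow(f); nc <- ncol(f)
  arr <- array(NA_real_, c(nr, nc, length(bands)),
               dimnames = list(NULL, NULL, bands))
  with_seed(seed, {
    for (b in bands) {
      r <- f * spectra$vegetation[[b]] + (1 - f) * spectra$soil[[b]]
      if (spectra$noise_sd[[b]] > 0)
        r <- r + matrix(stats::rnorm(nr * nc, sd = spectra$noise_sd[[b]]), nr, nc)
      arr[, , b] <- clamp01(r)
    }
  })
  scene_raster(arr, gsd = fvc$gsd, origin = fvc$origin, bands = bands)
}

#' Degrade a fine raster to a coarse sensor grid by block averaging
#'
#' Idealises the coarse sensor's point-spread function as the mean over each
#' `factor x factor` block of fine pixels.
#'
#' @param fine a `scene_raster` whose dimensions are divisible by `factor`.
#' @param factor integer aggregation factor.
#' @return `scene_raster` with `gsd * factor`.
#' @export
render_satellite_from_fine <- function(fine, factor) {
  stopifnot(is_scene_raster(fine))
  factor <- as.integer(factor)
  d <- raster_dim(fine)
  if (any(d %% factor != 0L))
    stop_wfvc("raster dimensions %d x %d not divisible by factor %d (crop first)",
              d[1], d[2], factor)
  if (is.matrix(fine$values)) {
    out <- block_mean(fine$values, factor)
    return(scene_raster(out, fine$gsd * factor, fine$origin))
  }
  arr <- array(NA_real_, c(d[1] %/% factor, d[2] %/% factor, n_bands(fine)),
               dimnames = list(NULL, NULL, fine$bands))
  for (b in fine$bands) arr[, , b] <- block_mean(fine$values[, , b], factor)
  scene_raster(arr, fine$gsd * factor, fine$origin, bands = fine$bands)
}

#' Render a synthetic ground photo with known cover
#'
#' A fraction `fvc_target` of pixels (to the nearest pixel) is assigned to
#' the vegetation class; a* values are drawn from the class Gaussians of the
#' colour model, L* and b* are per-class constants, and the L*a*b* image is
#' converted to sRGB (D65). Colours falling outside the sRGB gamut are
#' clipped and the clipped fraction reported.
#'
#' @param fvc_target target cover fraction in `[0, 1]`.
#' @param model a [photo_color_model()].
#' @param size `c(height, width)` in pixels.
#' @param seed integer seed.
#' @return list with elements `photo` (H x W x 3 sRGB array in `[0, 1]`),
#'   `mask` (logical truth mask, `TRUE` = vegetation), `fvc_realized`,
#'   `clip_fraction`.
#' @export
render_ground_photo <- function(fvc_target, model = photo_color_model(),
                                size = c(96, 96), seed = 1L) {
  stopifnot(inherits(model, "photo_color_model"))
  if (fvc_target < 0 || fvc_target > 1) stop_wfvc("fvc_target must lie in [0, 1]")
  h <- size[1]; w <- size[2]; n <- h * w
  n_veg <- round(fvc_target * n)
  with_seed(seed, {
    veg <- logical(n)
    if (n_veg > 0) veg[sample.int(n, n_veg)] <- TRUE
    a <- numeric(n)
    a[veg] <- stats::rnorm(n_veg, model$veg_a_mean, model$veg_a_sd)
    a[!veg] <- stats::rnorm(n - n_veg, model$bg_a_mean, model$bg_a_sd)
  })
  lab <- cbind(L = ifelse(veg, model$veg_L, model$bg_L),
               a = a,
               b = ifelse(veg, model$veg_b, model$bg_b))
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  clip_fraction <- mean(apply(srgb < 0 | srgb > 1, 1L, any))
  srgb <- clamp01(srgb)
  photo <- array(srgb, c(h, w, 3L))
  list(photo = photo, mask = matrix(veg, h, w),
       fvc_realized = n_veg / n, clip_fraction = clip_fraction)
}

# mean of fine cells whose centres fall inside a half-open square
square_mean <- function(r, cx, cy, half) {
  xs <- cell_x(r); ys <- cell_y(r)
  ix <- which(xs >= cx - half & xs < cx + half)
  iy <- which(ys >= cy - half & ys < cy + half)
  if (!length(ix) || !length(iy)) return(NA_real_)
  mean(r$values[iy, ix])
}

#' Lay out five-point ground sampling sites
#'
#' Each site is a 10 m square placed uniformly at random so that it fits
#' inside a single wheat plot; five 2 m sub-squares sit at its centre and on
#' its diagonals (sub-square 1 is the centre). The 2 m-scale reference value
#' of a site is the centre sub-square only; the 10 m-scale value is the mean
#' of all five. Candidate positions whose square falls outside the plot are
#' rejected and redrawn, with a bounded number of retries.
#'
#' @param config a [scene_config()].
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @param fvc optional fine cover field; regenerated from `config` if `NULL`.
#' @param site_size_m,sub_size_m side lengths of the site square and the
#'   photo sub-squares, metres.
#' @param diag_offset_m distance of the four diagonal sub-square centres from
#'   the site centre, along each axis.
#' @param max_tries rejection-sampling budget per site.
#' @return data.frame with columns `site_id, subsample_id, x, y, scale_m,
#'   truth_fvc`; `subsample_id == 1` marks the centre sub-square.
#' @export
place_ground_samples <- function(config, n_sites, seed = 1L, fvc = NULL,
                                 site_size_m = 10, sub_size_m = 2,
                                 diag_offset_m = 2.5, max_tries = 1000L) {
  stopifnot(inherits(config, "scene_config"), n_sites >= 1L)
  if (is.null(fvc)) fvc <- generate_fvc_field(config)
  half_site <- site_size_m / 2
  offs <- rbind(c(0, 0),
                c(-diag_offset_m,  diag_offset_m), c(diag_offset_m,  diag_offset_m),
                c(-diag_offset_m, -diag_offset_m), c(diag_offset_m, -diag_offset_m))
  fits <- config$plots$xmax - config$plots$xmin >= site_size_m &
          config$plots$ymax - config$plots$ymin >= site_size_m
  if (!any(fits)) stop_wfvc("no plot can hold a %g m site square", site_size_m)
  rows <- vector("list", n_sites)
  with_seed(seed, {
    for (s in seq_len(n_sites)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        k <- sample(which(fits), 1L)
        p <- config$plots[k, ]
        cx <- stats::runif(1, p$xmin, p$xmax)
        cy <- stats::runif(1, p$ymin, p$ymax)
        inside <- cx - half_site >= p$xmin && cx + half_site <= p$xmax &&
                  cy - half_site >= p$ymin && cy + half_site <= p$ymax
        if (inside) { placed <- TRUE; break }
      }
      if (!placed) stop_wfvc("could not place site %d inside a plot after %d tries",
                             s, max_tries)
      truth <- vapply(seq_len(5L), function(i) {
        square_mean(fvc, cx + offs[i, 1], cy + offs[i, 2], sub_size_m / 2)
      }, numeric(1))
      rows[[s]] <- data.frame(site_id = s, subsample_id = seq_len(5L),
                              x = cx + offs[, 1], y = cy + offs[, 2],
                              scale_m = sub_size_m, truth_fvc = truth)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
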