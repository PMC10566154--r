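# Shared fixtures and independent oracles used across test files.

# literal cubic-convolution interpolation: per target pixel, build the
# 1 x 4 row-weight vector, the 4 x 4 source neighbourhood (clamp padding)
# and the 4 x 1 column-weight vector, and take their product
bicubic_oracle <- function(src, factor) {
  W <- cubic_kernel
  nr_s <- nrow(src); nc_s <- ncol(src)
  out <- matrix(NA_real_, nr_s * factor, nc_s * factor)
  cl <- function(i, n) min(max(i, 1L), n)
  for (R in seq_len(nrow(out))) {
    sr <- (R - 0.5) / factor - 0.5
    i <- floor(sr); u <- sr - i
    A <- c(W(u + 1), W(u), W(u - 1), W(u - 2))
    for (C in seq_len(ncol(out))) {
      sc <- (C - 0.5) / factor - 0.5
      j <- floor(sc); v <- sc - j
      Cw <- c(W(v + 1), W(v), W(v - 1), W(v - 2))
      B <- matrix(0, 4, 4)
      for (a in 0:3) for (b in 0:3)
        B[a + 1, b + 1] <- src[cl(i + a, nr_s), cl(j + b, nc_s)]
      out[R, C] <- drop(A %*% B %*% Cw)
    }
  }
  out
}

# small two-plot scene for fast tests
tiny_scene <- function(stage = "jointing", seed = 1L, gsd = 0.25,
                       width = 60, height = 40, path_width = 4, ...) {
  default_scene(stage, width = width, height = height, path_width = path_width,
                gsd = gsd, seed = seed, ...)
}

# reflectance + truth sample table drawn from a rendered scene; with
# `cell_m` set, samples are taken from the zonally aggregated grids (the
# analysis scale of the workflow)
scene_samples <- function(scene, spectra, n = 150, seed = 1L,
                          bands = uas_bands(), cell_m = NULL) {
  truth <- generate_fvc_field(scene)
  refl <- render_reflectance(truth, spectra, bands, seed = seed + 1L)
  if (!is.null(cell_m)) {
    truth <- upscale_zonal(truth, cell_m = cell_m)
    refl <- upscale_zonal(refl, cell_m = cell_m)
  }
  idx <- withr::with_seed(seed, sample(which(truth$values > 0), n))
  df <- data.frame(fvc = as.numeric(truth$values)[idx])
  for (b in bands) df[[b]] <- as.numeric(get_band(refl, b))[idx]
  df
}
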