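# Gridded scene containers and plain-text raster / image I/O.
#
# Rasters are stored row-major from the top-left corner: row 1 is the
# northernmost line, `origin` is the (x, y) map coordinate of the top-left
# corner, and the centre of cell (r, c) sits at
#   x = origin[1] + (c - 0.5) * gsd,   y = origin[2] - (r - 0.5) * gsd.
# Nodata is represented as NA in memory and as -9999 on disk.

#' Construct a gridded scene raster
#'
#' The basic spatial container of the package: a single-band matrix (e.g. a
#' cover-fraction or NDVI grid) or a multi-band array (surface reflectance)
#' with a ground sampling distance and a top-left map origin.
#'
#' @param values numeric matrix (single band) or 3-d array with the third
#'   dimension indexing bands.
#' @param gsd ground sampling distance in metres (cell size, square cells).
#' @param origin length-2 numeric, map coordinate of the top-left corner.
#' @param bands character vector of band names for multi-band rasters;
#'   ignored (must be `NULL`) for single-band rasters.
#' @return an object of class `scene_raster`.
#' @export
scene_raster <- function(values, gsd, origin = c(0, 0), bands = NULL) {
  if (is.matrix(values)) {
    if (!is.null(bands) && length(bands) != 1L)
      stop_wfvc("single-band raster cannot carry %d band names", length(bands))
  } else if (is.array(values) && length(dim(values)) == 3L) {
    if (is.null(bands)) bands <- dimnames(values)[[3L]]
    if (is.null(bands) || length(bands) != dim(values)[3L])
      stop_wfvc("multi-band raster needs one name per band")
    dimnames(values)[[3L]] <- bands
  } else {
    stop_wfvc("values must be a matrix or a 3-d array")
  }
  if (!is.numeric(gsd) || length(gsd) != 1L || gsd <= 0)
    stop_wfvc("gsd must be a positive scalar")
  if (length(origin) != 2L || !is.numeric(origin))
    stop_wfvc("origin must be a length-2 numeric")
  structure(list(values = values, gsd = gsd, origin = as.numeric(origin),
                 bands = if (is.matrix(values)) NULL else bands),
            class = "scene_raster")
}

is_scene_raster <- function(x) inherits(x, "scene_raster")

n_bands <- function(r) if (is.matrix(r$values)) 1L else dim(r$values)[3L]

raster_dim <- function(r) dim(r$values)[1:2]

#' @export
print.scene_raster <- function(x, ...) {
  d <- raster_dim(x)
  bands <- if (is.null(x$bands)) "1 band" else
    sprintf("%d bands (%s)", length(x$bands), paste(x$bands, collapse = ", "))
  v <- as.numeric(x$values)
  cat(sprintf("<scene_raster> %d x %d cells, %s, gsd %g m\n", d[1], d[2], bands, x$gsd))
  cat(sprintf("  origin (%g, %g); values [%s, %s], %d nodata\n",
              x$origin[1], x$origin[2],
              format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
              format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4),
              sum(is.na(v))))
  invisible(x)
}

#' Extract one band of a raster as a matrix
#'
#' @param r a `scene_raster`.
#' @param band band name; ignored for single-band rasters.
#' @export
get_band <- function(r, band = NULL) {
  stopifnot(is_scene_raster(r))
  if (is.matrix(r$values)) return(r$values)
  if (is.null(band) || !(band %in% r$bands))
    stop_wfvc("band '%s' not present (have: %s)",
              band %||% "<NULL>", paste(r$bands, collapse = ", "))
  r$values[, , band]
}

# map coordinates of cell centres
cell_x <- function(r) r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$gsd
cell_y <- function(r) r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$gsd

# -- ESRI ASCII grid I/O ------------------------------------------------------
# Plain-text, single band per file; multi-band rasters are written as one
# file per band named <prefix>_<band>.asc. Nodata on disk is -9999.

write_one_asc <- function(m, gsd, origin, path, nodata = -9999) {
  nr <- nrow(m); nc <- ncol(m)
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2] - nr * gsd),
    sprintf("cellsize %.10g", gsd),
    sprintf("NODATA_value %g", nodata))
  rows <- apply(m, 1L, function(v) paste(sprintf("%.8g", v), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

read_one_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  for (need in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!need %in% key) stop_wfvc("malformed ASCII grid '%s': missing %s", path, need)
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  nr <- as.integer(val[["nrows"]]); nc <- as.integer(val[["ncols"]])
  if (length(body) != nr * nc)
    stop_wfvc("malformed ASCII grid '%s': expected %d values, found %d",
              path, nr * nc, length(body))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if ("nodata_value" %in% key) m[m == val[["nodata_value"]]] <- NA_real_
  list(values = m, gsd = val[["cellsize"]],
       origin = c(val[["xllcorner"]], val[["yllcorner"]] + nr * val[["cellsize"]]))
}

#' Write a raster to ESRI ASCII grid file(s)
#'
#' Single-band rasters are written to `<prefix>.asc`; multi-band rasters to
#' `<prefix>_<band>.asc`, one file per band. The format stores the cell size
#' and lower-left corner, so the geotransform round-trips exactly.
#'
#' @param r a `scene_raster`.
#' @param prefix output path without the `.asc` extension.
#' @return character vector of files written, invisibly.
#' @export
write_raster <- function(r, prefix) {
  stopifnot(is_scene_raster(r))
  if (is.matrix(r$values)) {
    files <- write_one_asc(r$values, r$gsd, r$origin, paste0(prefix, ".asc"))
  } else {
    files <- vapply(r$bands, function(b) {
      write_one_asc(r$values[, , b], r$gsd, r$origin,
                    sprintf("%s_%s.asc", prefix, b))
    }, character(1))
  }
  invisible(unname(files))
}

#' Read a raster written by [write_raster()]
#'
#' @param prefix path prefix used at write time.
#' @param bands `NULL` for a single-band raster, otherwise the band names to
#'   assemble from `<prefix>_<band>.asc` files.
#' @return a `scene_raster`.
#' @export
read_raster <- function(prefix, bands = NULL) {
  if (is.null(bands)) {
    one <- read_one_asc(if (file.exists(prefix)) prefix else paste0(prefix, ".asc"))
    return(scene_raster(one$values, one$gsd, one$origin))
  }
  parts <- lapply(bands, function(b) read_one_asc(sprintf("%s_%s.asc", prefix, b)))
  g <- parts[[1L]]
  arr <- array(NA_real_, c(dim(g$values), length(bands)),
               dimnames = list(NULL, NULL, bands))
  for (i in seq_along(bands)) arr[, , i] <- parts[[i]]$values
  scene_raster(arr, g$gsd, g$origin, bands = bands)
}

#' Write / read an RGB photo as PNG
#'
#' @param photo H x W x 3 array in `[0, 1]`, or the list returned by
#'   [render_ground_photo()].
#' @param path file path.
#' @export
write_photo <- function(photo, path) {
  if (is.list(photo) && !is.null(photo$photo)) photo <- photo$photo
  png::writePNG(photo, path)
  invisible(path)
}

#' @rdname write_photo
#' @export
read_photo <- function(path) png::readPNG(path)
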