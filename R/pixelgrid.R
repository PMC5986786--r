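# PixelGrid: a single-plane raster (integer labels or intensities) with an
# isotropic pixel size in micrometres. Matrix storage is image-style
# (values[row, col], row 1 at the top); all derived coordinates are in a y-up
# mathematical frame: pixel (r, c) has centre
#   x = (c - 0.5) * pixel_size,  y = (nrow - r + 0.5) * pixel_size,
# so pixel corners sit at integer multiples of pixel_size.

#' Construct a pixel grid
#'
#' @param values numeric or integer matrix; label grids must be non-negative
#'   integers with 0 reserved for background.
#' @param pixel_size micrometres per pixel (isotropic), > 0.
#' @param kind "labels" or "intensity".
#' @return a `pixel_grid` object.
#' @export
pixel_grid <- function(values, pixel_size, kind = c("intensity", "labels")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stopf("pixel_grid: values must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_grid: pixel_size must be a single positive number")
  if (kind == "labels") {
    if (any(values != round(values)) || any(values < 0))
      stopf("label grid must contain non-negative integers (0 = background)")
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "double"
  }
  structure(list(values = values, pixel_size = pixel_size, kind = kind),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid: %d x %d px, %.3g um/px, %s>\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$kind))
  invisible(x)
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

# pixel centre coordinates (um, y-up) for row/col index vectors
grid_xy <- function(grid, row, col) {
  cbind(x = (col - 0.5) * grid$pixel_size,
        y = (nrow(grid$values) - row + 0.5) * grid$pixel_size)
}

# inverse: um coordinates -> fractional (row, col)
grid_rc <- function(grid, x, y) {
  cbind(row = nrow(grid$values) - y / grid$pixel_size + 0.5,
        col = x / grid$pixel_size + 0.5)
}

#' Read a single-plane TIFF into a pixel grid
#'
#' Integer TIFFs (8/16-bit) are read as stored integers; float TIFFs as
#' doubles. Multi-channel images are rejected.
#'
#' @param path TIFF file path.
#' @param pixel_size micrometres per pixel; TIFF resolution tags are not
#'   relied upon.
#' @param kind "labels" or "intensity".
#' @return a `pixel_grid`.
#' @export
read_tiff_grid <- function(path, pixel_size, kind = c("intensity", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3) {
    if (dim(v)[3] == 1) v <- v[, , 1] else
      stopf("expected a single-plane TIFF, got %d channels: %s", dim(v)[3], path)
  }
  pixel_grid(v, pixel_size, kind)
}

#' Write a pixel grid to a single-plane TIFF
#'
#' Grids are written as 16-bit integers. Intensity values are rounded to the
#' nearest integer grey value, so the round trip is lossless for 8/16-bit
#' grey data (the native scale of confocal exports handled here).
#'
#' @param grid a `pixel_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  v <- if (grid$kind == "labels") grid$values else round(grid$values)
  if (max(v) > 65535L || min(v) < 0L)
    stopf("values outside the 16-bit grey range; cannot serialise")
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# read_tiff_grid's inverse scaling for 16-bit label TIFFs written above
read_label_tiff <- function(path, pixel_size) {
  g <- read_tiff_grid(path, pixel_size, "labels")
  g
}
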