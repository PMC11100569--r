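#' Construct a marker raster
#'
#' A single-channel intensity grid aligned to the cell coordinate frame.
#' Pixels follow the pixel-center convention: the center of pixel
#' \code{[i, j]} (row \code{i}, column \code{j}, 1-based) lies at
#' \code{origin + (j - 0.5, i - 0.5) * scale} micrometers, i.e. rows run
#' along y and columns along x.
#'
#' @param grid numeric matrix of non-negative intensities.
#' @param channel marker name.
#' @param scale micrometers per pixel (> 0); default 1.
#' @param origin length-2 offset (x, y) of the grid's outer corner, in um.
#' @return an object of class \code{marker_raster}.
#' @export
marker_raster <- function(grid, channel, scale = 1, origin = c(0, 0)) {
  grid <- as.matrix(grid)
  if (!is.numeric(grid) || any(!is.finite(grid)) || any(grid < 0))
    stop("grid values must be finite and >= 0")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  structure(list(grid = grid, channel = as.character(channel),
                 scale = scale, origin = as.numeric(origin)),
            class = "marker_raster")
}

#' @export
print.marker_raster <- function(x, ...) {
  cat(sprintf("marker_raster '%s': %d x %d px at %g um/px\n",
              x$channel, nrow(x$grid), ncol(x$grid), x$scale))
  invisible(x)
}

#' Read a single-channel TIFF marker raster
#'
#' @param path TIFF file, conventionally named
#'   \code{<region_id>_<marker>.tiff}.
#' @param channel marker name; default parsed from the filename pattern.
#' @param scale micrometers per pixel; default 1 (1-um^2 pixels).
#' @param origin coordinate offset in um; default \code{c(0, 0)}.
#' @return a \code{marker_raster}.
#' @export
read_marker_raster <- function(path, channel = NULL, scale = 1,
                               origin = c(0, 0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(channel)) {
    base <- sub("\\.tiff?$", "", basename(path))
    channel <- sub("^[^_]*_", "", base)
  }
  marker_raster(img, channel, scale = scale, origin = origin)
}

#' Write a marker raster to TIFF
#'
#' Intensities are stored as 32-bit floats so the grid round-trips exactly.
#'
#' @param x a \code{marker_raster}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_marker_raster <- function(x, path) {
  stopifnot(inherits(x, "marker_raster"))
  tiff::writeTIFF(x$grid / max(max(x$grid), 1e-12), path,
                  bits.per.sample = 32L)
  invisible(path)
}

# pixel-center coordinates (um) of raster rows (y) and columns (x)
raster_centers <- function(r) {
  list(x = r$origin[1] + (seq_len(ncol(r$grid)) - 0.5) * r$scale,
       y = r$origin[2] + (seq_len(nrow(r$grid)) - 0.5) * r$scale)
}
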