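#' Intensity raster with physical resolution
#'
#' The universal image carrier of the package: a 2-D grayscale matrix or an
#' H x W x 3 RGB array, together with the physical pixel size in micrometers
#' per pixel (isotropic) and the physical offset of pixel (0, 0).  Intensities
#' follow the 0--255 convention of 8-bit stained scans; derived feature images
#' may hold arbitrary floats.
#'
#' @param pixels numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @param resolution_um micrometers per pixel, a single positive number.
#' @param origin physical offset (x, y) of pixel (0, 0) center, in um.
#' @return An object of class `raster2d`.
#' @export
raster2d <- function(pixels, resolution_um = 1, origin = c(0, 0)) {
  if (is.matrix(pixels)) {
    nc <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    nc <- 3L
  } else {
    hf_stop("type_error", "raster pixels must be a matrix or an H x W x 3 array")
  }
  if (length(pixels) == 0) hf_stop("type_error", "raster pixel grid is empty")
  if (!is.numeric(resolution_um) || length(resolution_um) != 1 || resolution_um <= 0)
    hf_stop("type_error", "resolution_um must be a single positive number")
  structure(list(pixels = pixels, resolution_um = as.numeric(resolution_um),
                 origin = as.numeric(origin), channels = nc),
            class = "raster2d")
}

#' @export
print.raster2d <- function(x, ...) {
  d <- raster_shape(x)
  cat(sprintf("<raster2d %d x %d px, %d channel(s), %.4g um/px>\n",
              d[2], d[1], x$channels, x$resolution_um))
  invisible(x)
}

#' @export
dim.raster2d <- function(x) dim(x$pixels)

# (height, width)
raster_shape <- function(x) {
  if (inherits(x, "raster2d") || inherits(x, "binary_mask")) dim(x$pixels)[1:2]
  else dim(x)[1:2]
}

#' Binary tissue mask
#'
#' @param pixels logical matrix (TRUE = tissue).
#' @param resolution_um micrometers per pixel.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, resolution_um = 1) {
  if (!is.matrix(pixels)) hf_stop("type_error", "mask pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  structure(list(pixels = pixels, resolution_um = as.numeric(resolution_um)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d tissue px, %.4g um/px>\n",
              ncol(x$pixels), nrow(x$pixels), sum(x$pixels), x$resolution_um))
  invisible(x)
}

#' Mask area in square micrometers
#' @param mask a [binary_mask()].
#' @return total TRUE area in um^2.
#' @export
mask_area_um2 <- function(mask) sum(mask$pixels) * mask$resolution_um^2

# mask centroid in 0-based (x, y) pixel coordinates
mask_centroid <- function(mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0) hf_stop("no_tissue_error", "mask is empty (no tissue)")
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
}

# bounding box of TRUE pixels: 0-based (x0, y0, x1, y1), inclusive
mask_bbox <- function(mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0) hf_stop("no_tissue_error", "mask is empty (no tissue)")
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]) - 1, max(idx[, 1]) - 1)
}

# convert raster to grayscale matrix using the 0.299/0.587/0.114 luminance
to_gray <- function(img) {
  if (img$channels == 1) return(img$pixels)
  p <- img$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}

# apply a per-channel function returning same-shape matrices
map_channels <- function(img, f) {
  if (img$channels == 1) {
    out <- f(img$pixels)
  } else {
    out <- array(0, c(dim(f(img$pixels[, , 1])), 3))
    for (k in 1:3) out[, , k] <- f(img$pixels[, , k])
  }
  raster2d(out, img$resolution_um, img$origin)
}

# resize a raster to (h, w); interp "linear" or "nearest"
resize_raster <- function(img, h, w, interp = "linear") {
  code <- if (interp == "nearest") 0L else 1L
  map_channels(img, function(m) cpp_resize(m, as.integer(h), as.integer(w), code))
}
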