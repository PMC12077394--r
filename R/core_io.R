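#' Read a TIFF or PNG image as a raster
#'
#' Intensities are returned on the 0--255 scale.  RGB images keep their 3
#' channels; an alpha channel, if present, is dropped.  The physical pixel
#' size is not read from file metadata but supplied by the caller (stained
#' scans in this workflow are exported at a known resolution, typically
#' 1 um/px).
#'
#' @param path file path (.tif/.tiff/.png).
#' @param resolution_um micrometers per pixel to attach.
#' @return A [raster2d()].
#' @export
read_image <- function(path, resolution_um = 1) {
  if (!file.exists(path)) hf_stop("format_error", "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path),
           png = png::readPNG(path),
           hf_stop("format_error", "unsupported image format '%s' for %s", ext, path)),
    error = function(e) {
      if (inherits(e, "histofuse_error")) stop(e)
      hf_stop("format_error", "unreadable image file %s: %s", path, conditionMessage(e))
    })
  arr <- arr * 255
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
    else arr <- arr[, , 1]
  }
  raster2d(arr, resolution_um)
}

#' Write a raster to TIFF or PNG
#'
#' @param img a [raster2d()] with intensities on the 0--255 scale.
#' @param path destination (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  p <- pmin(pmax(img$pixels / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(p, path, bits.per.sample = 8L),
         png = png::writePNG(p, path),
         hf_stop("format_error", "unsupported image format '%s' for %s", ext, path))
  invisible(path)
}

#' Read a binary tissue mask from a single-channel TIFF or PNG (0/255)
#' @param path file path.
#' @param resolution_um micrometers per pixel to attach.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, resolution_um = 1) {
  img <- read_image(path, resolution_um)
  binary_mask(to_gray(img) > 127, resolution_um)
}

#' Write a binary mask as an 8-bit 0/255 image
#' @param mask a [binary_mask()].
#' @param path destination (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(0, nrow(mask$pixels), ncol(mask$pixels))
  m[mask$pixels] <- 255
  write_image(raster2d(m, mask$resolution_um), path)
}

#' Ordered 2-D pointset in pixel coordinates of a named image space
#'
#' @param points two-column matrix or data.frame of (x, y) pixel coordinates.
#' @param space free-text tag naming the image space the coordinates live in.
#' @return An object of class `pointset2d` (a data.frame with columns x, y).
#' @export
pointset2d <- function(points, space = "") {
  df <- as.data.frame(points)
  if (ncol(df) < 2) df <- data.frame(x = numeric(0), y = numeric(0))
  names(df)[1:2] <- c("x", "y")
  df <- df[, c("x", "y"), drop = FALSE]
  if (nrow(df) > 0 && (!is.numeric(df$x) || !is.numeric(df$y) ||
                       any(!is.finite(df$x)) || any(!is.finite(df$y))))
    hf_stop("schema_error", "pointset coordinates must be finite numerics")
  attr(df, "space") <- space
  class(df) <- c("pointset2d", "data.frame")
  df
}

#' Read a pointset from CSV (columns x, y; header required)
#' @param path CSV file path.
#' @param space space tag to attach.
#' @return A [pointset2d()] with point order preserved.
#' @export
read_pointset <- function(path, space = "") {
  if (!file.exists(path)) hf_stop("format_error", "pointset file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    hf_stop("schema_error", "pointset CSV %s must have columns 'x' and 'y'", path)
  if (nrow(df) > 0 && (!is.numeric(df$x) || !is.numeric(df$y)))
    hf_stop("schema_error", "non-numeric coordinate values in %s", path)
  pointset2d(df[, c("x", "y")], space)
}

#' Write a pointset to CSV
#' @param pts a [pointset2d()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_pointset <- function(pts, path) {
  write.csv(data.frame(x = pts$x, y = pts$y), path, row.names = FALSE)
  invisible(path)
}

#' Labeled polygon annotation
#'
#' `shapes` is a list of polygons; each polygon is a list with an `outer`
#' ring (n x 2 matrix of (x, y) vertices, not closed) and a possibly empty
#' list of `holes`.
#'
#' @param shapes list of polygons as described above.
#' @param labels character vector of class labels, one per shape.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(shapes, labels = rep("", length(shapes))) {
  for (s in shapes) {
    if (nrow(s$outer) < 3) hf_stop("type_error", "polygon ring needs >= 3 vertices")
    for (h in s$holes) if (nrow(h) < 3)
      hf_stop("type_error", "polygon hole ring needs >= 3 vertices")
  }
  structure(list(shapes = shapes, labels = as.character(labels)),
            class = "polygon_annotation")
}

# strip a closing vertex if the ring repeats its first point
ring_open <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geojson_label <- function(props) {
  if (is.null(props)) return("")
  cls <- props$classification
  if (!is.null(cls)) {
    if (is.list(cls) && !is.null(cls$name)) return(as.character(cls$name))
    return(as.character(cls))
  }
  if (!is.null(props$label)) return(as.character(props$label))
  ""
}

#' Read polygon annotations from a GeoJSON FeatureCollection
#'
#' Polygon and MultiPolygon geometries are supported; a MultiPolygon expands
#' into one shape per polygon sharing the feature's label.  Labels are taken
#' from a `classification` (QuPath-style, possibly nested with a `name`) or
#' `label` property.
#'
#' @param path GeoJSON file path.
#' @return A [polygon_annotation()].
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) hf_stop("format_error", "geojson file not found: %s", path)
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else hf_stop("format_error", "%s is not a GeoJSON FeatureCollection", path)
  shapes <- list(); labels <- character(0)
  poly_from_coords <- function(coords) {
    rings <- lapply(coords, function(r)
      ring_open(do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))))
    list(outer = rings[[1]],
         holes = if (length(rings) > 1) rings[-1] else list())
  }
  for (f in feats) {
    g <- f$geometry
    lab <- geojson_label(f$properties)
    if (identical(g$type, "Polygon")) {
      shapes[[length(shapes) + 1]] <- poly_from_coords(g$coordinates)
      labels <- c(labels, lab)
    } else if (identical(g$type, "MultiPolygon")) {
      for (pc in g$coordinates) {
        shapes[[length(shapes) + 1]] <- poly_from_coords(pc)
        labels <- c(labels, lab)
      }
    } else {
      hf_stop("unsupported_geometry_error",
              "unsupported GeoJSON geometry type '%s' (only Polygon/MultiPolygon)",
              as.character(g$type))
    }
  }
  polygon_annotation(shapes, labels)
}

#' Write polygon annotations as a GeoJSON FeatureCollection
#'
#' Vertices are written with 6 decimal places so a read/write round trip
#' preserves coordinates to that precision; rings are closed on output.
#'
#' @param ann a [polygon_annotation()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(ann, path) {
  close_ring <- function(m) {
    m <- round(m, 6)
    lapply(seq_len(nrow(m) + 1), function(i) {
      j <- if (i > nrow(m)) 1 else i
      list(m[j, 1], m[j, 2])
    })
  }
  feats <- lapply(seq_along(ann$shapes), function(i) {
    s <- ann$shapes[[i]]
    coords <- c(list(close_ring(s$outer)), lapply(s$holes, close_ring))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(label = ann$labels[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
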