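# Grid projection of parametric spot/pixel omics geometries into reference
# matrices (integer label rasters at stained-image resolution) and rigid
# registration of pixel-based omics (MSI) to its stained image.

#' Spot-based omics geometry (Visium-style circular capture spots)
#'
#' @param ids unique spot identifiers (e.g. barcodes).
#' @param centers_um n x 2 matrix of spot centers (x, y) in micrometers,
#'   stained-image space.
#' @param diameter_um spot diameter in micrometers (default 55).
#' @param pitch_um nominal center-to-center distance (default 100).
#' @return An object of class `spot_geometry`.
#' @export
spot_geometry <- function(ids, centers_um, diameter_um = 55, pitch_um = 100) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) hf_stop("type_error", "spot ids must be unique")
  centers_um <- as.matrix(centers_um)
  if (nrow(centers_um) != length(ids))
    hf_stop("type_error", "one center per spot id required")
  if (diameter_um > pitch_um)
    hf_stop("type_error", "spot diameter exceeds the lattice pitch (spots would overlap)")
  structure(list(ids = ids, centers_um = centers_um,
                 diameter_um = diameter_um, pitch_um = pitch_um),
            class = "spot_geometry")
}

#' Pixel-based omics geometry (MSI-style square raster)
#'
#' @param ids unique pixel identifiers.
#' @param cols,rows integer grid coordinates per pixel (0-based).
#' @param origin_um physical (x, y) of the top-left corner of grid cell
#'   (0, 0), in micrometers.
#' @param pitch_um pixel edge length in micrometers (default 30, square).
#' @return An object of class `pixel_geometry`.
#' @export
pixel_geometry <- function(ids, cols, rows, origin_um = c(0, 0), pitch_um = 30) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) hf_stop("type_error", "pixel ids must be unique")
  if (anyDuplicated(cbind(cols, rows)))
    hf_stop("type_error", "one pixel id per grid cell required")
  structure(list(ids = ids, cols = as.integer(cols), rows = as.integer(rows),
                 origin_um = as.numeric(origin_um), pitch_um = pitch_um),
            class = "pixel_geometry")
}

#' Reference matrix: integer label raster at stained-image resolution
#'
#' Raster cell value 0 denotes background; value k > 0 refers to the omics
#' data point `ids[k]`.
#'
#' @param labels integer matrix of label values.
#' @param ids character vector mapping label k to a data-point id.
#' @param resolution_um micrometers per raster cell.
#' @return An object of class `reference_matrix`.
#' @export
reference_matrix <- function(labels, ids, resolution_um = 1) {
  storage.mode(labels) <- "integer"
  if (max(labels, 0L) > length(ids))
    hf_stop("type_error", "label value without id lookup entry")
  structure(list(labels = labels, ids = as.character(ids),
                 resolution_um = resolution_um),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("<reference_matrix %d x %d, %d data point(s), %.4g um/px>\n",
              ncol(x$labels), nrow(x$labels), length(x$ids), x$resolution_um))
  invisible(x)
}

#' Project circular spots into a reference matrix
#'
#' A raster cell is labeled with a spot's reference iff the cell center lies
#' within the spot circle (pixel-center inclusion; the fusion weights recover
#' sub-spot precision).  Overlapping circles are resolved in favor of the
#' lower id with a warning; spots entirely outside the image are listed in
#' the `off_image` attribute.
#'
#' @param geom a [spot_geometry()].
#' @param image_shape (height, width) of the stained image in pixels.
#' @param resolution_um stained-image resolution (um per pixel).
#' @return A [reference_matrix()].
#' @export
project_spots <- function(geom, image_shape, resolution_um = 1) {
  H <- image_shape[1]; W <- image_shape[2]
  lab <- matrix(0L, H, W)
  r_px <- geom$diameter_um / 2 / resolution_um
  cx <- geom$centers_um[, 1] / resolution_um
  cy <- geom$centers_um[, 2] / resolution_um
  off <- character(0); clashes <- 0L
  ord <- rev(seq_along(geom$ids))  # paint earlier ids last -> they win ties
  for (k in ord) {
    x0 <- max(0, ceiling(cx[k] - r_px)); x1 <- min(W - 1, floor(cx[k] + r_px))
    y0 <- max(0, ceiling(cy[k] - r_px)); y1 <- min(H - 1, floor(cy[k] + r_px))
    if (x0 > x1 || y0 > y1) { off <- c(off, geom$ids[k]); next }
    xs <- x0:x1; ys <- y0:y1
    inside <- outer((ys - cy[k])^2, (xs - cx[k])^2, "+") <= r_px^2
    if (!any(inside)) { off <- c(off, geom$ids[k]); next }
    block <- lab[ys + 1, xs + 1, drop = FALSE]
    clashes <- clashes + sum(block[inside] != 0L)
    block[inside] <- k
    lab[ys + 1, xs + 1] <- block
  }
  if (clashes > 0)
    hf_warn("overlap_warning", "%d raster cells claimed by multiple spots (lower id kept)",
            clashes)
  out <- reference_matrix(lab, geom$ids, resolution_um)
  attr(out, "off_image") <- off
  out
}

#' Project square omics pixels into a reference matrix
#'
#' Each pixel occupies the axis-aligned square
#' `[origin + col * pitch, origin + (col + 1) * pitch)` (and likewise in y);
#' raster cells whose centers fall inside are labeled.  At 1 um/px and 30 um
#' pitch every interior pixel covers exactly 900 cells.
#'
#' @param geom a [pixel_geometry()].
#' @param image_shape (height, width) of the stained image in pixels.
#' @param resolution_um stained-image resolution (um per pixel).
#' @return A [reference_matrix()].
#' @export
project_pixels <- function(geom, image_shape, resolution_um = 1) {
  H <- image_shape[1]; W <- image_shape[2]
  lab <- matrix(0L, H, W)
  p <- geom$pitch_um / resolution_um
  ox <- geom$origin_um[1] / resolution_um
  oy <- geom$origin_um[2] / resolution_um
  for (k in seq_along(geom$ids)) {
    # raster centers (integers) in [x0, x0 + p) etc.
    x0 <- ox + geom$cols[k] * p; y0 <- oy + geom$rows[k] * p
    xs <- ceiling(x0):(ceiling(x0 + p) - 1)
    ys <- ceiling(y0):(ceiling(y0 + p) - 1)
    xs <- xs[xs >= 0 & xs < W]; ys <- ys[ys >= 0 & ys < H]
    if (!length(xs) || !length(ys)) next
    lab[ys + 1, xs + 1] <- k
  }
  reference_matrix(lab, geom$ids, resolution_um)
}

#' Molecular measurement table
#'
#' @param ids data-point identifiers matching a geometry's ids.
#' @param values numeric matrix or data.frame (one row per id, one column
#'   per named measure, e.g. per-m/z intensity or per-gene score).
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(ids, values) {
  ids <- as.character(ids)
  values <- as.matrix(values)
  if (nrow(values) != length(ids))
    hf_stop("type_error", "one value row per id required")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  structure(list(ids = ids, values = values), class = "measurement_table")
}

#' First-principal-component feature image of pixel-based omics data
#'
#' Spectra are mean-centered and projected on the first principal axis; the
#' scores are min-max scaled to \[0, 1\] with the sign chosen so that the
#' interior (on-tissue) mean exceeds the grid-border mean, rasterized on the
#' omics pixel grid and upscaled to the target resolution.  Single-channel
#' tables pass through (scaled).
#'
#' @param table a [measurement_table()] over `geom`'s ids.
#' @param geom a [pixel_geometry()].
#' @param target_resolution_um resolution of the output raster (um per px).
#' @return A [raster2d()] feature image in \[0, 1\].
#' @export
msi_feature_image <- function(table, geom, target_resolution_um = 1) {
  idx <- match(geom$ids, table$ids)
  if (anyNA(idx)) hf_stop("integrity_error", "measurement table is missing pixel ids")
  V <- table$values[idx, , drop = FALSE]
  if (ncol(V) == 1) {
    score <- V[, 1]
  } else {
    if (all(apply(V, 2, sd) < 1e-12))
      hf_stop("degenerate_component_error", "constant spectra: first principal component undefined")
    pc <- prcomp(V, center = TRUE, scale. = FALSE)
    score <- pc$x[, 1]
  }
  rng <- range(score)
  if (diff(rng) < 1e-300)
    hf_stop("degenerate_component_error", "degenerate feature scores (constant)")
  score <- (score - rng[1]) / diff(rng)
  # sign convention: interior pixels should score higher than border pixels
  key <- paste(geom$cols, geom$rows)
  nb <- function(dc, dr) paste(geom$cols + dc, geom$rows + dr) %in% key
  n_nb <- nb(1, 0) + nb(-1, 0) + nb(0, 1) + nb(0, -1)
  border <- n_nb < 4
  if (any(border) && any(!border) &&
      mean(score[!border]) < mean(score[border])) score <- 1 - score
  # rasterize on the omics grid
  c0 <- min(geom$cols); r0 <- min(geom$rows)
  grid <- matrix(0, max(geom$rows) - r0 + 1, max(geom$cols) - c0 + 1)
  grid[cbind(geom$rows - r0 + 1, geom$cols - c0 + 1)] <- score
  sc <- geom$pitch_um / target_resolution_um
  out <- cpp_resize(grid, as.integer(round(nrow(grid) * sc)),
                    as.integer(round(ncol(grid) * sc)), 1L)
  img <- raster2d(out, target_resolution_um)
  img$origin <- c(geom$origin_um[1] + c0 * geom$pitch_um,
                  geom$origin_um[2] + r0 * geom$pitch_um)
  img
}

#' Rigid registration of an omics feature image onto its stained image
#'
#' The stained image is segmented and cropped to the tissue boundary, both
#' images are padded to a uniform square plus a 100 px border, and a rigid
#' transform (rotation + translation only) is optimized under the windowed
#' NCC using the affine machinery restricted to 3 parameters.  When masks
#' are available for both images they are registered directly instead of
#' the intensities.
#'
#' @param feature moving [raster2d()] (e.g. from [msi_feature_image()]),
#'   already at the stained image's resolution.
#' @param stained fixed [raster2d()] stained image.
#' @param stained_mask optional [binary_mask()] for the stained image.
#' @param feature_mask optional moving-side mask; providing both masks
#'   switches to mask-on-mask registration.
#' @param opts a [reg_options()] list.
#' @param invert_feature if `TRUE` (default) the feature image is inverted
#'   so tissue is dark on light, matching stained-scan polarity.
#' @return A `registration_result` whose chain maps feature pixel
#'   coordinates to stained pixel coordinates (rigid).
#' @export
rigid_register_msi <- function(feature, stained, stained_mask = NULL,
                               feature_mask = NULL, opts = reg_options(),
                               invert_feature = TRUE) {
  if (is.null(stained_mask)) stained_mask <- segment_tissue(stained, opts$min_region_um2)
  mask_mode <- !is.null(feature_mask)
  if (mask_mode) {
    mv <- raster2d(255 * (1 - feature_mask$pixels), feature$resolution_um)
    fx <- raster2d(255 * (1 - stained_mask$pixels), stained$resolution_um)
  } else {
    g <- feature$pixels
    g <- (g - min(g)) / max(diff(range(g)), 1e-12)
    if (invert_feature) g <- 1 - g
    mv <- raster2d(g * 255, feature$resolution_um)
    fx <- raster2d(to_gray(stained), stained$resolution_um)
  }
  if (is.null(feature_mask))
    feature_mask <- segment_tissue(mv, opts$min_region_um2)
  opts$denoise <- FALSE
  pp <- prepare_pair(mv, fx, feature_mask, stained_mask, "nonrigid", opts)
  aff <- affine_register(pp$moving, pp$fixed, opts, rigid = TRUE)
  steps <- list(
    chain_step("affine", from = "feature", to = "work_m",
               fwd = pp$moving$bookkeeping$affine),
    chain_step("affine", from = "work_m", to = "work_f", fwd = aff),
    chain_step("affine", from = "work_f", to = "stained",
               fwd = affine_invert(pp$fixed$bookkeeping$affine)))
  chain <- transform_chain(steps, raster_shape(feature), raster_shape(stained),
                           stained$resolution_um)
  structure(list(chain = chain, affine = aff, field = NULL,
                 moving_bookkeeping = pp$moving$bookkeeping$affine,
                 fixed_bookkeeping = pp$fixed$bookkeeping$affine,
                 similarity = attr(aff, "similarity")),
            class = "registration_result")
}

#' Warp a reference matrix through a transform (nearest-neighbor)
#'
#' Nearest-neighbor resampling never invents labels, so the warped matrix
#' references the same data points.
#'
#' @param ref a [reference_matrix()].
#' @param transform a [transform_chain()], [displacement_field()] or
#'   [affine_transform()] into the target image space.
#' @return The warped [reference_matrix()].
#' @export
warp_reference_matrix <- function(ref, transform) {
  reference_matrix(warp_labels(ref$labels, transform), ref$ids, ref$resolution_um)
}

#' Write / read a reference matrix as TIFF labels + id lookup CSV
#' @param ref a [reference_matrix()].
#' @param label_path destination label TIFF (16-bit).
#' @param ids_path destination id lookup CSV (columns label, id).
#' @return `label_path`, invisibly.
#' @export
write_reference_matrix <- function(ref, label_path, ids_path) {
  tiff::writeTIFF(ref$labels / 65535, label_path, bits.per.sample = 16L)
  write.csv(data.frame(label = seq_along(ref$ids), id = ref$ids),
            ids_path, row.names = FALSE)
  invisible(label_path)
}

#' @rdname write_reference_matrix
#' @param resolution_um resolution to attach on read.
#' @export
read_reference_matrix <- function(label_path, ids_path, resolution_um = 1) {
  m <- tiff::readTIFF(label_path)
  ids <- read.csv(ids_path, stringsAsFactors = FALSE)
  reference_matrix(matrix(as.integer(round(m * 65535)), nrow(m)),
                   as.character(ids$id), resolution_um)
}
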