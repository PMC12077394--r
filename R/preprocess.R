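# Preprocessing: tissue segmentation, mean-shift denoising and construction
# of the registration-ready (grayscale, square, padded) image pair, with all
# geometric bookkeeping recorded as exact affine maps.

# Otsu threshold on a numeric vector (256-bin histogram, 0..255 scale)
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v) + 1, 1), 256), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1
}

#' Segment the tissue region of a stained image
#'
#' Classical segmentation pipeline: the image is resampled to 640 x 640 and
#' converted to grayscale, total-variation denoised (Chambolle's algorithm)
#' to suppress background noise, thresholded with Otsu's method (tissue =
#' darker than threshold on a light slide background by default), closed with
#' a 5 px disk, cleaned of small connected components, and the mask is
#' resampled back to the original size.
#'
#' @param image a [raster2d()].
#' @param min_region_um2 connected components with smaller area (in um^2,
#'   measured in the original space) are removed; default 10000.
#' @param dark_tissue if `TRUE` (default) tissue is darker than background.
#' @param tv_weight regularization weight of the total-variation denoiser.
#' @param threshold optional manual threshold overriding Otsu.
#' @return A [binary_mask()] in the original image space.  If no tissue is
#'   found the mask is empty and carries attribute `no_tissue = TRUE`.
#' @export
segment_tissue <- function(image, min_region_um2 = 10000, dark_tissue = TRUE,
                           tv_weight = 8, threshold = NULL) {
  seg_size <- 640L
  g <- to_gray(resize_raster(image, seg_size, seg_size))
  g <- cpp_tv_denoise(g, tv_weight, 40L)
  thr <- if (is.null(threshold)) otsu_threshold(as.numeric(g)) else threshold
  m <- if (dark_tissue) g < thr else g > thr
  rng <- diff(range(g))
  if (rng < 1) m[] <- FALSE  # fully uniform image: nothing to segment
  m <- cpp_morph_disk(cpp_morph_disk(m, 5L, 1L), 5L, 0L)  # closing
  # area filter at the 640 scale, threshold rescaled to 640-space pixels
  shp <- raster_shape(image)
  px_area_um2 <- (shp[1] / seg_size) * (shp[2] / seg_size) * image$resolution_um^2
  m <- filter_small_regions(binary_mask(m), min_region_um2 / px_area_um2)$pixels
  full <- cpp_resize(matrix(as.numeric(m), seg_size, seg_size),
                     shp[1], shp[2], 0L) > 0.5
  out <- binary_mask(full, image$resolution_um)
  if (!any(full)) {
    attr(out, "no_tissue") <- TRUE
    hf_warn("no_tissue_warning", "no tissue found during segmentation")
  }
  out
}

#' Remove small connected regions from a binary mask
#'
#' Regions are 8-connected; a region survives iff its area (pixel count times
#' squared resolution) is at least `min_area_um2`.
#'
#' @param mask a [binary_mask()].
#' @param min_area_um2 minimum region area in um^2.
#' @return The filtered [binary_mask()].
#' @export
filter_small_regions <- function(mask, min_area_um2) {
  lab <- cpp_label_components(mask$pixels)
  if (max(lab) == 0) return(mask)
  px_area <- mask$resolution_um^2
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(counts * px_area >= min_area_um2)
  binary_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)), mask$resolution_um)
}

# vectorized HSV <-> RGB on 0..255 matrices
rgb_to_hsv255 <- function(r, g, b) {
  h <- grDevices::rgb2hsv(rbind(as.numeric(r), as.numeric(g), as.numeric(b)),
                          maxColorValue = 255)
  list(h = matrix(h[1, ] * 255, nrow(r)), s = matrix(h[2, ] * 255, nrow(r)),
       v = matrix(h[3, ] * 255, nrow(r)))
}

hsv255_to_rgb <- function(h, s, v) {
  hh <- as.numeric(h) / 255 * 6
  ss <- as.numeric(s) / 255
  vv <- as.numeric(v)
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- vv * (1 - ss); q <- vv * (1 - f * ss); t <- vv * (1 - (1 - f) * ss)
  r <- ifelse(i == 0, vv, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, vv)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, vv, ifelse(i == 2, vv,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, vv, ifelse(i == 4, vv, q)))))
  n <- nrow(h)
  list(r = matrix(r, n), g = matrix(g, n), b = matrix(b, n))
}

#' Edge-preserving mean-shift denoising of a color image
#'
#' The image is resampled to 512 x 512, converted to HSV, and each pixel's
#' joint (x, y, H, S, V) vector is iteratively replaced by the mean over
#' neighbors within the spatial and color windows until the combined shift
#' drops below 1 or 10 iterations are reached; the result is converted back
#' to RGB and resampled to the original size.
#'
#' @param image a 3-channel [raster2d()].
#' @param spatial_radius spatial window radius in pixels (default 20).
#' @param color_radius color window radius in intensity units (default 15).
#' @return The denoised [raster2d()].
#' @export
denoise_mean_shift <- function(image, spatial_radius = 20, color_radius = 15) {
  if (image$channels != 3)
    hf_stop("channel_error", "mean-shift denoising requires a 3-channel image")
  shp <- raster_shape(image)
  small <- resize_raster(image, 512, 512)
  hsv <- rgb_to_hsv255(small$pixels[, , 1], small$pixels[, , 2], small$pixels[, , 3])
  res <- cpp_mean_shift(hsv$h, hsv$s, hsv$v, as.integer(spatial_radius),
                        color_radius, 10L, 1.0)
  rgb <- hsv255_to_rgb(res$c1, res$c2, res$c3)
  out <- array(0, c(512, 512, 3))
  out[, , 1] <- rgb$r; out[, , 2] <- rgb$g; out[, , 3] <- rgb$b
  resize_raster(raster2d(out, image$resolution_um), shp[1], shp[2])
}

# --- bookkeeping -----------------------------------------------------------

# crop a raster/mask matrix to a 0-based inclusive bbox (x0, y0, x1, y1)
crop_pixels <- function(px, bb) {
  if (is.matrix(px)) px[(bb[2] + 1):(bb[4] + 1), (bb[1] + 1):(bb[3] + 1), drop = FALSE]
  else px[(bb[2] + 1):(bb[4] + 1), (bb[1] + 1):(bb[3] + 1), , drop = FALSE]
}

pad_pixels <- function(px, l, r, t, b, value) {
  d <- dim(px)
  if (is.matrix(px)) {
    out <- matrix(value, d[1] + t + b, d[2] + l + r)
    out[(t + 1):(t + d[1]), (l + 1):(l + d[2])] <- px
  } else {
    out <- array(value, c(d[1] + t + b, d[2] + l + r, d[3]))
    out[(t + 1):(t + d[1]), (l + 1):(l + d[2]), ] <- px
  }
  out
}

preprocessed_image <- function(image, mask, bookkeeping, orig_shape) {
  structure(list(image = image, mask = mask, bookkeeping = bookkeeping,
                 orig_shape = orig_shape),
            class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  d <- raster_shape(x$image)
  cat(sprintf("<preprocessed_image %d x %d (from %d x %d)>\n",
              d[2], d[1], x$orig_shape[2], x$orig_shape[1]))
  invisible(x)
}

# preprocess one image: mask -> blank background -> crop to bbox -> pad to
# `target_square` -> (denoise) -> Gaussian sigma 2 -> resize to working_size
# -> grayscale -> pad pad_px.  Returns the preprocessed image and the exact
# original->working affine.
preprocess_one <- function(image, mask, target_square, for_stage, opts) {
  bb <- mask_bbox(mask)
  px <- image$pixels
  bg <- 255
  if (is.matrix(px)) px[!mask$pixels] <- bg
  else for (k in 1:3) { ch <- px[, , k]; ch[!mask$pixels] <- bg; px[, , k] <- ch }
  px <- crop_pixels(px, bb)
  mk <- crop_pixels(mask$pixels, bb)
  ch <- dim(px)[1]; cw <- dim(px)[2]
  pl <- floor((target_square - cw) / 2); pr <- target_square - cw - pl
  pt <- floor((target_square - ch) / 2); pb <- target_square - ch - pt
  px <- pad_pixels(px, pl, pr, pt, pb, bg)
  mk <- pad_pixels(mk, pl, pr, pt, pb, FALSE)
  img <- raster2d(px, image$resolution_um)
  if (identical(for_stage, "affine") && isTRUE(opts$denoise) && img$channels == 3)
    img <- denoise_mean_shift(img, opts$denoise_spatial_radius,
                              opts$denoise_color_radius)
  img <- map_channels(img, function(m) cpp_gauss_smooth(m, 2))
  ws <- opts$working_size
  img <- resize_raster(img, ws, ws)
  g <- raster2d(to_gray(img), image$resolution_um)
  pad <- opts$pad_px
  g <- raster2d(pad_pixels(g$pixels, pad, pad, pad, pad, bg), image$resolution_um)
  mk <- cpp_resize(matrix(as.numeric(mk), target_square, target_square),
                   ws, ws, 0L) > 0.5
  mk <- pad_pixels(mk, pad, pad, pad, pad, FALSE)
  # bookkeeping: translate(-bb0) -> translate(pad_lt) -> scale(ws/sq) -> translate(pad)
  steps <- list(
    crop = affine_translation(-bb[1], -bb[2]),
    square_pad = affine_translation(pl, pt),
    scale = shape_scale_affine(c(target_square, target_square), c(ws, ws)),
    border_pad = affine_translation(pad, pad))
  bk <- Reduce(function(a, b) affine_compose(b, a), steps)
  preprocessed_image(g, binary_mask(mk, image$resolution_um),
                     list(steps = steps, affine = bk), raster_shape(image))
}

#' Build the registration-ready image pair
#'
#' Both images are masked (background blanked to white), cropped to their
#' tissue bounding boxes, padded to a common square, optionally mean-shift
#' denoised (affine stage only), smoothed with a Gaussian (sigma 2),
#' resampled to the working resolution (default 1024 x 1024), converted to
#' grayscale and padded with 100 px on all sides to leave room for
#' deformations.  Every geometric step is recorded as an exact affine map
#' from the original to the working space.
#'
#' @param moving,fixed [raster2d()] images.
#' @param moving_mask,fixed_mask optional [binary_mask()]s; computed with
#'   [segment_tissue()] when missing.
#' @param for_stage `"affine"` (with denoising) or `"nonrigid"` (without).
#' @param opts a [reg_options()] list.
#' @return List with elements `moving` and `fixed`, each a
#'   `preprocessed_image` (working-space image + mask + bookkeeping).
#' @export
prepare_pair <- function(moving, fixed, moving_mask = NULL, fixed_mask = NULL,
                         for_stage = c("affine", "nonrigid"),
                         opts = reg_options()) {
  for_stage <- match.arg(for_stage)
  if (is.null(moving_mask)) moving_mask <- segment_tissue(moving, opts$min_region_um2)
  if (is.null(fixed_mask)) fixed_mask <- segment_tissue(fixed, opts$min_region_um2)
  if (!any(moving_mask$pixels) || !any(fixed_mask$pixels))
    hf_stop("no_tissue_error", "empty tissue mask; cannot prepare registration pair")
  bbm <- mask_bbox(moving_mask); bbf <- mask_bbox(fixed_mask)
  sq <- max(bbm[3] - bbm[1], bbm[4] - bbm[2], bbf[3] - bbf[1], bbf[4] - bbf[2]) + 1
  list(moving = preprocess_one(moving, moving_mask, sq, for_stage, opts),
       fixed = preprocess_one(fixed, fixed_mask, sq, for_stage, opts))
}
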