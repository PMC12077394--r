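# Transform chains: ordered geometric steps (bookkeeping affines, stage
# affine, stage displacement field, landmark splines) composited into a
# single full-resolution displacement field and applied to images, masks,
# pointsets and polygon annotations.

chain_step <- function(kind, from = "", to = "", ...) {
  c(list(kind = kind, from = from, to = to), list(...))
}

#' Transform chain between a moving and a fixed image space
#'
#' @param steps ordered list of steps (created internally by the
#'   registration drivers); each step carries its forward map and an exact
#'   or numeric backward map.
#' @param moving_shape,fixed_shape (height, width) of the two end spaces.
#' @param resolution_um physical resolution shared by the end spaces.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(steps, moving_shape, fixed_shape, resolution_um = 1) {
  for (i in seq_len(length(steps) - 1)) {
    a <- steps[[i]]$to; b <- steps[[i + 1]]$from
    if (nzchar(a) && nzchar(b) && !identical(a, b))
      hf_stop("chain_error", "chain spaces mismatch between step %d ('%s') and step %d ('%s')",
              i, a, i + 1, b)
  }
  structure(list(steps = steps, moving_shape = moving_shape,
                 fixed_shape = fixed_shape, resolution_um = resolution_um),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain %d step(s): %s>\n", length(x$steps),
              paste(vapply(x$steps, `[[`, "", "kind"), collapse = " -> ")))
  invisible(x)
}

# single-step chains
chain_from_affine <- function(a, moving_shape, fixed_shape, resolution_um = 1) {
  transform_chain(list(chain_step("affine", fwd = a)), moving_shape,
                  fixed_shape, resolution_um)
}

chain_from_field <- function(f, resolution_um = 1) {
  transform_chain(list(chain_step("field", field = f)), f$shape, f$shape,
                  resolution_um)
}

# forward map of one step applied to an n x 2 coordinate matrix
step_forward <- function(s, p) {
  switch(s$kind,
         affine = affine_apply(s$fwd, p),
         field = cbind(p[, 1] + cpp_sample_bilinear(s$field$fwd_x, p[, 1], p[, 2]),
                       p[, 2] + cpp_sample_bilinear(s$field$fwd_y, p[, 1], p[, 2])),
         tps = tps_eval(s$fwd, p),
         hf_stop("chain_error", "unknown chain step kind '%s'", s$kind))
}

step_backward <- function(s, p) {
  switch(s$kind,
         affine = affine_apply(affine_invert(s$fwd), p),
         field = cbind(p[, 1] + cpp_sample_bilinear(s$field$bwd_x, p[, 1], p[, 2]),
                       p[, 2] + cpp_sample_bilinear(s$field$bwd_y, p[, 1], p[, 2])),
         tps = tps_eval(s$bwd, p),
         hf_stop("chain_error", "unknown chain step kind '%s'", s$kind))
}

# map moving-space coords to fixed space (forward) through all steps
chain_forward <- function(chain, p) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  for (s in chain$steps) p <- step_forward(s, p)
  p
}

# map fixed-space coords back to moving space (backward), steps reversed
chain_backward <- function(chain, p) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  for (s in rev(chain$steps)) p <- step_backward(s, p)
  p
}

grid_coords <- function(shape) {
  cbind(rep(0:(shape[2] - 1), each = shape[1]), rep(0:(shape[1] - 1), shape[2]))
}

#' Composite a transform chain into a single displacement field
#'
#' The backward map is evaluated as a resample-free function composition on
#' the full fixed grid (each step sampled in sequence), so the materialized
#' field introduces a single interpolation during application; the forward
#' field is built analogously on the moving grid.
#'
#' @param chain a [transform_chain()].
#' @return A [displacement_field()] at full fixed-image resolution.
#' @export
composite <- function(chain) {
  fs <- chain$fixed_shape; ms <- chain$moving_shape
  g <- grid_coords(fs)
  b <- chain_backward(chain, g)
  bwd_x <- matrix(b[, 1] - g[, 1], fs[1], fs[2])
  bwd_y <- matrix(b[, 2] - g[, 2], fs[1], fs[2])
  gm <- grid_coords(ms)
  f <- chain_forward(chain, gm)
  fwd_x <- matrix(f[, 1] - gm[, 1], ms[1], ms[2])
  fwd_y <- matrix(f[, 2] - gm[, 2], ms[1], ms[2])
  displacement_field(bwd_x, bwd_y, fwd_x, fwd_y)
}

#' Rescale a transform to a different image size
#'
#' Affines are conjugated by the pixel-center coordinate scaling between the
#' two shapes; displacement fields are resampled bilinearly onto the new
#' grid with vectors multiplied by the per-axis scale factors.
#'
#' @param t an [affine_transform()] or [displacement_field()].
#' @param from_shape,to_shape (height, width) pairs.
#' @return The rescaled transform of the same type.
#' @export
rescale_transform <- function(t, from_shape, to_shape) {
  if (inherits(t, "affine_transform")) {
    s <- shape_scale_affine(from_shape, to_shape)
    return(affine_compose(s, affine_compose(t, affine_invert(s))))
  }
  if (inherits(t, "displacement_field")) {
    sx <- to_shape[2] / from_shape[2]; sy <- to_shape[1] / from_shape[1]
    rs <- function(m, f) cpp_resize(m, as.integer(to_shape[1]),
                                    as.integer(to_shape[2]), 1L) * f
    return(displacement_field(rs(t$bwd_x, sx), rs(t$bwd_y, sy),
                              rs(t$fwd_x, sx), rs(t$fwd_y, sy)))
  }
  hf_stop("type_error", "rescale_transform expects an affine or a displacement field")
}

as_backward_maps <- function(transform, out_shape) {
  g <- grid_coords(out_shape)
  b <- if (inherits(transform, "transform_chain")) chain_backward(transform, g)
  else if (inherits(transform, "displacement_field"))
    cbind(g[, 1] + cpp_sample_bilinear(transform$bwd_x, g[, 1], g[, 2]),
          g[, 2] + cpp_sample_bilinear(transform$bwd_y, g[, 1], g[, 2]))
  else if (inherits(transform, "affine_transform"))
    affine_apply(affine_invert(transform), g)
  else hf_stop("type_error", "unsupported transform of class %s",
               paste(class(transform), collapse = "/"))
  list(mapx = matrix(b[, 1], out_shape[1], out_shape[2]),
       mapy = matrix(b[, 2], out_shape[1], out_shape[2]))
}

transform_fixed_shape <- function(transform, img) {
  if (inherits(transform, "transform_chain")) transform$fixed_shape
  else if (inherits(transform, "displacement_field")) transform$shape
  else raster_shape(img)
}

#' Warp an image into the fixed space
#'
#' @param img a [raster2d()] in the moving space.
#' @param transform a [transform_chain()], [displacement_field()] or
#'   [affine_transform()].
#' @param interp `"linear"` (default) or `"nearest"`.
#' @param fill value for out-of-bounds source pixels (0 = black; use 255 to
#'   match white stained-scan backgrounds).
#' @return The warped [raster2d()] on the fixed grid.
#' @export
warp_image <- function(img, transform, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  out_shape <- transform_fixed_shape(transform, img)
  maps <- as_backward_maps(transform, out_shape)
  code <- if (interp == "nearest") 0L else 1L
  map_channels(img, function(m) cpp_warp(m, maps$mapx, maps$mapy, code, fill))
}

#' Warp a binary mask (nearest-neighbor)
#' @param mask a [binary_mask()].
#' @inheritParams warp_image
#' @return The warped [binary_mask()] (strictly boolean).
#' @export
warp_mask <- function(mask, transform) {
  out_shape <- transform_fixed_shape(transform, mask)
  maps <- as_backward_maps(transform, out_shape)
  m <- cpp_warp(matrix(as.numeric(mask$pixels), nrow(mask$pixels)),
                maps$mapx, maps$mapy, 0L, 0)
  binary_mask(m > 0.5, mask$resolution_um)
}

#' Warp an integer label raster (nearest-neighbor)
#'
#' Nearest-neighbor resampling never creates labels absent from the input;
#' used for annotation rasters and reference matrices.
#'
#' @param labels integer matrix (0 = background).
#' @inheritParams warp_image
#' @return The warped integer matrix on the fixed grid.
#' @export
warp_labels <- function(labels, transform) {
  out_shape <- transform_fixed_shape(transform, labels)
  maps <- as_backward_maps(transform, out_shape)
  out <- cpp_warp(matrix(as.numeric(labels), nrow(labels)),
                  maps$mapx, maps$mapy, 0L, 0)
  matrix(as.integer(round(out)), out_shape[1], out_shape[2])
}

#' Warp a pointset from the moving to the fixed space (forward direction)
#'
#' Points outside the moving image bounds are still mapped (field offsets are
#' sampled with clamped borders) and their indices are recorded in the
#' `outside_points` attribute.
#'
#' @param pts a [pointset2d()].
#' @inheritParams warp_image
#' @return The warped [pointset2d()].
#' @export
warp_points <- function(pts, transform) {
  if (nrow(pts) == 0) return(pts)
  p <- cbind(pts$x, pts$y)
  q <- if (inherits(transform, "transform_chain")) chain_forward(transform, p)
  else if (inherits(transform, "displacement_field"))
    cbind(p[, 1] + cpp_sample_bilinear(transform$fwd_x, p[, 1], p[, 2]),
          p[, 2] + cpp_sample_bilinear(transform$fwd_y, p[, 1], p[, 2]))
  else if (inherits(transform, "affine_transform")) affine_apply(transform, p)
  else hf_stop("type_error", "unsupported transform")
  out <- pointset2d(q, attr(pts, "space"))
  ms <- if (inherits(transform, "transform_chain")) transform$moving_shape else NULL
  if (!is.null(ms) && ms[1] > 0) {
    off <- which(p[, 1] < 0 | p[, 2] < 0 | p[, 1] >= ms[2] | p[, 2] >= ms[1])
    if (length(off)) attr(out, "outside_points") <- off
  }
  out
}

#' Warp polygon annotations vertex-wise (forward direction)
#'
#' Ring order, holes and labels are preserved.
#'
#' @param ann a [polygon_annotation()].
#' @inheritParams warp_image
#' @return The warped [polygon_annotation()].
#' @export
warp_geojson <- function(ann, transform) {
  wr <- function(m) {
    q <- warp_points(pointset2d(m), transform)
    cbind(q$x, q$y)
  }
  shapes <- lapply(ann$shapes, function(s)
    list(outer = wr(s$outer), holes = lapply(s$holes, wr)))
  polygon_annotation(shapes, ann$labels)
}
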