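#' Affine transform between two pixel coordinate spaces
#'
#' Maps a point p (0-based (x, y) pixel coordinates) to `matrix %*% p +
#' offset`.  Stored in its forward direction (moving to fixed); the backward
#' direction used for image resampling is its exact inverse.
#'
#' @param matrix 2 x 2 linear part.
#' @param offset length-2 translation.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(2), offset = c(0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  if (abs(det(matrix)) <= 1e-12)
    hf_stop("type_error", "affine matrix is singular (|det| <= 1e-12)")
  structure(list(matrix = matrix, offset = as.numeric(offset)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  m <- cbind(x$matrix, x$offset)
  rownames(m) <- c("x", "y"); colnames(m) <- c("a1", "a2", "t")
  print(round(m, 6))
  invisible(x)
}

#' Identity / translation / rotation / scaling affines
#' @param dx,dy translation components in pixels.
#' @return An [affine_transform()].
#' @export
affine_identity <- function() affine_transform()

#' @rdname affine_identity
#' @export
affine_translation <- function(dx, dy) affine_transform(diag(2), c(dx, dy))

#' @rdname affine_identity
#' @param degrees rotation angle (counter-clockwise in the (x, y) frame).
#' @param center rotation center (x, y); defaults to the origin.
#' @export
affine_rotation <- function(degrees, center = c(0, 0)) {
  th <- degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine_transform(R, center - R %*% center)
}

#' @rdname affine_identity
#' @param sx,sy scale factors.
#' @export
affine_scaling <- function(sx, sy = sx, center = c(0, 0)) {
  S <- diag(c(sx, sy))
  affine_transform(S, center - S %*% center)
}

#' Compose two affines: `affine_compose(a, b)` applies b first, then a
#' @param a,b [affine_transform()] objects.
#' @return Their composition a(b(x)).
#' @export
affine_compose <- function(a, b) {
  affine_transform(a$matrix %*% b$matrix,
                   as.numeric(a$matrix %*% b$offset) + a$offset)
}

#' Invert an affine transform
#' @param a an [affine_transform()].
#' @return The inverse transform.
#' @export
affine_invert <- function(a) {
  mi <- solve(a$matrix)
  affine_transform(mi, -as.numeric(mi %*% a$offset))
}

#' Apply an affine transform to points
#' @param a an [affine_transform()].
#' @param pts n x 2 matrix/data.frame of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
affine_apply <- function(a, pts) {
  p <- as.matrix(pts)[, 1:2, drop = FALSE]
  t(a$matrix %*% t(p) + a$offset)
}

# coordinate map between two image shapes under the pixel-center convention:
# x_to = (x_from + 0.5) * (W_to / W_from) - 0.5  (per axis)
shape_scale_affine <- function(from_shape, to_shape) {
  sx <- to_shape[2] / from_shape[2]
  sy <- to_shape[1] / from_shape[1]
  affine_transform(diag(c(sx, sy)), c(0.5 * sx - 0.5, 0.5 * sy - 0.5))
}

# warp a raster through the FORWARD affine `a` (moving -> fixed): the output
# grid is sampled through the inverse map
warp_raster_affine <- function(img, a, out_shape, interp = "linear", fill = 0) {
  inv <- affine_invert(a)
  code <- if (interp == "nearest") 0L else 1L
  map_channels(img, function(m)
    cpp_warp_affine(m, as.numeric(inv$matrix), inv$offset,
                    as.integer(out_shape[1]), as.integer(out_shape[2]),
                    code, fill))
}
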