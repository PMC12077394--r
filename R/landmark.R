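# Landmark-based registration: least-squares affine or exact thin-plate
# spline interpolation, usable wherever an automatic registration result is
# (e.g. as a manual fallback when image registration fails).

# fit TPS mapping src -> dst; returns parameter list for tps_eval
tps_fit <- function(src, dst) {
  n <- nrow(src)
  d2 <- as.matrix(dist(src))^2
  K <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)   # U(r) = r^2 log r^2 / 2
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rc <- rcond(L)
  if (!is.finite(rc) || rc < 1e-12)
    hf_stop("conditioning_error",
            "degenerate (collinear or duplicated) landmarks: TPS system is ill-conditioned")
  W <- solve(L, rbind(dst, matrix(0, 3, 2)))
  list(src = src, w = W[1:n, , drop = FALSE], a = W[(n + 1):(n + 3), , drop = FALSE])
}

tps_eval <- function(par, p) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  d2 <- outer(p[, 1], par$src[, 1], "-")^2 + outer(p[, 2], par$src[, 2], "-")^2
  U <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)
  cbind(1, p) %*% par$a + U %*% par$w
}

#' Register two pointsets by landmarks
#'
#' Fits either a least-squares affine map or an exact-interpolation
#' thin-plate spline from moving to fixed landmarks, returned as a
#' [transform_chain()] usable wherever an image-registration result is
#' (warping images, masks, pointsets, annotations).  For the spline, the
#' backward direction is fitted by swapping the roles of the two sets.
#'
#' @param moving_pts,fixed_pts paired [pointset2d()]s (equal counts; at
#'   least 3 pairs for affine, 4 for the spline).
#' @param model `"affine"` or `"thin_plate_spline"`.
#' @param moving_shape,fixed_shape optional (height, width) of the image
#'   spaces; needed only when the chain is used to warp images.
#' @return A [transform_chain()] with attribute `residual_rms` (forward
#'   residual at the landmarks, in pixels).
#' @export
landmark_register <- function(moving_pts, fixed_pts,
                              model = c("affine", "thin_plate_spline"),
                              moving_shape = NULL, fixed_shape = NULL) {
  model <- match.arg(model)
  if (nrow(moving_pts) != nrow(fixed_pts))
    hf_stop("pairing_error", "landmark sets differ in size (%d vs %d)",
            nrow(moving_pts), nrow(fixed_pts))
  src <- cbind(moving_pts$x, moving_pts$y)
  dst <- cbind(fixed_pts$x, fixed_pts$y)
  if (model == "affine") {
    if (nrow(src) < 3) hf_stop("pairing_error", "affine needs >= 3 landmark pairs")
    X <- cbind(src, 1)
    beta <- tryCatch(qr.solve(X, dst), error = function(e)
      hf_stop("conditioning_error", "degenerate landmarks for affine fit"))
    a <- affine_transform(t(beta[1:2, ]), beta[3, ])
    step <- chain_step("affine", fwd = a)
    fitted <- affine_apply(a, src)
  } else {
    if (nrow(src) < 4) hf_stop("pairing_error", "thin-plate spline needs >= 4 pairs")
    step <- chain_step("tps", fwd = tps_fit(src, dst), bwd = tps_fit(dst, src))
    fitted <- tps_eval(step$fwd, src)
  }
  shp_m <- if (is.null(moving_shape)) c(0, 0) else moving_shape
  shp_f <- if (is.null(fixed_shape)) shp_m else fixed_shape
  out <- transform_chain(list(step), shp_m, shp_f)
  attr(out, "residual_rms") <- sqrt(mean(rowSums((fitted - dst)^2)))
  out
}
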