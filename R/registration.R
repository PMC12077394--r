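# Affine and greedy diffeomorphic nonrigid registration between two
# preprocessed images under a windowed normalized cross-correlation metric.

#' Registration options
#'
#' Defaults follow the engine's reference configuration: NCC window radius
#' 10 px at the working resolution (1% of the 1024 px working image),
#' multiresolution pyramid with scaling factors 8, 4, 2, 1, nonrigid update
#' smoothing sigma 5 (pre) and total-field smoothing sigma 4 (post), 1024 px
#' working resolution padded by 100 px, mean-shift denoising radii 20
#' (spatial) and 15 (color), 10,000 um^2 minimum tissue region, and a seeded
#' 64-trial rigid random search.
#'
#' @param ncc_window_px local-NCC window radius in pixels.
#' @param pyramid strictly decreasing scaling factors ending at 1.
#' @param pre_sigma Gaussian sigma applied to each nonrigid update field.
#' @param post_sigma Gaussian sigma applied to the total field each iteration.
#' @param iterations nonrigid iteration cap per pyramid level (recycled).
#' @param affine_maxit quasi-Newton iteration cap per pyramid level (recycled).
#' @param rigid_trials number of seeded random rigid candidates.
#' @param seed RNG seed for the rigid random search (mandatory determinism).
#' @param working_size side of the square working image in pixels.
#' @param pad_px border padding of the working image in pixels.
#' @param denoise apply mean-shift denoising in the affine stage.
#' @param denoise_spatial_radius,denoise_color_radius mean-shift windows.
#' @param min_region_um2 segmentation minimum region area (um^2).
#' @param conv_tol relative similarity-gain convergence tolerance.
#' @param step_px maximum displacement per nonrigid iteration (pixels).
#' @param invert_iters,invert_tol fixed-point field-inversion controls.
#' @return A classed list of options.
#' @export
reg_options <- function(ncc_window_px = 10, pyramid = c(8, 4, 2, 1),
                        pre_sigma = 5, post_sigma = 4, iterations = 100,
                        affine_maxit = c(60, 40, 25, 12), rigid_trials = 64, seed = 1,
                        working_size = 1024, pad_px = 100, denoise = TRUE,
                        denoise_spatial_radius = 20, denoise_color_radius = 15,
                        min_region_um2 = 10000, conv_tol = 1e-5, step_px = 1,
                        invert_iters = 20, invert_tol = 0.05) {
  if (any(diff(pyramid) >= 0) || tail(pyramid, 1) != 1)
    hf_stop("type_error", "pyramid factors must be strictly decreasing and end at 1")
  if (pre_sigma < 0 || post_sigma < 0)
    hf_stop("type_error", "regularization sigmas must be >= 0")
  structure(list(ncc_window_px = ncc_window_px, pyramid = pyramid,
                 pre_sigma = pre_sigma, post_sigma = post_sigma,
                 iterations = rep_len(iterations, length(pyramid)),
                 affine_maxit = rep_len(affine_maxit, length(pyramid)),
                 rigid_trials = rigid_trials, seed = seed,
                 working_size = working_size, pad_px = pad_px,
                 denoise = denoise,
                 denoise_spatial_radius = denoise_spatial_radius,
                 denoise_color_radius = denoise_color_radius,
                 min_region_um2 = min_region_um2, conv_tol = conv_tol,
                 step_px = step_px, invert_iters = invert_iters,
                 invert_tol = invert_tol),
            class = "reg_options")
}

#' Center-of-mass initialization
#'
#' Pure translation mapping the moving tissue centroid onto the fixed tissue
#' centroid, both computed from the binary masks.
#'
#' @param moving_mask,fixed_mask non-empty [binary_mask()]s.
#' @return An [affine_transform()] (pure translation).
#' @export
center_of_mass_init <- function(moving_mask, fixed_mask) {
  d <- mask_centroid(fixed_mask) - mask_centroid(moving_mask)
  affine_translation(d[1], d[2])
}

#' Mean windowed normalized cross-correlation between two images
#'
#' The NCC is computed in a sliding box window of the given radius and
#' averaged over all pixels; windows with zero intensity variance in either
#' image contribute 0.
#'
#' @param a,b same-shape grayscale matrices or [raster2d()]s.
#' @param window_px window radius in pixels.
#' @return A scalar in \[-1, 1\].
#' @export
local_ncc <- function(a, b, window_px = 10) {
  ma <- if (inherits(a, "raster2d")) to_gray(a) else a
  mb <- if (inherits(b, "raster2d")) to_gray(b) else b
  if (!all(dim(ma) == dim(mb)))
    hf_stop("dimension_error", "local_ncc inputs differ in shape")
  cpp_local_ncc(ma, mb, as.integer(window_px), FALSE)$value
}

# image pyramid: list of grayscale [0,1] matrices, coarse -> fine order kept
# aligned with opts$pyramid
build_pyramid <- function(gray01, factors) {
  lapply(factors, function(f) {
    if (f == 1) return(gray01)
    sm <- cpp_gauss_smooth(gray01, f / 2)
    cpp_resize(sm, as.integer(round(nrow(gray01) / f)),
               as.integer(round(ncol(gray01) / f)), 1L)
  })
}

# forward affine from parameter vector p = (tx, ty, theta_deg, log sx,
# log sy, shear) anchored at the moving/fixed mask centroids:
#   x_f = c_f + t + R S H (x_m - c_m)
params_to_affine <- function(p, c_m, c_f) {
  th <- p[3] * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(c(exp(p[4]), exp(p[5])))
  H <- matrix(c(1, 0, p[6], 1), 2, 2)
  M <- R %*% S %*% H
  affine_transform(M, c_f + p[1:2] - as.numeric(M %*% c_m))
}

# conjugate a full-working-scale affine to pyramid level with factor f
affine_at_level <- function(a, full_shape, level_shape) {
  s <- shape_scale_affine(full_shape, level_shape)
  affine_compose(s, affine_compose(a, affine_invert(s)))
}

affine_objective <- function(p, c_m, c_f, mov_l, fix_l, full_shape, r) {
  a <- params_to_affine(p, c_m, c_f)
  al <- affine_at_level(a, full_shape, dim(fix_l))
  inv <- affine_invert(al)
  w <- cpp_warp_affine(mov_l, as.numeric(inv$matrix), inv$offset,
                       nrow(fix_l), ncol(fix_l), 1L, 1.0)
  v <- cpp_local_ncc(w, fix_l, r, FALSE)$value
  if (!is.finite(v))
    hf_stop("optimization_error",
            "non-finite similarity at parameters (%s)", paste(round(p, 3), collapse = ", "))
  v
}

#' Affine registration between two preprocessed images
#'
#' Stage 1 performs a seeded random search over rigid candidates (rotation
#' uniform in \[-180, 180) degrees, translations within +/-10% of the image
#' width around the center-of-mass initialization) at the coarsest pyramid
#' level.  Stage 2 refines the 6 affine parameters (translation, rotation,
#' log-scales, shear) per pyramid level, coarse to fine, by quasi-Newton
#' (BFGS) ascent on the windowed NCC.
#'
#' @param moving,fixed `preprocessed_image`s from
#'   [prepare_pair()] (`for_stage = "affine"`).
#' @param opts a [reg_options()] list.
#' @param rigid if `TRUE`, restrict to rotation + translation (3 parameters).
#' @return The working-space forward [affine_transform()] (moving to fixed),
#'   with attributes `similarity` (final NCC) and `params`.
#' @export
affine_register <- function(moving, fixed, opts = reg_options(), rigid = FALSE) {
  r <- as.integer(opts$ncc_window_px)
  I <- to_gray(moving$image) / 255
  J <- to_gray(fixed$image) / 255
  full_shape <- dim(J)
  pyr_m <- build_pyramid(I, opts$pyramid)
  pyr_f <- build_pyramid(J, opts$pyramid)
  c_m <- mask_centroid(moving$mask)
  c_f <- mask_centroid(fixed$mask)
  npar <- if (rigid) 3L else 6L
  obj <- function(p) {
    pp <- c(p, rep(0, 6 - length(p)))
    affine_objective(pp, c_m, c_f, pyr_m[[lv]], pyr_f[[lv]], full_shape, r)
  }
  # stage 1: seeded rigid random search at the coarsest level
  lv <- 1L
  cands <- with_seed(opts$seed, {
    n <- opts$rigid_trials
    # half the trials probe rotations at the center-of-mass translation,
    # half probe joint rotation/translation perturbations around it
    rbind(cbind(tx = 0, ty = 0, th = c(0, runif(n, -180, 180))),
          cbind(tx = runif(n, -0.1, 0.1) * full_shape[2],
                ty = runif(n, -0.1, 0.1) * full_shape[1],
                th = runif(n, -180, 180)))
  })
  vals <- apply(cands, 1, function(q) obj(q))
  best <- as.numeric(cands[which.max(vals), ])
  p <- c(best, 0, 0, 0)[1:npar]
  # stage 2: per-level bounded quasi-Newton refinement, coarse -> fine;
  # bounds around the incoming parameters keep the ascent in the basin the
  # random search found
  box <- c(0.06 * full_shape[2], 0.06 * full_shape[1], 25, 0.3, 0.3, 0.25)[1:npar]
  safe_obj <- function(q) {
    v <- tryCatch(-obj(q), error = function(e) NA_real_)
    if (!is.finite(v)) 1 else v
  }
  val <- NA_real_
  for (lv in seq_along(opts$pyramid)) {
    fit <- optim(p, safe_obj, method = "L-BFGS-B",
                 lower = p - box, upper = p + box,
                 control = list(maxit = opts$affine_maxit[lv],
                                ndeps = c(0.2, 0.2, 0.02, 5e-4, 5e-4, 5e-4)[1:npar],
                                factr = 1e9))
    p <- fit$par
    val <- -fit$value
  }
  out <- params_to_affine(c(p, rep(0, 6 - npar)), c_m, c_f)
  attr(out, "similarity") <- val
  attr(out, "params") <- p
  out
}

#' Displacement field between two same-shape image spaces
#'
#' Offsets are stored per grid pixel: the backward map sends fixed-space
#' pixel (x, y) to moving-space coordinate (x + bwd_x, y + bwd_y) and is used
#' for image resampling; the forward map sends moving-space points to fixed
#' space and is used for pointsets.
#'
#' @param bwd_x,bwd_y backward offset matrices (fixed grid).
#' @param fwd_x,fwd_y forward offset matrices (moving grid); computed by
#'   fixed-point inversion when omitted.
#' @param invert_iters,invert_tol fixed-point inversion controls.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(bwd_x, bwd_y, fwd_x = NULL, fwd_y = NULL,
                               invert_iters = 20, invert_tol = 0.05) {
  if (any(!is.finite(bwd_x)) || any(!is.finite(bwd_y)))
    hf_stop("type_error", "displacement field contains non-finite values")
  if (is.null(fwd_x)) {
    inv <- cpp_invert_field(bwd_x, bwd_y, invert_iters, invert_tol)
    fwd_x <- inv$ux; fwd_y <- inv$uy
  }
  structure(list(bwd_x = bwd_x, bwd_y = bwd_y, fwd_x = fwd_x, fwd_y = fwd_y,
                 shape = dim(bwd_x)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mx <- max(sqrt(x$bwd_x^2 + x$bwd_y^2))
  cat(sprintf("<displacement_field %d x %d, max |u| = %.2f px>\n",
              x$shape[2], x$shape[1], mx))
  invisible(x)
}

# identity field of a given (h, w) shape
identity_field <- function(shape) {
  z <- matrix(0, shape[1], shape[2])
  displacement_field(z, z, z, z)
}

# per-pixel Jacobian determinant of the map x + u(x) (finite differences)
field_jacobian_det <- function(ux, uy) {
  H <- nrow(ux); W <- ncol(ux)
  divc <- matrix(c(1, rep(2, max(W - 2, 0)), 1)[1:W], H, W, byrow = TRUE)
  divr <- matrix(c(1, rep(2, max(H - 2, 0)), 1)[1:H], H, W)
  ddx <- function(m) (m[, c(2:W, W), drop = FALSE] - m[, c(1, 1:(W - 1)), drop = FALSE]) / divc
  ddy <- function(m) (m[c(2:H, H), , drop = FALSE] - m[c(1, 1:(H - 1)), , drop = FALSE]) / divr
  (1 + ddx(ux)) * (1 + ddy(uy)) - ddy(ux) * ddx(uy)
}

#' Greedy diffeomorphic nonrigid registration
#'
#' Per pyramid level (coarse to fine) the loop (i) warps the moving image
#' through the current total field composed with the affine initialization,
#' (ii) computes the windowed-NCC gradient force field, (iii) smooths the
#' update with a Gaussian (`pre_sigma`), (iv) scales it so the maximum
#' displacement per iteration is at most `step_px`, (v) composes it into the
#' total field and (vi) smooths the total field (`post_sigma`).  Only
#' similarity-improving steps are kept; a level stops at its iteration cap or
#' when the relative similarity gain falls below `conv_tol`.  The forward
#' field is obtained by fixed-point inversion of the backward field.
#'
#' @param moving,fixed `preprocessed_image`s from
#'   [prepare_pair()] (`for_stage = "nonrigid"`).
#' @param init working-space affine initialization (moving to fixed), e.g.
#'   from [affine_register()].
#' @param opts a [reg_options()] list.
#' @return A [displacement_field()] in the working space *after* the affine
#'   initialization (the full map is `init` then this field), with attributes
#'   `similarity` (final NCC), `similarity_trace` (per-level accepted-step
#'   traces, each non-decreasing), `min_jacobian` and, if the
#'   forward/backward round trip over the mask exceeds 2 px on average,
#'   `invertibility_warning`.
#' @export
nonrigid_register <- function(moving, fixed, init = affine_identity(),
                              opts = reg_options()) {
  r <- as.integer(opts$ncc_window_px)
  I <- to_gray(moving$image) / 255
  J <- to_gray(fixed$image) / 255
  full_shape <- dim(J)
  pyr_m <- build_pyramid(I, opts$pyramid)
  pyr_f <- build_pyramid(J, opts$pyramid)
  ux <- uy <- NULL
  history <- vector("list", length(opts$pyramid))
  for (lv in seq_along(opts$pyramid)) {
    Jl <- pyr_f[[lv]]; Il <- pyr_m[[lv]]
    shp <- dim(Jl)
    a_bwd <- affine_invert(affine_at_level(init, full_shape, shp))
    if (is.null(ux)) {
      ux <- matrix(0, shp[1], shp[2]); uy <- matrix(0, shp[1], shp[2])
    } else {
      sc <- shp[1] / nrow(ux)
      ux <- cpp_resize(ux, shp[1], shp[2], 1L) * sc
      uy <- cpp_resize(uy, shp[1], shp[2], 1L) * sc
    }
    val_prev <- -Inf
    for (it in seq_len(opts$iterations[lv])) {
      w <- cpp_warp_field_affine(Il, ux, uy, as.numeric(a_bwd$matrix),
                                 a_bwd$offset, 1L, 1.0)
      st <- cpp_local_ncc(w, Jl, r, TRUE)
      if (!is.finite(st$value))
        hf_stop("optimization_error", "non-finite similarity at level %d iter %d", lv, it)
      if (st$value < val_prev) { ux <- ux_prev; uy <- uy_prev; break }
      history[[lv]] <- c(history[[lv]], st$value)
      if (it > 1 && (st$value - val_prev) < opts$conv_tol * max(abs(val_prev), 1e-8))
        break
      val_prev <- st$value
      sx <- cpp_gauss_smooth(st$gx, opts$pre_sigma)
      sy <- cpp_gauss_smooth(st$gy, opts$pre_sigma)
      mx <- max(sqrt(sx^2 + sy^2))
      if (mx < 1e-12) break
      sx <- sx * (opts$step_px / mx); sy <- sy * (opts$step_px / mx)
      ux_prev <- ux; uy_prev <- uy
      comp <- cpp_compose_field(ux, uy, sx, sy)
      ux <- cpp_gauss_smooth(comp$ux, opts$post_sigma)
      uy <- cpp_gauss_smooth(comp$uy, opts$post_sigma)
    }
  }
  fld <- displacement_field(ux, uy, invert_iters = opts$invert_iters,
                            invert_tol = opts$invert_tol)
  # per-level accepted-similarity traces (each non-decreasing); the final
  # value is the finest-level similarity
  attr(fld, "similarity_trace") <- history
  attr(fld, "similarity") <- tail(history[[length(history)]], 1)
  jd <- field_jacobian_det(ux, uy)
  attr(fld, "min_jacobian") <- min(jd[fixed$mask$pixels])
  # forward/backward round-trip check over the fixed mask
  idx <- which(fixed$mask$pixels, arr.ind = TRUE)
  if (nrow(idx) > 400) idx <- idx[seq(1, nrow(idx), length.out = 400), , drop = FALSE]
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  bx <- xs + cpp_sample_bilinear(fld$bwd_x, xs, ys)
  by <- ys + cpp_sample_bilinear(fld$bwd_y, xs, ys)
  rx <- bx + cpp_sample_bilinear(fld$fwd_x, bx, by)
  ry <- by + cpp_sample_bilinear(fld$fwd_y, bx, by)
  rt <- mean(sqrt((rx - xs)^2 + (ry - ys)^2))
  attr(fld, "roundtrip_px") <- rt
  if (rt > 2) attr(fld, "invertibility_warning") <- TRUE
  fld
}
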