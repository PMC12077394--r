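# Seeded synthetic data: histology-like gland/stroma scenes, smooth
# invertible deformations, serial-section series with drift and
# morphological churn, and spot/pixel omics layers with tissue-correlated
# molecular values.  Every generator is deterministic in its seed and
# exposes its ground truth so downstream tests never re-derive it from
# rendered data.

# H&E-like palette (RGB, 0-255): background, stroma, gland rim, lumen
.hf_palette <- list(bg = c(255, 255, 255), stroma = c(225, 160, 190),
                    rim = c(130, 70, 150), lumen = c(245, 242, 248))

# paint labels (0 bg, 1 stroma, 2 rim, 3 lumen) from mask + gland table
render_labels <- function(mask_px, glands, lumen_frac = 0.55) {
  lab <- matrix(0L, nrow(mask_px), ncol(mask_px))
  lab[mask_px] <- 1L
  H <- nrow(mask_px); W <- ncol(mask_px)
  for (i in seq_len(nrow(glands))) {
    g <- glands[i, ]
    if (!g$present) next
    a <- g$a * g$scale; b <- g$b * g$scale
    x0 <- max(0, floor(g$cx - a)); x1 <- min(W - 1, ceiling(g$cx + a))
    y0 <- max(0, floor(g$cy - a)); y1 <- min(H - 1, ceiling(g$cy + a))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - g$cx)
    dy <- outer(ys - g$cy, rep(1, length(xs)))
    xr <- dx * cos(g$theta) + dy * sin(g$theta)
    yr <- -dx * sin(g$theta) + dy * cos(g$theta)
    q <- (xr / a)^2 + (yr / b)^2
    block <- lab[ys + 1, xs + 1, drop = FALSE]
    block[q <= 1 & block > 0L] <- 2L
    block[q <= lumen_frac^2 & block > 0L] <- 3L
    lab[ys + 1, xs + 1] <- block
  }
  lab
}

# render an RGB stained-like image from labels + shared texture field
render_rgb <- function(labels, texture, noise_sd = 4) {
  pal <- .hf_palette
  H <- nrow(labels); W <- ncol(labels)
  out <- array(0, c(H, W, 3))
  base <- list(pal$bg, pal$stroma, pal$rim, pal$lumen)
  for (k in 1:3) {
    ch <- matrix(pal$bg[k], H, W)
    for (l in 1:3) ch[labels == l] <- base[[l + 1]][k]
    ch[labels > 0L] <- ch[labels > 0L] + texture[labels > 0L]
    if (noise_sd > 0) ch <- ch + matrix(rnorm(H * W, 0, noise_sd), H, W)
    out[, , k] <- pmin(pmax(ch, 0), 255)
  }
  out
}

#' Generate a histology-like synthetic scene
#'
#' A smooth random tissue blob on a white slide background, filled with
#' textured stroma and non-overlapping elliptical glands (dark rim + light
#' lumen) rendered in an H&E-like palette.  Ground truth (tissue mask,
#' gland/stroma/lumen label raster, gland parameters, texture) is retained
#' on the returned scene for oracle comparisons.
#'
#' @param seed RNG seed; the same seed reproduces the scene bit-identically.
#' @param size_px side of the square frame in pixels (>= 256).
#' @param n_glands target number of glands (placement is rejection-sampled;
#'   slightly fewer may fit).
#' @param resolution_um physical resolution (default 1 um/px).
#' @return An object of class `synthetic_scene`: `image` ([raster2d()] RGB),
#'   `mask` ([binary_mask()]), `labels` (0 background, 1 stroma, 2 gland
#'   rim, 3 lumen), `glands` (parameter table), `texture`, `seed`.
#' @export
make_tissue_image <- function(seed, size_px = 1500, n_glands = 40,
                              resolution_um = 1) {
  if (size_px < 256) hf_stop("type_error", "scene size must be >= 256 px")
  with_seed(hf_child_seed(seed, "image"), {
    W <- H <- as.integer(size_px)
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    r0 <- 0.33 * size_px
    ak <- rnorm(6, 0, 0.05); ph <- runif(6, 0, 2 * pi)
    dx <- outer(rep(1, H), 0:(W - 1) - cx)
    dy <- outer(0:(H - 1) - cy, rep(1, W))
    ang <- atan2(dy, dx)
    rb <- r0
    for (k in 1:6) rb <- rb + r0 * ak[k] * cos(k * ang + ph[k])
    mask_px <- sqrt(dx^2 + dy^2) <= rb
    # gland placement: fully inside the blob, pairwise non-overlapping
    glands <- data.frame()
    tries <- 0
    while (nrow(glands) < n_glands && tries < n_glands * 80) {
      tries <- tries + 1
      gx <- runif(1, 0.15 * W, 0.85 * W); gy <- runif(1, 0.15 * H, 0.85 * H)
      a <- runif(1, 0.022, 0.045) * size_px
      b <- a * runif(1, 0.55, 0.95)
      th <- runif(1, 0, pi)
      gang <- atan2(gy - cy, gx - cx)
      rbg <- r0 * (1 + sum(ak * cos((1:6) * gang + ph)))
      if (sqrt((gx - cx)^2 + (gy - cy)^2) + a > rbg - 4) next
      if (nrow(glands) > 0 &&
          any(sqrt((glands$cx - gx)^2 + (glands$cy - gy)^2) <
              (glands$a + a) * 1.15)) next
      glands <- rbind(glands, data.frame(id = nrow(glands) + 1, cx = gx, cy = gy,
                                         a = a, b = b, theta = th,
                                         scale = 1, present = TRUE))
    }
    labels <- render_labels(mask_px, glands)
    texture <- cpp_gauss_smooth(matrix(runif(H * W, -1, 1), H, W), 4)
    texture <- texture / max(abs(texture)) * 14
    rgb <- render_rgb(labels, texture)
    structure(list(seed = seed, size_px = W,
                   image = raster2d(rgb, resolution_um),
                   mask = binary_mask(mask_px, resolution_um),
                   labels = labels, glands = glands, texture = texture,
                   resolution_um = resolution_um),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d px, %d gland(s), seed %s>\n",
              x$size_px, sum(x$glands$present), format(x$seed)))
  invisible(x)
}

#' Generate a smooth invertible deformation field
#'
#' A stationary velocity field (sum of random Gaussian bumps, scaled to the
#' requested amplitude) is integrated by scaling-and-squaring, which
#' guarantees a diffeomorphic map; the exact inverse is the integral of the
#' negated velocity.  Both directions are returned on the full grid.
#'
#' @param seed RNG seed.
#' @param shape (height, width) of the grid.
#' @param amplitude_px maximum displacement magnitude in pixels.
#' @param smoothness_px Gaussian bump sigma in pixels.
#' @param n_bumps number of velocity bumps (default 3).
#' @return A [displacement_field()]; refuses (with a diagnostic) if the
#'   requested amplitude is too large for the smoothness to stay invertible.
#' @export
make_deformation <- function(seed, shape, amplitude_px, smoothness_px,
                             n_bumps = 3) {
  if (amplitude_px < 0) hf_stop("type_error", "amplitude must be >= 0")
  H <- shape[1]; W <- shape[2]
  if (amplitude_px == 0) return(identity_field(shape))
  with_seed(hf_child_seed(seed, "deformation"), {
    vx <- matrix(0, H, W); vy <- matrix(0, H, W)
    xs <- outer(rep(1, H), 0:(W - 1)); ys <- outer(0:(H - 1), rep(1, W))
    for (i in seq_len(n_bumps)) {
      bx <- runif(1, 0.2, 0.8) * W; by <- runif(1, 0.2, 0.8) * H
      dirang <- runif(1, 0, 2 * pi)
      g <- exp(-((xs - bx)^2 + (ys - by)^2) / (2 * smoothness_px^2))
      vx <- vx + cos(dirang) * g
      vy <- vy + sin(dirang) * g
    }
    sp <- sqrt(vx^2 + vy^2)
    sc <- amplitude_px / max(sp)
    vx <- vx * sc; vy <- vy * sc
    K <- max(1, ceiling(log2(max(amplitude_px / 0.25, 2))))
    integrate_v <- function(wx, wy) {
      ux <- wx / 2^K; uy <- wy / 2^K
      for (k in seq_len(K)) {
        cc <- cpp_compose_field(ux, uy, ux, uy)
        ux <- cc$ux; uy <- cc$uy
      }
      list(ux = ux, uy = uy)
    }
    fwd <- integrate_v(vx, vy)
    bwd <- integrate_v(-vx, -vy)
    jf <- min(field_jacobian_det(fwd$ux, fwd$uy))
    jb <- min(field_jacobian_det(bwd$ux, bwd$uy))
    if (jf <= 0.05 || jb <= 0.05)
      hf_stop("generator_error",
              "amplitude %.1f px too large for smoothness %.1f px (min Jacobian %.3f)",
              amplitude_px, smoothness_px, min(jf, jb))
    displacement_field(bwd$ux, bwd$uy, fwd$ux, fwd$uy)
  })
}

# invert a pure field step by swapping its directions
invert_field_step <- function(f) displacement_field(f$fwd_x, f$fwd_y, f$bwd_x, f$bwd_y)

#' Generate a serial-section series from a scene
#'
#' Section i is the scene re-rendered after i - 1 rounds of morphological
#' churn (each gland independently rescaled or removed with probability
#' `morph_rate` per step, emulating morphology drifting with axial
#' distance), warped by the composition of i - 1 smooth drift deformations,
#' with independent per-section noise.  Paired landmarks are carried through
#' the ground-truth fields; landmarks falling inside churned glands are
#' flagged.
#'
#' @param scene a [make_tissue_image()] scene.
#' @param n number of sections (>= 2).
#' @param drift_amplitude_px deformation amplitude per step (pixels).
#' @param smoothness_px deformation bump sigma (pixels).
#' @param morph_rate per-step probability that a gland churns.
#' @param noise_sd per-section additive intensity noise (0-255 scale).
#' @param n_landmarks number of tracked landmarks.
#' @param placement_rotation_deg,placement_shift_frac each section is
#'   mounted with a random rigid placement (rotation uniform within +/- this
#'   angle about the frame center, shift uniform within this fraction of the
#'   frame), emulating slide mounting.
#' @param texture_rho per-step correlation of the stromal micro-texture
#'   (AR(1) evolution; 1 = identical texture in every section).
#' @return An object of class `section_series_synthetic`: `sections` (each
#'   with `image`, `mask`, `labels`, `landmarks` data.frame (x, y, flagged),
#'   `glands`), and `chains` (ground-truth [transform_chain()] scene space
#'   to each section's space).
#' @export
make_serial_sections <- function(scene, n = 5, drift_amplitude_px = 6,
                                 smoothness_px = 80, morph_rate = 0.1,
                                 noise_sd = 5, n_landmarks = 60,
                                 placement_rotation_deg = 15,
                                 placement_shift_frac = 0.03,
                                 texture_rho = 0.75) {
  if (n < 2) hf_stop("type_error", "a series needs >= 2 sections")
  shape <- raster_shape(scene$mask)
  base_seed <- hf_child_seed(scene$seed, "serial")
  lm0 <- with_seed(base_seed, {
    idx <- which(scene$mask$pixels, arr.ind = TRUE)
    sel <- idx[sample.int(nrow(idx), min(n_landmarks, nrow(idx))), , drop = FALSE]
    data.frame(x = sel[, 2] - 1, y = sel[, 1] - 1)
  })
  glands <- scene$glands
  sections <- list(); chains <- list()
  steps <- list()
  texture <- scene$texture
  tex_amp <- max(abs(texture))
  for (i in seq_len(n)) {
    churned <- rep(FALSE, nrow(glands))
    if (i > 1 && texture_rho < 1) {
      # micro-texture decorrelates with axial distance (AR(1) with
      # correlation texture_rho per step), emulating growing tissue
      # heterogeneity between sections
      fresh <- with_seed(hf_child_seed(base_seed, paste0("texture", i)), {
        f <- cpp_gauss_smooth(matrix(runif(prod(shape), -1, 1), shape[1], shape[2]), 4)
        f / max(abs(f)) * tex_amp
      })
      texture <- texture_rho * texture + sqrt(1 - texture_rho^2) * fresh
    }
    if (i > 1) {
      with_seed(hf_child_seed(base_seed, paste0("churn", i)), {
        churned <- runif(nrow(glands)) < morph_rate & glands$present
        for (g in which(churned)) {
          if (runif(1) < 0.3) glands$present[g] <- FALSE
          else glands$scale[g] <- glands$scale[g] * runif(1, 0.6, 1.4)
        }
      })
      d <- make_deformation(hf_child_seed(base_seed, paste0("drift", i)),
                            shape, drift_amplitude_px, smoothness_px)
      steps <- c(steps, list(chain_step("field", field = d)))
      place <- with_seed(hf_child_seed(base_seed, paste0("place", i)), {
        ctr <- c((shape[2] - 1) / 2, (shape[1] - 1) / 2)
        affine_compose(
          affine_translation(runif(1, -1, 1) * placement_shift_frac * shape[2],
                             runif(1, -1, 1) * placement_shift_frac * shape[1]),
          affine_rotation(runif(1, -1, 1) * placement_rotation_deg, ctr))
      })
      steps <- c(steps, list(chain_step("affine", fwd = place)))
    }
    chain_i <- if (length(steps)) transform_chain(steps, shape, shape)
               else transform_chain(list(chain_step("affine", fwd = affine_identity())),
                                    shape, shape)
    labels_i <- render_labels(scene$mask$pixels, glands)
    rgb_i <- with_seed(hf_child_seed(base_seed, paste0("noise", i)),
                       render_rgb(labels_i, texture, noise_sd))
    img_i <- warp_image(raster2d(rgb_i, scene$resolution_um), chain_i, fill = 255)
    mask_i <- warp_mask(scene$mask, chain_i)
    lab_i <- warp_labels(labels_i, chain_i)
    lmw <- chain_forward(chain_i, cbind(lm0$x, lm0$y))
    # flag landmarks sitting in glands whose state has drifted from the base
    state0 <- scene$glands
    flagged <- rep(FALSE, nrow(lm0))
    chg <- which(glands$present != state0$present | glands$scale != state0$scale)
    for (g in chg) {
      gg <- state0[g, ]
      d2 <- ((lm0$x - gg$cx) / (gg$a * 1.2))^2 + ((lm0$y - gg$cy) / (gg$a * 1.2))^2
      flagged <- flagged | d2 <= 1
    }
    sections[[i]] <- list(image = img_i, mask = mask_i, labels = lab_i,
                          landmarks = data.frame(x = lmw[, 1], y = lmw[, 2],
                                                 flagged = flagged),
                          glands = glands)
    chains[[i]] <- chain_i
  }
  structure(list(sections = sections, chains = chains, scene = scene),
            class = "section_series_synthetic")
}

#' Ground-truth transform chain between two synthetic sections
#'
#' @param ss a [make_serial_sections()] result.
#' @param from,to section indices.
#' @return A [transform_chain()] mapping section `from` coordinates to
#'   section `to` coordinates exactly (by construction).
#' @export
serial_gt_chain <- function(ss, from, to) {
  inv_steps <- lapply(rev(ss$chains[[from]]$steps), function(s) {
    if (s$kind == "affine") chain_step("affine", fwd = affine_invert(s$fwd))
    else chain_step("field", field = invert_field_step(s$field))
  })
  shape <- ss$chains[[from]]$fixed_shape
  transform_chain(c(inv_steps, ss$chains[[to]]$steps), shape, shape)
}

# mean of a matrix over the axis-aligned box [x0,x1) x [y0,y1) (pixel centers)
box_mean <- function(m, x0, y0, x1, y1) {
  xs <- max(0, ceiling(x0)):min(ncol(m) - 1, ceiling(x1) - 1)
  ys <- max(0, ceiling(y0)):min(nrow(m) - 1, ceiling(y1) - 1)
  if (!length(xs) || !length(ys)) return(NA_real_)
  mean(m[ys + 1, xs + 1])
}

#' Generate spot and pixel omics layers over a scene or section
#'
#' Spots are laid out on a hexagonal lattice (row pitch
#' `pitch * sqrt(3) / 2`, alternate rows offset by half a pitch, so nearest
#' centers are exactly one pitch apart) clipped to the tissue; omics pixels
#' on a square grid over the tissue bounding box.  Per-spot "gene scores"
#' and per-pixel "metabolite" channels share the gland/stroma ground truth:
#' value = baseline + effect * gland_fraction + Gaussian noise, so the true
#' cross-layer correlation structure is known by construction.
#'
#' @param scene a `synthetic_scene`, or any list with `mask` ([binary_mask()])
#'   and `labels` (label raster) elements such as one section of
#'   [make_serial_sections()].
#' @param seed RNG seed for the molecular values (required when `scene` is a
#'   bare section; defaults to the scene's seed).
#' @param spot_diameter_um,spot_pitch_um Visium-style spot geometry
#'   (defaults 55 and 100).
#' @param msi_pitch_um square omics pixel size (default 30).
#' @param effect additive effect of gland tissue on the molecular scale.
#' @param noise_sd Gaussian noise of the molecular values.
#' @param n_channels number of pixel-side measurement channels.
#' @return List with `spots` (`geometry`, `table`, ground-truth
#'   `gland_frac`), `pixels` (likewise), and `annotation` (tissue-type label
#'   raster: 1 = stroma, 2 = gland).
#' @export
make_omics_layers <- function(scene, seed = scene$seed,
                              spot_diameter_um = 55, spot_pitch_um = 100,
                              msi_pitch_um = 30, effect = 1, noise_sd = 0.3,
                              n_channels = 6) {
  mask <- scene$mask; labels <- scene$labels
  res <- mask$resolution_um
  shape <- raster_shape(mask)
  gland <- matrix(as.numeric(labels >= 2L), shape[1], shape[2])
  bb <- mask_bbox(mask)
  # hexagonal spot lattice (um coordinates = px * res)
  pitch_px <- spot_pitch_um / res
  row_step <- pitch_px * sqrt(3) / 2
  rows_y <- seq(bb[2], bb[4], by = row_step)
  centers <- do.call(rbind, lapply(seq_along(rows_y), function(r) {
    xoff <- if (r %% 2 == 0) pitch_px / 2 else 0
    xs <- seq(bb[1] + xoff, bb[3], by = pitch_px)
    cbind(xs, rows_y[r])
  }))
  keep <- mask$pixels[cbind(pmin(round(centers[, 2]), shape[1] - 1) + 1,
                            pmin(round(centers[, 1]), shape[2] - 1) + 1)]
  centers <- centers[keep, , drop = FALSE]
  spot_ids <- sprintf("S%04d", seq_len(nrow(centers)))
  sg <- spot_geometry(spot_ids, centers * res, spot_diameter_um, spot_pitch_um)
  # per-spot gland fraction (circle pixel enumeration on the gland raster)
  r_px <- spot_diameter_um / 2 / res
  spot_frac <- vapply(seq_len(nrow(centers)), function(k) {
    xs <- max(0, ceiling(centers[k, 1] - r_px)):min(shape[2] - 1, floor(centers[k, 1] + r_px))
    ys <- max(0, ceiling(centers[k, 2] - r_px)):min(shape[1] - 1, floor(centers[k, 2] + r_px))
    inside <- outer((ys - centers[k, 2])^2, (xs - centers[k, 1])^2, "+") <= r_px^2
    mean(gland[ys + 1, xs + 1][inside])
  }, 0)
  # square omics pixel grid
  ppx <- msi_pitch_um / res
  ncol_g <- floor((bb[3] - bb[1] + 1) / ppx)
  nrow_g <- floor((bb[4] - bb[2] + 1) / ppx)
  grid <- expand.grid(col = 0:(ncol_g - 1), row = 0:(nrow_g - 1))
  cxs <- bb[1] + (grid$col + 0.5) * ppx
  cys <- bb[2] + (grid$row + 0.5) * ppx
  keepp <- mask$pixels[cbind(pmin(round(cys), shape[1] - 1) + 1,
                             pmin(round(cxs), shape[2] - 1) + 1)]
  grid <- grid[keepp, , drop = FALSE]
  pix_ids <- sprintf("P%05d", seq_len(nrow(grid)))
  pg <- pixel_geometry(pix_ids, grid$col, grid$row,
                       origin_um = c(bb[1] * res, bb[2] * res), msi_pitch_um)
  pix_frac <- vapply(seq_len(nrow(grid)), function(k) {
    v <- box_mean(gland, bb[1] + grid$col[k] * ppx, bb[2] + grid$row[k] * ppx,
                  bb[1] + (grid$col[k] + 1) * ppx, bb[2] + (grid$row[k] + 1) * ppx)
    if (is.na(v)) 0 else v
  }, 0)
  with_seed(hf_child_seed(seed, "omics"), {
    gene <- 1 + effect * spot_frac + rnorm(length(spot_frac), 0, noise_sd)
    st_tab <- measurement_table(spot_ids, matrix(gene, ncol = 1,
                                                 dimnames = list(NULL, "gene_score")))
    wch <- c(1, 0.8, -0.5, 0.4, -0.9, 0.6, 0.25, -0.7)[seq_len(n_channels)]
    V <- sapply(seq_len(n_channels), function(j)
      1 + effect * wch[j] * pix_frac + rnorm(length(pix_frac), 0, noise_sd))
    colnames(V) <- c("metabolite", paste0("channel_", seq_len(n_channels - 1)))[
      seq_len(n_channels)]
    msi_tab <- measurement_table(pix_ids, V)
    ann <- matrix(0L, shape[1], shape[2])
    ann[labels == 1L] <- 1L
    ann[labels >= 2L] <- 2L
    list(spots = list(geometry = sg, table = st_tab, gland_frac = spot_frac),
         pixels = list(geometry = pg, table = msi_tab, gland_frac = pix_frac),
         annotation = ann, annotation_names = c("stroma", "gland"))
  })
}
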