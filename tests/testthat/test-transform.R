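test_that("transform rescaling is exact for affines and linear for fields", {
  id <- affine_identity()
  r <- rescale_transform(id, c(100, 100), c(50, 50))
  expect_equal(r$matrix, diag(2))
  expect_equal(r$offset, c(0, 0))

  # uniform +5 px translation field upscaled 2x becomes +10 px
  f <- displacement_field(matrix(5, 40, 40), matrix(0, 40, 40))
  up <- rescale_transform(f, c(40, 40), c(80, 80))
  expect_equal(unique(as.numeric(up$bwd_x)), 10)
  expect_equal(unique(as.numeric(up$bwd_y)), 0)

  # random smooth field down- then upscaled: max vector error < 0.5 px
  d <- make_deformation(5, c(120, 120), 8, 40)
  down <- rescale_transform(d, c(120, 120), c(60, 60))
  back <- rescale_transform(down, c(60, 60), c(120, 120))
  err <- sqrt((back$bwd_x - d$bwd_x)^2 + (back$bwd_y - d$bwd_y)^2)
  expect_lt(max(err[10:110, 10:110]), 0.5)
})

test_that("compositing matches sequential application", {
  shp <- c(80, 80)
  idc <- transform_chain(list(
    histofuse:::chain_step("affine", fwd = affine_identity()),
    histofuse:::chain_step("affine", fwd = affine_identity())), shp, shp)
  cf <- composite(idc)
  expect_lt(max(abs(cf$bwd_x)) + max(abs(cf$bwd_y)), 1e-12)

  tc <- transform_chain(list(
    histofuse:::chain_step("affine", fwd = affine_translation(3, 0)),
    histofuse:::chain_step("affine", fwd = affine_translation(0, 4))), shp, shp)
  cf2 <- composite(tc)
  expect_equal(unique(as.numeric(cf2$fwd_x)), 3)
  expect_equal(unique(as.numeric(cf2$fwd_y)), 4)

  # affine + nonrigid chain vs step-by-step application on random points
  d <- make_deformation(8, c(150, 150), 10, 50)
  ch <- transform_chain(list(
    histofuse:::chain_step("affine", fwd = affine_compose(
      affine_rotation(10, c(75, 75)), affine_translation(4, -2))),
    histofuse:::chain_step("field", field = d)), c(150, 150), c(150, 150))
  pts <- hf_seeded(3, cbind(runif(1000, 10, 140), runif(1000, 10, 140)))
  seq_fwd <- histofuse:::chain_forward(ch, pts)
  cf3 <- composite(ch)
  comp_fwd <- cbind(
    pts[, 1] + histofuse:::cpp_sample_bilinear(cf3$fwd_x, pts[, 1], pts[, 2]),
    pts[, 2] + histofuse:::cpp_sample_bilinear(cf3$fwd_y, pts[, 1], pts[, 2]))
  expect_points_close(comp_fwd, seq_fwd, 0.5)

  # a chain with mismatched space tags is rejected naming the broken link
  expect_error(transform_chain(list(
    histofuse:::chain_step("affine", from = "a", to = "b", fwd = affine_identity()),
    histofuse:::chain_step("affine", from = "c", to = "d", fwd = affine_identity())),
    shp, shp), class = "histofuse_chain_error")
})

test_that("image warping handles identity, integer shifts and inverses", {
  # smooth image: double interpolation error must come from the field, not
  # from resampling unresolvable high-frequency content
  img <- raster2d(histofuse:::cpp_gauss_smooth(
    hf_seeded(4, matrix(runif(80 * 80, 0, 255), 80, 80)), 2) * 2)
  idf <- histofuse:::identity_field(c(80, 80))
  expect_equal(warp_image(img, idf)$pixels, img$pixels)

  sh <- histofuse:::chain_from_affine(affine_translation(5, 3), c(80, 80), c(80, 80))
  w <- warp_image(img, sh, fill = -1)
  expect_equal(w$pixels[10 + 3, 20 + 5], img$pixels[10, 20])
  expect_true(all(w$pixels[, 1:5] == -1))

  # warp by a known field and then by its inverse: small interior error
  d <- make_deformation(9, c(80, 80), 6, 30)
  wd <- warp_image(img, histofuse:::chain_from_field(d))
  back <- warp_image(wd, histofuse:::chain_from_field(
    histofuse:::invert_field_step(d)))
  interior <- abs(back$pixels - img$pixels)[15:65, 15:65]
  expect_lt(mean(interior), 0.02 * 255)
})

test_that("mask and label warping is strictly nearest-neighbor", {
  m <- matrix(FALSE, 60, 60); m[10:30, 5:40] <- TRUE; m[10:15, 5:10] <- FALSE
  mask <- binary_mask(m)
  idf <- histofuse:::identity_field(c(60, 60))
  expect_equal(warp_mask(mask, idf)$pixels, m)

  rot <- histofuse:::chain_from_affine(
    affine_rotation(180, c(29.5, 29.5)), c(60, 60), c(60, 60))
  wm <- warp_mask(mask, rot)
  expect_lt(abs(sum(wm$pixels) - sum(m)) / sum(m), 0.01)
  expect_equal(wm$pixels[60 - 12 + 1, 60 - 7 + 1], m[12, 7])

  lab <- fx_label_raster(5, c(60, 60), 7)
  wl <- warp_labels(lab, histofuse:::chain_from_field(make_deformation(10, c(60, 60), 4, 25)))
  expect_true(all(unique(as.numeric(wl)) %in% unique(as.numeric(lab))))
})

test_that("pointset and geojson warping follow the forward map", {
  pts <- pointset2d(rbind(c(5, 5), c(20, 11)))
  sh <- histofuse:::chain_from_affine(affine_translation(-3, 7), c(40, 40), c(40, 40))
  w <- warp_points(pts, sh)
  expect_equal(w$x, pts$x - 3)
  expect_equal(w$y, pts$y + 7)
  idf <- histofuse:::identity_field(c(40, 40))
  expect_equal(warp_points(pts, idf)$x, pts$x)

  sq <- matrix(c(2, 2, 8, 2, 8, 8, 2, 8), 4, 2, byrow = TRUE)
  ann <- polygon_annotation(list(list(outer = sq, holes = list())), "g")
  wa <- warp_geojson(ann, sh)
  expect_equal(wa$shapes[[1]]$outer, sweep(sq, 2, c(-3, 7), "+"))
  expect_equal(wa$labels, "g")
})

test_that("point warping and raster warping agree", {
  # points warped forward land on their own labels in the warped raster
  d <- make_deformation(11, c(100, 100), 6, 40)
  ch <- histofuse:::chain_from_field(d)
  lab <- matrix(rep(1:10, each = 1000), 100, 100)  # vertical label bands
  wl <- warp_labels(lab, ch)
  pts <- hf_seeded(12, cbind(runif(500, 5, 94), runif(500, 5, 94)))
  own <- lab[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)]
  w <- histofuse:::chain_forward(ch, pts)
  landed <- wl[cbind(pmin(pmax(round(w[, 2]), 0), 99) + 1,
                     pmin(pmax(round(w[, 1]), 0), 99) + 1)]
  expect_gte(mean(abs(landed - own) <= 1), 0.99)   # band neighbors allowed

  # a delta spike warped as an image matches its coordinate warped as a point
  img <- matrix(0, 100, 100); img[40, 60] <- 1    # spike at (x, y) = (59, 39)
  wi <- warp_image(raster2d(img), ch, interp = "nearest")
  peak <- which(wi$pixels == max(wi$pixels), arr.ind = TRUE)[1, ]
  wp <- histofuse:::chain_forward(ch, rbind(c(59, 39)))
  expect_lt(sqrt((peak[2] - 1 - wp[1])^2 + (peak[1] - 1 - wp[2])^2), 1.01)
})
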