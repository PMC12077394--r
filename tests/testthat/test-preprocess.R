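test_that("tissue segmentation finds dark tissue and drops small artifacts", {
  # pure white image: empty mask plus no-tissue warning
  white <- raster2d(matrix(255, 400, 400))
  expect_warning(m <- segment_tissue(white), class = "histofuse_no_tissue_warning")
  expect_false(any(m$pixels))
  expect_true(isTRUE(attr(m, "no_tissue")))

  # noisy dark disk: mask-vs-disk IoU >= 0.95
  n <- 1000
  xs <- outer(rep(1, n), 1:n - 500); ys <- t(xs)
  disk <- xs^2 + ys^2 <= 200^2
  px <- matrix(235, n, n)
  px[disk] <- 90
  px <- px + getFromNamespace("with_seed", "histofuse")(1, matrix(rnorm(n * n, 0, 5), n, n))
  m <- segment_tissue(raster2d(pmin(pmax(px, 0), 255)))
  iou <- sum(m$pixels & disk) / sum(m$pixels | disk)
  expect_gte(iou, 0.95)

  # two dark blobs, 50,000 and 5,000 um^2: only the large one survives 10,000
  px2 <- matrix(240, 800, 800)
  r_big <- sqrt(50000 / pi); r_small <- sqrt(5000 / pi)
  xs <- outer(rep(1, 800), 1:800); ys <- t(xs)
  big <- (xs - 200)^2 + (ys - 400)^2 <= r_big^2
  small <- (xs - 600)^2 + (ys - 400)^2 <= r_small^2
  px2[big | small] <- 80
  m2 <- segment_tissue(raster2d(px2))
  expect_gt(sum(m2$pixels & big) / sum(big), 0.8)
  expect_equal(sum(m2$pixels & small), 0)
})

test_that("segmented area is stable under a global linear intensity rescale", {
  scene <- fx_scene(5, 400, 8)
  g <- raster2d(histofuse:::to_gray(scene$image))
  a1 <- mask_area_um2(segment_tissue(g))
  resc <- raster2d(pmin(pmax(g$pixels * 0.8 + 30, 0), 255))
  a2 <- mask_area_um2(segment_tissue(resc))
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("small-region filter applies the 8-connected area rule", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE                        # 9 px < 10 um^2 at 1 um/px
  expect_false(any(filter_small_regions(binary_mask(m), 10)$pixels))
  m2 <- matrix(FALSE, 20, 20)
  m2[2:4, 2:5] <- TRUE                       # 12 px >= 10
  expect_equal(sum(filter_small_regions(binary_mask(m2), 10)$pixels), 12)
  empty <- binary_mask(matrix(FALSE, 5, 5))
  expect_false(any(filter_small_regions(empty, 10)$pixels))
})

test_that("mean-shift denoising preserves edges and flattens speckle", {
  # constant color image is unchanged
  flat <- raster2d(array(rep(c(100, 150, 200), each = 64 * 64), c(64, 64, 3)))
  out <- denoise_mean_shift(flat)
  expect_lt(max(abs(out$pixels - flat$pixels)), 1e-6)

  # grayscale input is a channel error
  expect_error(denoise_mean_shift(raster2d(matrix(100, 64, 64))),
               class = "histofuse_channel_error")

  # two tones farther apart than the color radius: edge preserved
  tone <- array(0, c(128, 128, 3))
  tone[, 1:64, ] <- 80; tone[, 65:128, ] <- 200
  td <- denoise_mean_shift(raster2d(tone))
  left <- mean(td$pixels[, 1:48, 1]); right <- mean(td$pixels[, 81:128, 1])
  expect_lt(abs(left - 80), 6)
  expect_lt(abs(right - 200), 6)

  # 1% salt speckle: the flat region keeps < 10% of the input variance
  # (mean shift preserves modes, so isolated impulse centers may survive,
  # but they must not bleed into the flat background)
  spk <- array(120, c(128, 128, 3))
  noise_at <- getFromNamespace("with_seed", "histofuse")(2,
    sample.int(128 * 128, round(0.01 * 128 * 128)))
  for (k in 1:3) { ch <- spk[, , k]; ch[noise_at] <- 255; spk[, , k] <- ch }
  ds <- denoise_mean_shift(raster2d(spk))
  flat <- setdiff(seq_len(128 * 128), noise_at)
  expect_lt(var(as.numeric(ds$pixels[, , 1])[flat]),
            0.1 * var(as.numeric(spk[, , 1])))
})

test_that("prepare_pair yields the padded working shape with exact bookkeeping", {
  scene <- fx_scene(5, 400, 8)
  img2 <- raster2d(scene$image$pixels[, 400:1, ])   # mirrored partner
  msk2 <- binary_mask(scene$mask$pixels[, 400:1])
  # default options: 1024 working + 2 x 100 padding = 1224
  pp <- prepare_pair(scene$image, img2, scene$mask, msk2, "nonrigid", reg_options())
  expect_equal(dim(pp$moving$image$pixels), c(1224, 1224))
  expect_equal(dim(pp$fixed$image$pixels), c(1224, 1224))

  # bookkeeping maps the original mask bbox corners to the working crop
  # corners exactly (the affine is the composition of recorded exact steps)
  bb <- histofuse:::mask_bbox(scene$mask)
  st <- pp$moving$bookkeeping$steps
  corner <- affine_apply(pp$moving$bookkeeping$affine, rbind(bb[1:2]))
  manual <- affine_apply(st$border_pad, affine_apply(st$scale,
    affine_apply(st$square_pad, affine_apply(st$crop, rbind(bb[1:2])))))
  expect_equal(corner, manual)

  # bookkeeping is exactly invertible: 100 random points round-trip < 1e-9
  pts <- getFromNamespace("with_seed", "histofuse")(9,
    cbind(runif(100, 0, 399), runif(100, 0, 399)))
  fwd <- affine_apply(pp$moving$bookkeeping$affine, pts)
  back <- affine_apply(affine_invert(pp$moving$bookkeeping$affine), fwd)
  expect_lt(max(abs(back - pts)), 1e-9)

  expect_error(prepare_pair(scene$image, img2,
                            binary_mask(matrix(FALSE, 400, 400)), msk2),
               class = "histofuse_no_tissue_error")
})

test_that("the nonrigid stage skips denoising", {
  scene <- fx_scene(5, 400, 8)
  opts <- reg_options(working_size = 128, pad_px = 16)
  ppa <- prepare_pair(scene$image, scene$image, scene$mask, scene$mask, "affine", opts)
  ppn <- prepare_pair(scene$image, scene$image, scene$mask, scene$mask, "nonrigid", opts)
  expect_gt(mean(abs(ppa$moving$image$pixels - ppn$moving$image$pixels)), 0.1)
})
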