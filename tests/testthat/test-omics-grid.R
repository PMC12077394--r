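# brute-force pixel-center-in-circle enumeration used as rasterization oracle
circle_cells <- function(cx, cy, r, shape) {
  xs <- 0:(shape[2] - 1); ys <- 0:(shape[1] - 1)
  sum(outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2)
}

test_that("spot projection matches point-in-circle enumeration", {
  g <- spot_geometry("A", rbind(c(100, 100)), diameter_um = 55)
  ref <- project_spots(g, c(200, 200), 1)
  oracle <- circle_cells(100, 100, 27.5, c(200, 200))
  expect_lt(abs(sum(ref$labels == 1L) - oracle) / oracle, 0.01)
  expect_gt(oracle, 2300)   # ~2376 cells for a 55 um spot at 1 um/px

  # spot fully outside the image: no labels, reported off-image
  g2 <- spot_geometry(c("A", "B"), rbind(c(50, 50), c(500, 500)), 55)
  ref2 <- project_spots(g2, c(100, 100), 1)
  expect_equal(attr(ref2, "off_image"), "B")
  expect_equal(sort(unique(as.numeric(ref2$labels))), c(0, 1))

  # two spots at 100 um pitch with 55 um diameter never share pixels
  g3 <- spot_geometry(c("A", "B"), rbind(c(60, 60), c(160, 60)), 55, 100)
  ref3 <- project_spots(g3, c(220, 220), 1)
  expect_equal(sum(ref3$labels == 1L), sum(ref3$labels == 2L))
  expect_silent(project_spots(g3, c(220, 220), 1))
})

test_that("pixel projection rasterizes exact 30 um squares", {
  g <- pixel_geometry("P1", 0, 0, origin_um = c(10, 10), pitch_um = 30)
  ref <- project_pixels(g, c(100, 100), 1)
  expect_equal(sum(ref$labels == 1L), 900)

  g2 <- pixel_geometry(c("P1", "P2"), c(0, 1), c(0, 0), c(10, 10), 30)
  ref2 <- project_pixels(g2, c(100, 100), 1)
  expect_equal(sum(ref2$labels > 0L), 1800)
  expect_equal(sum(ref2$labels == 1L & ref2$labels == 2L), 0)

  # grid clipped by the image edge: count equals the enumeration oracle
  g3 <- pixel_geometry("P1", 0, 0, origin_um = c(85, 90), pitch_um = 30)
  ref3 <- project_pixels(g3, c(100, 100), 1)
  xs <- 0:99
  oracle <- sum(xs >= 85 & xs < 115) * sum(xs >= 90 & xs < 120)
  expect_equal(sum(ref3$labels == 1L), oracle)
})

test_that("projection area equals geometry area within 1% at 1 um/px", {
  g <- spot_geometry(sprintf("S%d", 1:4),
                     rbind(c(70, 70), c(170, 70), c(120, 156.6), c(220, 156.6)),
                     55, 100)
  ref <- project_spots(g, c(300, 300), 1)
  for (k in 1:4)
    expect_lt(abs(sum(ref$labels == k) - pi * 27.5^2) / (pi * 27.5^2), 0.01)
})

test_that("first-PC feature image matches an eigen-decomposition oracle", {
  # single channel passes through (proportional after scaling)
  g <- pixel_geometry(sprintf("P%d", 1:9), rep(0:2, 3), rep(0:2, each = 3),
                      c(0, 0), 30)
  v <- matrix(1:9, 9, 1)
  f <- msi_feature_image(measurement_table(sprintf("P%d", 1:9), v), g, 30)
  expect_equal(dim(f$pixels), c(3, 3))
  expect_equal(cor(as.numeric(t(f$pixels)), 1:9), 1)

  # two perfectly correlated channels: scores proportional to either channel
  v2 <- cbind(a = as.numeric(1:9), b = 2 * as.numeric(1:9))
  f2 <- msi_feature_image(measurement_table(sprintf("P%d", 1:9), v2), g, 30)
  expect_equal(abs(cor(as.numeric(t(f2$pixels)), 1:9)), 1, tolerance = 1e-10)

  # random 50-pixel 20-channel table vs covariance eigenvector oracle
  gg <- pixel_geometry(sprintf("P%d", 1:50), rep(0:9, 5), rep(0:4, each = 10),
                       c(0, 0), 30)
  V <- hf_seeded(15, matrix(rnorm(50 * 20), 50, 20))
  f3 <- msi_feature_image(measurement_table(sprintf("P%d", 1:50), V), gg, 30)
  ev <- eigen(cov(V))$vectors[, 1]
  sc <- scale(V, scale = FALSE) %*% ev
  sc <- (sc - min(sc)) / diff(range(sc))
  got <- as.numeric(t(f3$pixels))[order(rep(0:4, each = 10) * 10 + rep(0:9, 5))]
  # sign convention may flip the oracle
  err <- min(max(abs(got - sc)), max(abs(got - (1 - sc))))
  expect_lt(err, 1e-8)

  expect_error(msi_feature_image(
    measurement_table(sprintf("P%d", 1:9), matrix(1, 9, 3)), g, 30),
    class = "histofuse_degenerate_component_error")
})

test_that("rigid omics-to-stain registration recovers rotation and shift", {
  scene <- fx_scene(7, 400, 8)
  stained <- scene$image
  gray <- histofuse:::to_gray(stained)
  A <- affine_compose(affine_rotation(10, c(200, 200)), affine_translation(20, -5))
  ch <- histofuse:::chain_from_affine(A, c(400, 400), c(400, 400))
  # moving "feature" image: transformed copy of the stained intensities,
  # warped by the INVERSE so that A maps feature -> stained
  inv <- histofuse:::chain_from_affine(affine_invert(A), c(400, 400), c(400, 400))
  feat <- warp_image(raster2d(1 - gray / 255), inv, fill = 0)
  opts <- fx_opts(seed = 31, working_size = 192, pad_px = 24)
  res <- rigid_register_msi(feat, stained, scene$mask, opts = opts)
  ctr <- rbind(histofuse:::mask_centroid(scene$mask))
  pts <- rbind(ctr, ctr + c(60, 0), ctr + c(0, 60))
  got <- histofuse:::chain_forward(res$chain, pts)
  want <- affine_apply(A, pts)
  expect_points_close(got, want, 3)

  # identical images give identity within half a pixel
  res2 <- rigid_register_msi(raster2d(1 - gray / 255), stained, scene$mask,
                             opts = fx_opts(seed = 32, working_size = 192, pad_px = 24))
  got2 <- histofuse:::chain_forward(res2$chain, pts)
  expect_points_close(got2, pts, 0.75)

  # mask-on-mask mode with identical masks is identity too
  res3 <- rigid_register_msi(raster2d(gray), stained, scene$mask,
                             feature_mask = scene$mask,
                             opts = fx_opts(seed = 33, working_size = 192, pad_px = 24))
  got3 <- histofuse:::chain_forward(res3$chain, pts)
  expect_points_close(got3, pts, 0.75)
})

test_that("warped reference matrices conserve labels and areas", {
  g <- spot_geometry(sprintf("S%d", 1:4),
                     rbind(c(70, 70), c(170, 70), c(120, 156.6), c(220, 156.6)),
                     55, 100)
  ref <- project_spots(g, c(300, 300), 1)
  d <- make_deformation(16, c(300, 300), 3, 80)   # near-rigid
  w <- warp_reference_matrix(ref, histofuse:::chain_from_field(d))
  expect_true(all(unique(as.numeric(w$labels)) %in% 0:4))
  for (k in 1:4) {
    n0 <- sum(ref$labels == k); n1 <- sum(w$labels == k)
    expect_lt(abs(n1 - n0) / n0, 0.05)
  }
})

test_that("reference matrices round-trip through TIFF + CSV", {
  g <- spot_geometry(c("A", "B"), rbind(c(40, 40), c(140, 40)), 55, 100)
  ref <- project_spots(g, c(200, 200), 1)
  lp <- withr::local_tempfile(fileext = ".tiff")
  ip <- withr::local_tempfile(fileext = ".csv")
  write_reference_matrix(ref, lp, ip)
  back <- read_reference_matrix(lp, ip, 1)
  expect_identical(back$labels, ref$labels)
  expect_identical(back$ids, ref$ids)
})
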