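# independent brute-force oracle: per-cell accumulation over the rasters
brute_overlap <- function(tref, sref) {
  out <- list()
  for (i in seq_len(nrow(tref$labels)))
    for (j in seq_len(ncol(tref$labels))) {
      t <- tref$labels[i, j]; s <- sref$labels[i, j]
      if (t > 0 && s > 0) {
        tid <- tref$ids[t]; sid <- sref$ids[s]
        key <- paste(tid, sid)
        out[[key]] <- (out[[key]] %||% 0) + 1
      }
    }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("overlap weights are per-spot area fractions", {
  # one source pixel covering the whole spot -> single weight 1
  t1 <- reference_matrix(matrix(c(0L, 1L, 1L, 0L), 2, 2), "S1")
  s1 <- reference_matrix(matrix(1L, 2, 2), "P1")
  w <- overlap_weights(t1, s1)
  expect_equal(w[["S1"]]$weight, 1)

  # 300 and 100 co-labeled cells -> weights 0.75 / 0.25
  tl <- matrix(0L, 20, 20); tl[1:20, 1:20] <- 1L
  sl <- matrix(0L, 20, 20); sl[1:15, 1:20] <- 1L; sl[16:20, 1:20] <- 2L
  w2 <- overlap_weights(reference_matrix(tl, "S1"),
                        reference_matrix(sl, c("P1", "P2")))
  expect_equal(sort(w2[["S1"]]$weight), c(0.25, 0.75))

  expect_error(overlap_weights(reference_matrix(matrix(0L, 3, 3), character(0)),
                               reference_matrix(matrix(0L, 4, 4), character(0))),
               class = "histofuse_space_error")
})

test_that("overlap weights match the exhaustive per-cell oracle", {
  tl <- fx_label_raster(21, c(60, 60), 20, 0.7)
  sl <- fx_label_raster(22, c(60, 60), 200, 0.7)
  tref <- reference_matrix(tl, sprintf("S%02d", 1:20))
  sref <- reference_matrix(sl, sprintf("P%03d", 1:200))
  w <- overlap_weights(tref, sref)
  oracle <- brute_overlap(tref, sref)
  got <- unlist(lapply(names(w), function(t)
    setNames(w[[t]]$cells, paste(t, w[[t]]$source_id))))
  expect_mapequal(as.list(got), oracle)
  for (t in names(w)) expect_equal(sum(w[[t]]$weight), 1, tolerance = 1e-9)
})

test_that("weighted statistics follow their definitions", {
  st <- weighted_stats(c(10, 20), c(0.75, 0.25))
  expect_equal(st$mean, 12.5)
  expect_equal(st$min, 10)
  expect_equal(st$max, 20)

  v <- c(4, 8, 15, 16, 23, 42)
  st2 <- weighted_stats(v, rep(1 / 6, 6))
  expect_equal(st2$mean, mean(v))
  expect_equal(st2$std, sqrt(mean((v - mean(v))^2)))   # population form
  expect_equal(st2$median, 15)                         # lower weighted median

  # 1000 random weighted sets vs a cumulative-scan / two-pass oracle
  hf_seeded(23, for (i in 1:1000) {
    n <- sample(1:12, 1)
    v <- rnorm(n); w <- runif(n); w <- w / sum(w)
    st <- weighted_stats(v, w)
    o <- order(v); cw <- cumsum(w[o])
    med_oracle <- v[o][which(cw >= 0.5)[1]]
    mean_oracle <- sum(w * v)
    std_oracle <- sqrt(sum(w * (v - mean_oracle)^2))
    expect_identical(st$median, med_oracle)
    expect_lt(abs(st$std - std_oracle), 1e-10)
    expect_lt(abs(st$mean - mean_oracle), 1e-12)
  })

  expect_true(weighted_stats(numeric(0), numeric(0))$missing)
  expect_error(weighted_stats(1:3, c(1, 1, 1)), class = "histofuse_type_error")
})

test_that("fusion reproduces constants, single pixels and area fractions", {
  tl <- fx_label_raster(24, c(40, 40), 5, 0.5)
  sl <- fx_label_raster(25, c(40, 40), 30, 0.8)
  tref <- reference_matrix(tl, sprintf("S%d", 1:5))
  sref <- reference_matrix(sl, sprintf("P%02d", 1:30))
  w <- overlap_weights(tref, sref)
  const <- measurement_table(sprintf("P%02d", 1:30),
                             matrix(7, 30, 1, dimnames = list(NULL, "m")))
  f <- fuse(const, w)
  on <- !f$no_overlap
  expect_true(all(abs(f$m.mean[on] - 7) < 1e-12))
  expect_true(all(f$m.std[on] < 1e-12))

  # single-source spots: fused mean equals that pixel's value exactly
  vals <- measurement_table(sprintf("P%02d", 1:30),
                            matrix(rnorm(30), 30, 1, dimnames = list(NULL, "m")))
  f2 <- fuse(vals, w)
  singles <- names(w)[vapply(w, nrow, 0L) == 1]
  for (s in singles)
    expect_equal(f2[f2$spot_id == s, "m.mean"],
                 vals$values[match(w[[s]]$source_id, vals$ids), 1])

  expect_error(fuse(measurement_table("X", matrix(1, 1, 1)), w),
               class = "histofuse_integrity_error")
})

test_that("fused means of a two-region fixture equal the area fractions", {
  # gland occupies the left half-plane; spots straddle the boundary
  shape <- c(420, 200)
  gland <- matrix(0, shape[1], shape[2]); gland[, 1:100] <- 1
  # spots along the boundary at >= 100 um spacing, straddling it variously
  centers <- rbind(c(100, 60), c(78, 160), c(122, 260), c(100, 360), c(40, 60))
  sg <- spot_geometry(sprintf("S%d", 1:5), centers, 55, 100)
  tref <- project_spots(sg, shape, 1)
  # fine source pixels (10 um) so rasterization error stays below 2%
  gp <- expand.grid(col = 0:19, row = 0:41)
  pg <- pixel_geometry(sprintf("P%03d", seq_len(nrow(gp))), gp$col, gp$row,
                       c(0, 0), 10)
  sref <- project_pixels(pg, shape, 1)
  val <- vapply(seq_len(nrow(gp)), function(k)
    mean(gland[gp$row[k] * 10 + 1:10, gp$col[k] * 10 + 1:10]), 0)
  tab <- measurement_table(pg$ids, matrix(val, ncol = 1, dimnames = list(NULL, "g")))
  f <- fuse(tab, overlap_weights(tref, sref))
  for (k in 1:5) {
    frac <- {
      xs <- 0:(shape[2] - 1); ys <- 0:(shape[1] - 1)
      inside <- outer((ys - centers[k, 2])^2, (xs - centers[k, 1])^2, "+") <= 27.5^2
      mean(gland[inside])
    }
    expect_lt(abs(f[f$spot_id == sprintf("S%d", k), "g.mean"] - frac), 0.02)
  }
})

test_that("fusion is linear and order-invariant", {
  tl <- fx_label_raster(26, c(40, 40), 5, 0.5)
  sl <- fx_label_raster(27, c(40, 40), 30, 0.8)
  tref <- reference_matrix(tl, sprintf("S%d", 1:5))
  sref <- reference_matrix(sl, sprintf("P%02d", 1:30))
  w <- overlap_weights(tref, sref)
  v <- hf_seeded(28, rnorm(30))
  f1 <- fuse(measurement_table(sprintf("P%02d", 1:30),
                               matrix(v, ncol = 1, dimnames = list(NULL, "m"))), w)
  f2 <- fuse(measurement_table(sprintf("P%02d", 1:30),
                               matrix(3 * v + 2, ncol = 1, dimnames = list(NULL, "m"))), w)
  expect_equal(f2$m.mean, 3 * f1$m.mean + 2)

  perm <- hf_seeded(29, sample(30))
  f3 <- fuse(measurement_table(sprintf("P%02d", 1:30)[perm],
                               matrix(v[perm], ncol = 1, dimnames = list(NULL, "m"))), w)
  expect_equal(f3$m.mean, f1$m.mean)
  expect_equal(f3$m.median, f1$m.median)
})

test_that("coverage filter keeps exactly-at-threshold spots", {
  # spot with 100 labeled cells, 80 inside tissue -> coverage 0.80, kept
  tl <- matrix(0L, 20, 10)
  tl[1:10, 1:10] <- 1L   # spot 1: 100 cells
  tl[11:20, 1:10] <- 2L  # spot 2: 100 cells
  mask <- matrix(FALSE, 20, 10)
  mask[1:8, 1:10] <- TRUE             # 80 of spot 1
  mask[11:18, 1:10] <- TRUE; mask[19, 10] <- TRUE  # 81 -> then drop one
  mask[19, 10] <- FALSE; mask[18, 10] <- FALSE     # 79 of spot 2
  cov <- spot_coverage(reference_matrix(tl, c("A", "B")), binary_mask(mask))
  expect_equal(unname(cov["A"]), 0.80)
  expect_equal(unname(cov["B"]), 0.79)
  expect_equal(filter_by_coverage(cov, 0.8), "A")

  # randomized fixture equals per-spot enumeration
  tl2 <- fx_label_raster(30, c(50, 50), 8, 0.6)
  m2 <- fx_label_raster(31, c(50, 50), 1, 0.5) > 0
  cov2 <- spot_coverage(reference_matrix(tl2, sprintf("S%d", 1:8)),
                        binary_mask(m2))
  for (k in 1:8) {
    sel <- tl2 == k
    expect_equal(unname(cov2[k]), sum(sel & m2) / sum(sel))
  }
})

test_that("tissue-type assignment and matching follow the majority rule", {
  tl <- matrix(0L, 10, 30)
  tl[, 1:10] <- 1L; tl[, 11:20] <- 2L; tl[, 21:30] <- 3L
  tref <- reference_matrix(tl, c("A", "B", "C"))
  ann_t <- matrix(0L, 10, 30); ann_t[, 1:20] <- 1L; ann_t[, 21:30] <- 2L
  ann_s <- matrix(0L, 10, 30); ann_s[, 1:10] <- 1L; ann_s[, 11:30] <- 2L
  at <- assign_tissue_type(tref, ann_t, c("gland", "stroma"))
  as_ <- assign_tissue_type(tref, ann_s, c("gland", "stroma"))
  expect_equal(at$label, c("gland", "gland", "stroma"))
  expect_equal(as_$label, c("gland", "stroma", "stroma"))
  expect_equal(sort(tissue_type_match(at, as_)), c("A", "C"))

  # below the majority threshold the spot stays unassigned
  half <- matrix(0L, 10, 10); half[1:4, ] <- 1L; half[5:8, ] <- 2L
  ref1 <- reference_matrix(matrix(1L, 10, 10), "A")
  expect_true(is.na(assign_tissue_type(ref1, half, c("g", "s"))$label))
})

test_that("sham rotation is an exact 180-degree involution", {
  shp <- c(50, 70)
  base <- histofuse:::chain_from_affine(affine_identity(), shp, shp)
  sham <- sham_rotate(base, 180)
  w <- histofuse:::chain_forward(sham, rbind(c(3, 4), c(0, 0)))
  expect_equal(w[1, ], c(70 - 1 - 3, 50 - 1 - 4))
  expect_equal(w[2, ], c(69, 49))
  twice <- sham_rotate(sham, 180)
  pts <- hf_seeded(32, cbind(runif(50, 0, 69), runif(50, 0, 49)))
  expect_points_close(histofuse:::chain_forward(twice, pts), pts, 0.5)
})

test_that("fused tables export and re-import faithfully", {
  tl <- matrix(0L, 30, 30)
  tl[3:10, 3:10] <- 1L; tl[15:22, 3:10] <- 2L; tl[3:10, 15:22] <- 3L
  tref <- reference_matrix(tl, c("A", "B", "C"))
  sref <- reference_matrix(matrix(rep(1:2, each = 450), 30, 30),
                           c("P1", "P2"))
  w <- overlap_weights(tref, sref)
  tab <- measurement_table(c("P1", "P2"),
                           matrix(c(1.123456789, 2.2, 3.3, 4.4), 2, 2,
                                  dimnames = list(NULL, c("m1", "m2"))))
  f <- fuse(tab, w)
  # 3 spots x 2 measures: 10 statistic columns + id + area + count + flag
  expect_equal(nrow(f), 3)
  expect_equal(sum(grepl("^m[12]\\.", names(f))), 10)
  p <- withr::local_tempfile(fileext = ".csv")
  export_fused(f, p)
  back <- read_fused(p)
  expect_equal(back$m1.mean, f$m1.mean, tolerance = 1e-9)

  ps <- withr::local_tempfile(fileext = ".tiff")
  export_fused(f, ps, "image_stack", target_ref = tref)
  pages <- tiff::readTIFF(ps, all = TRUE)
  expect_length(pages, 2)
  expect_equal(pages[[1]][1, 1], 0)   # background stays 0

  dup <- f; dup$spot_id[2] <- dup$spot_id[1]
  expect_error(export_fused(dup, p), class = "histofuse_export_error")
})
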