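# Shared fixtures, cached across test files (scenes are the expensive part).

.fx <- new.env(parent = emptyenv())

# run an expression under a temporary seed (internal helper re-used in tests)
hf_seeded <- getFromNamespace("with_seed", "histofuse")

fx_scene <- function(seed = 3, size = 500, n_glands = 12) {
  key <- sprintf("scene_%d_%d_%d", seed, size, n_glands)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_tissue_image(seed, size_px = size, n_glands = n_glands)
  .fx[[key]]
}

fx_serial <- function(seed = 3, size = 500, n = 2, ...) {
  key <- sprintf("serial_%d_%d_%d", seed, size, n)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_serial_sections(fx_scene(seed, size), n = n, ...)
  .fx[[key]]
}

# fast registration options for module-level tests
fx_opts <- function(seed = 7, working_size = 192, pad_px = 24, ...) {
  reg_options(working_size = working_size, pad_px = pad_px, seed = seed,
              denoise = FALSE, ...)
}

# landmarks spread over a scene's tissue mask
fx_landmarks <- function(scene, n = 150) {
  idx <- which(scene$mask$pixels, arr.ind = TRUE)
  sel <- idx[round(seq(1, nrow(idx), length.out = n)), , drop = FALSE]
  pointset2d(cbind(sel[, 2] - 1, sel[, 1] - 1))
}

# random label raster with k labels over an (h, w) grid (0 = background)
fx_label_raster <- function(seed, shape, k, fill_frac = 0.6) {
  with_seed <- getFromNamespace("with_seed", "histofuse")
  with_seed(seed, {
    m <- matrix(0L, shape[1], shape[2])
    n <- round(length(m) * fill_frac)
    m[sample.int(length(m), n)] <- sample.int(k, n, replace = TRUE)
    m
  })
}

expect_points_close <- function(a, b, tol) {
  expect_lt(max(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)), tol)
}
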