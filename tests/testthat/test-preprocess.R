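test_that("FOV masking zeroes outside the circle and is idempotent", {
  v <- cbct_volume(array(500, dim = c(220, 220, 1)))
  m <- apply_fov_mask(v, 208)
  ci <- (220 + 1) / 2
  # voxel at ~110 mm radius is outside a 208-mm FOV; 50 mm is inside
  expect_identical(m$values[ci + 110, ci, 1], -1000)
  expect_identical(m$values[ci + 50, ci, 1], 500)
  frac <- mean(m$values[, , 1] == -1000)
  expect_lt(abs(frac - (1 - pi * 104^2 / 220^2)), 0.01)
  expect_identical(apply_fov_mask(m, 208)$values, m$values)
})

test_that("isotropic resampling preserves constants, extent, and no-ops", {
  v <- cbct_volume(array(rnorm(20 * 24 * 8, 0, 100), dim = c(20, 24, 8)))
  expect_identical(resample_isotropic(v, 1)$values, v$values)
  up <- resample_isotropic(v, 1, in_spacing = c(2, 2, 2))
  expect_true(all(abs(dim(up$values) - dim(v$values) * 2) <= 1))
  const <- cbct_volume(array(77, dim = c(10, 10, 4)))
  cu <- resample_isotropic(const, 0.5)
  inner <- cu$values[3:17, 3:17, 2:6]
  expect_true(all(abs(inner - 77) < 1e-9))
})

test_that("HU normalization and its inverse are exact on the clip range", {
  expect_identical(normalize_hu(-1000), 0)
  expect_identical(normalize_hu(3100), 1)
  expect_identical(normalize_hu(1050), 0.5)
  hu <- seq(-1000, 3100, by = 13.7)
  expect_equal(denormalize_hu(normalize_hu(hu)), hu, tolerance = 1e-12)
  expect_identical(denormalize_hu(0), -1000)
  expect_identical(denormalize_hu(1), 3100)
  expect_warning(denormalize_hu(c(0.5, 1.2)), "clipped")
  # out-of-range HU is clipped before normalization
  expect_identical(normalize_hu(5000), 1)
})

test_that("padding centers the slice and cropping inverts it bit-exactly", {
  s <- matrix(runif(220 * 220), 220, 220)
  p <- pad_slice(s, 256)
  expect_identical(dim(p), c(256L, 256L))
  expect_identical(p[1, 1], 0)
  expect_identical(p[256, 128], 0)
  expect_identical(crop_slice(p, 220), s)
  expect_error(pad_slice(s, 128), "smaller")
  expect_error(crop_slice(s, 256), "larger")
})

test_that("dataset assembly splits 60/20/20, disjointly and reproducibly", {
  mk_vol <- function(seed, nz) {
    v <- cbct_volume(array(cbctshade:::with_seed(seed, rnorm(40 * 40 * nz, 0, 200)),
                           dim = c(40, 40, nz)))
    attr(v, "width_mm") <- 300 + seed
    v
  }
  pairs <- lapply(1:10, function(i) list(cbct = mk_vol(i, 10),
                                         ct = mk_vol(i + 100, 10)))
  ds <- build_dataset(pairs, seed = 1, split_level = "slice", pad_size = 64)
  expect_length(ds$train, 60)
  expect_length(ds$val, 20)
  expect_length(ds$test, 20)
  key <- function(p) paste(p$phantom, p$slice)
  keys <- c(sapply(ds$train, key), sapply(ds$val, key), sapply(ds$test, key))
  expect_identical(sort(keys), sort(as.vector(outer(1:10, 1:10, paste))))
  ds2 <- build_dataset(pairs, seed = 1, split_level = "slice", pad_size = 64)
  expect_identical(sapply(ds2$train, key), sapply(ds$train, key))
  # volume-level split keeps phantoms intact
  dv <- build_dataset(pairs, seed = 2, split_level = "volume", pad_size = 64)
  expect_length(intersect(unique(sapply(dv$train, function(p) p$phantom)),
                          unique(sapply(dv$test, function(p) p$phantom))), 0)
  bad <- pairs
  bad[[1]]$ct <- mk_vol(1, 9)
  expect_error(build_dataset(bad, pad_size = 64), "differ")
})

test_that("physics-off slice pairs stay strongly correlated inside the FOV", {
  cfg <- small_config()
  ph <- generate_phantom(150, n_slices = 1, seed = 8, config = cfg,
                         grid_size = 192)
  g <- cbct_geometry(n_views = 300)
  cb <- simulate_cbct(ph, g, physics_config(0, 1, 0), seed = 1,
                      extension_fraction = NULL)
  ct <- crop_volume_inplane(ph, 220)
  ds <- build_dataset(list(list(cbct = cb, ct = ct)), ratios = c(0, 0, 1),
                      split_level = "slice", fov_diameter = g$fov_mm)
  tp <- ds$test[[1]]
  n <- nrow(tp$input); ci <- (n + 1) / 2
  xs <- (1:n) - ci
  fov <- outer(xs^2, xs^2, `+`) <= (g$fov_mm / 2 - 2)^2
  expect_gt(cor(tp$input[fov], tp$label[fov]), 0.99)
})
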