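test_that("PSNR follows its closed form and the identity sentinel", {
  a <- matrix(runif(400), 20, 20)
  expect_identical(psnr(a, a), Inf)
  b <- a; b[] <- a + 0.1   # uniform offset: MSE = 0.01
  expect_equal(psnr(a, b), 20, tolerance = 1e-9)
  d <- matrix(runif(400), 20, 20)
  expect_equal(psnr(a, d), 10 * log10(1 / mean((a - d)^2)),
               tolerance = 1e-12)
  expect_error(psnr(a, matrix(0, 5, 5)), "shapes")
})

test_that("SSIM matches self-similarity, constants, and bounds", {
  a <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  # two distinct constant images: only the stabilized luminance term remains
  c1 <- matrix(0.3, 32, 32); c2 <- matrix(0.6, 32, 32)
  lum <- (2 * 0.3 * 0.6 + 0.01^2) / (0.3^2 + 0.6^2 + 0.01^2)
  expect_equal(ssim(c1, c2), lum, tolerance = 1e-9)
  for (s in 1:5) {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- matrix(runif(32 * 32), 32, 32)
    v <- ssim(x, y)
    expect_true(v >= -1 && v <= 1)
  }
})

test_that("air-mismatch masking excludes exactly the discordant voxels", {
  ph <- generate_phantom(300, n_slices = 4, seed = 12, grid_size = 384,
                         force_pockets = FALSE)
  expect_true(all(air_mismatch_mask(ph, ph)))
  # carve one rectal air pocket into a copy
  ph2 <- ph
  lt <- phantom_label_table()
  rec <- which(ph$labels == lt[["muscle"]] & ph$values > -300,
               arr.ind = TRUE)
  ctr <- rec[which.min(abs(rec[, 1] - 192) + abs(rec[, 2] - 250)), ]
  carved <- 0L
  for (dx in -3:3) for (dy in -3:3) for (dz in 0:1) {
    i <- ctr[1] + dx; j <- ctr[2] + dy; k <- min(ctr[3] + dz, 4)
    if (dx^2 + dy^2 <= 9 && ph2$values[i, j, k] > -300) {
      if (ph2$values[i, j, k] > -300) carved <- carved + 1L
      ph2$values[i, j, k] <- -1000
    }
  }
  m <- air_mismatch_mask(ph, ph2)
  expect_identical(sum(!m), carved)
})

test_that("masked MAE ignores a constructed corruption", {
  a <- array(rnorm(4000, 0, 10), dim = c(20, 20, 10))
  b <- a
  b[1:5, 1:5, 1] <- b[1:5, 1:5, 1] + 500
  mask <- array(TRUE, dim = dim(a))
  expect_equal(mae_hu(a, a), 0)
  expect_equal(mae_hu(a, a + 50), 50)
  mask[1:5, 1:5, 1] <- FALSE
  expect_lt(mae_hu(a, b, mask), mae_hu(a, b))
  expect_error(mae_hu(a, b, mask & FALSE), "empty")
})

test_that("ROI extraction is contained, sized, seeded, and fails loudly", {
  ph <- generate_phantom(320, n_slices = 10, seed = 13, grid_size = 384)
  rois <- extract_rois(ph, "spongy_bone", n = 3, edge = 8, seed = 5)
  expect_length(rois, 3)
  lt <- phantom_label_table()
  for (r in rois) {
    expect_identical(r$edge, 8L)
    cube <- ph$labels[r$corner[1]:(r$corner[1] + 7),
                      r$corner[2]:(r$corner[2] + 7),
                      r$corner[3]:(r$corner[3] + 7)]
    expect_identical(length(cube), 512L)
    expect_true(all(cube == lt[["spongy_bone"]]))
  }
  rois2 <- extract_rois(ph, "spongy_bone", n = 3, edge = 8, seed = 5)
  expect_identical(rois, rois2)
  expect_error(extract_rois(ph, "cortical_bone", edge = 30),
               "cortical_bone")
})

test_that("ROI HU differences and CNR follow their closed forms", {
  ph <- generate_phantom(320, n_slices = 10, seed = 14, grid_size = 384)
  rois <- extract_rois(ph, "bladder", n = 2, edge = 6, seed = 2)
  same <- roi_hu_difference(ph, ph, rois)
  expect_true(all(same$per_roi$abs_diff == 0))
  off <- ph; off$values <- ph$values - 100
  d <- roi_hu_difference(ph, off, rois)
  expect_true(all(abs(d$per_roi$abs_diff - 100) < 1e-9))
  expect_true(all(c("tissue", "n", "mean_diff", "sd_diff") %in%
                  names(d$per_tissue)))
  # CNR closed form and antisymmetry
  img <- array(0, dim = c(20, 20, 10))
  img[1:8, 1:8, 1:8] <- 100 + rnorm(512, 0, 10)
  img[11:18, 11:18, 1:8] <- rnorm(512, 0, 10)
  fg <- list(corner = c(1, 1, 1), edge = 8L, tissue = "ctv")
  bg <- list(corner = c(11, 11, 1), edge = 8L, tissue = "muscle")
  v <- cnr(img, fg, bg)
  pooled <- sqrt((var(as.vector(img[1:8, 1:8, 1:8])) +
                  var(as.vector(img[11:18, 11:18, 1:8]))) / 2)
  expect_equal(v, (mean(img[1:8, 1:8, 1:8]) - mean(img[11:18, 11:18, 1:8])) /
                 pooled, tolerance = 1e-12)
  expect_equal(cnr(img, bg, fg), -v, tolerance = 1e-12)
  flat <- array(5, dim = c(20, 20, 10))
  expect_error(cnr(flat, fg, bg), "zero")
})

test_that("width-vs-MAE aggregation ranks truncation severity", {
  rep <- data.frame(tag = rep(c("Base", "FT2"), each = 4),
                    width_mm = rep(c(260, 290, 320, 350), 2),
                    mae_median_hu = c(80, 120, 150, 200, 40, 42, 41, 45))
  wv <- width_vs_mae(rep)
  expect_identical(nrow(wv$rows), 8L)
  rho <- wv$correlation$spearman_rho[wv$correlation$tag == "Base"]
  expect_equal(rho, 1)
  expect_identical(nrow(width_vs_mae(rep[1, , drop = FALSE])$rows), 1L)
})

test_that("truncation severity grows with pelvis width", {
  # the out-of-FOV body fraction is the direct driver of truncation
  # artifacts; it must increase strictly with width
  fracs <- sapply(c(250, 300, 350), function(w) {
    ph <- generate_phantom(w, n_slices = 1, seed = 21, grid_size = 384)
    body <- ph$labels[, , 1] != phantom_label_table()[["air"]]
    n <- nrow(body); ci <- (n + 1) / 2
    xs <- ((1:n) - ci) * ph$spacing
    rr <- outer(xs^2, xs^2, `+`)
    sum(body & rr > 104^2) / sum(body)
  })
  expect_true(all(diff(fracs) > 0))
})
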