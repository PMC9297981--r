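test_that("HU to attenuation follows the 2^16 mapping with clipping", {
  expect_identical(hu_to_attenuation(-1000), 0)
  expect_equal(hu_to_attenuation(0), 1000 / 65536)
  expect_equal(hu_to_attenuation(3100), 4100 / 65536)
  expect_identical(hu_to_attenuation(-1500), 0)   # clipped below air
  expect_equal(attenuation_to_hu(hu_to_attenuation(123.4)), 123.4)
})

test_that("forward projection reproduces chord lengths and the null case", {
  g <- small_geometry(n_views = 12, detector_bins = 33)
  # uniform disk, radius 50 mm, mu = 0.01/mm: central chord integral = 1.0
  sl <- disk_slice(128, 50, 0.01)
  sino <- forward_project(sl, g, spacing = 1)
  central <- sino$values[, (ncol(sino$values) + 1) / 2]
  expect_true(all(abs(central - 1.0) < 0.01))
  expect_true(all(forward_project(matrix(0, 64, 64), g)$values == 0))
  tiny <- cbct_geometry(source_to_isocenter = 30, source_to_detector = 60,
                        arc_degrees = 220, n_views = 4, detector_bins = 8)
  expect_error(forward_project(matrix(0, 128, 128), tiny, spacing = 1),
               "degenerate")
})

test_that("ray-driven integrals match a 10x oversampled brute force", {
  g <- small_geometry(n_views = 10, detector_bins = 24)
  betas <- g$view_angles_deg * pi / 180
  set.seed(11)
  for (rep in 1:3) {
    sl <- matrix(runif(32 * 32, 0, 0.02), 32, 32)
    mine <- forward_project(sl, g, spacing = 1, step = 0.5)$values
    ref <- oracle_fan_project(sl, 1, betas, g$sdet,
                              g$source_to_isocenter, step = 0.05)
    rms <- sqrt(mean((mine - ref)^2)) / sqrt(mean(ref^2))
    expect_lt(rms, 0.01)
  }
})

test_that("projection-domain physics honors identity, monotonicity, seeding", {
  g <- small_geometry()
  sino <- forward_project(disk_slice(96, 40, 0.012), g)
  ident <- apply_physics(sino, physics_config(0, 1, 0), seed = 1)
  expect_identical(ident$values, sino$values)
  sc <- apply_physics(sino, physics_config(0.001, 1, 0,
                                           scatter_kernel_width = 100), 1)
  expect_true(all(sc$values <= sino$values + 1e-12))
  n1 <- apply_physics(sino, physics_config(0, 1, 0.001), seed = 5)
  n2 <- apply_physics(sino, physics_config(0, 1, 0.001), seed = 5)
  n3 <- apply_physics(sino, physics_config(0, 1, 0.001), seed = 6)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
})

test_that("truncation extension is continuous, decaying, and pass-through", {
  g <- small_geometry(n_views = 8, detector_bins = 40)
  # untruncated: disk well inside the FOV
  s_ok <- forward_project(disk_slice(128, 40, 0.01), g)
  corr <- ohnesorge_correct(s_ok, 0.30)
  expect_identical(corr$values, s_ok$values)
  expect_true(all(corr$ext_left == 0) && all(corr$ext_right == 0))
  # truncated: disk wider than the FOV
  s_tr <- forward_project(disk_slice(300, 130, 0.01), g)
  expect_gt(s_tr$values[1, 1], 0.5)
  ct <- ohnesorge_correct(s_tr, 0.30)
  ne <- ncol(ct$ext_left)
  expect_identical(ne, as.integer(round(0.30 * 40)))
  for (v in c(1, 5)) {
    edge <- ct$values[v, 1]
    expect_lt(abs(ct$ext_left[v, 1] - edge), 0.05 * edge)  # continuous
    expect_equal(ct$ext_left[v, ne], 0)                    # reaches zero
  }
  expect_error(ohnesorge_correct(s_tr, 0), "extension_fraction")
})

test_that("short-scan redundancy weights of conjugate rays sum to one", {
  g <- small_geometry(n_views = 40, detector_bins = 21)
  arc <- g$arc_degrees * pi / 180
  gamma <- atan(g$sdet / g$source_to_isocenter)
  betas <- g$view_angles_deg * pi / 180
  W <- shortscan_weights(g)
  for (k in c(1, 6, 11, 16, 21)) {
    # conjugate ray: opposite fan angle (mirrored bin on the symmetric
    # detector), source angle shifted forward or backward
    fwd <- betas + pi - 2 * gamma[k]
    bwd <- betas - pi - 2 * gamma[k]
    in_f <- fwd >= 0 & fwd <= arc
    in_b <- bwd >= 0 & bwd <= arc
    mk <- length(gamma) + 1 - k
    Wf <- shortscan_weights(g, betas = fwd)[, mk]
    Wb <- shortscan_weights(g, betas = bwd)[, mk]
    expect_true(all(abs(W[in_f, k] + Wf[in_f] - 1) < 1e-6))
    expect_true(all(abs(W[in_b, k] + Wb[in_b] - 1) < 1e-6))
    none <- !in_f & !in_b
    expect_true(all(abs(W[none, k] - 1) < 1e-6))
  }
})

test_that("FBP reconstructs air from an empty sinogram", {
  g <- small_geometry()
  sino <- forward_project(matrix(0, 96, 96), g)
  rec <- reconstruct_fbp(sino, g, out_n = 64)
  expect_true(all(abs(rec + 1000) < 1e-6))
  expect_error(cbct_geometry(arc_degrees = 150), "short-scan")
})

test_that("simulated CBCT has the reference grid and is seeded", {
  cfg <- small_config()
  ph <- generate_phantom(160, n_slices = 2, seed = 4, config = cfg,
                         grid_size = 192)
  g <- small_geometry(n_views = 64, detector_bins = 128)
  cb <- simulate_cbct(ph, g, physics_config(), seed = 9)
  expect_identical(dim(cb$values), c(220L, 220L, 2L))
  expect_identical(cb$spacing, ph$spacing)
  cb2 <- simulate_cbct(ph, g, physics_config(), seed = 9)
  expect_identical(cb$values, cb2$values)
  cb3 <- simulate_cbct(ph, g, physics_config(), seed = 10)
  expect_false(identical(cb$values, cb3$values))
})

test_that("physics-off simulation closes the loop within 50 HU in-body", {
  cfg <- small_config()
  ph <- generate_phantom(160, n_slices = 1, seed = 5, config = cfg,
                         grid_size = 192)
  g <- cbct_geometry(n_views = 300)   # fully inside the 208-mm FOV
  cb <- simulate_cbct(ph, g, physics_config(0, 1, 0), seed = 1,
                      extension_fraction = NULL)
  ct <- crop_volume_inplane(ph, 220)
  body <- ct$labels[, , 1] != phantom_label_table()[["air"]]
  mae <- mean(abs(cb$values[, , 1][body] - ct$values[, , 1][body]))
  expect_lt(mae, 50)
})

test_that("truncated body fraction matches the ellipse-circle overlap", {
  width <- 300
  ph <- generate_phantom(width, n_slices = 1, seed = 6, grid_size = 384)
  a <- width / 2; b <- 0.70 * a; rf <- 104
  # numeric ellipse-circle overlap on a fine independent grid
  xs <- seq(-a, a, length.out = 2001)
  inside_frac <- function(r) {
    ytop <- b * sqrt(pmax(0, 1 - (xs / a)^2))
    ycirc <- ifelse(abs(xs) <= r, sqrt(pmax(0, r^2 - xs^2)), 0)
    sum(pmin(ytop, ycirc)) / sum(ytop)
  }
  frac_out_expected <- 1 - inside_frac(rf)
  sl <- ph$labels[, , 1] != phantom_label_table()[["air"]]
  ci <- (nrow(sl) + 1) / 2
  xs2 <- ((1:nrow(sl)) - ci) * ph$spacing
  rr <- sqrt(outer(xs2^2, xs2^2, `+`))
  frac_out <- sum(sl & rr > rf) / sum(sl)
  expect_lt(abs(frac_out - frac_out_expected), 0.02)
})
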