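# Independent reference implementations used as oracles. These deliberately
# share no code with the package: straightforward loops and closed forms.

# brute-force fan-beam line integral: sample the ray at a fixed fine step
# with bilinear interpolation written from scratch
oracle_fan_project <- function(slice, spacing, betas, sdet, sid, step) {
  H <- nrow(slice); W <- ncol(slice)
  ci <- (H - 1) / 2; cj <- (W - 1) / 2
  interp_vec <- function(fi, fj) {
    ok <- fi >= 0 & fj >= 0 & fi <= H - 1 & fj <= W - 1
    fi <- pmin(pmax(fi, 0), H - 1); fj <- pmin(pmax(fj, 0), W - 1)
    i0 <- pmin(floor(fi), H - 2); j0 <- pmin(floor(fj), W - 2)
    a <- fi - i0; b <- fj - j0
    v <- (1 - a) * (1 - b) * slice[cbind(i0 + 1, j0 + 1)] +
      a * (1 - b) * slice[cbind(i0 + 2, j0 + 1)] +
      (1 - a) * b * slice[cbind(i0 + 1, j0 + 2)] +
      a * b * slice[cbind(i0 + 2, j0 + 2)]
    v[!ok] <- 0
    v
  }
  rad <- 0.5 * spacing * sqrt(H^2 + W^2) + spacing
  out <- matrix(0, length(betas), length(sdet))
  for (v in seq_along(betas)) {
    sx <- sid * cos(betas[v]); sy <- sid * sin(betas[v])
    ex <- -sin(betas[v]); ey <- cos(betas[v])
    for (b in seq_along(sdet)) {
      dx <- sdet[b] * ex - sx; dy <- sdet[b] * ey - sy
      len <- sqrt(dx^2 + dy^2); ux <- dx / len; uy <- dy / len
      pb <- sx * ux + sy * uy
      disc <- pb^2 - (sid^2 - rad^2)
      if (disc <= 0) next
      t0 <- -pb - sqrt(disc); t1 <- -pb + sqrt(disc)
      ns <- ceiling((t1 - t0) / step)
      dt <- (t1 - t0) / ns
      ts <- t0 + (seq_len(ns) - 0.5) * dt
      out[v, b] <- sum(interp_vec(ci + (sx + ts * ux) / spacing,
                                  cj + (sy + ts * uy) / spacing)) * dt
    }
  }
  out
}

# definitional SSIM: explicit sliding window with Gaussian weights, valid
# positions only
oracle_ssim <- function(ref, test, sigma = 1.5, size = 11L, K1 = 0.01,
                        K2 = 0.03, data_range = 1) {
  half <- (size - 1) / 2
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- outer(g, g); k <- k / sum(k)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  d <- dim(ref)
  vals <- c()
  for (i in (half + 1):(d[1] - half))
    for (j in (half + 1):(d[2] - half)) {
      wr <- ref[(i - half):(i + half), (j - half):(j + half)]
      wt <- test[(i - half):(i + half), (j - half):(j + half)]
      mu1 <- sum(k * wr); mu2 <- sum(k * wt)
      v1 <- sum(k * wr^2) - mu1^2
      v2 <- sum(k * wt^2) - mu2^2
      cv <- sum(k * wr * wt) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
                  ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
    }
  mean(vals)
}

oracle_psnr <- function(ref, test, peak = 1) {
  10 * log10(peak^2 / mean((ref - test)^2))
}

# tiny geometry for fast projector tests
small_geometry <- function(n_views = 24, detector_bins = 48)
  cbct_geometry(n_views = n_views, detector_pitch = 0.388 * 765 / detector_bins,
                detector_bins = detector_bins)

# centered disk of constant attenuation on an n x n grid
disk_slice <- function(n, radius_mm, mu, spacing = 1) {
  ci <- (n + 1) / 2
  xs <- ((1:n) - ci) * spacing
  m <- matrix(0, n, n)
  m[outer(xs^2, xs^2, `+`) <= radius_mm^2] <- mu
  m
}

# permissive tissue config for sub-FOV phantoms used in closed-loop tests
small_config <- function() tissue_config(width_range_mm = c(120, 400))

# toy slice-pair datasets for trainer tests: smooth blob label, input is the
# label under a multiplicative shading plus offset (a learnable correction)
toy_pair <- function(i, n = 32, seed = i) {
  s <- cbctshade:::with_seed(seed, {
    ci <- (n + 1) / 2
    xs <- ((1:n) - ci) / n
    r2 <- outer(xs^2, xs^2, `+`)
    lab <- 0.25 * exp(-r2 * runif(1, 4, 12)) +
      0.05 * matrix(runif(n * n), n, n)
    inp <- lab * 0.7 + 0.08 + 0.1 * exp(-r2 * 2)
    list(input = pmin(pmax(inp, 0), 1), label = pmin(pmax(lab, 0), 1))
  })
  structure(list(input = s$input, label = s$label, phantom = i, slice = 1L,
                 orig_size = n, spacing = 1, fov_diameter = 2 * n,
                 width_mm = NA_real_), class = "slice_pair")
}

toy_dataset <- function(n_train = 8, n_val = 2, n_test = 2, n = 32,
                        seed_off = 0) {
  ids <- seq_len(n_train + n_val + n_test) + seed_off
  ps <- lapply(ids, toy_pair, n = n)
  structure(list(train = ps[seq_len(n_train)],
                 val = ps[n_train + seq_len(n_val)],
                 test = ps[n_train + n_val + seq_len(n_test)],
                 split_ratios = c(0.6, 0.2, 0.2), split_seed = 1L,
                 split_level = "slice"), class = "dataset_split")
}
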