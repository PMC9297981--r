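#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` between a reference and a test image. By
#' convention the package computes image metrics on the normalized `[0, 1]`
#' representation with `peak = 1`.
#'
#' @param ref,test equal-shaped numeric arrays.
#' @param peak peak signal value (default 1).
#' @return PSNR in dB; `Inf` for identical inputs.
#' @export
psnr <- function(ref, test, peak = 1) {
  if (!identical(dim(ref), dim(test))) stop("shapes differ")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

gaussian_kernel2d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (SD 1.5), stabilizers
#' `K1 = 0.01`, `K2 = 0.03`, and unit data range. Local statistics are
#' Gaussian-weighted; the map is averaged over positions where the full
#' window fits (borders are cropped), so the result is independent of any
#' padding convention.
#'
#' @param ref,test equal-shaped numeric matrices.
#' @param sigma Gaussian window SD (default 1.5).
#' @param size window edge (default 11).
#' @param K1,K2 stabilizer constants.
#' @param data_range dynamic range of the data (default 1).
#' @return SSIM value in `[-1, 1]`; 1 for identical inputs.
#' @export
ssim <- function(ref, test, sigma = 1.5, size = 11L, K1 = 0.01, K2 = 0.03,
                 data_range = 1) {
  if (!identical(dim(ref), dim(test))) stop("shapes differ")
  if (min(dim(ref)) < size)
    stop(sprintf("images smaller than the %dx%d SSIM window", size, size))
  k <- gaussian_kernel2d(size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  f <- function(m) EBImage::filter2(m, k)
  mu1 <- f(ref); mu2 <- f(test)
  s11 <- f(ref * ref) - mu1^2
  s22 <- f(test * test) - mu2^2
  s12 <- f(ref * test) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  half <- (size - 1) / 2
  d <- dim(ref)
  valid <- smap[(half + 1):(d[1] - half), (half + 1):(d[2] - half)]
  mean(valid)
}

#' Inclusion mask excluding mismatching air
#'
#' A voxel is excluded when exactly one of the two aligned volumes is below
#' the air threshold there (e.g., a rectal gas pocket present in only one
#' scan); voxels that agree (both air, or both tissue) are included.
#'
#' @param ct,cbct aligned [cbct_volume]s or HU arrays.
#' @param air_threshold HU below which a voxel counts as air (default
#'   -300).
#' @return logical array, `TRUE` where the voxel is included.
#' @export
air_mismatch_mask <- function(ct, cbct, air_threshold = -300) {
  a <- if (inherits(ct, "cbct_volume")) ct$values else ct
  b <- if (inherits(cbct, "cbct_volume")) cbct$values else cbct
  if (!identical(dim(a), dim(b))) stop("volumes are not aligned")
  !xor(a < air_threshold, b < air_threshold)
}

#' Mean absolute HU difference over a mask
#'
#' @param ref,test aligned [cbct_volume]s or HU arrays.
#' @param mask optional logical array of included voxels (default: all).
#' @return mean absolute difference in HU.
#' @export
mae_hu <- function(ref, test, mask = NULL) {
  a <- if (inherits(ref, "cbct_volume")) ref$values else ref
  b <- if (inherits(test, "cbct_volume")) test$values else test
  if (!identical(dim(a), dim(b))) stop("volumes are not aligned")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(a))
  if (!any(mask)) stop("empty inclusion mask")
  mean(abs(a[mask] - b[mask]))
}

#' Extract cubic regions of interest inside one tissue
#'
#' Seeded placement of `n` non-overlapping axis-aligned cubes of edge
#' `edge` voxels lying entirely inside the requested tissue label.
#'
#' @param labels a label array or a labeled [cbct_volume].
#' @param tissue tissue name (resolved through the volume's label table, or
#'   [phantom_label_table()] for plain arrays).
#' @param n number of cubes.
#' @param edge cube edge in voxels (default 8).
#' @param seed placement seed.
#' @param label_table named code table when `labels` is a plain array.
#' @return a `roi_set`: list of `list(corner =, edge =, tissue =)`.
#' @export
extract_rois <- function(labels, tissue, n = 3L, edge = 8L, seed = 1L,
                         label_table = phantom_label_table()) {
  if (inherits(labels, "cbct_volume")) {
    label_table <- labels$label_table
    labels <- labels$labels
  }
  if (is.null(labels)) stop("no label map available")
  if (!tissue %in% names(label_table))
    stop(sprintf("unknown tissue '%s'", tissue))
  edge <- as.integer(edge)
  code <- label_table[[tissue]]
  d <- dim(labels)
  inside <- labels == code
  if (!any(inside))
    stop(sprintf("tissue '%s' not present in the label map", tissue))
  idx <- which(inside, arr.ind = TRUE)
  # candidate corners: voxels whose full cube stays in bounds
  ok <- idx[, 1] <= d[1] - edge + 1 & idx[, 2] <= d[2] - edge + 1 &
    idx[, 3] <= d[3] - edge + 1
  idx <- idx[ok, , drop = FALSE]
  rois <- list()
  with_seed(seed, {
    order <- sample.int(nrow(idx))
    taken <- matrix(numeric(0), ncol = 3)
    for (r in order) {
      if (length(rois) >= n) break
      corner <- idx[r, ]
      cube <- labels[corner[1]:(corner[1] + edge - 1),
                     corner[2]:(corner[2] + edge - 1),
                     corner[3]:(corner[3] + edge - 1)]
      if (!all(cube == code)) next
      if (nrow(taken) > 0 &&
          any(apply(taken, 1, function(tc) all(abs(tc - corner) < edge))))
        next
      rois[[length(rois) + 1L]] <- list(corner = unname(corner),
                                        edge = edge, tissue = tissue)
      taken <- rbind(taken, corner)
    }
  })
  if (length(rois) == 0L)
    stop(sprintf("tissue '%s' region too small for any %dx%dx%d cube",
                 tissue, edge, edge, edge))
  structure(rois, class = "roi_set")
}

roi_values <- function(vol, roi) {
  a <- if (inherits(vol, "cbct_volume")) vol$values else vol
  co <- roi$corner; e <- roi$edge
  a[co[1]:(co[1] + e - 1), co[2]:(co[2] + e - 1), co[3]:(co[3] + e - 1)]
}

#' Per-ROI HU comparison between two aligned volumes
#'
#' Averages HU inside every cube in both volumes and reports the absolute
#' difference of the means, plus a per-tissue aggregate (mean and SD across
#' cubes).
#'
#' @param ct,cbct aligned [cbct_volume]s or HU arrays.
#' @param rois a `roi_set` (or list of them, concatenated).
#' @return list with `per_roi` and `per_tissue` data.frames.
#' @export
roi_hu_difference <- function(ct, cbct, rois) {
  if (inherits(rois, "roi_set")) rois <- list(rois)
  all_rois <- do.call(c, lapply(rois, unclass))
  if (length(all_rois) == 0L) stop("empty ROI set")
  per <- do.call(rbind, lapply(all_rois, function(r) data.frame(
    tissue = r$tissue,
    mean_ct = mean(roi_values(ct, r)),
    mean_cbct = mean(roi_values(cbct, r)))))
  per$abs_diff <- abs(per$mean_ct - per$mean_cbct)
  agg <- do.call(rbind, lapply(split(per, per$tissue), function(g)
    data.frame(tissue = g$tissue[1], n = nrow(g),
               mean_diff = mean(g$abs_diff),
               sd_diff = if (nrow(g) > 1) sd(g$abs_diff) else NA_real_)))
  rownames(agg) <- NULL
  list(per_roi = per, per_tissue = agg)
}

#' Contrast-to-noise ratio between two regions
#'
#' Signed CNR `(mean_fg - mean_bg) / SD` with the pooled SD
#' `sqrt((var_fg + var_bg) / 2)` by default, or the background-only SD.
#'
#' @param image a [cbct_volume] or HU array.
#' @param fg,bg single ROI entries (from a `roi_set`).
#' @param method `"pooled"` (default) or `"background"`.
#' @return signed CNR value.
#' @export
cnr <- function(image, fg, bg, method = c("pooled", "background")) {
  method <- match.arg(method)
  vf <- roi_values(image, fg)
  vb <- roi_values(image, bg)
  s <- switch(method,
              pooled = sqrt((var(as.vector(vf)) + var(as.vector(vb))) / 2),
              background = sd(as.vector(vb)))
  if (!is.finite(s) || s == 0) stop("zero spread: CNR undefined")
  (mean(vf) - mean(vb)) / s
}

#' Cupping depth of a reconstructed slice
#'
#' Center-minus-periphery mean HU inside uniform tissue: the mean over a
#' central disk minus the mean over a mid-radius annulus (chosen inside the
#' FOV, away from the truncation-dominated rim). Negative values indicate
#' cupping; scatter deepens it.
#'
#' @param slice 2D HU matrix centered on the isocenter.
#' @param spacing pixel size in mm.
#' @param r_center central disk radius in mm (default 20).
#' @param r_annulus annulus radii in mm (default `c(40, 70)`).
#' @param mask optional logical matrix restricting both regions (e.g., one
#'   tissue).
#' @return center minus periphery mean HU.
#' @export
cupping_depth <- function(slice, spacing = 1, r_center = 20,
                          r_annulus = c(40, 70), mask = NULL) {
  d <- dim(slice)
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  xs <- ((1:d[1]) - ci) * spacing
  ys <- ((1:d[2]) - cj) * spacing
  r <- sqrt(outer(xs^2, ys^2, `+`))
  cen <- r <= r_center
  ann <- r > r_annulus[1] & r <= r_annulus[2]
  if (!is.null(mask)) { cen <- cen & mask; ann <- ann & mask }
  mean(slice[cen]) - mean(slice[ann])
}

#' Evaluate one slice pair under a model (or as-is)
#'
#' Applies the shading correction of `net` to the pair's input slice (pass
#' `net = NULL` for the unprocessed Base input), crops back to the original
#' reconstruction grid, and computes PSNR and SSIM on the normalized scale
#' plus MAE in HU.
#'
#' @param pair a `slice_pair` from [build_dataset()].
#' @param net a trained `unet`, or `NULL` for the Base input.
#' @return named numeric vector `psnr`, `ssim`, `mae_hu`.
#' @export
slice_pair_metrics <- function(pair, net = NULL) {
  pred <- if (is.null(net)) pair$input
          else correct_slice(net, pair$input,
                             fov_diameter = pair$fov_diameter %||% 208,
                             spacing = pair$spacing %||% 1)
  os <- pair$orig_size %||% nrow(pair$input)
  p <- crop_slice(pred, os)
  l <- crop_slice(pair$label, os)
  c(psnr = psnr(l, p), ssim = ssim(l, p),
    mae_hu = mean(abs(denormalize_hu(p) - denormalize_hu(l))))
}

#' Pelvis width versus MAE table
#'
#' Collects `(width, MAE)` rows per model tag from a cross-validation
#' report and computes, per tag, the Spearman rank correlation between
#' phantom width and MAE (wider pelves are truncated more severely, so the
#' unprocessed Base error is expected to grow with width).
#'
#' @param reports data.frame with columns `tag`, `width_mm`,
#'   `mae_median_hu` (e.g. from [run_loocv()]).
#' @return list with `rows` (width/MAE per tag) and `correlation`
#'   (per-tag Spearman rho).
#' @export
width_vs_mae <- function(reports) {
  need <- c("tag", "width_mm", "mae_median_hu")
  if (!all(need %in% names(reports)))
    stop("reports must have tag, width_mm, mae_median_hu columns")
  rows <- reports[, need]
  cors <- do.call(rbind, lapply(split(rows, rows$tag), function(g)
    data.frame(tag = g$tag[1],
               spearman_rho = if (nrow(g) >= 3 && sd(g$width_mm) > 0)
                 cor(g$width_mm, g$mae_median_hu, method = "spearman")
               else NA_real_)))
  rownames(cors) <- NULL
  list(rows = rows, correlation = cors)
}
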