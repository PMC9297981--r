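#' Mask a CT volume to a circular field of view
#'
#' Sets voxels whose in-plane radius from the volume center exceeds
#' `fov_diameter / 2` to -1000 HU, mimicking the reconstructible FOV of the
#' paired CBCT. Idempotent.
#'
#' @param ct a [cbct_volume].
#' @param fov_diameter FOV diameter in mm (default 208).
#' @return the masked [cbct_volume].
#' @export
apply_fov_mask <- function(ct, fov_diameter = 208) {
  stopifnot_scalar_num(fov_diameter, "fov_diameter", positive = TRUE)
  d <- dim(ct$values)
  ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
  xs <- ((1:d[1]) - ci) * ct$spacing
  ys <- ((1:d[2]) - cj) * ct$spacing
  outside <- outer(xs^2, ys^2, `+`) > (fov_diameter / 2)^2
  out <- ct
  for (z in seq_len(d[3])) {
    sl <- out$values[, , z]
    sl[outside] <- -1000
    out$values[, , z] <- sl
  }
  out
}

#' Trilinear resampling to an isotropic grid
#'
#' Resamples the volume onto an isotropic grid of the requested spacing,
#' preserving the world-coordinate extent (the volume center is the fixed
#' point). Values outside the source grid are treated as air (-1000 HU).
#'
#' @param v a [cbct_volume] (isotropic input; anisotropic input is handled
#'   by passing a length-3 `in_spacing`).
#' @param spacing target isotropic spacing in mm.
#' @param in_spacing optional length-3 per-axis input spacing overriding
#'   `v$spacing`.
#' @return a resampled [cbct_volume] (labels are dropped).
#' @export
resample_isotropic <- function(v, spacing = 1, in_spacing = NULL) {
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  sp_in <- if (is.null(in_spacing)) rep(v$spacing, 3) else in_spacing
  if (any(sp_in <= 0)) stop("input spacing must be > 0")
  d <- dim(v$values)
  if (all(sp_in == spacing)) return(v)
  d_out <- pmax(1L, as.integer(round(d * sp_in / spacing)))
  # world coordinate of output voxel centers, volume center as fixed point
  coord <- function(n_out, n_in, sp_out, sp_in_ax) {
    w <- ((1:n_out) - (n_out + 1) / 2) * sp_out     # world, mm
    w / sp_in_ax + (n_in + 1) / 2                   # fractional input index
  }
  fx <- coord(d_out[1], d[1], spacing, sp_in[1])
  fy <- coord(d_out[2], d[2], spacing, sp_in[2])
  fz <- coord(d_out[3], d[3], spacing, sp_in[3])
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  ix0 <- clamp(floor(fx), d[1]); ax <- clamp(fx, d[1]) - ix0
  iy0 <- clamp(floor(fy), d[2]); ay <- clamp(fy, d[2]) - iy0
  iz0 <- clamp(floor(fz), d[3]); az <- clamp(fz, d[3]) - iz0
  ix1 <- clamp(ix0 + 1, d[1]); iy1 <- clamp(iy0 + 1, d[2])
  iz1 <- clamp(iz0 + 1, d[3])
  out <- array(-1000, dim = d_out)
  vals <- v$values
  for (k in seq_len(d_out[3])) {
    w0 <- 1 - az[k]; w1 <- az[k]
    sl0a <- vals[ix0, iy0, iz0[k]] * w0 + vals[ix0, iy0, iz1[k]] * w1
    sl1a <- vals[ix1, iy0, iz0[k]] * w0 + vals[ix1, iy0, iz1[k]] * w1
    sl0b <- vals[ix0, iy1, iz0[k]] * w0 + vals[ix0, iy1, iz1[k]] * w1
    sl1b <- vals[ix1, iy1, iz0[k]] * w0 + vals[ix1, iy1, iz1[k]] * w1
    A <- sl0a * (1 - ax) + sl1a * ax
    B <- sl0b * (1 - ax) + sl1b * ax
    out[, , k] <- A * matrix(1 - ay, d_out[1], d_out[2], byrow = TRUE) +
      B * matrix(ay, d_out[1], d_out[2], byrow = TRUE)
  }
  cbct_volume(out, spacing = spacing)
}

#' Normalize HU to the unit interval
#'
#' Clips to `[-1000, 3100]` and maps linearly to `[0, 1]`.
#'
#' @param v a [cbct_volume], array, or matrix of HU values.
#' @return object of the same shape on the `[0, 1]` scale.
#' @export
normalize_hu <- function(v) {
  f <- function(x) (pmin(pmax(x, -1000), 3100) + 1000) / 4100
  if (inherits(v, "cbct_volume")) { v$values <- f(v$values); v } else f(v)
}

#' Map normalized values back to HU
#'
#' Inverse of [normalize_hu()]: `HU = 4100 * x - 1000`. Out-of-range input
#' is clipped to `[0, 1]` with a warning.
#'
#' @param x normalized values (volume, array, or matrix) in `[0, 1]`.
#' @return same shape in HU.
#' @export
denormalize_hu <- function(x) {
  f <- function(u) {
    if (any(u < 0 | u > 1)) {
      warning("values outside [0, 1] clipped before denormalization")
      u <- pmin(pmax(u, 0), 1)
    }
    4100 * u - 1000
  }
  if (inherits(x, "cbct_volume")) { x$values <- f(x$values); x } else f(x)
}

#' Zero-pad a slice to a square grid
#'
#' Centers the input in a `size x size` grid filled with 0 (normalized air).
#'
#' @param s 2D matrix (normalized scale).
#' @param size target edge, >= both input dimensions (default 256).
#' @return `size x size` matrix.
#' @export
pad_slice <- function(s, size = 256) {
  d <- dim(s)
  if (size < max(d)) stop("'size' smaller than the input slice")
  out <- matrix(0, size, size)
  oi <- (size - d[1]) %/% 2
  oj <- (size - d[2]) %/% 2
  out[oi + seq_len(d[1]), oj + seq_len(d[2])] <- s
  out
}

#' Center-crop a padded slice back to its original size
#'
#' Exact inverse of [pad_slice()].
#'
#' @param s padded square matrix.
#' @param size original edge length.
#' @return `size x size` matrix.
#' @export
crop_slice <- function(s, size) {
  d <- dim(s)
  if (size > min(d)) stop("'size' larger than the input slice")
  oi <- (d[1] - size) %/% 2
  oj <- (d[2] - size) %/% 2
  s[oi + seq_len(size), oj + seq_len(size)]
}

#' Assemble normalized slice pairs and split them
#'
#' For each (CBCT, CT) volume pair: masks the CT to the CBCT field of view,
#' normalizes both to `[0, 1]`, zero-pads every axial slice to
#' `pad_size x pad_size`, and collects input/label slice pairs. The pairs
#' are then partitioned into train/validation/test sets with a seeded
#' shuffle, either at `volume` level (all slices of a phantom stay
#' together; default, avoids leakage between adjacent slices) or at
#' `slice` level.
#'
#' @param pairs list of `list(cbct = , ct = )` of aligned [cbct_volume]s.
#' @param ratios length-3 positive ratios summing to 1 (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param seed shuffle seed.
#' @param split_level `"volume"` or `"slice"`.
#' @param fov_diameter FOV diameter passed to [apply_fov_mask()].
#' @param pad_size padded slice edge (default 256).
#' @return a `dataset_split`: `list(train, val, test)`, each a list of
#'   `slice_pair`s (`input`, `label` 2D matrices in `[0, 1]` plus
#'   `phantom`, `slice`, `width_mm` provenance).
#' @export
build_dataset <- function(pairs, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          split_level = c("volume", "slice"),
                          fov_diameter = 208, pad_size = 256) {
  split_level <- match.arg(split_level)
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("'ratios' must be three non-negative numbers summing to 1")
  all_pairs <- list()
  for (i in seq_along(pairs)) {
    cb <- pairs[[i]]$cbct; ct <- pairs[[i]]$ct
    if (!identical(dim(cb$values), dim(ct$values)))
      stop(sprintf("pair %d: CBCT and CT shapes differ", i))
    ctm <- normalize_hu(apply_fov_mask(ct, fov_diameter))
    cbn <- normalize_hu(cb)
    for (z in seq_len(dim(cb$values)[3])) {
      all_pairs[[length(all_pairs) + 1L]] <- structure(list(
        input = pad_slice(cbn$values[, , z], pad_size),
        label = pad_slice(ctm$values[, , z], pad_size),
        phantom = i, slice = z,
        orig_size = dim(cb$values)[1],
        spacing = cb$spacing,
        fov_diameter = fov_diameter,
        width_mm = attr(cb, "width_mm") %||% NA_real_),
        class = "slice_pair")
    }
  }
  n <- length(all_pairs)
  if (n == 0L) stop("no slices to split")
  take <- function(ids) all_pairs[ids]
  if (split_level == "slice") {
    idx <- with_seed(seed, sample.int(n))
    n_tr <- round(ratios[1] * n)
    n_va <- round(ratios[2] * n)
    sel <- list(train = idx[seq_len(n_tr)],
                val = idx[n_tr + seq_len(n_va)],
                test = idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  } else {
    vols <- vapply(all_pairs, function(p) p$phantom, integer(1))
    uv <- unique(vols)
    ord <- with_seed(seed, sample(uv))
    n_tr <- max(1L, round(ratios[1] * length(uv)))
    n_va <- max(0L, round(ratios[2] * length(uv)))
    n_va <- min(n_va, length(uv) - n_tr)
    g_tr <- ord[seq_len(n_tr)]
    g_va <- if (n_va > 0) ord[n_tr + seq_len(n_va)] else integer(0)
    g_te <- setdiff(ord, c(g_tr, g_va))
    sel <- list(train = which(vols %in% g_tr),
                val = which(vols %in% g_va),
                test = which(vols %in% g_te))
  }
  structure(list(train = take(sel$train), val = take(sel$val),
                 test = take(sel$test), split_ratios = ratios,
                 split_seed = seed, split_level = split_level),
            class = "dataset_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d/%d/%d train/val/test slice pairs (%s-level split)\n",
              length(x$train), length(x$val), length(x$test), x$split_level))
  invisible(x)
}
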