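#' Convert HU to linear-attenuation-like units
#'
#' Maps Hounsfield units to the attenuation scale used by the projector,
#' `mu = (HU + 1000) / 2^16` per mm, clipping below -1000 HU so attenuation
#' is never negative. Air maps to exactly 0.
#'
#' @param ct a [cbct_volume] in HU, or a plain numeric array/matrix.
#' @return object of the same shape in attenuation units (per mm).
#' @export
hu_to_attenuation <- function(ct) {
  if (inherits(ct, "cbct_volume")) {
    out <- ct
    out$values <- (pmax(ct$values, -1000) + 1000) / 65536
    class(out) <- c("attenuation_volume", "cbct_volume")
    return(out)
  }
  (pmax(ct, -1000) + 1000) / 65536
}

#' Convert attenuation back to HU
#' @param mu attenuation array (per mm).
#' @return HU array (inverse of [hu_to_attenuation()]).
#' @export
attenuation_to_hu <- function(mu) mu * 65536 - 1000

new_sinogram <- function(values, geometry) {
  structure(list(values = values, geometry = geometry,
                 view_angles = geometry$view_angles_deg,
                 ext_left = NULL, ext_right = NULL),
            class = "cbct_sinogram")
}

#' @export
print.cbct_sinogram <- function(x, ...) {
  cat(sprintf("<cbct_sinogram> %d views x %d bins, range [%.3g, %.3g]%s\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              if (is.null(x$ext_left)) "" else ", with truncation extension"))
  invisible(x)
}

#' Fan-beam forward projection of an attenuation slice
#'
#' Computes post-log line integrals along every (view, detector bin) ray by
#' sampling the slice with bilinear interpolation at a fixed step. Rays that
#' miss the collimated detector are simply absent, so an object wider than
#' the field of view produces laterally truncated projections.
#'
#' @param slice 2D matrix of attenuation (per mm); the isocenter is at the
#'   grid center.
#' @param geometry a [cbct_geometry()].
#' @param spacing pixel size of `slice` in mm.
#' @param step ray sampling step in mm (default `spacing / 2`).
#' @return a `cbct_sinogram` (`n_views` x `detector_bins`).
#' @export
forward_project <- function(slice, geometry, spacing = 1,
                            step = spacing / 2) {
  if (!is.matrix(slice)) stop("'slice' must be a matrix")
  half_extent <- spacing * max(dim(slice)) / 2 * sqrt(2)
  if (geometry$source_to_isocenter <= half_extent)
    stop("degenerate geometry: source lies inside the object grid")
  sino <- cpp_fan_project(slice, spacing,
                          geometry$view_angles_deg * pi / 180,
                          geometry$sdet, geometry$source_to_isocenter, step)
  new_sinogram(sino, geometry)
}

# Gaussian-weighted convolution of each sinogram row. With normalize = TRUE
# this is plain smoothing; with normalize = FALSE the kernel integrates the
# row (per mm of detector), so the result scales with how much transmitted
# intensity surrounds a bin -- the form used by the scatter term.
gauss_smooth_rows <- function(m, sigma_bins, normalize = TRUE,
                              bin_width = 1) {
  if (sigma_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- exp(-0.5 * ((-half:half) / sigma_bins)^2)
  k <- if (normalize) k / sum(k) else k * bin_width
  nb <- ncol(m)
  # replicate-pad columns, then FFT convolution row by row
  padded <- cbind(m[, rep(1L, half), drop = FALSE], m,
                  m[, rep(nb, half), drop = FALSE])
  t(apply(padded, 1L, function(r)
    stats::convolve(r, rev(k), type = "open")[(2 * half + 1):(2 * half + nb)]))
}

#' Apply scatter, beam hardening, and noise to projections
#'
#' Works in intensity space `I = I0 exp(-p)` with `I0 = 1`: beam hardening
#' compresses the post-log attenuation (`p -> p^(1/f_bh)`, fixed point at
#' `p = 1`), scatter adds a low-frequency term
#' `f_sc * G(I)` (`G` a wide Gaussian-weighted integral of the transmitted
#' intensity along the detector row, per mm of detector), and
#' Gaussian noise of SD `f_n * I0` is added to the intensity. Intensities
#' are clipped at a small positive floor before the final log transform.
#' The identity configuration `(0, 1, 0)` returns the input bit-identically.
#'
#' @param sino a `cbct_sinogram`.
#' @param physics a [physics_config()].
#' @param seed integer seed for the noise draw.
#' @return a corrupted `cbct_sinogram`.
#' @export
apply_physics <- function(sino, physics, seed = 1L) {
  p <- sino$values
  identity_cfg <- physics$scatter_factor == 0 &&
    physics$beam_hardening_factor == 1 && physics$noise_factor == 0
  if (identity_cfg) return(sino)
  if (physics$beam_hardening_factor > 1)
    p <- p^(1 / physics$beam_hardening_factor)
  I <- exp(-p)
  if (physics$scatter_factor > 0) {
    # additive scatter: a wide Gaussian-weighted integral (per mm of
    # detector) of the transmitted intensity, scaled by scatter_factor --
    # bins surrounded by bright transmission collect more scatter
    sigma_bins <- physics$scatter_kernel_width / sino$geometry$pitch_iso
    I <- I + physics$scatter_factor *
      gauss_smooth_rows(I, sigma_bins, normalize = FALSE,
                        bin_width = sino$geometry$pitch_iso)
  }
  if (physics$noise_factor > 0)
    I <- I + with_seed(seed, array(rnorm(length(I), 0, physics$noise_factor),
                                   dim = dim(I)))
  I <- pmax(I, physics$intensity_floor)
  out <- sino
  out$values <- -log(I)
  out
}

#' Truncation correction by mirrored cosine extrapolation
#'
#' Rows whose edge value exceeds `threshold` (i.e., the object extends past
#' the detector) are extended on the truncated side(s) by
#' `extension_fraction` of the active detector width: the row is mirrored
#' about its edge and weighted by a cosine rolloff that starts at the edge
#' value and reaches zero at the extension end. The extension is stored as
#' metadata and used only during ramp filtering; the returned sinogram keeps
#' its original bin support.
#'
#' @param sino a `cbct_sinogram`.
#' @param extension_fraction fraction of the active detector width used for
#'   each extension (default 0.30); must be > 0.
#' @param threshold attenuation below which an edge counts as untruncated.
#' @return the sinogram with `ext_left` / `ext_right` matrices attached
#'   (`n_views` x `n_ext`; column 1 adjacent to the detector edge).
#' @export
ohnesorge_correct <- function(sino, extension_fraction = 0.30,
                              threshold = 0.01) {
  if (extension_fraction <= 0) stop("'extension_fraction' must be > 0")
  p <- sino$values
  nb <- ncol(p)
  ne <- max(1L, round(extension_fraction * nb))
  w <- cos(pi * (1:ne) / (2 * ne))
  # reflect about the edge bin (the edge itself is the first mirrored
  # sample), so the extension starts within a cosine factor of the edge
  mirror <- pmin(1:ne, nb)
  extl <- matrix(0, nrow(p), ne)
  extr <- matrix(0, nrow(p), ne)
  lt <- p[, 1L] > threshold
  rt <- p[, nb] > threshold
  if (any(lt))
    extl[lt, ] <- p[lt, mirror, drop = FALSE] *
      matrix(w, sum(lt), ne, byrow = TRUE)
  if (any(rt))
    extr[rt, ] <- p[rt, nb + 1L - mirror, drop = FALSE] *
      matrix(w, sum(rt), ne, byrow = TRUE)
  out <- sino
  out$ext_left <- extl
  out$ext_right <- extr
  out$extension_fraction <- extension_fraction
  out
}

# Smooth taper used to build pairwise-normalized short-scan redundancy
# weights: sin^2 ramps of width tau at both ends of the arc.
shortscan_taper <- function(beta, arc, tau) {
  f <- rep(1, length(beta))
  lo <- beta < tau
  hi <- beta > arc - tau
  f[lo] <- sin(pi / 2 * beta[lo] / tau)^2
  f[hi] <- sin(pi / 2 * (arc - beta[hi]) / tau)^2
  f[beta < 0 | beta > arc] <- 0
  f
}

#' Short-scan redundancy weights
#'
#' Over-scan generalization of Parker weighting: each ray `(beta, gamma)`
#' acquired twice in the arc (its conjugate lies at `beta + pi + 2 gamma`)
#' receives a weight `f / (f + f_conjugate)` built from a smooth sin^2 taper,
#' so conjugate weights sum to exactly 1 and singly-measured rays get 1.
#'
#' @param geometry a [cbct_geometry()].
#' @param betas optional vector of view angles in radians overriding the
#'   geometry's views (used to evaluate weights at conjugate rays).
#' @return `length(betas)` x `detector_bins` weight matrix.
#' @export
shortscan_weights <- function(geometry, betas = NULL) {
  arc <- geometry$arc_degrees * pi / 180
  gamma <- atan(geometry$sdet / geometry$source_to_isocenter)
  if (is.null(betas)) betas <- geometry$view_angles_deg * pi / 180
  tau <- arc - pi - 2 * max(abs(gamma))    # overscan angle
  tau <- max(tau, 1e-3)
  W <- matrix(0, length(betas), length(gamma))
  f <- shortscan_taper(betas, arc, tau)
  for (j in seq_along(gamma)) {
    # with the detector axis oriented along (-sin b, cos b) and the source at
    # angle b, the conjugate of (beta, gamma) is (beta + pi - 2 gamma, -gamma);
    # inside the arc it appears there or at that minus 2 pi
    fc <- shortscan_taper(betas + pi - 2 * gamma[j], arc, tau) +
      shortscan_taper(betas - pi - 2 * gamma[j], arc, tau)
    W[, j] <- ifelse(f + fc > 0, f / (f + fc), 0)
  }
  W
}

ramlak_kernel <- function(n, ds) {
  idx <- -(n - 1):(n - 1)
  h <- numeric(length(idx))
  h[idx == 0] <- 1 / (4 * ds^2)
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi^2 * idx[odd]^2 * ds^2)
  h
}

filter_rows_ramp <- function(p, ds, apodize = TRUE) {
  nb <- ncol(p)
  h <- ramlak_kernel(nb, ds)
  L <- 2^ceiling(log2(length(h) + nb))
  hpad <- c(h, rep(0, L - length(h)))
  Hf <- fft(hpad)
  if (apodize) {
    # cosine apodization of the ramp in the frequency domain
    fr <- seq(0, L - 1) / L
    fr <- pmin(fr, 1 - fr) * 2        # 0..1, symmetric
    Hf <- Hf * cos(pi / 2 * fr)
  }
  out <- matrix(0, nrow(p), nb)
  for (i in seq_len(nrow(p))) {
    xp <- c(p[i, ], rep(0, L - nb))
    conv <- Re(fft(fft(xp) * Hf, inverse = TRUE)) / L
    out[i, ] <- conv[nb:(2 * nb - 1)] * ds
  }
  out
}

#' Short-scan fan-beam filtered backprojection
#'
#' Cosine pre-weighting, over-scan redundancy weighting, Ram-Lak ramp
#' filtering per row (cosine-apodized by default), and distance-weighted
#' backprojection onto a square grid centered at the isocenter. When the
#' sinogram carries a truncation extension (see [ohnesorge_correct()]), the
#' extension participates in the filtering only. The output is converted to
#' HU; pixels outside the field-of-view circle are set to -1000.
#'
#' @param sino a `cbct_sinogram` of attenuation line integrals.
#' @param geometry a [cbct_geometry()]; defaults to the sinogram's own.
#' @param out_n output grid edge in pixels (default 220).
#' @param out_spacing output pixel size in mm (default 1).
#' @param apodize cosine-apodize the ramp filter (default TRUE).
#' @return `out_n` x `out_n` HU matrix.
#' @export
reconstruct_fbp <- function(sino, geometry = sino$geometry, out_n = 220,
                            out_spacing = 1, apodize = TRUE) {
  p <- sino$values
  sdet <- geometry$sdet
  ds <- geometry$pitch_iso
  sid <- geometry$source_to_isocenter
  nb <- length(sdet)
  # attach truncation extension for filtering
  if (!is.null(sino$ext_left)) {
    ne <- ncol(sino$ext_left)
    p <- cbind(sino$ext_left[, ne:1, drop = FALSE], p, sino$ext_right)
    sdet_f <- c(sdet[1] - ds * (ne:1), sdet, sdet[nb] + ds * (1:ne))
  } else {
    sdet_f <- sdet
  }
  cosw <- sid / sqrt(sid^2 + sdet_f^2)
  pw <- sweep(p, 2L, cosw, `*`)
  # redundancy weights on the physical bins; extension bins reuse edge weight
  W <- shortscan_weights(geometry)
  if (ncol(pw) > nb) {
    ne <- (ncol(pw) - nb) / 2
    W <- cbind(W[, rep(1L, ne), drop = FALSE], W,
               W[, rep(nb, ne), drop = FALSE])
  }
  pw <- pw * W
  q <- filter_rows_ramp(pw, ds, apodize = apodize)
  # drop the extension after filtering
  if (ncol(q) > nb) {
    ne <- (ncol(q) - nb) / 2
    q <- q[, (ne + 1):(ne + nb), drop = FALSE]
  }
  dbeta <- geometry$arc_degrees * pi / 180 / geometry$n_views
  mu <- cpp_fan_backproject(q, geometry$view_angles_deg * pi / 180, sdet,
                            sid, out_n, out_n, out_spacing, dbeta)
  hu <- attenuation_to_hu(mu)
  ci <- (out_n + 1) / 2
  xs <- ((1:out_n) - ci) * out_spacing
  r2 <- outer(xs^2, xs^2, `+`)
  hu[r2 > (geometry$fov_mm / 2)^2] <- -1000
  hu
}

#' Simulate a narrow-FOV CBCT volume from a CT-like volume
#'
#' Per axial slice: HU to attenuation, fan-beam forward projection under the
#' acquisition geometry, projection-domain physics (scatter, beam hardening,
#' noise), truncation handling by mirrored cosine extrapolation, and
#' short-scan filtered backprojection onto the output grid. The result is
#' intrinsically voxel-aligned with the input CT (both grids share the
#' isocenter at their centers).
#'
#' @param ct a [cbct_volume] with isotropic spacing.
#' @param geometry a [cbct_geometry()].
#' @param physics a [physics_config()].
#' @param seed master seed; per-slice noise seeds are derived from it.
#' @param out_n output in-plane grid edge (default 220).
#' @param extension_fraction truncation-correction extension fraction;
#'   `NULL` disables the correction.
#' @param step ray sampling step in mm.
#' @param apodize cosine-apodize the ramp filter.
#' @return a [cbct_volume] of simulated CBCT HU values (labels, when present
#'   on the input, are center-cropped onto the output grid).
#' @export
simulate_cbct <- function(ct, geometry = cbct_geometry(),
                          physics = physics_config(), seed = 1L,
                          out_n = 220, extension_fraction = 0.30,
                          step = ct$spacing / 2, apodize = TRUE) {
  nz <- dim(ct$values)[3]
  seeds <- derive_seeds(seed, nz)
  mu <- hu_to_attenuation(ct)
  out <- array(-1000, dim = c(out_n, out_n, nz))
  for (z in seq_len(nz)) {
    sino <- forward_project(mu$values[, , z], geometry, spacing = ct$spacing,
                            step = step)
    sino <- apply_physics(sino, physics, seed = seeds[z])
    if (!is.null(extension_fraction))
      sino <- ohnesorge_correct(sino, extension_fraction)
    out[, , z] <- reconstruct_fbp(sino, geometry, out_n = out_n,
                                  out_spacing = ct$spacing, apodize = apodize)
  }
  labs <- NULL
  if (!is.null(ct$labels)) {
    labs <- crop_center_inplane(ct$labels, out_n)
  }
  v <- cbct_volume(out, spacing = ct$spacing, labels = labs,
                   label_table = ct$label_table)
  attr(v, "width_mm") <- attr(ct, "width_mm")
  v
}

# center crop (or zero/air pad) of the first two array dims to n x n
crop_center_inplane <- function(a, n, fill = 0L) {
  d <- dim(a)
  out <- array(fill, dim = c(n, n, d[3]))
  src <- function(full) {
    o <- max(0L, (full - n) %/% 2L)
    seq_len(min(n, full)) + o
  }
  dst <- function(full) {
    o <- max(0L, (n - full) %/% 2L)
    seq_len(min(n, full)) + o
  }
  out[dst(d[1]), dst(d[2]), ] <- a[src(d[1]), src(d[2]), ]
  out
}

#' Center-crop a volume in-plane
#'
#' Crops (or air-pads) the axial grid to `n x n` around the volume center,
#' e.g. to put a wide CT on the CBCT output grid for voxelwise comparison.
#'
#' @param v a [cbct_volume].
#' @param n target in-plane edge in voxels.
#' @return a [cbct_volume].
#' @export
crop_volume_inplane <- function(v, n) {
  vals <- crop_center_inplane(v$values, n, fill = -1000)
  labs <- if (!is.null(v$labels)) crop_center_inplane(v$labels, n) else NULL
  out <- cbct_volume(vals, spacing = v$spacing, labels = labs,
                     label_table = v$label_table)
  attr(out, "width_mm") <- attr(v, "width_mm")
  out
}
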